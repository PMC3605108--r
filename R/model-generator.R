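# Random pure, strict epistatic model generation: random parameters plus a
# random direction give a pre-penetrance table; affine rescaling hits the
# requested heritability and (optionally) prevalence.

#' Bundle of model-generation constraints
#'
#' @param n Number of interacting loci (>= 2).
#' @param mafs Minor allele frequencies, length `n`, each in (0, 0.5].
#' @param heritability Target broad-sense heritability in (0, 1].
#' @param prevalence Optional target population prevalence in (0, 1). When
#'   omitted, prevalence is left free and the value emerging from
#'   normalization is reported with the model.
#' @param attempt_limit Maximum generation attempts per model (default
#'   100000).
#' @param method Parameter-selection method: `"auto"` (Sudoku for n <= 5,
#'   Point for n >= 6), `"sudoku"` or `"point"`.
#' @return An object of class `model_constraints`.
#' @export
model_constraints <- function(n, mafs, heritability, prevalence = NULL,
                              attempt_limit = 100000L,
                              method = c("auto", "sudoku", "point")) {
  method <- match.arg(method)
  stopifnot(n >= 2, length(mafs) == n,
            is.numeric(heritability), length(heritability) == 1L,
            heritability > 0, heritability <= 1,
            attempt_limit >= 1)
  for (q in mafs) hwe_genotype_freqs(q)  # validates range
  if (!is.null(prevalence)) {
    stopifnot(is.numeric(prevalence), length(prevalence) == 1L,
              prevalence > 0, prevalence < 1)
  }
  structure(list(n = as.integer(n), mafs = as.numeric(mafs),
                 heritability = heritability, prevalence = prevalence,
                 attempt_limit = as.integer(attempt_limit), method = method),
            class = "model_constraints")
}

#' Random direction in parameter space
#'
#' Draws a uniformly distributed unit vector in `R^dim` by normalizing a
#' vector of independent standard normal deviates (G. W. Brown's method);
#' the rotation invariance of the multivariate normal makes the direction
#' uniform on the sphere.
#'
#' @param dim Dimension (the number of parameter cells, `2^n`).
#' @return Numeric unit vector of length `dim`.
#' @export
random_unit_vector <- function(dim) {
  repeat {
    v <- stats::rnorm(dim)
    nrm <- sqrt(sum(v * v))
    if (nrm > 0) return(v / nrm)
  }
}

#' Complete a direction into a pre-penetrance table
#'
#' Seeds the parameter cells with the coordinates of `d` and fills the
#' remaining cells with the unique completion under the line constraints:
#' every line dot product of the result is zero.
#'
#' @param params A `parameter_set` from [sudoku_select], [point_select] or
#'   [build_solution_map].
#' @param d Numeric vector of length `length(params$cells)` (typically a
#'   [random_unit_vector]).
#' @return An object of class `pre_penetrance` (list with `n`, `mafs`,
#'   `values`, `cells`).
#' @export
pre_penetrance_from_direction <- function(params, d) {
  stopifnot(inherits(params, "parameter_set"),
            length(d) == length(params$cells))
  structure(list(n = params$n, mafs = params$mafs,
                 values = drop(params$map %*% d),
                 cells = params$cells),
            class = "pre_penetrance")
}

#' @export
print.pre_penetrance <- function(x, ...) {
  cat(sprintf("Pre-penetrance table: %d loci, %d cells, max |line residual| = %.3g\n",
              x$n, length(x$values), max(abs(line_dot_products(x)))))
  invisible(x)
}

#' Scale a pre-penetrance table onto [0, 1]
#'
#' Applies `S(G) = (G - m) / (M - m)` entrywise, with `M` and `m` the
#' extremes of the table. The result spans \[0, 1\] exactly and is a pure,
#' strict penetrance model; its prevalence is `-m / (M - m)`. `S` is
#' invariant under positive scaling of its argument, so a direction and
#' any positive multiple of it yield the same model.
#'
#' @param pre A `pre_penetrance` table.
#' @return A [penetrance_model], or `NULL` when the table is (numerically)
#'   constant so that no direction is defined (`M - m < 1e-12`).
#' @export
normalize_S <- function(pre) {
  stopifnot(inherits(pre, "pre_penetrance"))
  M <- max(pre$values)
  m <- min(pre$values)
  if (M - m < 1e-12) return(NULL)
  penetrance_model(pre$mafs, (pre$values - m) / (M - m))
}

# clamp floating-point overshoot from affine rescales
.clip01 <- function(v, tol = 1e-12) {
  if (min(v) < -tol || max(v) > 1 + tol) return(NULL)
  pmin(pmax(v, 0), 1)
}

#' Rescale a model to a target heritability, preserving prevalence
#'
#' Applies `f(x) = m x + b` with `m = sqrt(h / H2)` and `b = (1 - m) K`,
#' which leaves the prevalence K unchanged and scales the penetrance
#' variance by `m^2`, setting heritability to `h`. Feasible exactly when
#' `h` does not exceed the model's current heritability (otherwise some
#' entry would leave \[0, 1\]): random models can only be scaled down.
#'
#' @param model A [penetrance_model] spanning \[0, 1\] (the output of
#'   [normalize_S]).
#' @param h Target heritability in (0, 1].
#' @return The rescaled [penetrance_model], or `NULL` when infeasible.
#' @export
rescale_heritability <- function(model, h) {
  stopifnot(inherits(model, "penetrance_model"), h > 0, h <= 1)
  K <- prevalence(model)
  H2 <- heritability(model)
  m <- sqrt(h / H2)
  v <- .clip01(m * model$values + (1 - m) * K)
  if (is.null(v)) return(NULL)
  penetrance_model(model$mafs, v)
}

#' Rescale a model to target heritability and prevalence
#'
#' Applies `f(x) = m x + b` with
#' `m = sqrt(h K_t (1 - K_t) / V)` and `b = K_t - m K`, where `V` is the
#' penetrance variance `sum P(g) (f_g - K)^2` of the input. The output has
#' heritability `h` and prevalence `K_t` whenever all transformed entries
#' stay in \[0, 1\]; otherwise the combination is infeasible for this
#' model's class.
#'
#' @inheritParams rescale_heritability
#' @param K_t Target prevalence in (0, 1).
#' @return The rescaled [penetrance_model], or `NULL` when infeasible.
#' @export
rescale_heritability_prevalence <- function(model, h, K_t) {
  stopifnot(inherits(model, "penetrance_model"),
            h > 0, h <= 1, K_t > 0, K_t < 1)
  P <- mlg_frequencies(model$mafs)
  K <- sum(P * model$values)
  V <- sum(P * (model$values - K)^2)
  if (V <= 0) return(NULL)
  m <- sqrt(h * K_t * (1 - K_t) / V)
  b <- K_t - m * K
  v <- .clip01(m * model$values + b)
  if (is.null(v)) return(NULL)
  penetrance_model(model$mafs, v)
}

# Precomputed per-constraints context so repeated attempts are cheap.
.gen_context <- function(constraints) {
  n <- constraints$n
  method <- if (constraints$method == "auto") choose_method(n) else constraints$method
  list(n = n, mafs = constraints$mafs,
       h = constraints$heritability, K_t = constraints$prevalence,
       method = method,
       geom = .line_geometry(n),
       grid = mlg_grid(n),
       B = .solution_basis(constraints$mafs),
       P = mlg_frequencies(constraints$mafs))
}

# One generation attempt; returns a penetrance_model or NULL.
.gen_attempt <- function(ctx) {
  n <- ctx$n
  if (ctx$method == "sudoku") {
    cells <- .sudoku_pick(n, ctx$geom)
    if (is.null(cells)) return(NULL)
  } else {
    ref <- ctx$grid[sample.int(3L^n, 1L), ]
    cells <- which(rowSums(ctx$grid == matrix(ref, 3L^n, n, byrow = TRUE)) == 0L)
  }
  d <- random_unit_vector(2L^n)
  tab <- drop(ctx$B %*% solve(ctx$B[cells, , drop = FALSE], d))
  M <- max(tab)
  m0 <- min(tab)
  if (M - m0 < 1e-12) return(NULL)
  S <- (tab - m0) / (M - m0)
  K <- sum(ctx$P * S)
  V <- sum(ctx$P * (S - K)^2)
  if (V <= 0 || K <= 0 || K >= 1) return(NULL)
  if (is.null(ctx$K_t)) {
    m <- sqrt(ctx$h / (V / (K * (1 - K))))
    v <- .clip01(m * S + (1 - m) * K)
  } else {
    m <- sqrt(ctx$h * ctx$K_t * (1 - ctx$K_t) / V)
    v <- .clip01(m * S + (ctx$K_t - m * K))
  }
  if (is.null(v)) return(NULL)
  penetrance_model(ctx$mafs, v)
}

#' Generate one random pure, strict epistatic model
#'
#' Iterates the full pipeline -- parameter selection (Sudoku or Point),
#' random unit direction, pre-penetrance completion, scaling onto \[0, 1\],
#' affine rescale to the requested heritability and optional prevalence --
#' until an attempt succeeds or the attempt limit is reached. Each attempt
#' draws an independent random architecture, so successful models are a
#' random sample of the constrained model space.
#'
#' @param constraints A [model_constraints] object.
#' @return A list of class `epi_model_result` with elements `model` (a
#'   [penetrance_model], or `NULL` when the attempt limit was exhausted),
#'   `attempts` (attempts consumed) and `success`.
#' @examples
#' set.seed(1)
#' res <- generate_model(model_constraints(2, c(0.5, 0.5), 0.05))
#' res$model
#' @export
generate_model <- function(constraints) {
  stopifnot(inherits(constraints, "model_constraints"))
  ctx <- .gen_context(constraints)
  for (a in seq_len(constraints$attempt_limit)) {
    model <- .gen_attempt(ctx)
    if (!is.null(model)) {
      return(structure(list(model = model, attempts = a, success = TRUE),
                       class = "epi_model_result"))
    }
  }
  structure(list(model = NULL, attempts = constraints$attempt_limit,
                 success = FALSE),
            class = "epi_model_result")
}

#' @export
print.epi_model_result <- function(x, ...) {
  if (x$success) {
    cat(sprintf("Model generated after %d attempt(s)\n", x$attempts))
    print(x$model)
  } else {
    cat(sprintf("No model found within %d attempts\n", x$attempts))
  }
  invisible(x)
}

#' Generate a population of random model architectures
#'
#' Repeats [generate_model] independently. Slots whose attempt limit is
#' exhausted are reported with a warning and returned as `NULL`; the
#' overall generation frequency (successes over all attempts) is recorded.
#'
#' @inheritParams generate_model
#' @param count Number of models requested.
#' @return A list of class `epi_model_population` with `models` (list,
#'   `NULL` for exhausted slots), `attempts` (per-slot attempt counts),
#'   `successes`, and `generation_frequency`.
#' @export
generate_population <- function(constraints, count) {
  stopifnot(count >= 1)
  results <- lapply(seq_len(count), function(i) generate_model(constraints))
  models <- lapply(results, `[[`, "model")
  attempts <- vapply(results, `[[`, integer(1), "attempts")
  successes <- sum(vapply(results, `[[`, logical(1), "success"))
  if (successes < count) {
    warning(sprintf("%d of %d model slot(s) exhausted the attempt limit",
                    count - successes, count), call. = FALSE)
  }
  structure(list(models = models, attempts = attempts,
                 successes = successes,
                 generation_frequency = successes / sum(attempts)),
            class = "epi_model_population")
}

#' @export
print.epi_model_population <- function(x, ...) {
  cat(sprintf(
    "Model population: %d/%d generated; %d total attempts (frequency %.4g)\n",
    x$successes, length(x$models), sum(x$attempts), x$generation_frequency))
  invisible(x)
}

#' Empirical model-generation frequency
#'
#' Runs a fixed number of independent single attempts of the full
#' generation pipeline and reports the fraction that succeed. This is the
#' per-iteration success probability of [generate_model] under the given
#' constraints, the natural measure of how hard a constraint combination
#' is.
#'
#' @inheritParams generate_model
#' @param attempts Number of independent attempts.
#' @return A list with `successes`, `attempts` and `frequency`.
#' @export
generation_frequency <- function(constraints, attempts) {
  stopifnot(inherits(constraints, "model_constraints"), attempts >= 1)
  ctx <- .gen_context(constraints)
  succ <- 0L
  for (i in seq_len(attempts)) {
    if (!is.null(.gen_attempt(ctx))) succ <- succ + 1L
  }
  list(successes = succ, attempts = attempts, frequency = succ / attempts)
}
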