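# Empirical limits on achievable heritability for pure, strict models.

#' Estimate the maximum achievable heritability
#'
#' Samples random classes of pure, strict epistatic models (random
#' parameters plus a random direction, scaled onto \[0, 1\]) and records,
#' per class, the largest heritability compatible with the requested
#' prevalence; the estimate is the running maximum over samples. When
#' `prevalence` is given, the class member with that prevalence and
#' maximal heritability is obtained by the largest feasible slope
#' `m = min(K_t / K_S, (1 - K_t) / (1 - K_S))` of the affine map
#' `f(x) = m x + (K_t - m K_S)` applied to the \[0, 1\]-spanning class
#' representative with prevalence `K_S`; its heritability is
#' `m^2 V / (K_t (1 - K_t))`. When `prevalence` is omitted the
#' representative's own heritability is recorded.
#'
#' Being a sampling estimate, the result is a lower bound that improves
#' with `samples`; near-degenerate optima may be under-covered.
#'
#' @param mafs Minor allele frequencies, one per locus (n >= 2).
#' @param prevalence Optional target prevalence in (0, 1).
#' @param samples Number of random classes to examine.
#' @param method Parameter-selection method (`"auto"`, `"sudoku"`,
#'   `"point"`). Selection failures are redrawn so every sample examines
#'   one class.
#' @return A list of class `herit_limit` with `mafs`, `prevalence`,
#'   `estimate`, and `samples`.
#' @examples
#' set.seed(1)
#' estimate_max_heritability(c(0.5, 0.5), prevalence = 0.5, samples = 200)
#' @export
estimate_max_heritability <- function(mafs, prevalence = NULL,
                                      samples = 1000,
                                      method = c("auto", "sudoku", "point")) {
  method <- match.arg(method)
  stopifnot(samples >= 1)
  n <- length(mafs)
  ctx <- .gen_context(model_constraints(n, mafs, heritability = 0.5,
                                        prevalence = prevalence,
                                        method = method))
  best <- 0
  for (s in seq_len(samples)) {
    h <- NULL
    while (is.null(h)) h <- .class_max_heritability(ctx)
    if (h > best) best <- h
  }
  structure(list(mafs = as.numeric(mafs), prevalence = prevalence,
                 estimate = best, samples = as.integer(samples)),
            class = "herit_limit")
}

# Max heritability of one random class (NULL when parameter selection or
# normalization fails and the sample must be redrawn).
.class_max_heritability <- function(ctx) {
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
  if (K <= 0 || K >= 1) return(NULL)
  V <- sum(ctx$P * (S - K)^2)
  if (is.null(ctx$K_t)) return(V / (K * (1 - K)))
  K_t <- ctx$K_t
  m <- min(K_t / K, (1 - K_t) / (1 - K))
  m^2 * V / (K_t * (1 - K_t))
}

#' @export
print.herit_limit <- function(x, ...) {
  cat(sprintf(
    "Max-heritability estimate %.4g (MAFs %s%s; %d sampled classes)\n",
    x$estimate, paste(x$mafs, collapse = ", "),
    if (is.null(x$prevalence)) "" else sprintf("; K = %g", x$prevalence),
    x$samples))
  invisible(x)
}

#' Maximum-heritability curve over a MAF grid
#'
#' Convenience wrapper estimating the maximum achievable heritability of
#' 2-locus pure, strict models where both SNPs share a common MAF, over a
#' grid of MAF values at fixed prevalence. For prevalence near 0.5 the
#' curve peaks at MAF 0.5 and near `1 - sqrt(1/2)` (about 0.29) and falls
#' off away from them.
#'
#' @param maf_grid Numeric vector of common MAF values in (0, 0.5].
#' @param prevalence Target prevalence (default 0.5).
#' @param samples Sampled classes per grid point.
#' @return A data.frame with columns `maf` and `max_heritability`.
#' @export
max_heritability_curve <- function(maf_grid, prevalence = 0.5,
                                   samples = 1000) {
  est <- vapply(maf_grid, function(q) {
    estimate_max_heritability(c(q, q), prevalence = prevalence,
                              samples = samples)$estimate
  }, numeric(1))
  data.frame(maf = maf_grid, max_heritability = est)
}

#' Plot a maximum-heritability curve
#'
#' @param curve Output of [max_heritability_curve].
#' @param file Optional path; when given, the plot is written as a PNG.
#' @param ... Passed to [graphics::plot].
#' @return Invisibly, the curve.
#' @export
plot_heritability_curve <- function(curve, file = NULL, ...) {
  draw <- function() {
    graphics::plot(curve$maf, curve$max_heritability, type = "b", pch = 16,
                   xlab = "Minor allele frequency (both SNPs)",
                   ylab = "Estimated maximum heritability", ...)
  }
  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = 600)
    on.exit(grDevices::dev.off())
    draw()
  } else {
    draw()
  }
  invisible(curve)
}
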