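#' Hardy-Weinberg genotype frequencies for a biallelic SNP
#'
#' Converts a minor allele frequency into the three genotype frequencies
#' implied by Hardy-Weinberg equilibrium: with minor allele frequency
#' \eqn{q} and major allele frequency \eqn{p = 1 - q}, the genotypes
#' AA, Aa and aa occur with frequencies \eqn{p^2}, \eqn{2pq} and
#' \eqn{q^2}.
#'
#' @param maf Minor allele frequency, a single number in (0, 0.5].
#'   Frequencies above 0.5 must be supplied as `1 - q`; the mathematics is
#'   symmetric in the allele labels.
#' @return A named numeric vector `c(AA=, Aa=, aa=)` summing to 1.
#' @examples
#' hwe_genotype_freqs(0.5)  # 0.25 0.50 0.25
#' hwe_genotype_freqs(0.4)  # 0.36 0.48 0.16
#' @export
hwe_genotype_freqs <- function(maf) {
  if (!is.numeric(maf) || length(maf) != 1L || is.na(maf) ||
      maf <= 0 || maf > 0.5) {
    stop("'maf' must be a single frequency in (0, 0.5]", call. = FALSE)
  }
  q <- maf
  p <- 1 - q
  c(AA = p * p, Aa = 2 * p * q, aa = q * q)
}

#' Describe one biallelic locus
#'
#' Bundles a minor allele frequency with its derived Hardy-Weinberg
#' genotype frequencies.
#'
#' @inheritParams hwe_genotype_freqs
#' @return An object of class `locus_spec` with elements `maf` and
#'   `genotype_freqs`.
#' @export
locus_spec <- function(maf) {
  structure(list(maf = maf, genotype_freqs = hwe_genotype_freqs(maf)),
            class = "locus_spec")
}

#' @export
print.locus_spec <- function(x, ...) {
  cat(sprintf("Biallelic locus: MAF = %g; HWE genotype frequencies %s\n",
              x$maf, paste(signif(x$genotype_freqs, 6), collapse = " / ")))
  invisible(x)
}

#' Multi-locus genotype enumeration
#'
#' A multi-locus genotype (MLG) over `n` biallelic SNPs is a vector in
#' \{0,1,2\}^n counting minor alleles per locus (0 = homozygous major,
#' 1 = heterozygous, 2 = homozygous minor). MLGs are enumerated row-major
#' with locus 1 most significant, so the flat (0-based) index of a
#' genotype vector g is \eqn{\sum_i g_i 3^{n-1-i}}.
#'
#' `mlg_grid` returns all `3^n` genotype vectors in flat-index order;
#' `mlg_index` and `mlg_vector` convert between the two representations.
#'
#' @param n Number of loci.
#' @return `mlg_grid`: an integer matrix with `3^n` rows and `n` columns.
#' @export
mlg_grid <- function(n) {
  stopifnot(n >= 1)
  g <- as.matrix(rev(expand.grid(rev(lapply(seq_len(n), function(i) 0:2)),
                                 KEEP.OUT.ATTRS = FALSE)))
  dimnames(g) <- NULL
  storage.mode(g) <- "integer"
  g
}

#' @rdname mlg_grid
#' @param g Integer genotype vector in \{0,1,2\}^n.
#' @return `mlg_index`: the 0-based flat index.
#' @export
mlg_index <- function(g) {
  if (any(!(g %in% 0:2))) stop("genotype codes must be 0, 1 or 2", call. = FALSE)
  n <- length(g)
  sum(g * 3^((n - 1):0))
}

#' @rdname mlg_grid
#' @param index 0-based flat index in `0:(3^n - 1)`.
#' @return `mlg_vector`: the genotype vector.
#' @export
mlg_vector <- function(index, n) {
  if (index < 0 || index >= 3^n) stop("flat index out of range", call. = FALSE)
  out <- integer(n)
  for (i in n:1) {
    out[i] <- index %% 3
    index <- index %/% 3
  }
  out
}

#' Population frequencies of all multi-locus genotypes
#'
#' Under Hardy-Weinberg equilibrium at each locus and linkage equilibrium
#' between loci, the frequency of an MLG is the product of its per-locus
#' genotype frequencies. Frequencies are returned in flat MLG order
#' (see [mlg_grid]).
#'
#' @param mafs Numeric vector of minor allele frequencies, one per locus.
#' @return Numeric vector of length `3^length(mafs)` summing to 1.
#' @export
mlg_frequencies <- function(mafs) {
  Reduce(kronecker, lapply(mafs, function(q) unname(hwe_genotype_freqs(q))))
}

#' Construct an n-locus penetrance model
#'
#' A penetrance model assigns to each of the `3^n` multi-locus genotypes a
#' penetrance: the probability of disease given that genotype. Values are
#' stored in flat MLG order (row-major, locus 1 most significant; see
#' [mlg_grid]).
#'
#' @param mafs Minor allele frequencies of the `n >= 2` interacting loci.
#' @param values Numeric vector of `3^n` penetrances, each in \[0, 1\].
#' @return An object of class `penetrance_model` with elements `n`,
#'   `mafs`, `loci` (list of [locus_spec]) and `values`.
#' @examples
#' # the classic fully penetrant XOR interaction
#' m <- xor_model()
#' prevalence(m)     # 0.5
#' heritability(m)   # 1
#' @export
penetrance_model <- function(mafs, values) {
  n <- length(mafs)
  if (n < 2) stop("a penetrance model needs at least 2 loci", call. = FALSE)
  if (length(values) != 3^n) {
    stop(sprintf("expected %d penetrance values, got %d", 3^n, length(values)),
         call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < -1e-12) || any(values > 1 + 1e-12)) {
    stop("penetrance values must lie in [0, 1]", call. = FALSE)
  }
  values <- pmin(pmax(as.numeric(values), 0), 1)
  structure(list(n = n,
                 mafs = as.numeric(mafs),
                 loci = lapply(mafs, locus_spec),
                 values = values),
            class = "penetrance_model")
}

#' @export
print.penetrance_model <- function(x, digits = 4, ...) {
  cat(sprintf("Penetrance model: %d loci, MAFs %s\n", x$n,
              paste(x$mafs, collapse = ", ")))
  if (x$n == 2L) {
    tab <- matrix(x$values, 3, 3, byrow = TRUE,
                  dimnames = list(SNP1 = c("AA", "Aa", "aa"),
                                  SNP2 = c("BB", "Bb", "bb")))
    print(round(tab, digits))
  } else {
    cat(sprintf("  %d penetrance values in [%.4g, %.4g]\n",
                length(x$values), min(x$values), max(x$values)))
  }
  K <- prevalence(x)
  cat(sprintf("  prevalence K = %.6g", K))
  if (K > 0 && K < 1) cat(sprintf(", heritability = %.6g", heritability(x)))
  cat("\n")
  invisible(x)
}

#' The fully penetrant XOR interaction model
#'
#' The textbook 2-locus purely epistatic model: disease occurs exactly when
#' one locus is heterozygous and the other is not. With both MAFs 0.5 its
#' prevalence is 0.5 and its (broad-sense) heritability is 1, and no single
#' locus shows any marginal effect.
#'
#' @param mafs MAFs of the two loci (default `c(0.5, 0.5)`).
#' @return A [penetrance_model].
#' @export
xor_model <- function(mafs = c(0.5, 0.5)) {
  stopifnot(length(mafs) == 2L)
  penetrance_model(mafs, c(0, 1, 0,
                           1, 0, 1,
                           0, 1, 0))
}

#' A worked 2-locus example with continuous penetrances
#'
#' A purely, strictly epistatic 2-locus model with SNP 1 MAF 0.4 and SNP 2
#' MAF 0.5 whose penetrances are continuous rather than 0/1. All six
#' marginal penetrances equal the prevalence (0.614 to three decimals), so
#' neither SNP alone is predictive of status even though the pair is.
#' Values are printed to three decimals, so purity holds to roughly 1e-3,
#' not machine precision.
#'
#' @return A [penetrance_model].
#' @export
example_model <- function() {
  penetrance_model(c(0.4, 0.5), c(0.266, 0.764, 0.664,
                                  0.928, 0.398, 0.733,
                                  0.456, 0.927, 0.147))
}

# internal: accept a penetrance model, a pre-penetrance table, or raw values
.table_values <- function(x) {
  if (inherits(x, "penetrance_model") || inherits(x, "pre_penetrance")) {
    list(values = x$values, mafs = x$mafs, n = x$n)
  } else {
    stop("expected a penetrance_model or pre_penetrance object", call. = FALSE)
  }
}

#' Marginal penetrance of one genotype at one locus
#'
#' The marginal penetrance of genotype `g` at locus `i` is the expected
#' penetrance over the joint Hardy-Weinberg distribution of all the other
#' loci, holding locus `i` fixed at `g`. In a purely epistatic model these
#' marginals are equal across genotypes for every locus (and equal the
#' prevalence).
#'
#' @param model A [penetrance_model] (or pre-penetrance table).
#' @param locus Locus index, 1-based.
#' @param genotype Genotype code 0, 1 or 2.
#' @return The marginal penetrance (a probability).
#' @examples
#' marginal_penetrance(example_model(), 1, 0)  # ~0.614
#' @export
marginal_penetrance <- function(model, locus, genotype) {
  tv <- .table_values(model)
  n <- tv$n
  stopifnot(locus >= 1, locus <= n, genotype %in% 0:2)
  grid <- mlg_grid(n)
  sel <- grid[, locus] == genotype
  P <- mlg_frequencies(tv$mafs)
  w <- P[sel] / unname(hwe_genotype_freqs(tv$mafs[locus]))[genotype + 1L]
  sum(w * tv$values[sel])
}

#' All line dot products of a penetrance or pre-penetrance table
#'
#' A "line" fixes the genotypes of all loci but one and lets the remaining
#' locus range over its three genotypes. Dotting the three table entries on
#' a line with that locus's genotype frequencies gives a conditional
#' penetrance; there are \eqn{n 3^{n-1}} such products. Their equality
#' across all lines is the defining property of pure, strict epistasis, and
#' their common value is then the prevalence. For a pre-penetrance table
#' every line dot product is zero.
#'
#' @param x A [penetrance_model] or `pre_penetrance` table.
#' @return Numeric vector of length `n * 3^(n-1)`.
#' @export
line_dot_products <- function(x) {
  tv <- .table_values(x)
  lines <- enumerate_lines(tv$n, tv$mafs)
  vals <- matrix(tv$values[lines$cells], nrow(lines$cells), 3L)
  rowSums(vals * lines$weights)
}

#' Test whether a model is purely and strictly epistatic
#'
#' An n-locus model is pure (no single-locus marginal effects) and strict
#' (no proper subset of loci is predictive) exactly when all
#' \eqn{n 3^{n-1}} line dot products are equal. The test compares the
#' spread (max minus min) of [line_dot_products] against an absolute
#' tolerance.
#'
#' @inheritParams line_dot_products
#' @param tol Absolute tolerance on the spread; the default 1e-9 suits
#'   double-precision linear solves on tables of up to a few hundred cells.
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_pure_strict(xor_model())                 # TRUE
#' is_pure_strict(example_model(), tol = 1e-2) # printed to 3 decimals
#' @export
is_pure_strict <- function(x, tol = 1e-9) {
  d <- line_dot_products(x)
  (max(d) - min(d)) <= tol
}

#' Population prevalence of a penetrance model
#'
#' The prevalence K is the frequency-weighted mean penetrance,
#' \eqn{K = \sum_g P(g) f_g}, with P the Hardy-Weinberg MLG distribution.
#'
#' @inheritParams marginal_penetrance
#' @return The prevalence, a probability.
#' @export
prevalence <- function(model) {
  tv <- .table_values(model)
  sum(mlg_frequencies(tv$mafs) * tv$values)
}

#' Broad-sense heritability of a penetrance model
#'
#' The fraction of disease-status variance attributable to genotype,
#' \deqn{H^2 = \frac{\sum_g P(g) (f_g - K)^2}{K (1 - K)},}
#' where K is the prevalence. For a fully penetrant model whose prevalence
#' is 0.5 (such as [xor_model] with MAFs 0.5) this equals exactly 1; a
#' constant model has heritability 0.
#'
#' @inheritParams marginal_penetrance
#' @return Heritability in \[0, 1\].
#' @export
heritability <- function(model) {
  tv <- .table_values(model)
  P <- mlg_frequencies(tv$mafs)
  K <- sum(P * tv$values)
  if (K <= 0 || K >= 1) {
    stop("heritability is undefined when prevalence is 0 or 1", call. = FALSE)
  }
  sum(P * (tv$values - K)^2) / (K * (1 - K))
}
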