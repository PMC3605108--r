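# Balanced case/control dataset simulation from a penetrance model.

#' Case and control multi-locus genotype distributions
#'
#' Bayes inversion of the penetrance function: given disease status, the
#' MLG distribution is
#' \deqn{P(g \mid case) = P(g) f_g / K, \quad
#'       P(g \mid control) = P(g) (1 - f_g) / (1 - K),}
#' with P the Hardy-Weinberg MLG distribution and K the prevalence.
#' Sampling cases and controls directly from these distributions is
#' equivalent to population sampling with Bernoulli(f_g) status followed
#' by conditioning, but does not waste draws when K is small.
#'
#' @param model A [penetrance_model].
#' @return A list with numeric vectors `case` and `control`, each of
#'   length `3^n` and summing to 1.
#' @export
conditional_mlg_distributions <- function(model) {
  stopifnot(inherits(model, "penetrance_model"))
  P <- mlg_frequencies(model$mafs)
  K <- sum(P * model$values)
  if (K <= 0 || K >= 1) {
    stop("conditional distributions are undefined when prevalence is 0 or 1",
         call. = FALSE)
  }
  list(case = P * model$values / K,
       control = P * (1 - model$values) / (1 - K))
}

#' Simulate one case/control SNP dataset
#'
#' Draws the predictive SNPs' multi-locus genotypes from the case and
#' control conditional distributions of `model`, adds unlinked noise SNPs
#' drawn per individual under Hardy-Weinberg equilibrium (each noise
#' SNP's MAF drawn once, uniformly from `noise_maf_range`), places the
#' predictive SNPs at random column positions, and shuffles the rows.
#' Genotypes are coded 0/1/2 as minor-allele counts; status is 1 for
#' cases, 0 for controls.
#'
#' @param model A [penetrance_model] with `n` loci.
#' @param n_cases,n_controls Numbers of cases and controls (>= 1).
#' @param total_snps Total SNP count including the `n` predictive ones
#'   (default 20).
#' @param noise_maf_range Length-2 range for noise-SNP MAFs (default
#'   `c(0.05, 0.5)`).
#' @return An object of class `epi_dataset`: list with integer matrix
#'   `genotypes` (individuals by SNPs), integer `status`, integer
#'   `predictive_columns`, character `snp_names` (predictive SNPs are
#'   named `P1..Pn`, noise SNPs `N1..`), and `noise_mafs`.
#' @examples
#' set.seed(1)
#' ds <- simulate_dataset(xor_model(), 100, 100)
#' dim(ds$genotypes)  # 200 x 20
#' @export
simulate_dataset <- function(model, n_cases, n_controls, total_snps = 20,
                             noise_maf_range = c(0.05, 0.5)) {
  stopifnot(inherits(model, "penetrance_model"),
            n_cases >= 1, n_controls >= 1)
  n <- model$n
  if (total_snps < n) stop("'total_snps' must be at least the model's locus count",
                           call. = FALSE)
  if (length(noise_maf_range) != 2L || noise_maf_range[1] > noise_maf_range[2] ||
      noise_maf_range[1] <= 0 || noise_maf_range[2] > 0.5) {
    stop("'noise_maf_range' must be an increasing range within (0, 0.5]",
         call. = FALSE)
  }
  dists <- conditional_mlg_distributions(model)
  grid <- mlg_grid(n)
  n_ind <- n_cases + n_controls
  idx <- c(sample.int(3L^n, n_cases, replace = TRUE, prob = dists$case),
           sample.int(3L^n, n_controls, replace = TRUE, prob = dists$control))
  pred <- grid[idx, , drop = FALSE]
  status <- rep(c(1L, 0L), c(n_cases, n_controls))

  n_noise <- total_snps - n
  noise_mafs <- stats::runif(n_noise, noise_maf_range[1], noise_maf_range[2])
  noise <- matrix(stats::rbinom(n_ind * n_noise, 2L,
                                rep(noise_mafs, each = n_ind)),
                  n_ind, n_noise)
  pred_cols <- sort(sample.int(total_snps, n))
  geno <- matrix(0L, n_ind, total_snps)
  geno[, pred_cols] <- pred
  geno[, setdiff(seq_len(total_snps), pred_cols)] <- noise
  snp_names <- character(total_snps)
  snp_names[pred_cols] <- paste0("P", seq_len(n))
  snp_names[setdiff(seq_len(total_snps), pred_cols)] <- paste0("N", seq_len(n_noise))

  ord <- sample.int(n_ind)
  structure(list(genotypes = geno[ord, , drop = FALSE],
                 status = status[ord],
                 predictive_columns = pred_cols,
                 snp_names = snp_names,
                 noise_mafs = noise_mafs),
            class = "epi_dataset")
}

#' @export
print.epi_dataset <- function(x, ...) {
  cat(sprintf(
    "Case/control SNP dataset: %d individuals (%d cases), %d SNPs (predictive: %s)\n",
    nrow(x$genotypes), sum(x$status), ncol(x$genotypes),
    paste(x$snp_names[x$predictive_columns], collapse = ", ")))
  invisible(x)
}

#' Simulate an archive of replicate datasets
#'
#' For each model and each balanced sample size, generates `replicates`
#' independent datasets. Per-dataset seeds are drawn from the stream
#' seeded by `seed`, so the archive is reproducible as a whole and each
#' dataset is reproducible on its own from the recorded seed. When
#' `out_dir` is given, each dataset is written as a tab-delimited file
#' (with a provenance sidecar) named
#' `<model>_s<size>_r<replicate>.txt`; otherwise the datasets are
#' returned in memory.
#'
#' @param models A list of [penetrance_model] objects (or a single model).
#' @param sizes Balanced total sample sizes (each split half cases, half
#'   controls), e.g. `c(200, 400, 800, 1600)`.
#' @param replicates Replicate datasets per model and size.
#' @param total_snps,noise_maf_range Passed to [simulate_dataset].
#' @param seed Master seed for the archive.
#' @param out_dir Optional output directory.
#' @return A list of class `epi_archive`; element `entries` is a list of
#'   records with `model_id`, `size`, `replicate`, `seed`, and either
#'   `dataset` (in-memory mode) or `file`.
#' @export
simulate_archive <- function(models, sizes, replicates, total_snps = 20,
                             noise_maf_range = c(0.05, 0.5),
                             seed = 1L, out_dir = NULL) {
  if (inherits(models, "penetrance_model")) models <- list(models)
  stopifnot(length(models) >= 1, length(sizes) >= 1, replicates >= 1,
            all(sizes >= 2), all(sizes %% 2 == 0))
  set.seed(seed)
  n_total <- length(models) * length(sizes) * replicates
  child_seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  entries <- vector("list", n_total)
  k <- 0L
  for (mi in seq_along(models)) {
    for (sz in sizes) {
      for (r in seq_len(replicates)) {
        k <- k + 1L
        set.seed(child_seeds[k])
        ds <- simulate_dataset(models[[mi]], sz %/% 2L, sz %/% 2L,
                               total_snps, noise_maf_range)
        rec <- list(model_id = mi, size = sz, replicate = r,
                    seed = child_seeds[k])
        if (is.null(out_dir)) {
          rec$dataset <- ds
        } else {
          file <- file.path(out_dir,
                            sprintf("model%d_s%d_r%d.txt", mi, sz, r))
          write_dataset_file(ds, file)
          write_provenance(ds, paste0(file, ".prov"),
                           model_label = sprintf("model %d", mi),
                           seed = child_seeds[k])
          rec$file <- file
        }
        entries[[k]] <- rec
      }
    }
  }
  structure(list(entries = entries, seed = seed), class = "epi_archive")
}

#' @export
print.epi_archive <- function(x, ...) {
  cat(sprintf("Dataset archive: %d datasets (master seed %d)\n",
              length(x$entries), x$seed))
  invisible(x)
}
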