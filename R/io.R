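# Plain-text readers and writers for models, datasets, and run configs.

# 17 significant decimal digits round-trip an IEEE double exactly
.fmt17 <- function(x) sprintf("%.17g", x)

#' Write a penetrance model to a text file
#'
#' The format is a small self-describing key/value header (locus count,
#' MAFs, genotype ordering convention, derived prevalence and
#' heritability) followed by the `3^n` penetrance values in flat MLG
#' order, one per line, at 17 significant digits so that
#' [read_model_file] inverts the write bit-exactly.
#'
#' @param model A [penetrance_model].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_model_file <- function(model, path) {
  stopifnot(inherits(model, "penetrance_model"))
  K <- prevalence(model)
  h <- if (K > 0 && K < 1) heritability(model) else NA_real_
  lines <- c(
    "# epistasim penetrance model",
    sprintf("n: %d", model$n),
    sprintf("mafs: %s", paste(.fmt17(model$mafs), collapse = " ")),
    "order: row-major flat MLG index, locus 1 most significant; genotype 0=AA 1=Aa 2=aa",
    sprintf("prevalence: %s", .fmt17(K)),
    sprintf("heritability: %s", .fmt17(h)),
    "values:",
    .fmt17(model$values))
  res <- tryCatch(writeLines(lines, path),
                  error = function(e) stop(sprintf("cannot write model file '%s': %s",
                                                   path, conditionMessage(e)),
                                           call. = FALSE))
  invisible(path)
}

#' Read a penetrance model from a text file
#'
#' @param path Path to a file written by [write_model_file].
#' @return A [penetrance_model].
#' @export
read_model_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("model file '%s' not found", path),
                               call. = FALSE)
  lines <- readLines(path)
  fail <- function(i, why) {
    stop(sprintf("malformed model file '%s' at line %d: %s", path, i, why),
         call. = FALSE)
  }
  field <- function(key) {
    i <- grep(paste0("^", key, ":"), lines)
    if (length(i) != 1L) fail(if (length(i)) i[2] else 0L,
                              sprintf("expected exactly one '%s:' entry", key))
    sub(paste0("^", key, ":\\s*"), "", lines[i])
  }
  n <- suppressWarnings(as.integer(field("n")))
  if (is.na(n) || n < 2) fail(grep("^n:", lines)[1], "invalid locus count")
  mafs <- suppressWarnings(as.numeric(strsplit(trimws(field("mafs")), "\\s+")[[1]]))
  if (anyNA(mafs) || length(mafs) != n) {
    fail(grep("^mafs:", lines)[1], "invalid MAF list")
  }
  vstart <- grep("^values:", lines)
  if (length(vstart) != 1L) fail(0L, "missing 'values:' section")
  vlines <- lines[(vstart + 1L):length(lines)]
  vlines <- vlines[nzchar(trimws(vlines))]
  values <- suppressWarnings(as.numeric(vlines))
  if (anyNA(values)) fail(vstart + which(is.na(values))[1],
                          "non-numeric penetrance value")
  if (length(values) != 3^n) fail(length(lines),
                                  sprintf("expected %d values, found %d",
                                          3^n, length(values)))
  penetrance_model(mafs, values)
}

#' Write a case/control dataset as a tab-delimited text file
#'
#' GAMETES-style flat format: a header row of SNP names followed by the
#' literal column name `Class`; then one row per individual with 0/1/2
#' genotype codes and 0/1 status. Consumable by MDR-like analysis tools.
#'
#' @param dataset An `epi_dataset` from [simulate_dataset].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_dataset_file <- function(dataset, path) {
  stopifnot(inherits(dataset, "epi_dataset"))
  df <- as.data.frame(dataset$genotypes)
  names(df) <- dataset$snp_names
  df$Class <- dataset$status
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-delimited case/control dataset
#'
#' Inverts [write_dataset_file]. Predictive-column positions are restored
#' from the `P`-prefixed SNP names.
#'
#' @param path Path to a dataset file.
#' @return An `epi_dataset` (without `noise_mafs`, which are not stored in
#'   the flat file).
#' @export
read_dataset_file <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  if (!"Class" %in% names(df)) {
    stop(sprintf("dataset file '%s' lacks a 'Class' column", path),
         call. = FALSE)
  }
  status <- as.integer(df$Class)
  geno <- as.matrix(df[setdiff(names(df), "Class")])
  storage.mode(geno) <- "integer"
  snp_names <- colnames(geno)
  dimnames(geno) <- NULL
  structure(list(genotypes = geno, status = status,
                 predictive_columns = which(startsWith(snp_names, "P")),
                 snp_names = snp_names,
                 noise_mafs = NULL),
            class = "epi_dataset")
}

#' Write a provenance sidecar for a simulated dataset
#'
#' Records the generating model, the dataset seed, and the names and
#' positions of the predictive SNPs, so detection-success studies can
#' score hits without guessing.
#'
#' @param dataset An `epi_dataset`.
#' @param path Sidecar file path.
#' @param model_label Label or path of the generating model.
#' @param seed The seed the dataset was simulated under.
#' @return Invisibly, `path`.
#' @export
write_provenance <- function(dataset, path, model_label = "", seed = NA) {
  writeLines(c(
    "# epistasim dataset provenance",
    sprintf("model: %s", model_label),
    sprintf("seed: %s", seed),
    sprintf("predictive_columns: %s",
            paste(dataset$predictive_columns, collapse = " ")),
    sprintf("predictive_snps: %s",
            paste(dataset$snp_names[dataset$predictive_columns],
                  collapse = " "))), path)
  invisible(path)
}

#' Run configuration
#'
#' Bundles every knob of a full model-plus-archive run so it can be saved
#' to, and restored from, a YAML file losslessly.
#'
#' @param n,mafs,heritability,prevalence,attempt_limit,method Model
#'   constraints; see [model_constraints].
#' @param models Number of models to generate.
#' @param sizes,replicates,total_snps,noise_maf_range Dataset parameters;
#'   see [simulate_archive].
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @param verbose Logical; log progress.
#' @return An object of class `run_config`.
#' @export
run_config <- function(n, mafs, heritability, prevalence = NULL,
                       attempt_limit = 100000L, method = "auto",
                       models = 1L, sizes = c(200L, 400L, 800L, 1600L),
                       replicates = 100L, total_snps = 20L,
                       noise_maf_range = c(0.05, 0.5),
                       seed = 1L, out_dir = ".", verbose = TRUE) {
  structure(list(n = as.integer(n), mafs = as.numeric(mafs),
                 heritability = as.numeric(heritability),
                 prevalence = if (is.null(prevalence)) NULL else as.numeric(prevalence),
                 attempt_limit = as.integer(attempt_limit),
                 method = method,
                 models = as.integer(models),
                 sizes = as.integer(sizes),
                 replicates = as.integer(replicates),
                 total_snps = as.integer(total_snps),
                 noise_maf_range = as.numeric(noise_maf_range),
                 seed = as.integer(seed),
                 out_dir = out_dir, verbose = isTRUE(verbose)),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, x)
}
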