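Package: epistasim
Title: Simulation of Pure, Strict Epistatic Disease Models and Case-Control SNP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministically constructs random n-locus biallelic penetrance
    models that are purely and strictly epistatic (no locus and no proper
    subset of loci carries any marginal effect) while satisfying
    user-specified heritability, minor allele frequencies and, optionally,
    population prevalence. Parameter positions for the underlying linear
    constraint system are chosen by sequential constraint-propagation
    ("Sudoku") or antipodal-cell ("Point") selection, seeded with a random
    direction on the unit sphere, and rescaled affinely to the requested
    constraints. Includes empirical estimation of the maximum achievable
    heritability, a balanced case/control genotype dataset simulator with
    Hardy-Weinberg noise SNPs for benchmarking epistasis-detection methods,
    plain-text model and dataset formats, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
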