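test_that("HWE genotype frequencies match the closed form and validate input", {
  expect_equal(unname(hwe_genotype_freqs(0.5)), c(0.25, 0.5, 0.25))
  expect_equal(unname(hwe_genotype_freqs(0.4)), c(0.36, 0.48, 0.16))
  # degenerate-allele limit: everything collapses onto the major homozygote
  f <- unname(hwe_genotype_freqs(1e-9))
  expect_equal(f[1], 1, tolerance = 1e-8)
  expect_lt(f[2] + f[3], 3e-9)
  expect_error(hwe_genotype_freqs(0), "maf")
  expect_error(hwe_genotype_freqs(0.6), "maf")
  expect_error(hwe_genotype_freqs(c(0.1, 0.2)), "maf")
})

test_that("genotype frequencies sum to one across random MAFs", {
  set.seed(11)
  mafs <- runif(1000, 1e-6, 0.5)
  sums <- vapply(mafs, function(q) sum(hwe_genotype_freqs(q)), numeric(1))
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("MLG flat indexing is a row-major bijection", {
  for (n in 2:4) {
    grid <- mlg_grid(n)
    expect_equal(nrow(grid), 3^n)
    idx <- apply(grid, 1, mlg_index)
    expect_equal(idx, 0:(3^n - 1))
    for (i in c(0, 1, 3^n - 1)) {
      expect_equal(mlg_index(mlg_vector(i, n)), i)
    }
  }
  expect_error(mlg_vector(3^3, 3), "range")
  expect_error(mlg_index(c(0, 3)), "genotype")
})

test_that("MLG frequencies are per-locus products under linkage equilibrium", {
  P <- mlg_frequencies(c(0.5, 0.5))
  expect_equal(P[mlg_index(c(0, 1)) + 1], 0.125)  # (AA, Bb)
  P2 <- mlg_frequencies(c(0.4, 0.5))
  expect_equal(P2[mlg_index(c(2, 2)) + 1], 0.04)  # (aa, bb)
  expect_equal(sum(P2), 1, tolerance = 1e-12)
  set.seed(5)
  for (rep in 1:5) {
    mafs <- runif(3, 0.05, 0.5)
    expect_equal(sum(mlg_frequencies(mafs)), 1, tolerance = 1e-12)
  }
})

test_that("worked continuous-penetrance example has flat marginals of .614", {
  m <- example_model()
  # printed to three decimals: agreement within half a unit in the last place
  expect_lt(abs(marginal_penetrance(m, 1, 0) - 0.614), 5.1e-4)
  expect_lt(abs(marginal_penetrance(m, 1, 1) - 0.614), 5.1e-4)
  expect_lt(max(abs(line_dot_products(m) - 0.614)), 5.1e-4)
  expect_lt(abs(prevalence(m) - 0.614), 5.1e-4)
})

test_that("XOR model is the canonical pure strict case", {
  m <- xor_model()
  expect_equal(line_dot_products(m), rep(0.5, 6))
  expect_true(is_pure_strict(m, tol = 1e-9))
  expect_equal(prevalence(m), 0.5)
  expect_equal(heritability(m), 1)
})

test_that("a single-locus recessive effect embedded with an inert SNP is impure", {
  # penetrance depends on locus 1 alone: a main effect, so not pure
  recessive <- penetrance_model(c(0.5, 0.5), c(0, 0, 0, 0, 0, 0, 1, 1, 1))
  expect_false(is_pure_strict(recessive, tol = 1e-9))
})

test_that("constant models behave as the degenerate case", {
  const <- penetrance_model(c(0.3, 0.4), rep(0.37, 9))
  expect_equal(marginal_penetrance(const, 2, 1), 0.37)
  expect_true(is_pure_strict(const))
  expect_equal(prevalence(const), 0.37)
  expect_equal(heritability(const), 0)
  zero <- penetrance_model(c(0.3, 0.4), rep(0, 9))
  expect_error(heritability(zero), "undefined")
})

test_that("heritability matches a brute-force arithmetic oracle", {
  m <- example_model()
  expect_equal(heritability(m),
               oracle_heritability(m$mafs, m$values), tolerance = 1e-12)
  set.seed(21)
  res <- generate_model(model_constraints(3, c(0.2, 0.35, 0.5), 0.03))
  expect_equal(heritability(res$model),
               oracle_heritability(res$model$mafs, res$model$values),
               tolerance = 1e-9)
})

test_that("line dot products agree with joint-distribution marginals (n = 2)", {
  set.seed(31)
  for (rep in 1:10) {
    mafs <- runif(2, 0.1, 0.5)
    m <- penetrance_model(mafs, runif(9))
    d <- line_dot_products(m)
    # line order: locus 1 varies first (weights = locus 1 freqs, i.e. the
    # marginals of locus 2's genotypes), then locus 2 varies
    for (g in 0:2) {
      expect_equal(d[g + 1], oracle_marginal(mafs, m$values, 2, g),
                   tolerance = 1e-12)
      expect_equal(d[g + 4], oracle_marginal(mafs, m$values, 1, g),
                   tolerance = 1e-12)
    }
  }
})

test_that("purity is equivalent to all marginals equalling the prevalence", {
  set.seed(41)
  for (rep in 1:50) {
    n <- sample(2:3, 1)
    mafs <- runif(n, 0.2, 0.5)
    res <- generate_model(model_constraints(n, mafs, heritability = 0.02))
    m <- res$model
    K <- prevalence(m)
    marg <- unlist(lapply(seq_len(n), function(i) {
      vapply(0:2, function(g) marginal_penetrance(m, i, g), numeric(1))
    }))
    expect_true(is_pure_strict(m, tol = 1e-9))
    expect_true(all(abs(marg - K) < 1e-9))
    # perturb one cell: purity and marginal flatness break together
    bad <- m
    bad$values[1] <- min(1, bad$values[1] + 0.05)
    expect_false(is_pure_strict(bad, tol = 1e-9))
    marg_bad <- vapply(0:2, function(g) marginal_penetrance(bad, 1, g),
                       numeric(1))
    expect_gt(max(abs(marg_bad - prevalence(bad))), 1e-9)
  }
})

test_that("pure strict models are closed under in-range affine maps", {
  set.seed(51)
  for (rep in 1:100) {
    mafs <- runif(2, 0.2, 0.5)
    m <- generate_model(model_constraints(2, mafs, 0.05))$model
    a <- runif(1, 0.1, 0.6)
    b <- runif(1, 0, 1 - a)
    K <- prevalence(m)
    tr <- penetrance_model(mafs, a * m$values + b)
    expect_true(is_pure_strict(tr, tol = 1e-9))
    expect_equal(prevalence(tr), a * K + b, tolerance = 1e-12)
  }
})
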