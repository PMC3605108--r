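test_that("random unit vectors are unit length and rotation symmetric", {
  set.seed(121)
  v <- random_unit_vector(16)
  expect_length(v, 16)
  expect_equal(sum(v^2), 1, tolerance = 1e-12)
  # Monte Carlo: components of a uniform direction in R^4 have mean 0 and
  # variance 1/4; check the mean against its standard error
  draws <- replicate(20000, random_unit_vector(4))
  means <- rowMeans(draws)
  expect_true(all(abs(means) < 4 * 0.5 / sqrt(20000)))
  expect_equal(mean(draws[1, ] > 0), 0.5, tolerance = 0.02)
})

test_that("direction completion seeds parameters and satisfies the lines", {
  set.seed(131)
  ps <- point_select(3, c(0.5, 0.3, 0.2))
  d <- random_unit_vector(8)
  pre <- pre_penetrance_from_direction(ps, d)
  expect_equal(pre$values[ps$cells], d, tolerance = 1e-12)
  expect_lt(max(abs(line_dot_products(pre))), 1e-9)
})

test_that("S normalization spans [0,1] and is scale invariant", {
  set.seed(141)
  ps <- point_select(2, c(0.5, 0.5))
  d <- random_unit_vector(4)
  pre <- pre_penetrance_from_direction(ps, d)
  m1 <- normalize_S(pre)
  expect_equal(min(m1$values), 0)
  expect_equal(max(m1$values), 1)
  expect_true(is_pure_strict(m1, tol = 1e-9))
  for (c0 in c(0.5, 3)) {
    scaled <- pre
    scaled$values <- c0 * pre$values
    expect_equal(normalize_S(scaled)$values, m1$values, tolerance = 1e-12)
  }
  degenerate <- structure(list(n = 2, mafs = c(0.5, 0.5),
                               values = rep(0.3, 9), cells = ps$cells),
                          class = "pre_penetrance")
  expect_null(normalize_S(degenerate))
})

test_that("heritability rescale preserves prevalence and hits the target", {
  set.seed(151)
  for (rep in 1:20) {
    mafs <- runif(2, 0.2, 0.5)
    pre <- pre_penetrance_from_direction(point_select(2, mafs),
                                         random_unit_vector(4))
    m <- normalize_S(pre)
    h0 <- heritability(m)
    K0 <- prevalence(m)
    # identity at the current heritability
    expect_equal(rescale_heritability(m, h0)$values, m$values,
                 tolerance = 1e-9)
    half <- rescale_heritability(m, h0 / 2)
    expect_equal(heritability(half), h0 / 2, tolerance = 1e-9)
    expect_equal(prevalence(half), K0, tolerance = 1e-12)
    # infeasible exactly above the class maximum
    expect_null(rescale_heritability(m, min(1, h0 * 1.01)))
    expect_true(!is.null(rescale_heritability(m, h0 * 0.99)))
  }
})

test_that("joint heritability/prevalence rescale hits both targets", {
  set.seed(161)
  for (rep in 1:20) {
    mafs <- runif(2, 0.3, 0.5)
    m <- normalize_S(pre_penetrance_from_direction(point_select(2, mafs),
                                                   random_unit_vector(4)))
    h0 <- heritability(m)
    K0 <- prevalence(m)
    ident <- rescale_heritability_prevalence(m, h0, K0)
    expect_equal(ident$values, m$values, tolerance = 1e-9)
    out <- rescale_heritability_prevalence(m, h0 / 4, 0.5)
    if (!is.null(out)) {
      expect_equal(heritability(out), h0 / 4, tolerance = 1e-9)
      expect_equal(prevalence(out), 0.5, tolerance = 1e-9)
      expect_true(is_pure_strict(out, tol = 1e-9))
    }
    # heritability 1 with prevalence 0.25 is impossible for any table
    expect_null(rescale_heritability_prevalence(m, 1, 0.25))
  }
})

test_that("generated models satisfy every requested constraint", {
  set.seed(171)
  cases <- list(list(n = 2, h = 0.05, K = 0.5, reps = 40),
                list(n = 2, h = 0.01, K = NULL, reps = 40),
                list(n = 3, h = 0.05, K = NULL, reps = 30),
                list(n = 3, h = 0.01, K = 0.4, reps = 30),
                list(n = 4, h = 0.01, K = 0.5, reps = 15))
  for (cs in cases) {
    for (rep in seq_len(cs$reps)) {
      mafs <- runif(cs$n, 0.2, 0.5)
      res <- generate_model(model_constraints(cs$n, mafs, cs$h,
                                              prevalence = cs$K))
      expect_true(res$success)
      m <- res$model
      expect_true(is_pure_strict(m, tol = 1e-9))
      expect_equal(heritability(m), cs$h, tolerance = 1e-9)
      expect_equal(m$mafs, mafs)
      if (!is.null(cs$K)) {
        expect_equal(prevalence(m), cs$K, tolerance = 1e-12)
      }
    }
  }
})

test_that("a direction and its positive multiples give one model class", {
  set.seed(181)
  ps <- point_select(3, rep(0.4, 3))
  d <- random_unit_vector(8)
  ref <- normalize_S(pre_penetrance_from_direction(ps, d))
  for (c0 in c(0.5, 2)) {
    m <- normalize_S(pre_penetrance_from_direction(ps, c0 * d))
    expect_identical(m$values, ref$values)
  }
})

test_that("generation gets monotonically harder with target heritability", {
  set.seed(191)
  freqs <- vapply(c(0.01, 0.1, 0.3), function(h) {
    generation_frequency(model_constraints(3, rep(0.5, 3), h,
                                           prevalence = 0.5),
                         attempts = 400)$frequency
  }, numeric(1))
  expect_true(freqs[1] > freqs[2])
  expect_true(freqs[2] > freqs[3])
})

test_that("identical seeds reproduce identical model populations", {
  cons <- model_constraints(3, c(0.2, 0.3, 0.5), 0.02, prevalence = 0.4)
  set.seed(7)
  p1 <- generate_population(cons, 4)
  set.seed(7)
  p2 <- generate_population(cons, 4)
  expect_identical(p1, p2)
  # distinct slots carry distinct architectures
  vals <- lapply(p1$models, `[[`, "values")
  expect_equal(length(unique(vals)), 4)
})

test_that("exhaustion is reported per slot, not raised", {
  cons <- model_constraints(2, c(0.5, 0.5), 0.9, prevalence = 0.5,
                            attempt_limit = 5)
  set.seed(201)
  expect_warning(pop <- generate_population(cons, 3), "exhausted")
  expect_true(all(vapply(pop$models, is.null, logical(1))))
  expect_equal(pop$successes, 0)
})
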