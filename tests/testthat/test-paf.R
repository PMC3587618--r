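test_that("per-unit relative risk extrapolates log-linearly with a floor at 1", {
  expect_equal(rr_at(30, 1.06, 10, x0 = 20), 1.06)
  expect_equal(rr_at(20, 1.06, 10, x0 = 20), 1.0)
  expect_equal(rr_at(10, 1.06, 10, x0 = 20), 1.0)  # never protective
  # two log decades above the floor
  expect_equal(rr_at(100, 1.34, 1, x0 = 0.5, transform = "log10"),
               1.34^2)
  expect_equal(rr_at(0.2, 1.34, 1, x0 = 0, transform = "log10"), 1.0)
  expect_equal(rr_at(c(0, 10, 20), 1.08, 100), c(1, 1.08^0.1, 1.08^0.2))
  expect_error(rr_at(5, -1, 10), "positive")
  expect_error(rr_at(5, 1.1, 0), "unit")
})

test_that("categorical PAF matches the counterfactual-difference formula", {
  expect_equal(paf_categorical(0.19, 1.25), 0.0475 / 1.0475,
               tolerance = 1e-12)
  x <- 0.4354 * 0.8 + 0.4286 * 0.2
  expect_equal(paf_categorical(c(0.4354, 0.4286), c(1.8, 1.2)), x / (1 + x),
               tolerance = 1e-12)
  expect_equal(paf_categorical(c(0.2, 0.3), c(1, 1)), 0)
  # explicit counterfactual: shifting mass to the reference
  expect_equal(paf_categorical(0.5, 2, counterfactual_prevalences = 0.5), 0)
  expect_gt(paf_categorical(0.5, 2, counterfactual_prevalences = 0.2),
            0)
  expect_error(paf_categorical(c(0.7, 0.6), c(1.2, 1.3)), "sum")
  expect_error(paf_categorical(-0.1, 1.2), "negative")
})

test_that("all-reference categorical PAF equals the closed form to machine precision", {
  set.seed(42)
  for (i in 1:200) {
    k <- sample(1:4, 1)
    p <- runif(k); p <- p / sum(p) * runif(1, 0.1, 0.99)
    r <- exp(rnorm(k, 0, 0.5))
    x <- sum(p * (r - 1))
    expect_equal(paf_categorical(p, r), x / (1 + x), tolerance = 1e-12)
  }
})

test_that("categorical PAF is monotone in prevalence and relative risk", {
  set.seed(7)
  for (i in 1:50) {
    p <- runif(2, 0, 0.4); r <- exp(abs(rnorm(2, 0, 0.5)))
    base <- paf_categorical(p, r)
    expect_gte(paf_categorical(p + c(0.05, 0), r), base)
    expect_gte(paf_categorical(p, r + c(0.3, 0)), base)
    expect_gte(paf_categorical(p, r * 1.1), base)
  }
})

test_that("continuous PAF reduces to (RR-1)/RR for point exposures", {
  expect_equal(paf_continuous(dist_point(30), dist_point(20),
                              rr_unit = 1.06, unit = 10),
               (1.06^3 - 1.06^2) / 1.06^3, tolerance = 1e-12)
  # one unit above the counterfactual, both referenced to zero
  expect_equal(paf_continuous(dist_point(10), dist_point(0), 1.06, 10),
               0.06 / 1.06, tolerance = 1e-12)
  # identical exposure and counterfactual
  expect_equal(paf_continuous(dist_uniform(5, 25), dist_uniform(5, 25),
                              1.1, 10), 0)
  expect_error(paf_continuous(dist_point(1), dist_point(0), 1.1, 10,
                              n_quad = 4), "n_quad")
})

test_that("continuous PAF quadrature agrees with brute-force sampling", {
  # radon-style case: lognormal variability, RR per 100 units
  sp <- lognormal_from_mean_sd(14.4, 7.37)
  got <- paf_continuous(sp, dist_point(0), rr_unit = 1.08, unit = 100,
                        n_quad = 2048)
  set.seed(123)
  n <- 2e5
  x <- rlnorm(n, sp$params$meanlog, sp$params$sdlog)
  rr <- pmax(1.08^(x / 100), 1)
  mc_paf <- (mean(rr) - 1) / mean(rr)
  se <- sd(rr) / sqrt(n) / mean(rr)   # delta-method scale
  expect_lt(abs(got - mc_paf), 3 * se + 1e-6)
  # random spec / RR combinations
  set.seed(5)
  for (i in 1:5) {
    sp <- dist_uniform(runif(1, 0, 10), runif(1, 20, 60))
    rru <- runif(1, 1.01, 1.5)
    got <- paf_continuous(sp, dist_point(0), rru, 10, n_quad = 2048)
    x <- runif(2e5, sp$params$lower, sp$params$upper)
    rr <- rru^(x / 10)
    want <- (mean(rr) - 1) / mean(rr)
    expect_equal(got, want, tolerance = 3 * sd(rr) / sqrt(2e5) + 1e-5)
  }
})

test_that("multiplicative combination of PAFs has the complement-product form", {
  expect_equal(combine_pafs(c(0.5, 0.5)), 0.75)
  expect_equal(combine_pafs(0.3), 0.3)
  expect_equal(combine_pafs(c(0.302669, 0.027707)),
               1 - (1 - 0.302669) * (1 - 0.027707), tolerance = 1e-12)
  set.seed(9)
  for (i in 1:50) {
    p <- runif(sample(2:5, 1), 0, 0.8)
    got <- combine_pafs(p)
    expect_gte(got, max(p))
    expect_lte(got, sum(p))
    # order invariance and idempotence under appended zeros
    expect_equal(combine_pafs(sample(p)), got, tolerance = 1e-14)
    expect_equal(combine_pafs(c(p, 0, 0)), got, tolerance = 1e-14)
  }
  expect_error(combine_pafs(c(0.5, 1)), "< 1")
})

test_that("attributable cases scale the baseline and never exceed it", {
  expect_equal(attributable_cases(0.570, 81110), 46232.7)
  expect_equal(attributable_cases(0, 1e6), 0)
  expect_equal(attributable_cases(1, 28), 28)
  set.seed(2)
  p <- runif(100); d <- runif(100, 0, 1e5)
  expect_true(all(attributable_cases(p, d) <= d))
  expect_error(attributable_cases(1.2, 10), "paf")
  expect_error(attributable_cases(0.5, -1), "d_total")
})

test_that("fixed-fraction attribution mixes sex-specific case counts", {
  expect_equal(fixed_fraction_attribution(10, 4, 0.9, 0.25), 10)
  expect_equal(fixed_fraction_attribution(0, 0, 0.9, 0.25), 0)
  expect_equal(fixed_fraction_attribution(8, 0, 1, 1), 8)
  expect_error(fixed_fraction_attribution(-1, 0, 1, 1), ">= 0")
  expect_error(fixed_fraction_attribution(1, 1, 1.5, 0.2), "fractions")
})
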