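test_that("lognormal from median and CI matches the closed form and keeps the median", {
  cases <- list(
    # median, lcl, ucl, expected meanlog, expected sdlog
    list(1.25, 1.17, 1.32, 0.22314355, 0.03077301),
    list(2.28, 1.15, 4.53, 0.82417544, 0.34974112),
    list(1.0, 1.0, 1.0, 0.0, 0.0))
  for (cs in cases) {
    sp <- lognormal_from_median_ci(cs[[1]], cs[[2]], cs[[3]])
    expect_equal(sp$params$meanlog, cs[[4]], tolerance = 1e-7)
    expect_equal(sp$params$sdlog, cs[[5]], tolerance = 1e-7)
    # the spec's median is the published central estimate
    expect_equal(q_dist(sp, 0.5), cs[[1]], tolerance = 1e-12)
    # the CI *ratio* is reproduced by the 2.5/97.5 quantiles
    if (cs[[2]] < cs[[3]])
      expect_equal(q_dist(sp, 0.975) / q_dist(sp, 0.025),
                   cs[[3]] / cs[[2]], tolerance = 1e-9)
  }
  expect_error(lognormal_from_median_ci(1.2, 1.3, 1.5), "lcl")
  expect_error(lognormal_from_median_ci(1.2, -1, 1.5), "lcl")
  expect_error(lognormal_from_median_ci(1.2, 1.1, 1.1), "ucl")
})

test_that("lognormal from mean/sd is moment-matched", {
  for (cs in list(c(14.4, 7.37), c(22.5, 63.6))) {
    sp <- lognormal_from_mean_sd(cs[1], cs[2])
    s2 <- sp$params$sdlog^2
    # closed-form arithmetic moments of the fitted spec
    expect_equal(exp(sp$params$meanlog + s2 / 2), cs[1], tolerance = 1e-12)
    expect_equal(exp(sp$params$meanlog + s2 / 2) * sqrt(exp(s2) - 1),
                 cs[2], tolerance = 1e-12)
  }
  sp <- lognormal_from_mean_sd(14.4, 7.37)
  expect_equal(sp$params$meanlog, 2.5509011, tolerance = 1e-6)
  expect_equal(sp$params$sdlog, 0.4823423, tolerance = 1e-6)
  # Monte Carlo recovery of the input moments
  x <- q_dist(sp, ((1:1e5) - 0.5) / 1e5)
  expect_equal(mean(x), 14.4, tolerance = 0.01)
  expect_equal(sd(x), 7.37, tolerance = 0.02)
  # sd = 0 degenerates to a point mass
  sp0 <- lognormal_from_mean_sd(5, 0)
  expect_equal(unique(q_dist(sp0, c(0.01, 0.5, 0.99))), 5)
  expect_error(lognormal_from_mean_sd(-3, 1), "positive")
})

test_that("spec validation rejects malformed parameters", {
  expect_error(dist_uniform(2, 1), "lower")
  expect_error(dist_triangular(0, 5, 3), "mode")
  expect_error(dist_normal(0, -1), "sd")
  expect_error(dist_bernoulli(1.4), "prob")
  expect_error(dist_spec("uniform", lower = 0), "upper")
  expect_error(dist_spec("weird", value = 1))
})

test_that("LHS stratification puts one draw in each equiprobable stratum", {
  m <- sample_lhs(list(u = dist_uniform(0, 1)), n = 4, seed = 11)
  expect_equal(sort(floor(m[, "u"] * 4)), 0:3)
  m <- sample_lhs(list(u = dist_uniform(0, 1)), n = 100, seed = 5)
  expect_equal(sort(floor(m[, "u"] * 100)), 0:99)
  # point spec: all draws identical
  m <- sample_lhs(list(p = dist_point(3.7)), n = 100, seed = 1)
  expect_equal(m[, "p"], rep(3.7, 100))
  # lognormal sample median close to exp(meanlog)
  m <- sample_lhs(list(l = dist_lognormal(0, 0.5)), n = 1e4, seed = 3)
  expect_equal(median(m[, "l"]), 1.0, tolerance = 0.02)
})

test_that("sampling is reproducible and variables use independent substreams", {
  specs <- list(a = dist_uniform(0, 1), b = dist_normal(5, 2))
  m1 <- sample_lhs(specs, 50, seed = 7)
  m2 <- sample_lhs(specs, 50, seed = 7)
  expect_identical(m1, m2)
  expect_false(identical(sample_lhs(specs, 50, seed = 8), m1))
  # adding a variable does not perturb the others' draws
  m3 <- sample_lhs(c(specs, list(c = dist_uniform(2, 3))), 50, seed = 7)
  expect_identical(m3[, c("a", "b")], unclass(m1)[, c("a", "b")])
  expect_error(sample_lhs(specs, 0, seed = 1), "positive")
  expect_error(sample_lhs(list(dist_point(1)), 5, seed = 1), "names")
})

test_that("truncation renormalizes mass and never yields values below the bound", {
  sp <- dist_normal(50, 40, truncate_lower = 0)
  for (seed in 1:5) {
    x <- sample_lhs(list(x = sp), 500, seed = seed)[, "x"]
    expect_true(all(x >= 0))
  }
  # truncated quantiles span the conditional distribution
  expect_gt(q_dist(sp, 0), -1e-12)
  expect_equal(q_dist(sp, 1), Inf)
  # renormalization: median of truncated spec is the conditional median
  f0 <- pnorm(0, 50, 40)
  expect_equal(q_dist(sp, 0.5), qnorm(f0 + 0.5 * (1 - f0), 50, 40))
})

test_that("LHS and SRS estimates of a smooth functional agree within 3 SE", {
  specs <- list(u = dist_uniform(0, 2), t = dist_triangular(1, 2, 6),
                l = dist_lognormal(0.2, 0.4), nrm = dist_normal(10, 3),
                b = dist_bernoulli(0.3), p = dist_point(4))
  n <- 2000
  lhs_m <- sample_lhs(specs, n, seed = 31, method = "lhs")
  srs_m <- sample_lhs(specs, n, seed = 32, method = "srs")
  for (v in names(specs)) {
    g_l <- sqrt(abs(lhs_m[, v])); g_s <- sqrt(abs(srs_m[, v]))
    se <- sqrt(var(g_l) / n + var(g_s) / n)
    expect_lt(abs(mean(g_l) - mean(g_s)), max(3 * se, 1e-12))
  }
})

test_that("LHS mean estimator beats simple random sampling variance on uniforms", {
  n <- 64
  means <- sapply(1:50, function(s) c(
    lhs = mean(sample_lhs(list(u = dist_uniform(0, 1)), n, seed = s)[, "u"]),
    srs = mean(sample_lhs(list(u = dist_uniform(0, 1)), n, seed = s,
                          method = "srs")[, "u"])))
  expect_lt(var(means["lhs", ]), var(means["srs", ]))
})

test_that("hand-rolled LHS matches the lhs package's stratification contract", {
  # independent implementation of the same sampling plan: both place one
  # uniform sub-draw in each of n strata, so stratum occupancy must match
  library(lhs)
  n <- 32
  set.seed(99)
  ref <- lhs::randomLHS(n, 1)
  ours <- sample_lhs(list(u = dist_uniform(0, 1)), n, seed = 99)[, "u"]
  expect_equal(sort(floor(ref[, 1] * n)), sort(floor(ours * n)))
})

test_that("summarize_draws reports mean and interpolated 95% interval", {
  expect_equal(summarize_draws(rep(3.2, 10)),
               c(mean = 3.2, p2.5 = 3.2, p97.5 = 3.2))
  s <- summarize_draws(1:1000)
  expect_equal(s[["mean"]], 500.5)
  expect_equal(s[["p2.5"]], 25.975)
  expect_equal(s[["p97.5"]], 975.025)
  z <- sample_lhs(list(z = dist_normal(0, 1)), 1e5, seed = 2)[, "z"]
  expect_equal(summarize_draws(z)[["p2.5"]], qnorm(0.025), tolerance = 0.03)
  expect_error(summarize_draws(numeric(0)), "non-empty")
})
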