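test_that("results are bit-identical under the same seed and differ otherwise", {
  scen <- uae_scenario()
  mc <- mc_config(200, seed = 42)
  r1 <- run_scenario(scen, mc, routes = c("indoor_air", "drinking_water"))
  r2 <- run_scenario(scen, mc, routes = c("indoor_air", "drinking_water"))
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$draws, r2$draws)
  r3 <- run_scenario(scen, mc_config(200, seed = 43),
                     routes = c("indoor_air", "drinking_water"))
  expect_false(identical(r1$summary, r3$summary))
})

test_that("all-point routes collapse to zero-width intervals", {
  pair <- risk_pair("indoor_air", "x", "y", "visits", baseline = 1000,
    exposure = list(kind = "categorical", categories = list(
      list(name = "e", prevalence = dist_point(0.4)))),
    rr = list(form = "categorical", categories = list(
      list(name = "e", spec = dist_point(1.5)))))
  res <- run_route(route_model("indoor_air", list(pair)),
                   mc_config(100, seed = 1))
  s <- res$summary
  expect_equal(s$af_p2.5, s$af_p97.5)
  expect_equal(s$af_mean, 0.2 / 1.2, tolerance = 1e-12)
  expect_equal(length(unique(res$draws[[1]]$paf)), 1L)
})

test_that("drinking-water PAF matches an independent quadrature oracle", {
  scen <- uae_scenario()
  pair <- find_pair(scen, "microbial", "gastroenteritis", "visits")
  res <- run_route(route_model("drinking_water", list(pair)),
                   mc_config(1000, seed = 17))
  # 3-variable midpoint-quadrature oracle over (p1, RR1, RR2)
  n <- 40; u <- (1:n - 0.5) / n
  gr <- expand.grid(p1 = q_dist(dist_triangular(0.96, 0.98, 1), u),
                    r1 = qunif(u, 1, 4), r2 = qunif(u, 7.2, 10.2))
  x <- gr$p1 * (gr$r1 - 1) + (1 - gr$p1) * (gr$r2 - 1)
  oracle <- mean(x / (1 + x))
  expect_equal(oracle, 0.5689, tolerance = 1e-3)
  expect_equal(res$summary$af_mean, oracle, tolerance = 0.02)
})

test_that("doubling iterations moves the mean by less than 2 standard errors", {
  scen <- uae_scenario()
  pair <- find_pair(scen, "microbial", "gastroenteritis", "visits")
  rm <- route_model("drinking_water", list(pair))
  r1 <- run_route(rm, mc_config(1000, seed = 3))
  r2 <- run_route(rm, mc_config(2000, seed = 3))
  se <- sd(r1$draws[[1]]$paf) / sqrt(1000)
  expect_lt(abs(r1$summary$af_mean - r2$summary$af_mean), 2 * se)
})

test_that("LHS and SRS means agree within 3 combined SEs on bundled pairs", {
  scen <- uae_scenario()
  pairs <- list(
    find_pair(scen, "microbial", "gastroenteritis", "visits"),
    find_pair(scen, "ets", "leukemia", "visits"),
    find_pair(scen, "enterococci", "gastroenteritis", "visits"))
  ctx <- list(noncitizen_share = 0.81, dubai_share = 0.30,
              default_sex_split = 0.5)
  n <- 1500
  for (pair in pairs) {
    rm <- route_model(pair$route, list(pair))
    a <- run_route(rm, mc_config(n, seed = 21, sampler = "lhs"),
                   context = ctx)
    b <- run_route(rm, mc_config(n, seed = 22, sampler = "srs"),
                   context = ctx)
    se <- sqrt(var(a$draws[[1]]$paf) / n + var(b$draws[[1]]$paf) / n)
    expect_lt(abs(a$summary$af_mean - b$summary$af_mean), 3 * se)
  }
})

test_that("combination groups merge pollutants sharing an endpoint", {
  scen <- uae_scenario()
  res <- run_route(scen$routes[[which(vapply(scen$routes, `[[`,
    character(1), "route") == "indoor_air")]],
    mc_config(500, seed = 9),
    context = list(noncitizen_share = 0.81, dubai_share = 0.3,
                   default_sex_split = 0.5))
  s <- res$summary
  lung <- s[s$endpoint == "lung_cancer" & s$measure == "deaths" &
              !s$report_separately, ]
  expect_equal(nrow(lung), 1)           # ETS + incense merged
  expect_equal(lung$pollutant, "ets+incense")
  # combined PAF at least as large as each member's alone
  ets <- find_pair(scen, "ets", "lung_cancer", "deaths")
  alone <- run_route(route_model("indoor_air", list(ets)),
                     mc_config(500, seed = 9))
  expect_gt(lung$af_mean, alone$summary$af_mean)
  # draw-wise: combined count draws match 1-(1-a)(1-b) reconstruction
  inc <- find_pair(scen, "incense", "lung_cancer", "deaths")
  alone_inc <- run_route(route_model("indoor_air", list(inc)),
                         mc_config(500, seed = 9))
  # negative (protective) draws are floored at zero before combining
  reconstructed <- 1 - (1 - pmax(alone$draws[[1]]$paf, 0)) *
    (1 - pmax(alone_inc$draws[[1]]$paf, 0))
  expect_equal(res$draws[["indoor_air.lung_cancer.deaths"]]$paf,
               reconstructed, tolerance = 1e-12)
})

test_that("route totals are draw-wise sums excluding separately reported pairs", {
  scen <- uae_scenario()
  res <- run_scenario(scen, mc_config(300, seed = 13),
                      routes = "indoor_air")
  s <- res$summary
  for (ms in c("deaths", "visits")) {
    tot <- s[s$is_total & s$measure == ms, ]
    members <- s[!s$is_total & !s$report_separately & s$measure == ms, ]
    expect_equal(tot$count_mean, sum(members$count_mean),
                 tolerance = 1e-9)
    # formaldehyde and radon stay out of the totals
    seps <- s[!s$is_total & s$report_separately & s$measure == ms, ]
    expect_gt(nrow(seps), 0)
    expect_lt(sum(members$count_mean),
              sum(members$count_mean) + sum(seps$count_mean))
    # total interval comes from summed draws, not summed bounds
    key <- paste("indoor_air.Total", ms, sep = ".")
    expect_equal(summarize_draws(res$draws[[key]]$count)[["mean"]],
                 tot$count_mean)
  }
})

test_that("spatial pairs demand a grid and run on synthetic ones", {
  scen <- uae_scenario()
  outdoor <- scen$routes[[1]]
  expect_error(run_route(outdoor, mc_config(10, seed = 1)),
               "requires a grid")
  g <- generate_grid(60, 4.5e6, list(
    pm25 = list(mean_range = c(25, 80), sd_range = c(2, 12)),
    pm10 = list(mean_range = c(80, 250), sd_range = c(10, 40)),
    ozone = list(mean_range = c(20, 60), sd_range = c(3, 10))), seed = 6)
  res <- run_route(outdoor, mc_config(100, seed = 1), grid = g)
  s <- res$summary
  expect_equal(nrow(s), 4)   # PM10+O3 respiratory visits merged
  expect_true(all(s$af_mean > 0 & s$af_mean < 1))
  expect_true(all(s$count_mean <= s$baseline))
})
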