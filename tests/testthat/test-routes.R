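test_that("the bundled national scenario loads with full route coverage", {
  scen <- uae_scenario()
  expect_s3_class(scen, "ebd_scenario")
  expect_equal(length(scen$routes), 6)
  expect_equal(length(scenario_pairs(scen)), 39)
  expect_equal(scen$population$noncitizen_share, 0.81)
  # row manifest: every encoded pollutant-endpoint-measure combination
  got <- sort(vapply(scenario_pairs(scen), function(p)
    paste(p$route, p$pollutant, p$endpoint, p$measure, sep = "|"),
    character(1)))
  expect_false(anyDuplicated(got) > 0)
  # spot-check rows that anchor the published tables
  must_have <- c(
    "outdoor_air|pm25|all_cause_mortality_over30|deaths",
    "indoor_air|ets|cardiovascular_disease|visits",
    "indoor_air|incense|lung_cancer|deaths",
    "indoor_air|radon|lung_cancer|deaths",
    "occupational|asbestos|mesothelioma|visits",
    "drinking_water|microbial|gastroenteritis|visits",
    "coastal_water|enterococci|gastroenteritis|visits",
    "climate_change|ambient_temperature|cardiovascular_disease|deaths")
  expect_true(all(must_have %in% got))
  # radon is flagged for separate reporting; coastal Dubai doubling is on
  radon <- find_pair(scen, "radon", "lung_cancer", "deaths")
  expect_true(radon$report_separately)
  coastal <- find_pair(scen, "enterococci", "gastroenteritis", "visits")
  expect_true(coastal$exposure$dubai_double)
  expect_equal(length(coastal$exposure$months), 12)
})

test_that("scenario loading reports schema violations with their key path", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("name: empty\nroutes: []", f)
  scen <- load_scenario(f)
  expect_equal(length(scen$routes), 0)
  expect_equal(nrow(run_scenario(scen)$summary), 0)

  writeLines(c(
    "routes:",
    "- route: drinking_water",
    "  risk_pairs:",
    "  - pollutant: microbial",
    "    endpoint: gastro",
    "    measure: visits",
    "    baseline: 10",
    "    exposure:",
    "      kind: categorical",
    "      categories:",
    "      - name: g1",
    "        prevalence: {kind: triangular, lower: 1.0, mode: 0.98, upper: 0.9}",
    "    rr:",
    "      form: categorical",
    "      categories:",
    "      - name: g1",
    "        spec: {kind: point, value: 2}"), f)
  expect_error(load_scenario(f), "risk_pairs\\[1\\].*mode")

  writeLines(c(
    "routes:",
    "- route: indoor_air",
    "  risk_pairs:",
    "  - pollutant: x",
    "    endpoint: y",
    "    measure: visits",
    "    baseline: 1",
    "    exposure: {kind: categorical, categories: [{name: a, prevalence: {kind: wat, value: 1}}]}",
    "    rr: {form: categorical, categories: [{name: a, spec: {kind: point, value: 1}}]}"), f)
  expect_error(load_scenario(f), "unknown distribution kind")
  expect_error(load_scenario("missing.yaml"), "not found")
})

test_that("scenarios round-trip through serialization", {
  scen <- uae_scenario()
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(serialize_scenario(scen), f)
  scen2 <- load_scenario(f)
  expect_equal(serialize_scenario(scen2), serialize_scenario(scen))
  # and the reloaded scenario produces identical results
  mc <- mc_config(100, seed = 5)
  expect_equal(run_scenario(scen, mc, routes = "climate_change")$summary,
               run_scenario(scen2, mc, routes = "climate_change")$summary)
})

test_that("coastal builder reproduces the monthly closed form", {
  # all months at zero concentration: below the log10 floor, nothing
  # attributable
  pair0 <- build_coastal_model(
    monthly_conc = rep(list(dist_point(0)), 12),
    swim_prev = 0.062, rr_log10 = dist_point(1.34), baseline = 81110,
    dubai_double = FALSE)
  res0 <- run_route(route_model("coastal_water", list(pair0)),
                    mc_config(50, seed = 1))
  expect_equal(res0$summary$af_mean, 0)
  # constant 100/100 ml, everyone swims: PAF = (1.34^2-1)/1.34^2 monthly
  pair1 <- build_coastal_model(
    monthly_conc = rep(list(dist_point(100)), 12),
    swim_prev = 1.0, rr_log10 = dist_point(1.34), baseline = 81110,
    dubai_double = FALSE)
  res1 <- run_route(route_model("coastal_water", list(pair1)),
                    mc_config(50, seed = 1))
  expect_equal(res1$summary$af_mean, (1.34^2 - 1) / 1.34^2,
               tolerance = 1e-12)
  expect_error(build_coastal_model(rep(list(dist_point(1)), 11), 0.1,
                                   dist_point(1.3), 10), "12 monthly")
})

test_that("two-group water builder matches its closed form", {
  mk <- function(p1, r1, r2) build_two_group_water_model(
    dist_point(p1), dist_point(r1), dist_point(r2), baseline = 81110)
  run1 <- function(pair) run_route(route_model("drinking_water",
    list(pair)), mc_config(20, seed = 2))$summary
  expect_equal(run1(mk(1, 1, 9))$af_mean, 0)
  x <- 0.98 * 1.5 + 0.02 * 7.7
  expect_equal(run1(mk(0.98, 2.5, 8.7))$af_mean, x / (1 + x),
               tolerance = 1e-12)
})

test_that("tap-water builder mixes citizen and noncitizen prevalence", {
  ctx <- list(noncitizen_share = 0.81, dubai_share = 0,
              default_sex_split = 0.5)
  mk <- function(ct, nct, rr) build_tap_water_cancer_model(
    citizen_tap = ct, noncitizen_tap = nct, rr_male = rr, rr_female = rr,
    baseline = 929, endpoint = "bladder_cancer")
  run1 <- function(pair) run_route(route_model("drinking_water",
    list(pair)), mc_config(20, seed = 2), context = ctx)$summary
  # prevalence 0.19*0.105 + 0.81*0.902 = 0.7506
  p <- 0.19 * 0.105 + 0.81 * 0.902
  expect_equal(run1(mk(0.105, dist_point(0.902), dist_point(1.2)))$af_mean,
               0.2 * p / (1 + 0.2 * p), tolerance = 1e-12)
  # RR = 1 gives zero regardless of prevalence
  expect_equal(run1(mk(0.105, dist_point(0.902), dist_point(1)))$af_mean, 0)
  # all-citizen population with no tap use
  ctx0 <- ctx; ctx0$noncitizen_share <- 0
  pair <- mk(0, dist_point(0.9), dist_point(1.3))
  expect_equal(run_route(route_model("drinking_water", list(pair)),
    mc_config(20, seed = 2), context = ctx0)$summary$af_mean, 0)
})
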