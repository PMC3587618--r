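#' @title Scenario configuration: routes, risk pairs and builders
#' @description
#' A scenario is a declarative encoding of the whole assessment: six
#' exposure routes, each a list of risk pairs (one pollutant-endpoint
#' link), every uncertain quantity a [dist_spec()]. The bundled
#' `uae_2008.yaml` encodes the published parameter tables of the 2008
#' national assessment; [load_scenario()] parses and validates any file
#' with the same schema.
#' @name scenario
NULL

ROUTE_NAMES <- c("outdoor_air", "indoor_air", "occupational",
                 "drinking_water", "coastal_water", "climate_change")

# spec-node parsing ------------------------------------------------------

# Parse a YAML/JSON node into a dist_spec; `where` is the config path used
# in error messages. Sugar kinds lognormal_ci / lognormal_meansd map onto
# the published-summary converters. The raw node is kept in attr "src" so
# serialization round-trips byte-identically.
parse_spec <- function(node, where) {
  if (is_dist_spec(node)) return(node)
  if (is.numeric(node) && length(node) == 1L) {
    sp <- dist_point(node)
    attr(sp, "src") <- node
    return(sp)
  }
  if (!is.list(node) || is.null(node$kind))
    stop(sprintf("%s: distribution node must have a 'kind'", where),
         call. = FALSE)
  tl <- node$truncate_lower
  sp <- tryCatch(
    switch(node$kind,
      point = dist_point(node$value),
      uniform = dist_spec("uniform", lower = node$lower, upper = node$upper,
                          truncate_lower = tl),
      triangular = dist_spec("triangular", lower = node$lower,
                             mode = node$mode, upper = node$upper,
                             truncate_lower = tl),
      lognormal = dist_lognormal(node$meanlog, node$sdlog,
                                 truncate_lower = tl),
      normal = dist_normal(node$mean, node$sd, truncate_lower = tl),
      bernoulli = dist_bernoulli(node$prob),
      lognormal_ci = lognormal_from_median_ci(node$median, node$lcl,
                                              node$ucl),
      lognormal_meansd = lognormal_from_mean_sd(node$mean, node$sd),
      stop(sprintf("unknown distribution kind '%s'", node$kind),
           call. = FALSE)),
    error = function(e)
      stop(sprintf("%s: %s", where, conditionMessage(e)), call. = FALSE))
  attr(sp, "src") <- node
  sp
}

spec_to_node <- function(sp) {
  src <- attr(sp, "src")
  if (!is.null(src)) return(src)
  c(list(kind = sp$kind), sp$params,
    if (!is.null(sp$truncate_lower))
      list(truncate_lower = sp$truncate_lower))
}

# risk pairs -------------------------------------------------------------

#' Construct a risk pair
#'
#' One pollutant-to-endpoint link: an exposure model, a relative-risk
#' model, the baseline count the attributable fraction is applied to, and
#' an optional combination-group tag joining pollutants that act on the
#' same endpoint (merged multiplicatively by [combine_pafs()]).
#'
#' @param route exposure route name (one of the six route names).
#' @param pollutant pollutant name.
#' @param endpoint health endpoint name.
#' @param measure `"deaths"` or `"visits"`.
#' @param baseline baseline count for the endpoint (>= 0).
#' @param exposure exposure model: a list with a `kind` field, one of
#'   `"categorical"`, `"continuous_scalar"`, `"continuous_mixture"`,
#'   `"continuous_spatial"`, `"seasonal_swim"`, `"tap_water"`, `"none"`.
#' @param rr relative-risk model: a list with a `form` field, one of
#'   `"categorical"`, `"per_unit"`, `"fixed_fraction"`.
#' @param combine_group optional group id; pairs sharing a group (within
#'   one route, same endpoint and measure) are merged.
#' @param baseline_by_sex optional `list(male =, female =)` for
#'   fixed-fraction attribution.
#' @param baseline_scale optional multiplier in (0, 1\] restricting the
#'   baseline to a subpopulation (e.g. emirates with exposure data).
#' @param sex_split optional male share used to mix sex-specific RRs;
#'   defaults to the scenario's `default_sex_split`.
#' @param report_separately if `TRUE`, the pair is excluded from route
#'   totals and reported as a footnote line.
#' @param note free-text provenance / caveat note.
#' @return object of class `risk_pair`.
#' @export
risk_pair <- function(route, pollutant, endpoint, measure, baseline,
                      exposure, rr, combine_group = NULL,
                      baseline_by_sex = NULL, baseline_scale = NULL,
                      sex_split = NULL, report_separately = FALSE,
                      note = NULL) {
  route <- match.arg(route, ROUTE_NAMES)
  if (!measure %in% c("deaths", "visits"))
    stop("'measure' must be 'deaths' or 'visits'", call. = FALSE)
  if (!is.numeric(baseline) || baseline < 0)
    stop("'baseline' must be a non-negative count", call. = FALSE)
  if (is.null(exposure$kind) ||
      !exposure$kind %in% c("categorical", "continuous_scalar",
                            "continuous_mixture", "continuous_spatial",
                            "seasonal_swim", "tap_water", "none"))
    stop(sprintf("unknown exposure kind for %s/%s", pollutant, endpoint),
         call. = FALSE)
  if (is.null(rr$form) ||
      !rr$form %in% c("categorical", "per_unit", "fixed_fraction"))
    stop(sprintf("unknown rr form for %s/%s", pollutant, endpoint),
         call. = FALSE)
  structure(list(route = route, pollutant = pollutant, endpoint = endpoint,
                 measure = measure, baseline = baseline,
                 exposure = exposure, rr = rr,
                 combine_group = combine_group,
                 baseline_by_sex = baseline_by_sex,
                 baseline_scale = baseline_scale, sex_split = sex_split,
                 report_separately = isTRUE(report_separately),
                 note = note),
            class = "risk_pair")
}

pair_id <- function(pair)
  paste(pair$route, pair$pollutant, pair$endpoint, pair$measure, sep = ".")

#' Construct a route model
#'
#' @param route route name.
#' @param risk_pairs list of [risk_pair()] objects belonging to the route.
#' @param notes optional route-level notes.
#' @return object of class `route_model`.
#' @export
route_model <- function(route, risk_pairs, notes = NULL) {
  route <- match.arg(route, ROUTE_NAMES)
  for (p in risk_pairs) {
    if (!inherits(p, "risk_pair")) stop("all elements must be risk_pair",
                                        call. = FALSE)
    if (p$route != route)
      stop(sprintf("pair %s does not belong to route %s", pair_id(p), route),
           call. = FALSE)
  }
  # combination groups must stay within one endpoint x measure
  grp <- vapply(risk_pairs, function(p)
    if (is.null(p$combine_group)) NA_character_ else p$combine_group,
    character(1))
  for (g in unique(stats::na.omit(grp))) {
    members <- risk_pairs[which(grp == g)]
    em <- unique(vapply(members, function(p)
      paste(p$endpoint, p$measure), character(1)))
    if (length(em) > 1L)
      stop(sprintf("combine_group '%s' mixes endpoints: %s", g,
                   paste(em, collapse = "; ")), call. = FALSE)
    bl <- unique(vapply(members, function(p) p$baseline, numeric(1)))
    if (length(bl) > 1L)
      stop(sprintf("combine_group '%s' members disagree on baseline", g),
           call. = FALSE)
  }
  structure(list(route = route, risk_pairs = risk_pairs, notes = notes),
            class = "route_model")
}

# scenario loading -------------------------------------------------------

parse_exposure <- function(node, where) {
  kind <- node$kind
  if (is.null(kind)) stop(sprintf("%s: exposure needs a 'kind'", where),
                          call. = FALSE)
  out <- switch(kind,
    categorical = {
      if (is.null(node$categories))
        stop(sprintf("%s: categorical exposure needs 'categories'", where),
             call. = FALSE)
      n_rem <- 0L
      cats <- lapply(seq_along(node$categories), function(i) {
        cat <- node$categories[[i]]
        w <- sprintf("%s/categories[%d]", where, i)
        prev <- if (identical(cat$prevalence, "remainder")) {
          n_rem <<- n_rem + 1L
          "remainder"
        } else parse_spec(cat$prevalence, paste0(w, "/prevalence"))
        list(name = cat$name %||% paste0("cat", i), prevalence = prev)
      })
      if (n_rem > 1L)
        stop(sprintf("%s: at most one 'remainder' category", where),
             call. = FALSE)
      list(kind = kind, categories = cats)
    },
    continuous_scalar = list(
      kind = kind,
      spec = parse_spec(node$spec, paste0(where, "/spec")),
      counterfactual = if (is.null(node$counterfactual)) dist_point(0)
        else parse_spec(node$counterfactual,
                        paste0(where, "/counterfactual"))),
    continuous_mixture = {
      comps <- lapply(seq_along(node$components), function(i) {
        cm <- node$components[[i]]
        w <- sprintf("%s/components[%d]", where, i)
        if (is.null(cm$weight) || cm$weight < 0)
          stop(sprintf("%s: needs a non-negative 'weight'", w),
               call. = FALSE)
        list(weight = cm$weight,
             spec = parse_spec(cm$spec, paste0(w, "/spec")))
      })
      wsum <- sum(vapply(comps, `[[`, numeric(1), "weight"))
      if (abs(wsum - 1) > 1e-6)
        stop(sprintf("%s: component weights must sum to 1", where),
             call. = FALSE)
      list(kind = kind, components = comps,
           counterfactual = if (is.null(node$counterfactual)) dist_point(0)
             else parse_spec(node$counterfactual,
                             paste0(where, "/counterfactual")))
    },
    continuous_spatial = {
      if (is.null(node$pollutant))
        stop(sprintf("%s: spatial exposure needs 'pollutant'", where),
             call. = FALSE)
      list(kind = kind, pollutant = node$pollutant,
           background = parse_spec(node$background,
                                   paste0(where, "/background")))
    },
    seasonal_swim = {
      if (length(node$months) != 12L)
        stop(sprintf("%s: seasonal_swim needs 12 monthly distributions (got %d)",
                     where, length(node$months)), call. = FALSE)
      months <- lapply(seq_len(12L), function(m)
        parse_spec(node$months[[m]], sprintf("%s/months[%d]", where, m)))
      if (is.null(node$swim_prevalence))
        stop(sprintf("%s: seasonal_swim needs 'swim_prevalence'", where),
             call. = FALSE)
      list(kind = kind, months = months,
           swim_prevalence = node$swim_prevalence,
           dubai_double = isTRUE(node$dubai_double))
    },
    tap_water = {
      if (is.null(node$citizen_tap))
        stop(sprintf("%s: tap_water needs 'citizen_tap'", where),
             call. = FALSE)
      list(kind = kind, citizen_tap = node$citizen_tap,
           noncitizen_tap = parse_spec(node$noncitizen_tap,
                                       paste0(where, "/noncitizen_tap")))
    },
    none = list(kind = "none"),
    stop(sprintf("%s: unknown exposure kind '%s'", where, kind),
         call. = FALSE))
  out
}

parse_rr <- function(node, where) {
  form <- node$form
  if (is.null(form)) stop(sprintf("%s: rr needs a 'form'", where),
                          call. = FALSE)
  switch(form,
    categorical = {
      cats <- lapply(seq_along(node$categories), function(i) {
        cat <- node$categories[[i]]
        w <- sprintf("%s/categories[%d]", where, i)
        if (!is.null(cat$spec_male) || !is.null(cat$spec_female)) {
          if (is.null(cat$spec_male) || is.null(cat$spec_female))
            stop(sprintf("%s: need both spec_male and spec_female", w),
                 call. = FALSE)
          list(name = cat$name %||% paste0("cat", i),
               spec_male = parse_spec(cat$spec_male, paste0(w, "/spec_male")),
               spec_female = parse_spec(cat$spec_female,
                                        paste0(w, "/spec_female")))
        } else {
          list(name = cat$name %||% paste0("cat", i),
               spec = parse_spec(cat$spec, paste0(w, "/spec")))
        }
      })
      list(form = form, categories = cats)
    },
    per_unit = {
      if (is.null(node$unit) || node$unit <= 0)
        stop(sprintf("%s: per_unit rr needs a positive 'unit'", where),
             call. = FALSE)
      tr <- node$transform %||% "linear"
      if (!tr %in% c("linear", "log10"))
        stop(sprintf("%s: transform must be 'linear' or 'log10'", where),
             call. = FALSE)
      list(form = form,
           spec = parse_spec(node$spec, paste0(where, "/spec")),
           unit = node$unit, transform = tr, floor = node$floor %||% 1)
    },
    fixed_fraction = {
      fm <- node$male; ff <- node$female
      if (is.null(fm) || is.null(ff) || fm < 0 || fm > 1 || ff < 0 || ff > 1)
        stop(sprintf("%s: fixed_fraction needs 'male' and 'female' in [0,1]",
                     where), call. = FALSE)
      list(form = form, male = fm, female = ff)
    },
    stop(sprintf("%s: unknown rr form '%s'", where, form), call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a scenario configuration
#'
#' Parses and validates a YAML (or JSON) scenario file into a list of
#' [route_model()] objects plus scenario-level context (population shares,
#' default sex split). Every distribution node is validated on load;
#' errors name the offending key path.
#'
#' @param config_path path to a scenario YAML file; the bundled 2008
#'   national scenario ships as
#'   `system.file("extdata", "uae_2008.yaml", package = "ebdpaf")`.
#' @return object of class `ebd_scenario`: a list with elements `name`,
#'   `population`, `default_sex_split`, `routes` (list of `route_model`).
#' @export
load_scenario <- function(config_path) {
  if (!file.exists(config_path))
    stop(sprintf("scenario file not found: %s", config_path), call. = FALSE)
  raw <- yaml::read_yaml(config_path)
  pop <- raw$population %||% list()
  scen <- list(
    name = raw$name %||% basename(config_path),
    description = raw$description,
    population = list(
      total = pop$total %||% NA_real_,
      noncitizen_share = pop$noncitizen_share %||% 0.5,
      dubai_share = pop$dubai_share %||% 0),
    default_sex_split = (raw$default_sex_split %||% list(male = 0.5))$male,
    routes = list())
  routes <- raw$routes %||% list()
  scen$routes <- lapply(seq_along(routes), function(ri) {
    rt <- routes[[ri]]
    wroute <- sprintf("routes[%d]", ri)
    if (is.null(rt$route))
      stop(sprintf("%s: missing 'route' name", wroute), call. = FALSE)
    pairs <- lapply(seq_along(rt$risk_pairs), function(pi) {
      nd <- rt$risk_pairs[[pi]]
      w <- sprintf("%s(%s)/risk_pairs[%d]", wroute, rt$route, pi)
      for (fld in c("pollutant", "endpoint", "measure", "baseline"))
        if (is.null(nd[[fld]]))
          stop(sprintf("%s: missing '%s'", w, fld), call. = FALSE)
      tryCatch(
        risk_pair(route = rt$route, pollutant = nd$pollutant,
                  endpoint = nd$endpoint, measure = nd$measure,
                  baseline = nd$baseline,
                  exposure = parse_exposure(nd$exposure,
                                            paste0(w, "/exposure")),
                  rr = parse_rr(nd$rr, paste0(w, "/rr")),
                  combine_group = nd$combine_group,
                  baseline_by_sex = nd$baseline_by_sex,
                  baseline_scale = nd$baseline_scale,
                  sex_split = nd$sex_split,
                  report_separately = isTRUE(nd$report_separately),
                  note = nd$note),
        error = function(e)
          stop(sprintf("%s: %s", w, conditionMessage(e)), call. = FALSE))
    })
    route_model(rt$route, pairs, notes = rt$notes)
  })
  class(scen) <- "ebd_scenario"
  scen
}

#' @export
print.ebd_scenario <- function(x, ...) {
  np <- sum(vapply(x$routes, function(r) length(r$risk_pairs), integer(1)))
  cat(sprintf("<ebd_scenario> %s: %d routes, %d risk pairs\n",
              x$name, length(x$routes), np))
  for (r in x$routes)
    cat(sprintf("  %-15s %d pairs\n", r$route, length(r$risk_pairs)))
  invisible(x)
}

#' All risk pairs of a scenario as a flat list
#' @param scenario an `ebd_scenario`.
#' @return list of `risk_pair` objects.
#' @export
scenario_pairs <- function(scenario)
  unlist(lapply(scenario$routes, `[[`, "risk_pairs"), recursive = FALSE)

# serialization ----------------------------------------------------------

exposure_to_node <- function(ex) {
  switch(ex$kind,
    categorical = list(kind = "categorical", categories =
      lapply(ex$categories, function(cat)
        list(name = cat$name,
             prevalence = if (identical(cat$prevalence, "remainder"))
               "remainder" else spec_to_node(cat$prevalence)))),
    continuous_scalar = list(kind = ex$kind,
      spec = spec_to_node(ex$spec),
      counterfactual = spec_to_node(ex$counterfactual)),
    continuous_mixture = list(kind = ex$kind,
      components = lapply(ex$components, function(cm)
        list(weight = cm$weight, spec = spec_to_node(cm$spec))),
      counterfactual = spec_to_node(ex$counterfactual)),
    continuous_spatial = list(kind = ex$kind, pollutant = ex$pollutant,
      background = spec_to_node(ex$background)),
    seasonal_swim = list(kind = ex$kind,
      months = lapply(ex$months, spec_to_node),
      swim_prevalence = ex$swim_prevalence,
      dubai_double = ex$dubai_double),
    tap_water = list(kind = ex$kind, citizen_tap = ex$citizen_tap,
      noncitizen_tap = spec_to_node(ex$noncitizen_tap)),
    none = list(kind = "none"))
}

rr_to_node <- function(rr) {
  switch(rr$form,
    categorical = list(form = "categorical", categories =
      lapply(rr$categories, function(cat)
        if (!is.null(cat$spec)) list(name = cat$name,
                                     spec = spec_to_node(cat$spec))
        else list(name = cat$name,
                  spec_male = spec_to_node(cat$spec_male),
                  spec_female = spec_to_node(cat$spec_female)))),
    per_unit = list(form = "per_unit", spec = spec_to_node(rr$spec),
                    unit = rr$unit, transform = rr$transform,
                    floor = rr$floor),
    fixed_fraction = list(form = "fixed_fraction", male = rr$male,
                          female = rr$female))
}

#' Serialize a scenario back to its configuration list form
#'
#' Inverse of [load_scenario()] up to key order; `serialize_scenario()`
#' returns the list, suitable for `yaml::write_yaml()`.
#'
#' @param scenario an `ebd_scenario`.
#' @return a plain list mirroring the YAML schema.
#' @export
serialize_scenario <- function(scenario) {
  drop_null <- function(x) x[!vapply(x, is.null, logical(1))]
  list(name = scenario$name,
       description = scenario$description,
       population = scenario$population,
       default_sex_split = list(male = scenario$default_sex_split),
       routes = lapply(scenario$routes, function(rt)
         drop_null(list(route = rt$route, notes = rt$notes,
              risk_pairs = lapply(rt$risk_pairs, function(p)
                drop_null(list(
                  pollutant = p$pollutant, endpoint = p$endpoint,
                  measure = p$measure, baseline = p$baseline,
                  exposure = exposure_to_node(p$exposure),
                  rr = rr_to_node(p$rr),
                  combine_group = p$combine_group,
                  baseline_by_sex = p$baseline_by_sex,
                  baseline_scale = p$baseline_scale,
                  sex_split = p$sex_split,
                  report_separately = if (p$report_separately) TRUE,
                  note = p$note))))))) |> drop_null()
}

# builders ---------------------------------------------------------------

#' Population-weighted swim prevalence
#'
#' Collapses stratified swimming prevalences (citizen strata by age/sex
#' with within-citizen shares; noncitizen strata likewise) into one
#' population-level prevalence using the noncitizen population share.
#'
#' @param swim_prevalence nested list: `citizen` and `noncitizen`, each a
#'   named list of strata with `share` (within-group share, summing to 1)
#'   and `prevalence`.
#' @param noncitizen_share noncitizen share of the total population.
#' @return single prevalence in \[0, 1\].
#' @export
swim_prevalence_weighted <- function(swim_prevalence, noncitizen_share) {
  grp_prev <- function(grp) {
    if (is.numeric(grp)) return(grp)
    sh <- vapply(grp, `[[`, numeric(1), "share")
    pv <- vapply(grp, `[[`, numeric(1), "prevalence")
    if (abs(sum(sh) - 1) > 1e-6)
      stop("stratum shares must sum to 1", call. = FALSE)
    sum(sh * pv)
  }
  (1 - noncitizen_share) * grp_prev(swim_prevalence$citizen) +
    noncitizen_share * grp_prev(swim_prevalence$noncitizen)
}

#' Build the coastal-water gastroenteritis risk pair
#'
#' Recreational-water illness from fecal-indicator bacteria: each month's
#' beach concentration is a distribution (one draw per iteration), the
#' dose response is a per-log10 relative risk with a concentration floor
#' of 1 organism/100 ml, and the monthly attributable fractions among the
#' whole population (swimmers at the population-weighted swim prevalence)
#' are averaged with equal monthly weights. With `dubai_double = TRUE`,
#' the Dubai population share is exposed to doubled concentrations.
#'
#' @param monthly_conc list of 12 [dist_spec()] concentration
#'   distributions (organisms/100 ml), January to December.
#' @param swim_prev either a single prevalence or the nested stratum list
#'   accepted by [swim_prevalence_weighted()].
#' @param rr_log10 `dist_spec` for the RR per log10 concentration.
#' @param baseline annual gastroenteritis visit count.
#' @param dubai_double double concentrations for the Dubai share?
#' @param measure outcome measure, default `"visits"`.
#' @return a [risk_pair()] on the `coastal_water` route.
#' @export
build_coastal_model <- function(monthly_conc, swim_prev, rr_log10, baseline,
                                dubai_double = TRUE, measure = "visits") {
  if (length(monthly_conc) != 12L)
    stop(sprintf("need 12 monthly concentration distributions, got %d",
                 length(monthly_conc)), call. = FALSE)
  monthly_conc <- lapply(monthly_conc, parse_spec, where = "monthly_conc")
  risk_pair(route = "coastal_water", pollutant = "enterococci",
            endpoint = "gastroenteritis", measure = measure,
            baseline = baseline,
            exposure = list(kind = "seasonal_swim", months = monthly_conc,
                            swim_prevalence = swim_prev,
                            dubai_double = isTRUE(dubai_double)),
            rr = list(form = "per_unit",
                      spec = parse_spec(rr_log10, "rr_log10"),
                      unit = 1, transform = "log10", floor = 1))
}

#' Build the two-group drinking-water gastroenteritis risk pair
#'
#' The population splits into a group with access to regulated water
#' supply and sanitation (fraction `group1_frac`, low relative risk) and
#' the complement with improved-but-unregulated water and no sanitation
#' (high relative risk), against an all-at-minimal-risk counterfactual:
#' `PAF = (p1(RR1-1) + p2(RR2-1)) / (1 + p1(RR1-1) + p2(RR2-1))`.
#'
#' @param group1_frac `dist_spec` for the regulated-access population
#'   fraction; group 2 is the remainder.
#' @param rr_group1,rr_group2 `dist_spec`s for the per-group relative
#'   risks.
#' @param baseline annual gastroenteritis count.
#' @param measure `"visits"` (default) or `"deaths"`.
#' @return a [risk_pair()] on the `drinking_water` route.
#' @export
build_two_group_water_model <- function(group1_frac, rr_group1, rr_group2,
                                        baseline, measure = "visits") {
  risk_pair(route = "drinking_water", pollutant = "microbial",
            endpoint = "gastroenteritis", measure = measure,
            baseline = baseline,
            exposure = list(kind = "categorical", categories = list(
              list(name = "regulated",
                   prevalence = parse_spec(group1_frac, "group1_frac")),
              list(name = "unregulated", prevalence = "remainder"))),
            rr = list(form = "categorical", categories = list(
              list(name = "regulated",
                   spec = parse_spec(rr_group1, "rr_group1")),
              list(name = "unregulated",
                   spec = parse_spec(rr_group2, "rr_group2")))))
}

#' Build a chlorination by-product cancer risk pair
#'
#' Exposure is drinking chlorinated tap water; the exposed prevalence per
#' draw mixes a fixed citizen tap-water share with a sampled noncitizen
#' share: `p = citizen_share * citizen_tap + (1 - citizen_share) * U`,
#' and the sex-specific relative risks are mixed by the endpoint's sex
#' split.
#'
#' @param citizen_tap fixed fraction of citizens drinking tap water.
#' @param noncitizen_tap `dist_spec` for the noncitizen tap-water
#'   fraction.
#' @param rr_male,rr_female `dist_spec`s for the sex-specific RRs.
#' @param baseline baseline count.
#' @param endpoint endpoint name, e.g. `"bladder_cancer"`.
#' @param measure `"deaths"` or `"visits"`.
#' @param sex_split optional male share for RR mixing.
#' @return a [risk_pair()] on the `drinking_water` route.
#' @export
build_tap_water_cancer_model <- function(citizen_tap, noncitizen_tap,
                                         rr_male, rr_female, baseline,
                                         endpoint, measure = "visits",
                                         sex_split = NULL) {
  if (citizen_tap < 0 || citizen_tap > 1)
    stop("'citizen_tap' must be in [0, 1]", call. = FALSE)
  risk_pair(route = "drinking_water", pollutant = "tthm",
            endpoint = endpoint, measure = measure, baseline = baseline,
            exposure = list(kind = "tap_water", citizen_tap = citizen_tap,
                            noncitizen_tap = parse_spec(noncitizen_tap,
                                                        "noncitizen_tap")),
            rr = list(form = "categorical", categories = list(
              list(name = "exposed",
                   spec_male = parse_spec(rr_male, "rr_male"),
                   spec_female = parse_spec(rr_female, "rr_female")))),
            sex_split = sex_split)
}
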