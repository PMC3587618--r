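#' Monte Carlo configuration
#'
#' @param iterations number of Monte Carlo iterations (default 1000, the
#'   point at which results stabilise for scenarios of this size).
#' @param seed integer root seed; every random input derives its own
#'   substream from it.
#' @param sampler `"lhs"` (Latin hypercube, default) or `"srs"` (simple
#'   random sampling, for comparisons).
#' @param n_quad quadrature points for continuous-exposure integration
#'   (default 512).
#' @return object of class `mc_config`.
#' @export
mc_config <- function(iterations = 1000, seed = 1,
                      sampler = c("lhs", "srs"), n_quad = 512) {
  sampler <- match.arg(sampler)
  if (!is.numeric(iterations) || iterations < 1)
    stop("'iterations' must be >= 1", call. = FALSE)
  structure(list(iterations = as.integer(iterations),
                 seed = as.integer(seed), sampler = sampler,
                 n_quad = n_quad),
            class = "mc_config")
}

# expected RR over an exposure distribution, vectorized over rr draws;
# pointwise no-protective floor at RR = 1, matching rr_at()
e_rr_quad <- function(spec, rr, unit, transform, floor, n_quad) {
  u <- (seq_len(n_quad) - 0.5) / n_quad
  x <- q_dist(spec, u)
  if (any(!is.finite(x)))
    stop(sprintf("quadrature failed for distribution '%s'", spec$kind),
         call. = FALSE)
  e <- if (transform == "linear") pmax(x, 0) / unit
       else pmax(log10(pmax(x, floor)) - log10(floor), 0) / unit
  m <- exp(e %o% log(rr))      # n_quad x n_draws
  colMeans(pmax(m, 1))
}

mix_sex_rr <- function(draws, id, cat, sex_split) {
  if (!is.null(cat$spec)) return(draws[, paste0(id, "|rr|", cat$name)])
  sex_split * draws[, paste0(id, "|rrm|", cat$name)] +
    (1 - sex_split) * draws[, paste0(id, "|rrf|", cat$name)]
}

rr_cat_specs <- function(id, rr) {
  specs <- list()
  for (cat in rr$categories) {
    if (!is.null(cat$spec)) {
      specs[[paste0(id, "|rr|", cat$name)]] <- cat$spec
    } else {
      specs[[paste0(id, "|rrm|", cat$name)]] <- cat$spec_male
      specs[[paste0(id, "|rrf|", cat$name)]] <- cat$spec_female
    }
  }
  specs
}

# Per-pair Monte Carlo evaluation: returns list(paf, count) draw vectors.
evaluate_pair <- function(pair, mc, context, grid = NULL) {
  id <- pair_id(pair)
  n <- mc$iterations
  ex <- pair$exposure
  rr <- pair$rr
  sex_split <- pair$sex_split %||% context$default_sex_split
  baseline <- pair$baseline * (pair$baseline_scale %||% 1)
  draw <- function(specs) sample_lhs(specs, n, mc$seed, method = mc$sampler)

  if (rr$form == "fixed_fraction") {
    bs <- pair$baseline_by_sex
    if (is.null(bs))
      stop(sprintf("%s: fixed_fraction attribution needs 'baseline_by_sex'",
                   id), call. = FALSE)
    count <- fixed_fraction_attribution(bs$male, bs$female, rr$male,
                                        rr$female)
    paf <- if (pair$baseline > 0) count / pair$baseline else 0
    return(list(paf = rep(paf, n), count = rep(count, n)))
  }

  paf <- switch(ex$kind,
    categorical = {
      if (rr$form != "categorical")
        stop(sprintf("%s: categorical exposure needs categorical rr", id),
             call. = FALSE)
      k <- length(ex$categories)
      if (length(rr$categories) != k)
        stop(sprintf("%s: exposure and rr category counts differ", id),
             call. = FALSE)
      specs <- rr_cat_specs(id, rr)
      rem <- integer(0)
      for (i in seq_len(k)) {
        cat <- ex$categories[[i]]
        if (identical(cat$prevalence, "remainder")) rem <- c(rem, i)
        else specs[[paste0(id, "|prev|", cat$name)]] <- cat$prevalence
      }
      draws <- draw(specs)
      P <- matrix(NA_real_, n, k)
      for (i in seq_len(k))
        if (!i %in% rem)
          P[, i] <- draws[, paste0(id, "|prev|", ex$categories[[i]]$name)]
      if (length(rem))
        P[, rem] <- pmax(1 - rowSums(P[, -rem, drop = FALSE]), 0)
      R <- vapply(seq_len(k), function(i)
        mix_sex_rr(draws, id, rr$categories[[i]], sex_split),
        numeric(n))
      paf_categorical(matrix(P, n, k), matrix(R, n, k))
    },
    tap_water = {
      specs <- rr_cat_specs(id, rr)
      specs[[paste0(id, "|prev|tap")]] <- ex$noncitizen_tap
      draws <- draw(specs)
      ncs <- context$noncitizen_share
      p <- (1 - ncs) * ex$citizen_tap + ncs * draws[, paste0(id, "|prev|tap")]
      R <- mix_sex_rr(draws, id, rr$categories[[1L]], sex_split)
      paf_categorical(matrix(p, n, 1L), matrix(R, n, 1L))
    },
    continuous_scalar = {
      draws <- draw(stats::setNames(list(rr$spec), paste0(id, "|rr")))
      paf_continuous(ex$spec, ex$counterfactual, draws[, 1L], rr$unit,
                     transform = rr$transform, floor = rr$floor,
                     n_quad = mc$n_quad)
    },
    continuous_mixture = {
      draws <- draw(stats::setNames(list(rr$spec), paste0(id, "|rr")))
      rrv <- draws[, 1L]
      e_obs <- Reduce(`+`, lapply(ex$components, function(cm)
        cm$weight * e_rr_quad(cm$spec, rrv, rr$unit, rr$transform,
                              rr$floor, mc$n_quad)))
      e_cf <- e_rr_quad(ex$counterfactual, rrv, rr$unit, rr$transform,
                        rr$floor, mc$n_quad)
      (e_obs - e_cf) / e_obs
    },
    continuous_spatial = {
      if (is.null(grid))
        stop(sprintf("%s: spatial exposure requires a grid (see load_grid)",
                     id), call. = FALSE)
      specs <- stats::setNames(list(rr$spec, ex$background),
                               paste0(id, c("|rr", "|background")))
      draws <- draw(specs)
      U <- local({
        old <- if (exists(".Random.seed", globalenv()))
          get(".Random.seed", globalenv()) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
        set.seed(substream_seed(mc$seed, paste0(id, "|cells")))
        matrix(stats::runif(n * nrow(grid)), n, nrow(grid))
      })
      vapply(seq_len(n), function(i)
        paf_spatial(grid, ex$pollutant, draws[i, 1L], draws[i, 2L],
                    rr$unit, cell_u = U[i, ]),
        numeric(1))
    },
    seasonal_swim = {
      p_swim <- if (is.numeric(ex$swim_prevalence)) ex$swim_prevalence
        else swim_prevalence_weighted(ex$swim_prevalence,
                                      context$noncitizen_share)
      specs <- stats::setNames(list(rr$spec), paste0(id, "|rr"))
      for (m in seq_len(12L))
        specs[[sprintf("%s|conc|m%02d", id, m)]] <- ex$months[[m]]
      draws <- draw(specs)
      rrv <- draws[, paste0(id, "|rr")]
      C <- draws[, sprintf("%s|conc|m%02d", id, seq_len(12L)), drop = FALSE]
      month_paf <- function(conc) {
        lg <- log10(pmax(conc, rr$floor)) - log10(rr$floor)
        rr_c <- pmax(exp((lg / rr$unit) * log(rrv)), 1)
        x <- p_swim * (rr_c - 1)
        x / (1 + x)
      }
      ds <- if (isTRUE(ex$dubai_double)) context$dubai_share else 0
      pafm <- (1 - ds) * month_paf(C) + ds * month_paf(2 * C)
      rowMeans(pafm)
    },
    stop(sprintf("%s: cannot evaluate exposure kind '%s'", id, ex$kind),
         call. = FALSE))

  list(paf = paf, count = attributable_cases(pmin(pmax(paf, 0), 1),
                                             baseline))
}

default_context <- function()
  list(noncitizen_share = 0.5, dubai_share = 0, default_sex_split = 0.5)

scenario_context <- function(scenario)
  list(noncitizen_share = scenario$population$noncitizen_share,
       dubai_share = scenario$population$dubai_share,
       default_sex_split = scenario$default_sex_split)

#' Run the Monte Carlo for one exposure route
#'
#' Evaluates every risk pair of the route, merges combination groups
#' (pollutants acting on the same endpoint) by [combine_pafs()] on the
#' per-draw attributable fractions, and summarizes each resulting
#' endpoint as mean and 2.5/97.5 percentile interval of the PAF and
#' attributable-count draws.
#'
#' @param route a [route_model()].
#' @param mc an [mc_config()].
#' @param context scenario-level context (population shares, default sex
#'   split); taken from the scenario by [run_scenario()], defaults
#'   otherwise.
#' @param grid an `exposure_grid`, required when the route contains
#'   spatial exposure pairs.
#' @return object of class `ebd_result_set`: `summary` (one data-frame
#'   row per endpoint) and `draws` (per-endpoint PAF and count draw
#'   vectors).
#' @export
run_route <- function(route, mc = mc_config(), context = NULL,
                      grid = NULL) {
  stopifnot(inherits(route, "route_model"))
  if (is.null(context)) context <- default_context()
  pairs <- route$risk_pairs
  if (length(pairs) == 0L)
    return(structure(list(summary = empty_summary(), draws = list()),
                     class = "ebd_result_set"))
  evals <- lapply(pairs, evaluate_pair, mc = mc, context = context,
                  grid = grid)
  keys <- vapply(pairs, function(p)
    p$combine_group %||% pair_id(p), character(1))
  out_rows <- list(); out_draws <- list()
  for (key in unique(keys)) {
    idx <- which(keys == key)
    members <- pairs[idx]
    p1 <- members[[1L]]
    baseline <- p1$baseline * (p1$baseline_scale %||% 1)
    if (length(idx) == 1L) {
      paf <- evals[[idx]]$paf
      count <- evals[[idx]]$count
    } else {
      pafm <- vapply(evals[idx], `[[`, numeric(mc$iterations), "paf")
      paf <- combine_pafs(pmin(pmax(pafm, 0), 1 - 1e-12))
      count <- attributable_cases(paf, baseline)
    }
    sp <- summarize_draws(paf); sc <- summarize_draws(count)
    draw_key <- paste(p1$route, p1$endpoint, p1$measure, sep = ".")
    if (draw_key %in% names(out_draws))   # e.g. separately reported pair
      draw_key <- paste(draw_key, p1$pollutant, sep = ".")
    out_rows[[key]] <- data.frame(
      route = p1$route, endpoint = p1$endpoint, measure = p1$measure,
      pollutant = paste(vapply(members, `[[`, character(1), "pollutant"),
                        collapse = "+"),
      baseline = baseline,
      af_mean = sp[["mean"]], af_p2.5 = sp[["p2.5"]],
      af_p97.5 = sp[["p97.5"]],
      count_mean = sc[["mean"]], count_p2.5 = sc[["p2.5"]],
      count_p97.5 = sc[["p97.5"]],
      report_separately = any(vapply(members, `[[`, logical(1),
                                     "report_separately")),
      is_total = FALSE, draw_key = draw_key, stringsAsFactors = FALSE)
    out_draws[[draw_key]] <- list(paf = paf, count = count)
  }
  summary <- do.call(rbind, out_rows)
  rownames(summary) <- NULL
  structure(list(summary = summary, draws = out_draws),
            class = "ebd_result_set")
}

empty_summary <- function()
  data.frame(route = character(), endpoint = character(),
             measure = character(), pollutant = character(),
             baseline = numeric(), af_mean = numeric(),
             af_p2.5 = numeric(), af_p97.5 = numeric(),
             count_mean = numeric(), count_p2.5 = numeric(),
             count_p97.5 = numeric(), report_separately = logical(),
             is_total = logical(), draw_key = character(),
             stringsAsFactors = FALSE)

#' Run the full scenario
#'
#' Runs every route (each route's burden is estimated separately — PAFs
#' are never combined across routes) and appends a Total row per route
#' and measure: the draw-wise sum of the endpoint attributable-count
#' draws, so the total's interval reflects the joint draws rather than
#' summed endpoint bounds. Pairs flagged `report_separately` (e.g. radon,
#' whose exposure data cover only part of the country) are excluded from
#' totals.
#'
#' @param scenario an `ebd_scenario` from [load_scenario()], or a list of
#'   [route_model()]s.
#' @param mc an [mc_config()].
#' @param grid optional `exposure_grid` for spatial pairs.
#' @param routes optional character vector of route names to run.
#' @return an `ebd_result_set` covering all requested routes plus total
#'   rows.
#' @export
run_scenario <- function(scenario, mc = mc_config(), grid = NULL,
                         routes = NULL) {
  if (inherits(scenario, "ebd_scenario")) {
    context <- scenario_context(scenario)
    rms <- scenario$routes
  } else {
    context <- default_context()
    rms <- scenario
  }
  if (!is.null(routes))
    rms <- Filter(function(r) r$route %in% routes, rms)
  summaries <- list(); draws <- list()
  for (rm in rms) {
    res <- run_route(rm, mc = mc, context = context, grid = grid)
    if (nrow(res$summary) == 0L) next
    s <- res$summary
    draws <- c(draws, res$draws)
    for (ms in unique(s$measure)) {
      keep <- which(s$measure == ms & !s$report_separately & !s$is_total)
      if (length(keep) == 0L) next
      total_draws <- Reduce(`+`, lapply(draws[s$draw_key[keep]], `[[`,
                                        "count"))
      st <- summarize_draws(total_draws)
      total_key <- paste(rm$route, "Total", ms, sep = ".")
      s <- rbind(s, data.frame(
        route = rm$route, endpoint = "Total", measure = ms,
        pollutant = "", baseline = sum(s$baseline[keep]),
        af_mean = NA_real_, af_p2.5 = NA_real_, af_p97.5 = NA_real_,
        count_mean = st[["mean"]], count_p2.5 = st[["p2.5"]],
        count_p97.5 = st[["p97.5"]], report_separately = FALSE,
        is_total = TRUE, draw_key = total_key, stringsAsFactors = FALSE))
      draws[[total_key]] <- list(paf = NULL, count = total_draws)
    }
    summaries[[rm$route]] <- s
  }
  summary <- if (length(summaries)) do.call(rbind, summaries)
             else empty_summary()
  rownames(summary) <- NULL
  structure(list(summary = summary, draws = draws,
                 mc = mc),
            class = c("ebd_results", "ebd_result_set"))
}

#' @export
print.ebd_result_set <- function(x, ...) {
  s <- x$summary
  if (nrow(s) == 0L) { cat("<ebd results> (empty)\n"); return(invisible(x)) }
  cat(sprintf("<ebd results> %d endpoint rows\n", sum(!s$is_total)))
  s$af <- ifelse(is.na(s$af_mean), "",
                 sprintf("%.1f%%", 100 * s$af_mean))
  s$attributable <- sprintf("%s (%s-%s)",
    format_count(s$count_mean), format_count(s$count_p2.5),
    format_count(s$count_p97.5))
  print(s[, c("route", "endpoint", "measure", "af", "attributable")],
        row.names = FALSE)
  invisible(x)
}
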