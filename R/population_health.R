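#' Validate a baseline health table
#'
#' Baseline deaths / health-care-facility visits by endpoint, optionally
#' stratified (emirate, sex, citizenship, age band). Columns: `endpoint`,
#' `measure` (`"deaths"` or `"visits"`), `count`, plus any of `emirate`,
#' `sex`, `citizenship`, `age_band`.
#'
#' @param df data frame of baseline records.
#' @return the validated data frame, class `baseline_health`.
#' @export
as_baseline_health <- function(df) {
  req <- c("endpoint", "measure", "count")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(sprintf("baseline table missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (!all(df$measure %in% c("deaths", "visits")))
    stop("'measure' must be 'deaths' or 'visits'", call. = FALSE)
  if (any(df$count < 0)) stop("baseline counts must be >= 0", call. = FALSE)
  structure(df, class = c("baseline_health", "data.frame"))
}

#' Extrapolate stratum-specific death rates to the rest of the country
#'
#' Death registration is complete only in the reference region, so
#' national baselines are built by computing death rates per
#' gender-citizenship stratum in the reference region and applying those
#' rates to the population of the same strata elsewhere, then summing the
#' observed and expected counts.
#'
#' All three inputs are data frames with stratum columns `sex` and
#' `citizenship`; `abu_dhabi_deaths` additionally has `endpoint`,
#' `measure` and `count` (deaths), the population tables have
#' `population`.
#'
#' @param abu_dhabi_deaths observed stratified deaths in the reference
#'   emirate.
#' @param abu_dhabi_pop reference-emirate population by stratum.
#' @param other_pop population of the remaining emirates by stratum.
#' @return a national [as_baseline_health()] table, one row per endpoint x
#'   measure x stratum, with an `origin` column (`observed` / `expected`).
#' @export
extrapolate_death_rates <- function(abu_dhabi_deaths, abu_dhabi_pop,
                                    other_pop) {
  key <- c("sex", "citizenship")
  for (nm in c("abu_dhabi_deaths", "abu_dhabi_pop", "other_pop")) {
    df <- get(nm)
    miss <- setdiff(key, names(df))
    if (length(miss))
      stop(sprintf("'%s' missing stratum column(s): %s", nm,
                   paste(miss, collapse = ", ")), call. = FALSE)
  }
  strata_of <- function(df) unique(paste(df$sex, df$citizenship, sep = "/"))
  need <- strata_of(abu_dhabi_deaths)
  for (nm in c("abu_dhabi_pop", "other_pop")) {
    have <- strata_of(get(nm))
    miss <- setdiff(need, have)
    if (length(miss))
      stop(sprintf("'%s' missing strata: %s", nm,
                   paste(miss, collapse = ", ")), call. = FALSE)
  }
  rate_tab <- merge(abu_dhabi_deaths, abu_dhabi_pop, by = key)
  if (any(rate_tab$population <= 0 & rate_tab$count > 0))
    stop("zero population in a stratum with observed deaths", call. = FALSE)
  rate_tab$rate <- ifelse(rate_tab$population > 0,
                          rate_tab$count / rate_tab$population, 0)
  expected <- merge(rate_tab[, c(key, "endpoint", "measure", "rate")],
                    other_pop, by = key)
  expected$count <- expected$rate * expected$population
  expected$origin <- "expected"
  observed <- abu_dhabi_deaths
  observed$origin <- "observed"
  cols <- c("endpoint", "measure", "sex", "citizenship", "count", "origin")
  out <- rbind(observed[, cols], expected[, cols])
  as_baseline_health(out[order(out$endpoint, out$origin, out$sex,
                               out$citizenship), ])
}

#' National endpoint totals from a stratified baseline table
#'
#' @param baseline a [as_baseline_health()] table.
#' @return data frame with one row per endpoint x measure and the summed
#'   count.
#' @export
baseline_totals <- function(baseline) {
  agg <- stats::aggregate(count ~ endpoint + measure, data = baseline, sum)
  agg[order(agg$endpoint), ]
}

#' Scale insurance-claims visit counts to the full population and year
#'
#' Claims data cover only the insured share of one emirate's population
#' and sometimes only part of the year. The national annual estimate is
#' `visits * period_factor / coverage * population_factor`, where
#' `period_factor` annualizes a partial observation window (e.g. 2 for a
#' half year assumed to hold 50% of annual visits), `coverage` is the
#' insured fraction of the source population, and `population_factor`
#' scales from the source emirate to the whole country.
#'
#' @param visits observed claim count (>= 0).
#' @param coverage insured fraction of the source population, in (0, 1\].
#' @param period_factor annualization multiplier (> 0), default 1.
#' @param population_factor source-to-national population multiplier
#'   (> 0), default 1.
#' @return scaled visit count (real-valued).
#' @examples
#' scale_claims(10581, coverage = 0.73, period_factor = 2)
#' @export
scale_claims <- function(visits, coverage, period_factor = 1,
                         population_factor = 1) {
  if (any(visits < 0)) stop("'visits' must be >= 0", call. = FALSE)
  if (coverage <= 0 || coverage > 1)
    stop("'coverage' must be in (0, 1]", call. = FALSE)
  if (period_factor <= 0 || population_factor <= 0)
    stop("scaling factors must be positive", call. = FALSE)
  visits * period_factor / coverage * population_factor
}
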