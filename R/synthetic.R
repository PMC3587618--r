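#' Generate a synthetic exposure grid
#'
#' Emulates a national concentration grid: `n_cells` cells with a
#' log-uniform population allocation (a few dense urban cells, many
#' sparse desert cells) summing to `pop_total`, split into citizen and
#' noncitizen counts, and per-pollutant concentration mean/sd parameters
#' drawn uniformly from the supplied ranges. Deterministic under `seed`.
#'
#' @param n_cells number of grid cells (>= 1).
#' @param pop_total total population across the grid.
#' @param pollutants named list; one entry per pollutant with elements
#'   `mean_range` and `sd_range` (each `c(lo, hi)`), e.g.
#'   `list(pm25 = list(mean_range = c(20, 80), sd_range = c(2, 15)))`.
#' @param seed integer seed.
#' @param citizen_share citizen fraction of each cell's population.
#' @param spatial_corr if `TRUE`, concentration means get exponential
#'   (AR(1)-style along cell index) spatial autocorrelation rather than
#'   independent draws — used to probe sensitivity to the independence
#'   assumption; off by default.
#' @return an `exposure_grid` (see [as_exposure_grid()]).
#' @examples
#' g <- generate_grid(50, 1e5,
#'   list(pm25 = list(mean_range = c(20, 80), sd_range = c(0, 10))),
#'   seed = 1)
#' @export
generate_grid <- function(n_cells, pop_total, pollutants, seed,
                          citizen_share = 0.19, spatial_corr = FALSE) {
  if (n_cells < 1) stop("'n_cells' must be >= 1", call. = FALSE)
  if (pop_total <= 0) stop("'pop_total' must be positive", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(substream_seed(seed, "grid"))
  w <- exp(stats::runif(n_cells, 0, log(1000)))
  pop <- round(pop_total * w / sum(w))
  pop[1L] <- pop[1L] + (pop_total - sum(pop))   # absorb rounding remainder
  pop <- pmax(pop, 0)
  df <- data.frame(cell_id = seq_len(n_cells),
                   pop_citizen = round(pop * citizen_share),
                   pop_noncitizen = pop - round(pop * citizen_share))
  for (pl in names(pollutants)) {
    mr <- pollutants[[pl]]$mean_range
    sr <- pollutants[[pl]]$sd_range
    if (length(mr) != 2L || length(sr) != 2L)
      stop(sprintf("pollutant '%s': mean_range and sd_range must be c(lo, hi)",
                   pl), call. = FALSE)
    if (spatial_corr && n_cells > 1L) {
      # exponential-kernel correlation along the cell index
      z <- stats::rnorm(n_cells)
      rho <- exp(-1 / 10)
      for (i in 2:n_cells) z[i] <- rho * z[i - 1L] + sqrt(1 - rho^2) * z[i]
      u <- stats::pnorm(z)
      df[[paste0(pl, "_mean")]] <- mr[1L] + u * (mr[2L] - mr[1L])
    } else {
      df[[paste0(pl, "_mean")]] <- stats::runif(n_cells, mr[1L], mr[2L])
    }
    df[[paste0(pl, "_sd")]] <- stats::runif(n_cells, sr[1L], sr[2L])
  }
  as_exposure_grid(df)
}

#' Generate a scenario with analytically known attributable fraction
#'
#' Solves for exposure/relative-risk parameters that produce exactly
#' `target_paf` and packages them as a one-pair route, so the whole
#' pipeline (sampling, PAF evaluation, attribution, summarization) can be
#' checked against ground truth:
#' \describe{
#'   \item{categorical}{single exposed category at prevalence `p`;
#'     `RR = 1 + target / (p * (1 - target))` inverts the closed form.}
#'   \item{continuous}{uniform exposure with zero counterfactual and a
#'     linear per-unit RR chosen so the population-average RR satisfies
#'     `(E[RR] - 1) / E[RR] = target` (solved numerically on the
#'     quadrature form).}
#'   \item{spatial}{a generated grid with `sd = 0` and a common
#'     concentration 10 units above a point background;
#'     `rr_unit = 1 / (1 - target)` per 10 units.}
#' }
#' Relative risks are point specs, so the ground truth is exact and any
#' pipeline deviation is a defect, not Monte Carlo noise.
#'
#' @param target_paf target attributable fraction in \[0, 1).
#' @param structure `"categorical"`, `"continuous"` or `"spatial"`.
#' @param seed integer seed (used by the grid generator and stored).
#' @param baseline baseline count for the pair (default 10000).
#' @param prevalence exposed prevalence for the categorical structure.
#' @return list with `route` (a [route_model()]), `grid` (spatial
#'   structure only, else `NULL`), and `ground_truth`
#'   (`list(paf, attributable)`).
#' @export
generate_known_paf_scenario <- function(target_paf,
                                        structure = c("categorical",
                                                      "continuous",
                                                      "spatial"),
                                        seed = 1, baseline = 10000,
                                        prevalence = 0.5) {
  structure <- match.arg(structure)
  if (target_paf < 0 || target_paf >= 1)
    stop("'target_paf' must be in [0, 1)", call. = FALSE)
  grid <- NULL
  if (structure == "categorical") {
    if (target_paf > 0 && prevalence <= 0)
      stop("positive target unreachable with zero prevalence",
           call. = FALSE)
    rr <- if (target_paf == 0) 1
          else 1 + target_paf / (prevalence * (1 - target_paf))
    pair <- risk_pair(route = "indoor_air", pollutant = "synthetic",
      endpoint = "synthetic_endpoint", measure = "visits",
      baseline = baseline,
      exposure = list(kind = "categorical", categories = list(
        list(name = "exposed", prevalence = dist_point(prevalence)))),
      rr = list(form = "categorical", categories = list(
        list(name = "exposed", spec = dist_point(rr)))))
  } else if (structure == "continuous") {
    exposure <- dist_uniform(5, 15)
    unit <- 10
    f <- function(rru) {
      paf_continuous(exposure, dist_point(0), rru, unit,
                     n_quad = 4096) - target_paf
    }
    rru <- if (target_paf == 0) 1
           else stats::uniroot(f, c(1 + 1e-12, 1e6), tol = 1e-12)$root
    pair <- risk_pair(route = "indoor_air", pollutant = "synthetic",
      endpoint = "synthetic_endpoint", measure = "visits",
      baseline = baseline,
      exposure = list(kind = "continuous_scalar", spec = exposure,
                      counterfactual = dist_point(0)),
      rr = list(form = "per_unit", spec = dist_point(rru), unit = unit,
                transform = "linear", floor = 1))
  } else {
    grid <- generate_grid(64, 1e5,
      list(syn = list(mean_range = c(30, 30), sd_range = c(0, 0))),
      seed = seed)
    rru <- if (target_paf == 0) 1 else 1 / (1 - target_paf)
    pair <- risk_pair(route = "outdoor_air", pollutant = "synthetic",
      endpoint = "synthetic_endpoint", measure = "deaths",
      baseline = baseline,
      exposure = list(kind = "continuous_spatial", pollutant = "syn",
                      background = dist_point(20)),
      rr = list(form = "per_unit", spec = dist_point(rru), unit = 10,
                transform = "linear", floor = 1))
  }
  list(route = route_model(pair$route, list(pair)), grid = grid,
       seed = seed,
       ground_truth = list(paf = target_paf,
                           attributable = target_paf * baseline))
}

#' Generate a stratified baseline health table
#'
#' Expected counts `rate * population` per stratum. By default noise is
#' off (deterministic expected-count mode) so downstream checks are
#' sharp; with `noise = TRUE` counts are binomial draws with the stratum
#' rate as the success probability.
#'
#' @param rates data frame with stratum columns (`sex`, `citizenship`),
#'   `endpoint`, `measure` and a `rate` column (per-person annual rate,
#'   >= 0).
#' @param population data frame with the same stratum columns and a
#'   `population` column.
#' @param seed integer seed (only consumed when `noise = TRUE`).
#' @param noise draw binomial sampling noise?
#' @return a [as_baseline_health()] table with one row per rate stratum.
#' @export
generate_baseline_health <- function(rates, population, seed = 1,
                                     noise = FALSE) {
  if (any(rates$rate < 0)) stop("rates must be >= 0", call. = FALSE)
  key <- intersect(c("sex", "citizenship", "emirate"), names(rates))
  tab <- merge(rates, population, by = key)
  if (noise) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(substream_seed(seed, "baseline_health"))
    tab$count <- stats::rbinom(nrow(tab), size = round(tab$population),
                               prob = pmin(tab$rate, 1))
  } else {
    tab$count <- tab$rate * tab$population
  }
  as_baseline_health(tab[, c("endpoint", "measure", key, "count")])
}

#' Write an exposure grid to CSV
#'
#' Companion to [load_grid()]; generated grids round-trip through this
#' writer byte-identically under a fixed seed.
#'
#' @param grid an `exposure_grid`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  utils::write.csv(as.data.frame(grid), path, row.names = FALSE)
  invisible(path)
}
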