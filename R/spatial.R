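#' Load a gridded exposure table
#'
#' Reads a delimited text file of spatial grid cells with population by
#' citizenship and per-pollutant concentration parameters. Expected
#' columns: `cell_id`, `pop_citizen`, `pop_noncitizen`, and one
#' `<pollutant>_mean` / `<pollutant>_sd` pair per pollutant (units are
#' whatever the matching relative risk is expressed in, e.g. ug/m3 for
#' particulates, ppb for ozone; concentration basis — annual or
#' daily-average — follows the epidemiologic study the RR comes from).
#'
#' @param path path to a CSV file.
#' @return a data frame of class `exposure_grid`, one row per cell, with
#'   attribute `pollutants` listing the pollutant names found.
#' @export
load_grid <- function(path) {
  if (!file.exists(path)) stop(sprintf("grid file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_exposure_grid(df)
}

#' Validate a data frame as an exposure grid
#'
#' @param df data frame with the columns documented in [load_grid()].
#' @return the validated `exposure_grid`.
#' @export
as_exposure_grid <- function(df) {
  if (nrow(df) == 0L) stop("exposure grid is empty", call. = FALSE)
  req <- c("cell_id", "pop_citizen", "pop_noncitizen")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(sprintf("grid missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  if (anyDuplicated(df$cell_id))
    stop(sprintf("duplicate cell id(s): %s",
                 paste(unique(df$cell_id[duplicated(df$cell_id)]),
                       collapse = ", ")), call. = FALSE)
  if (any(df$pop_citizen < 0 | df$pop_noncitizen < 0))
    stop("cell populations must be >= 0", call. = FALSE)
  if (sum(df$pop_citizen + df$pop_noncitizen) <= 0)
    stop("grid has no population", call. = FALSE)
  means <- grep("_mean$", names(df), value = TRUE)
  polls <- sub("_mean$", "", means)
  for (pl in polls) {
    mcol <- paste0(pl, "_mean"); scol <- paste0(pl, "_sd")
    if (!scol %in% names(df))
      stop(sprintf("grid has %s but no %s", mcol, scol), call. = FALSE)
    bad <- which(!is.finite(df[[mcol]]) | !is.finite(df[[scol]]))
    if (length(bad))
      stop(sprintf("non-finite %s parameters in cell(s): %s", pl,
                   paste(df$cell_id[bad], collapse = ", ")), call. = FALSE)
    neg <- which(df[[scol]] < 0)
    if (length(neg))
      stop(sprintf("negative %s_sd in cell(s): %s", pl,
                   paste(df$cell_id[neg], collapse = ", ")), call. = FALSE)
  }
  if (length(polls) == 0L)
    stop("grid has no <pollutant>_mean/_sd columns", call. = FALSE)
  structure(df, pollutants = polls,
            class = c("exposure_grid", "data.frame"))
}

#' Population-weighted spatial PAF for one Monte Carlo draw
#'
#' Attributable fraction over a concentration grid: each cell's
#' concentration is drawn from a normal with the cell's mean/sd truncated
#' at zero (cells with `sd = 0` are deterministic), converted to a
#' relative risk against a single national background level shared by all
#' cells within the iteration, and the cell RRs are population-weighted:
#' \deqn{PAF = \frac{\sum_c w_c RR_c - \sum_c w_c}{\sum_c w_c RR_c}}
#' Cell draws are independent across cells; the background draw is a
#' counterfactual policy level, so it is drawn once per iteration, not per
#' cell. Cells at or below the background contribute RR = 1.
#'
#' Uses the current RNG stream for the cell draws; seed upstream (the
#' Monte Carlo engine derives a substream per risk pair).
#'
#' @param grid an `exposure_grid` (see [load_grid()]).
#' @param pollutant pollutant name, matching the grid's `<pollutant>_mean`
#'   column.
#' @param rr_draw relative risk per `unit` for this iteration (> 0).
#' @param background_draw background concentration for this iteration.
#' @param unit exposure step size the RR refers to.
#' @param cell_u optional vector of uniforms (one per cell) used for the
#'   cell concentration draws; supplied by the engine for reproducible
#'   streams, defaults to fresh `runif` draws.
#' @return a single PAF value.
#' @examples
#' g <- as_exposure_grid(data.frame(cell_id = 1, pop_citizen = 100,
#'   pop_noncitizen = 400, pm25_mean = 30, pm25_sd = 0))
#' paf_spatial(g, "pm25", rr_draw = 1.06, background_draw = 20, unit = 10)
#' @export
paf_spatial <- function(grid, pollutant, rr_draw, background_draw, unit,
                        cell_u = NULL) {
  if (!inherits(grid, "exposure_grid")) grid <- as_exposure_grid(grid)
  if (!pollutant %in% attr(grid, "pollutants"))
    stop(sprintf("pollutant '%s' not in grid (has: %s)", pollutant,
                 paste(attr(grid, "pollutants"), collapse = ", ")),
         call. = FALSE)
  if (rr_draw <= 0) stop("'rr_draw' must be positive", call. = FALSE)
  w <- grid$pop_citizen + grid$pop_noncitizen
  mu <- grid[[paste0(pollutant, "_mean")]]
  sd <- grid[[paste0(pollutant, "_sd")]]
  if (is.null(cell_u)) cell_u <- stats::runif(nrow(grid))
  if (length(cell_u) != nrow(grid))
    stop("'cell_u' must have one value per cell", call. = FALSE)
  # inverse-CDF draw from normal truncated below at 0
  f0 <- stats::pnorm(0, mu, sd)
  x <- ifelse(sd > 0,
              stats::qnorm(f0 + cell_u * (1 - f0), mu, sd),
              pmax(mu, 0))
  rrs <- rr_at(x, rr_draw, unit, x0 = background_draw)
  s <- sum(w * rrs)
  (s - sum(w)) / s
}
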