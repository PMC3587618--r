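#' Display rounding for attributable counts
#'
#' Rounds to the precision pattern national burden tables use: counts of
#' 10,000 and above to three significant figures, 1,000-9,999 to the
#' nearest 10, below 1,000 to the nearest integer. Raw values are always
#' retained in the result object; this is display-only.
#'
#' @param x numeric count(s).
#' @return rounded numeric vector.
#' @export
round_display <- function(x) {
  out <- round(x)
  mid <- !is.na(x) & x >= 1000 & x < 10000
  hi <- !is.na(x) & x >= 10000
  out[mid] <- round(x[mid] / 10) * 10
  out[hi] <- signif(x[hi], 3)
  out
}

format_count <- function(x)
  ifelse(is.na(x), "", formatC(round_display(x), format = "d",
                               big.mark = ","))

format_af <- function(af)
  ifelse(is.na(af), "", sprintf("%.1f%%", 100 * af))

#' Write result tables
#'
#' Writes the per-endpoint summary of an `ebd_result_set` in a fixed
#' column order. Formats: `csv` (raw numeric columns), `json` (the same
#' rows as an array of objects), `markdown` (display-rounded tables
#' grouped by route with Total rows, one block per measure).
#'
#' @param results an `ebd_result_set` (from [run_route()] or
#'   [run_scenario()]).
#' @param path output file path.
#' @param format `"csv"`, `"json"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_tables <- function(results, path, format = c("csv", "json",
                                                   "markdown")) {
  format <- match.arg(format)
  s <- results$summary
  if (is.null(s) || nrow(s) == 0L)
    stop("empty result set: nothing to write", call. = FALSE)
  cols <- c("route", "endpoint", "measure", "pollutant", "baseline",
            "af_mean", "af_p2.5", "af_p97.5", "count_mean", "count_p2.5",
            "count_p97.5", "report_separately", "is_total")
  s <- s[, cols]
  switch(format,
    csv = utils::write.csv(s, path, row.names = FALSE),
    json = jsonlite::write_json(s, path, dataframe = "rows",
                                auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
    markdown = {
      con <- file(path, "w"); on.exit(close(con))
      for (ms in unique(s$measure)) {
        unit <- if (ms == "deaths") "deaths" else "health-care facility visits"
        writeLines(sprintf("## Attributable %s\n", unit), con)
        writeLines(paste("| Exposure route | Endpoint | Attributable",
                         "fraction | Attributable count | CI lower |",
                         "CI upper |"), con)
        writeLines("|---|---|---|---|---|---|", con)
        sm <- s[s$measure == ms, ]
        for (i in seq_len(nrow(sm))) {
          r <- sm[i, ]
          nm <- if (r$report_separately)
            paste0(r$endpoint, " (reported separately)") else r$endpoint
          writeLines(sprintf("| %s | %s | %s | %s | %s | %s |",
            r$route, nm, format_af(r$af_mean), format_count(r$count_mean),
            format_count(r$count_p2.5), format_count(r$count_p97.5)), con)
        }
        writeLines("", con)
      }
    })
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run: scenario path, Monte
#' Carlo configuration, package version, timestamp and the output files
#' written.
#'
#' @param path manifest file path (JSON).
#' @param scenario_path path of the scenario file that was run.
#' @param mc the [mc_config()] used.
#' @param outputs character vector of output file paths.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, scenario_path, mc, outputs) {
  jsonlite::write_json(list(
    scenario = scenario_path,
    iterations = mc$iterations, seed = mc$seed, sampler = mc$sampler,
    n_quad = mc$n_quad,
    package_version = as.character(utils::packageVersion("ebdpaf")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(outputs)),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
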