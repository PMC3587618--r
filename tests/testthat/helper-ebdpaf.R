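# shared fixtures, built in code

uae_scenario_path <- function()
  system.file("extdata", "uae_2008.yaml", package = "ebdpaf")

uae_scenario <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_scenario(uae_scenario_path())
    cache
  }
})

# tiny deterministic grid for spatial tests
tiny_grid <- function(conc = c(30, 30), sd = c(0, 0), pop = c(500, 500)) {
  as_exposure_grid(data.frame(
    cell_id = seq_along(conc),
    pop_citizen = round(pop * 0.2),
    pop_noncitizen = pop - round(pop * 0.2),
    pm_mean = conc, pm_sd = sd))
}

# pull one risk pair out of the bundled scenario by fields
find_pair <- function(scenario, pollutant, endpoint, measure) {
  for (p in scenario_pairs(scenario))
    if (p$pollutant == pollutant && p$endpoint == endpoint &&
        p$measure == measure)
      return(p)
  stop("pair not found")
}
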