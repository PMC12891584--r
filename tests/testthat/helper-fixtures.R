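# Shared fixture builders. Everything is generated in code from fixed
# seeds; no files are read.

# A small site with simulated observations from a known truth model.
make_test_site <- function(spec, true_params, years = 2001:2020,
                           noise_sd = 0, seed = 11, site_seed = 1L,
                           config = NULL) {
  if (is.null(config))
    config <- synthetic_config(n_sites = max(site_seed, 1L), years = years,
                               seed = seed)
  site <- generate_site_dataset(config, site_seed)
  simulate_observed_dfs(site, spec, true_params, noise_sd = noise_sd,
                        seed = seed + 100L)
}

# Deterministic 365-day temperature series: warm before the solstice,
# then a linear autumn cooling ramp. Guarantees every model family finds
# an onset and a crossing for reasonable parameters.
ramp_year <- function(summer = 25, fall_rate = 0.25) {
  doy <- 1:365
  pmax(summer - fall_rate * pmax(doy - 180, 0), -15)
}

small_pso <- function(particles = 20L, iterations = 50L)
  pso_config(particles = particles, iterations = iterations)
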