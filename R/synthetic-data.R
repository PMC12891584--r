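# Seeded synthetic site generator. Emulates the statistical structure of
# the real inputs -- a seasonal temperature cycle with AR(1) noise and a
# warming trend, monotonically growing noisy ALAN radiance, seasonal
# monthly precipitation and shortwave radiation, annual leaf-unfolding
# dates, exponentially growing GDP -- and simulates observed senescence
# dates from a known model so every downstream stage has ground truth.

#' Synthetic experiment configuration
#'
#' Defaults describe a 22-year (2001-2022) record for mid-latitude
#' Northern-Hemisphere cities: mean annual temperature 10 degC with a
#' 12 degC seasonal amplitude peaking near day 200, AR(1) day-to-day
#' noise (coefficient 0.7, stationary sd 2 degC), a 0.03 degC/yr warming
#' trend, ALAN starting at 5 nW cm-2 sr-1 and growing 0.4 per year, and
#' integer-day DFS observation noise of 5 days.
#'
#' @param n_sites Number of sites.
#' @param years Integer vector of consecutive years.
#' @param latitude_range Two-element range of site latitudes (degrees).
#' @param temp_mean_annual Mean annual temperature (degC).
#' @param temp_seasonal_amplitude Seasonal half-amplitude (degC).
#' @param temp_ar1_coeff AR(1) coefficient of daily noise, in \[0, 1).
#' @param temp_noise_sd Stationary sd of the AR(1) noise (degC).
#' @param warming_trend Warming trend (degC per year).
#' @param alan_start Initial annual ALAN (nW cm-2 sr-1).
#' @param alan_growth ALAN growth (nW cm-2 sr-1 per year).
#' @param alan_noise_sd ALAN observation noise sd.
#' @param dfs_noise_sd DFS observation noise sd (days).
#' @param outlier_fraction Fraction of gross outliers in \[0, 0.3\].
#' @param seed Master integer seed.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_sites = 5L, years = 2001:2022,
                             latitude_range = c(30, 55),
                             temp_mean_annual = 10,
                             temp_seasonal_amplitude = 12,
                             temp_ar1_coeff = 0.7, temp_noise_sd = 2,
                             warming_trend = 0.03,
                             alan_start = 5, alan_growth = 0.4,
                             alan_noise_sd = 0.3,
                             dfs_noise_sd = 5, outlier_fraction = 0,
                             seed = 1L) {
  cfg <- list(n_sites = as.integer(n_sites), years = as.integer(years),
              latitude_range = as.numeric(latitude_range),
              temp_mean_annual = temp_mean_annual,
              temp_seasonal_amplitude = temp_seasonal_amplitude,
              temp_ar1_coeff = temp_ar1_coeff, temp_noise_sd = temp_noise_sd,
              warming_trend = warming_trend,
              alan_start = alan_start, alan_growth = alan_growth,
              alan_noise_sd = alan_noise_sd, dfs_noise_sd = dfs_noise_sd,
              outlier_fraction = outlier_fraction, seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  if (cfg$n_sites < 1L) stop("`n_sites` must be >= 1")
  if (length(cfg$years) == 0L) stop("`years` must be non-empty")
  lr <- cfg$latitude_range
  if (length(lr) != 2L || any(lr < -90) || any(lr > 90) || lr[1] > lr[2])
    stop("`latitude_range` must be an ordered pair within [-90, 90]")
  for (nm in c("temp_seasonal_amplitude", "temp_noise_sd", "alan_start",
               "alan_growth", "alan_noise_sd", "dfs_noise_sd"))
    if (cfg[[nm]] < 0) stop("`", nm, "` must be non-negative")
  if (cfg$temp_ar1_coeff < 0 || cfg$temp_ar1_coeff >= 1)
    stop("`temp_ar1_coeff` must be in [0, 1)")
  if (cfg$outlier_fraction < 0 || cfg$outlier_fraction > 0.3)
    stop("`outlier_fraction` must be in [0, 0.3]")
  invisible(cfg)
}

# Counter-based substream derivation: a fixed multiplicative hash of
# (master seed, stream index) keeps each site's stream independent of
# n_sites and of generation order. Kept below 2^31 for R's 32-bit seeds.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 1664525 + 1013904223) %%
               2147483647)
}

#' Generate daily temperature series
#'
#' One 365-day series per year: mean + seasonal sinusoid (maximum near
#' day 200) + a warming offset of `warming_trend * (year - years[1])`
#' + AR(1) noise continuous across year boundaries with stationary sd
#' `temp_noise_sd`.
#'
#' @param latitude Site latitude (unused by the temperature model itself;
#'   kept for interface symmetry with site generation).
#' @param years Non-empty integer year vector.
#' @param config A [synthetic_config()].
#' @param seed Integer seed for this stream.
#' @return Matrix `length(years) x 365`, rownames = years.
#' @export
generate_daily_temperature <- function(latitude, years, config, seed) {
  if (length(years) == 0L) stop("`years` must be non-empty")
  validate_synthetic_config(config)
  ny <- length(years)
  doy <- seq_len(365L)
  seasonal <- config$temp_mean_annual +
    config$temp_seasonal_amplitude * sin(2 * pi * (doy - 108.75) / 365)
  set.seed(seed)
  phi <- config$temp_ar1_coeff
  innov_sd <- config$temp_noise_sd * sqrt(1 - phi^2)
  n_days <- ny * 365L
  noise <- numeric(n_days)
  if (config$temp_noise_sd > 0) {
    e <- stats::rnorm(n_days, sd = innov_sd)
    noise[1] <- stats::rnorm(1, sd = config$temp_noise_sd)
    for (t in 2:n_days) noise[t] <- phi * noise[t - 1] + e[t]
  }
  out <- matrix(NA_real_, ny, 365L, dimnames = list(years, NULL))
  for (i in seq_len(ny)) {
    trend <- config$warming_trend * (years[i] - years[1])
    out[i, ] <- seasonal + trend + noise[((i - 1L) * 365L + 1L):(i * 365L)]
  }
  out
}

#' Generate one synthetic site dataset
#'
#' Builds the full forcing/phenology bundle for one site: daily
#' temperature, annual ALAN (linear growth + noise, floored at 0),
#' monthly precipitation and shortwave radiation (seasonal cycle +
#' noise), annual leaf-unfolding date (around day 110), and annual GDP
#' (3%/yr exponential growth with lognormal noise). The observed-DFS
#' field stays NA until [simulate_observed_dfs()] fills it.
#'
#' @param config A [synthetic_config()].
#' @param site_index 1-based site index, <= `config$n_sites`.
#' @return A `site_dataset` list: `site_id`, `latitude`, `years`,
#'   `daily_temp` (years x 365), `alan`, `precip` and `shortwave`
#'   (years x 12), `lud`, `gdp`, `dfs_true`, `dfs_observed`.
#' @export
generate_site_dataset <- function(config, site_index) {
  validate_synthetic_config(config)
  stopifnot(site_index >= 1L, site_index <= config$n_sites)
  yrs <- config$years
  ny <- length(yrs)
  site_seed <- derive_seed(config$seed, site_index)

  set.seed(site_seed)
  lat <- stats::runif(1, config$latitude_range[1], config$latitude_range[2])
  daily_temp <- generate_daily_temperature(lat, yrs, config,
                                           derive_seed(site_seed, 1L))

  set.seed(derive_seed(site_seed, 2L))
  t_idx <- seq_len(ny) - 1L
  alan <- pmax(0, config$alan_start + config$alan_growth * t_idx +
                 stats::rnorm(ny, sd = config$alan_noise_sd))
  set.seed(derive_seed(site_seed, 3L))
  month_mid <- (.MONTH_START + .MONTH_END) / 2
  precip_seasonal <- 60 + 30 * sin(2 * pi * (month_mid - 108.75) / 365)
  precip <- matrix(pmax(0, rep(precip_seasonal, each = ny) +
                          stats::rnorm(ny * 12L, sd = 10)),
                   ny, 12L, dimnames = list(yrs, NULL))
  sw_seasonal <- 180 + 90 * sin(2 * pi * (month_mid - 108.75) / 365)
  shortwave <- matrix(pmax(0, rep(sw_seasonal, each = ny) +
                             stats::rnorm(ny * 12L, sd = 15)),
                      ny, 12L, dimnames = list(yrs, NULL))
  set.seed(derive_seed(site_seed, 4L))
  lud <- round(110 + stats::rnorm(ny, sd = 6))
  set.seed(derive_seed(site_seed, 5L))
  gdp <- 100 * exp(0.03 * t_idx + stats::rnorm(ny, sd = 0.05))

  structure(list(site_id = sprintf("site%03d", site_index), latitude = lat,
                 years = yrs, daily_temp = daily_temp, alan = alan,
                 precip = precip, shortwave = shortwave, lud = lud,
                 gdp = gdp, dfs_true = rep(NA_real_, ny),
                 dfs_observed = rep(NA_real_, ny)),
            class = "site_dataset")
}

#' @export
print.site_dataset <- function(x, ...) {
  cat(sprintf("<site_dataset> %s at %.2f deg, %d years (%d-%d)%s\n",
              x$site_id, x$latitude, length(x$years), min(x$years),
              max(x$years),
              if (all(is.na(x$dfs_observed))) "" else ", DFS simulated"))
  invisible(x)
}

#' Simulate observed senescence dates for a site
#'
#' Runs the given model with known ("true") parameters over every year,
#' stores the noise-free prediction in `dfs_true`, and fills
#' `dfs_observed` with the prediction plus iid Gaussian noise rounded to
#' whole days (mimicking in-situ records). Years with no threshold
#' crossing stay NA.
#'
#' @param site A `site_dataset`.
#' @param spec A [senescence_spec()] acting as the data-generating model.
#' @param true_params Named parameter vector within [param_bounds()].
#' @param noise_sd Observation noise sd in days.
#' @param seed Integer seed for the noise draws.
#' @return The site with `dfs_true` and `dfs_observed` filled.
#' @export
simulate_observed_dfs <- function(site, spec, true_params, noise_sd = 5,
                                  seed = 1L) {
  stopifnot(inherits(site, "site_dataset"), noise_sd >= 0)
  truth <- predict_dfs_site(spec, true_params, site)
  set.seed(seed)
  noise <- stats::rnorm(length(truth), sd = noise_sd)
  obs <- round(truth + noise)
  obs[is.na(truth)] <- NA_real_
  site$dfs_true <- unname(truth)
  site$dfs_observed <- unname(obs)
  site
}

#' Inject gross outliers into a DFS series
#'
#' Shifts `round(fraction * length)` randomly chosen entries by
#' +/- `magnitude` days (random sign), returning the corrupted series and
#' the true outlier mask for recovery scoring of the MAD filter.
#'
#' @param dfs_series Numeric day-of-year series.
#' @param fraction Fraction of entries to corrupt, in \[0, 1\].
#' @param magnitude Shift magnitude in days.
#' @param seed Integer seed.
#' @return List with `series` (corrupted) and `mask` (logical, TRUE where
#'   corrupted).
#' @export
inject_outliers <- function(dfs_series, fraction, magnitude, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1, magnitude >= 0)
  n <- length(dfs_series)
  n_out <- round(fraction * n)
  mask <- rep(FALSE, n)
  if (n_out > 0) {
    set.seed(seed)
    idx <- sample.int(n, n_out)
    sign <- sample(c(-1, 1), n_out, replace = TRUE)
    dfs_series[idx] <- dfs_series[idx] + sign * magnitude
    mask[idx] <- TRUE
  }
  list(series = dfs_series, mask = mask)
}

#' Write a site dataset as a plain-CSV bundle
#'
#' One file per table inside `dir`: `daily_temperature.csv` (site, year,
#' doy, temp), `annual_series.csv` (site, year, alan, lud, gdp, dfs_true,
#' dfs_observed), `monthly_climate.csv` (site, year, month, precip,
#' shortwave), plus `manifest.json` with site metadata. Appends when the
#' files already exist so multiple sites share one bundle.
#'
#' @param site A `site_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_site_dataset <- function(site, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ny <- length(site$years)
  daily <- data.frame(site = site$site_id,
                      year = rep(site$years, each = 365L),
                      doy = rep(1:365, times = ny),
                      temp = as.vector(t(site$daily_temp)))
  annual <- data.frame(site = site$site_id, year = site$years,
                       latitude = site$latitude, alan = site$alan,
                       lud = site$lud, gdp = site$gdp,
                       dfs_true = site$dfs_true,
                       dfs_observed = site$dfs_observed)
  monthly <- data.frame(site = site$site_id,
                        year = rep(site$years, times = 12L),
                        month = rep(1:12, each = ny),
                        precip = as.vector(site$precip),
                        shortwave = as.vector(site$shortwave))
  paths <- file.path(dir, c("daily_temperature.csv", "annual_series.csv",
                            "monthly_climate.csv"))
  tables <- list(daily, annual, monthly)
  for (i in seq_along(paths)) {
    append <- file.exists(paths[i])
    utils::write.table(tables[[i]], paths[i], sep = ",", row.names = FALSE,
                       col.names = !append, append = append, quote = FALSE)
  }
  invisible(paths)
}
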