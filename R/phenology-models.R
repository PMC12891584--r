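# Process-based autumn senescence models. Four families:
#   CDD  - cooling degree days below T_th accumulated to CDD_th
#   DM   - daily rate [T_b - T]^x * f(P)^y accumulated to Y_crit
#   SIAM - DM with Y_crit = a + b * (leaf-unfolding-date anomaly)
#   DMT  - DM with Y_crit = a + b * (spring-summer mean temperature)
# Each family has an ALAN-enhanced variant that multiplies the daily rate
# by the annual coefficient exp(k * (ALAN_i - ALAN_max) / ALAN_max).

MODEL_FAMILIES <- c("CDD", "DM", "SIAM", "DMT")

#' Senescence model specification
#'
#' Declares a model family, whether the ALAN multiplier is enabled, which
#' photoperiod response variant the DM-family rate uses, and (for DMT)
#' which calendar months define the spring-summer mean temperature.
#'
#' @param family One of `"CDD"`, `"DM"`, `"SIAM"`, `"DMT"`.
#' @param alan_enabled Logical; multiply the daily rate by the annual ALAN
#'   coefficient.
#' @param photoperiod_variant `"ratio"` (f = P/P_s, forcing grows with day
#'   length) or `"one_minus_ratio"` (f = 1 - P/P_s, forcing grows as days
#'   shorten). Ignored by CDD.
#' @param tss_months Months averaged for the DMT threshold; default
#'   March-August.
#' @return An object of class `senescence_spec`.
#' @export
senescence_spec <- function(family = c("CDD", "DM", "SIAM", "DMT"),
                            alan_enabled = FALSE,
                            photoperiod_variant = c("one_minus_ratio", "ratio"),
                            tss_months = 3:8) {
  family <- match.arg(family)
  photoperiod_variant <- match.arg(photoperiod_variant)
  stopifnot(is.logical(alan_enabled), length(alan_enabled) == 1L)
  if (family == "DMT" && length(tss_months) == 0L)
    stop("DMT requires a non-empty `tss_months` set")
  structure(list(family = family, alan_enabled = alan_enabled,
                 photoperiod_variant = photoperiod_variant,
                 tss_months = as.integer(tss_months)),
            class = "senescence_spec")
}

#' @export
print.senescence_spec <- function(x, ...) {
  cat(sprintf("<senescence_spec> %s%s (photoperiod: %s)\n", x$family,
              if (x$alan_enabled) "_ALAN" else "", x$photoperiod_variant))
  invisible(x)
}

#' Model name of a specification
#' @param spec A [senescence_spec()].
#' @return e.g. `"DM"` or `"DM_ALAN"`.
#' @export
model_name <- function(spec) {
  paste0(spec$family, if (spec$alan_enabled) "_ALAN" else "")
}

#' Parameter names and default calibration bounds for a model family
#'
#' CDD has (T_th, CDD_th); DM has (T_b, P_s, x, y, Y_crit); SIAM and DMT
#' replace Y_crit with the linear-threshold coefficients (a, b). ALAN
#' variants gain the modulation strength k, bounded in \[-10, 10\].
#' Exponents x and y are bounded in \[0, 2\] and T_th in \[0, 50\] degC.
#'
#' @param spec A [senescence_spec()].
#' @return data.frame with columns `param`, `lower`, `upper`.
#' @export
param_bounds <- function(spec) {
  b <- switch(spec$family,
    CDD = data.frame(param = c("T_th", "CDD_th"),
                     lower = c(0, 1), upper = c(50, 2000)),
    DM = data.frame(param = c("T_b", "P_s", "x", "y", "Y_crit"),
                    lower = c(0, 6, 0, 0, 0.1), upper = c(40, 20, 2, 2, 500)),
    SIAM = data.frame(param = c("T_b", "P_s", "x", "y", "a", "b"),
                      lower = c(0, 6, 0, 0, 0.1, -20),
                      upper = c(40, 20, 2, 2, 500, 20)),
    DMT = data.frame(param = c("T_b", "P_s", "x", "y", "a", "b"),
                     lower = c(0, 6, 0, 0, -500, -50),
                     upper = c(40, 20, 2, 2, 500, 50)))
  if (spec$alan_enabled)
    b <- rbind(b, data.frame(param = "k", lower = -10, upper = 10))
  b
}

#' Number of free parameters of a model
#' @param spec A [senescence_spec()].
#' @return Integer parameter count (enters the AIC penalty).
#' @export
n_params <- function(spec) nrow(param_bounds(spec))

validate_params <- function(spec, params) {
  b <- param_bounds(spec)
  missing <- setdiff(b$param, names(params))
  if (length(missing))
    stop("missing parameter(s) for ", model_name(spec), ": ",
         paste(missing, collapse = ", "))
  params[b$param]
}

#' Photoperiod response function
#'
#' The two published forms of the DM-family photoperiod term:
#' `"ratio"` gives f = P/P_s; `"one_minus_ratio"` gives f = 1 - P/P_s,
#' clamped below at 0 so the response is never negative.
#'
#' @param p Day length (hours) in \[0, 24\]; vectorized.
#' @param p_s Critical photoperiod threshold, > 0.
#' @param variant `"ratio"` or `"one_minus_ratio"`.
#' @return Non-negative dimensionless response.
#' @export
photoperiod_response <- function(p, p_s,
                                 variant = c("ratio", "one_minus_ratio")) {
  variant <- match.arg(variant)
  if (length(p_s) != 1L || !is.finite(p_s) || p_s <= 0)
    stop("`p_s` must be a single positive value")
  stopifnot(all(p >= 0), all(p <= 24))
  f <- if (variant == "ratio") p / p_s else 1 - p / p_s
  pmax(f, 0)
}

#' Spring-summer mean temperature
#'
#' Arithmetic mean of the daily temperatures falling in the given calendar
#' months; the covariate of the DMT threshold.
#'
#' @param daily_temp 365 daily mean temperatures (degC).
#' @param months Calendar months to average over (default March-August).
#' @return Mean temperature in degC.
#' @export
spring_summer_mean_temp <- function(daily_temp, months = 3:8) {
  stopifnot(length(daily_temp) == 365L, length(months) >= 1L)
  doys <- unlist(lapply(sort(unique(as.integer(months))), month_doys))
  mean(daily_temp[doys])
}

#' Leaf-unfolding-date anomalies
#'
#' Centers a spring-phenology series on its multi-year mean; the SIAM
#' threshold is linear in this anomaly.
#'
#' @param lud_series Leaf-unfolding day of year per year (NA allowed).
#' @return Anomalies (days), summing to zero over non-missing years.
#' @export
lud_anomaly <- function(lud_series) {
  if (sum(!is.na(lud_series)) < 2L)
    stop("need at least 2 non-missing LUD years")
  lud_series - mean(lud_series, na.rm = TRUE)
}

# Daily rate of one model-year. `alanin` is the annual multiplier (1 for
# base models). Negative forcing bases are clamped at 0 before
# exponentiation, with 0^0 := 0 so warm days contribute nothing even when
# x = 0.
daily_rate <- function(spec, params, daily_temp, photoperiod) {
  if (spec$family == "CDD") {
    pmax(params[["T_th"]] - daily_temp, 0)
  } else {
    base <- pmax(params[["T_b"]] - daily_temp, 0)
    tpart <- ifelse(base > 0, base^params[["x"]], 0)
    f <- photoperiod_response(photoperiod, params[["P_s"]],
                              spec$photoperiod_variant)
    ppart <- ifelse(f > 0, f^params[["y"]], 0)
    tpart * ppart
  }
}

#' Predict the date of foliar senescence for one year
#'
#' Runs one model-year: finds the onset day (first day at or after the
#' summer solstice, day 172, where the start condition holds: temperature
#' below T_th for CDD; temperature at or below T_b *and* photoperiod at or
#' below P_s for the DM family), accumulates the daily forcing rate from
#' the onset day, and reports the first day the cumulative state reaches
#' the threshold (CDD_th, Y_crit, a + b*LUD_a, or a + b*Tss). When the
#' ALAN variant is enabled the daily rate is multiplied by the constant
#' annual coefficient [alan_forcing_coefficient()].
#'
#' @param spec A [senescence_spec()].
#' @param params Named parameter vector covering [param_bounds()].
#' @param daily_temp 365 daily mean temperatures (degC).
#' @param latitude Site latitude in degrees (drives the photoperiod).
#' @param alanin Annual ALAN multiplier; required (non-NULL) when
#'   `spec$alan_enabled`. Default 1.
#' @param lud_anom LUD anomaly for the year (days); required for SIAM.
#' @param tss Spring-summer mean temperature; computed from `daily_temp`
#'   and `spec$tss_months` when omitted (DMT only).
#' @return A `senescence_trace`: list with `onset_day`, `crossing_day`
#'   (NA when the threshold is never reached by day 365 or the threshold
#'   is non-positive), `threshold`, `daily_state` (cumulative, length
#'   365), `daily_increment`, and `alanin_applied`.
#' @export
predict_dfs <- function(spec, params, daily_temp, latitude,
                        alanin = 1, lud_anom = NULL, tss = NULL) {
  stopifnot(length(daily_temp) == 365L)
  params <- validate_params(spec, params)
  if (spec$alan_enabled) {
    if (is.null(alanin)) stop(model_name(spec), " requires an ALAN multiplier")
  } else alanin <- 1
  if (spec$family == "SIAM" && is.null(lud_anom))
    stop("SIAM requires the LUD anomaly covariate")

  threshold <- switch(spec$family,
    CDD = params[["CDD_th"]],
    DM = params[["Y_crit"]],
    SIAM = params[["a"]] + params[["b"]] * lud_anom,
    DMT = {
      if (is.null(tss)) tss <- spring_summer_mean_temp(daily_temp, spec$tss_months)
      params[["a"]] + params[["b"]] * tss
    })

  doy <- seq_len(365L)
  photoperiod <- day_length(latitude, doy)
  eligible <- doy >= SOLSTICE_DOY
  start_ok <- if (spec$family == "CDD")
    daily_temp < params[["T_th"]]
  else
    daily_temp <= params[["T_b"]] & photoperiod <= params[["P_s"]]
  onset_candidates <- which(eligible & start_ok)

  trace <- list(onset_day = NA_integer_, crossing_day = NA_integer_,
                threshold = threshold,
                daily_state = numeric(365L), daily_increment = numeric(365L),
                alanin_applied = alanin)
  class(trace) <- "senescence_trace"
  if (!is.finite(threshold) || threshold <= 0 || length(onset_candidates) == 0L)
    return(trace)

  onset <- onset_candidates[1L]
  rate <- numeric(365L)
  idx <- onset:365L
  rate[idx] <- daily_rate(spec, params, daily_temp[idx], photoperiod[idx]) * alanin
  state <- cumsum(rate)
  crossing <- which(state >= threshold)
  trace$onset_day <- onset
  trace$daily_increment <- rate
  trace$daily_state <- state
  if (length(crossing)) trace$crossing_day <- crossing[1L]
  trace
}

#' @export
print.senescence_trace <- function(x, ...) {
  cat(sprintf("<senescence_trace> onset %s, crossing %s (threshold %.3f, ALANin %.4f)\n",
              ifelse(is.na(x$onset_day), "none", x$onset_day),
              ifelse(is.na(x$crossing_day), "none", x$crossing_day),
              x$threshold, x$alanin_applied))
  invisible(x)
}

#' Predict DFS for every year of a site dataset
#'
#' Vector wrapper around [predict_dfs()]: builds the per-year ALAN
#' multipliers, LUD anomalies, and spring-summer temperatures the family
#' needs, and returns one predicted day of year per year.
#'
#' @param spec A [senescence_spec()].
#' @param params Named parameter vector.
#' @param site A `site_dataset` (see [generate_site_dataset()]).
#' @return Named numeric vector (names = years) of predicted DFS; NA for
#'   years with no threshold crossing.
#' @export
predict_dfs_site <- function(spec, params, site) {
  yrs <- site$years
  n <- length(yrs)
  alanin <- rep(1, n)
  if (spec$alan_enabled) {
    ser <- alan_series(yrs, site$alan)
    alanin <- alan_forcing_coefficient(ser$alan, ser$alan_max, params[["k"]])
  }
  lud_a <- if (spec$family == "SIAM") lud_anomaly(site$lud) else rep(NA_real_, n)
  out <- vapply(seq_len(n), function(i) {
    tr <- predict_dfs(spec, params, site$daily_temp[i, ], site$latitude,
                      alanin = alanin[i],
                      lud_anom = if (spec$family == "SIAM") lud_a[i] else NULL)
    as.numeric(tr$crossing_day)
  }, numeric(1))
  names(out) <- yrs
  out
}
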