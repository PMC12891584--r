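# ALAN-specific transforms: monthly disaggregation by night length, the
# exponential ALAN forcing coefficient, the MAD outlier filter applied to
# in-situ senescence records, resource-use-efficiency ratios, and the
# pooled ALAN ~ GDP regression used to project future ALAN.

#' Annual ALAN series container
#'
#' Bundles a per-year ALAN radiance series with its running maximum and
#' multi-year mean, the two normalizers used downstream (the forcing
#' coefficient divides by the series maximum; the GDP regression uses the
#' mean).
#'
#' @param years Integer vector of calendar years.
#' @param alan Non-negative radiance (nW cm-2 sr-1) per year.
#' @return An object of class `alan_series` with fields `years`, `alan`,
#'   `alan_max` and `alan_mean`.
#' @export
alan_series <- function(years, alan) {
  stopifnot(length(years) == length(alan), length(alan) >= 1L)
  if (any(!is.finite(alan)) || any(alan < 0))
    stop("ALAN radiance must be finite and non-negative")
  structure(
    list(years = as.integer(years), alan = as.numeric(alan),
         alan_max = max(alan), alan_mean = mean(alan)),
    class = "alan_series")
}

#' @export
print.alan_series <- function(x, ...) {
  cat(sprintf("<alan_series> %d years (%d-%d), mean %.3f, max %.3f nW cm-2 sr-1\n",
              length(x$years), min(x$years), max(x$years),
              x$alan_mean, x$alan_max))
  invisible(x)
}

#' Disaggregate annual ALAN to months by night length
#'
#' Splits an annual ALAN value across the 12 calendar months in proportion
#' to the mean nightly hours of each month:
#' \deqn{ALAN_{month} = \frac{NH_{month} \times 12}{\sum_m NH_m} ALAN_{year}}
#' so that the mean of the 12 monthly values equals the annual value
#' exactly. Months with longer nights (winter at high latitude) receive
#' more than the annual mean.
#'
#' @param alan_year Annual ALAN radiance, >= 0.
#' @param latitude Site latitude in degrees.
#' @return Numeric vector of 12 monthly ALAN values.
#' @export
disaggregate_alan_monthly <- function(alan_year, latitude) {
  stopifnot(length(alan_year) == 1L, is.finite(alan_year), alan_year >= 0)
  nh <- night_length_monthly(latitude)
  total <- sum(nh)
  if (total <= 0)
    stop("total night length over the year is zero; cannot disaggregate")
  nh * 12 / total * alan_year
}

#' ALAN forcing coefficient
#'
#' The annual multiplier applied to the daily senescence forcing rate in
#' ALAN-enhanced model variants:
#' \deqn{ALANin_i = \exp\!\big(k \, (ALAN_i - ALAN_{max}) / ALAN_{max}\big)}
#' It equals 1 in the brightest year (or when k = 0) and moves
#' monotonically with ALAN_i in the direction of sign(k): k < 0 means
#' dimmer years accumulate forcing faster, so rising ALAN slows
#' accumulation and delays senescence.
#'
#' @param alan_i Annual ALAN radiance, >= 0 (vector allowed).
#' @param alan_max Series maximum radiance, > 0.
#' @param k Dimensionless modulation strength.
#' @return Strictly positive multiplier(s).
#' @examples
#' alan_forcing_coefficient(5, 10, 1)  # exp(-0.5)
#' @export
alan_forcing_coefficient <- function(alan_i, alan_max, k) {
  if (length(alan_max) != 1L || !is.finite(alan_max) || alan_max <= 0)
    stop("`alan_max` must be a single positive value")
  stopifnot(all(alan_i >= 0), length(k) == 1L, is.finite(k))
  exp(k * (alan_i - alan_max) / alan_max)
}

#' MAD outlier filter for senescence records
#'
#' Flags observations whose absolute deviation from the series median
#' exceeds `multiplier` times the median absolute deviation
#' MAD = median(|x_i - median(x)|) (raw MAD, no normal-consistency
#' scaling). With a degenerate MAD of 0 the strict inequality flags any
#' value differing from the median, and nothing when all values are equal.
#'
#' @param dfs_series Numeric day-of-year series, length >= 3.
#' @param multiplier Positive MAD multiple defining an outlier (default 2.5).
#' @return List with `kept` (values passing), `mask` (logical, TRUE =
#'   outlier), `median` and `mad`.
#' @examples
#' mad_filter(c(10, 12, 11, 50))$mask  # only 50 flagged
#' @export
mad_filter <- function(dfs_series, multiplier = 2.5) {
  x <- dfs_series[!is.na(dfs_series)]
  if (length(x) < 3L)
    stop("need at least 3 non-missing values for a stable median/MAD")
  stopifnot(multiplier > 0)
  med <- stats::median(x)
  mad_raw <- stats::median(abs(x - med))
  mask <- rep(NA, length(dfs_series))
  dev <- abs(dfs_series - med)
  mask <- !is.na(dfs_series) & dev > multiplier * mad_raw
  list(kept = dfs_series[!mask & !is.na(dfs_series)],
       mask = mask, median = med, mad = mad_raw)
}

#' Water- and light-use efficiency ratios
#'
#' WUE = GPP / ET and LUE = GPP / (SW * 0.45 * FPAR), where the factor
#' 0.45 converts shortwave radiation to photosynthetically active
#' radiation.
#'
#' @param gpp Gross primary productivity (>= 0).
#' @param et Evapotranspiration, > 0.
#' @param sw Shortwave radiation (W m-2), > 0.
#' @param fpar Fraction of absorbed photosynthetically active radiation,
#'   in (0, 1].
#' @return List with elements `wue` and `lue`.
#' @export
efficiency_ratios <- function(gpp, et, sw, fpar) {
  stopifnot(all(gpp >= 0))
  if (any(et <= 0)) stop("`et` must be positive")
  if (any(sw <= 0)) stop("`sw` must be positive")
  if (any(fpar <= 0) || any(fpar > 1)) stop("`fpar` must be in (0, 1]")
  list(wue = gpp / et, lue = gpp / (sw * 0.45 * fpar))
}

#' Fit the pooled ALAN ~ GDP projection regression
#'
#' Ordinary least squares of annual ALAN on each site's multi-year mean
#' ALAN and the log of annual GDP,
#' \deqn{ALAN_i = a\,ALAN_{mean} + b\,\ln(GDP_i) + c,}
#' fitted pooled across sites and scored by k-fold cross-validation.
#'
#' @param data data.frame with columns `site`, `year`, `alan`, `gdp`
#'   (GDP must be positive). A single site is allowed, in which case
#'   `ALAN_mean` is constant and the fit reduces to ALAN ~ ln(GDP).
#' @param folds Number of cross-validation folds (default 5).
#' @param seed Integer seed for the fold shuffle.
#' @return List with `coefficients` (named a, b, c), `cv` (per-fold RMSE
#'   and R^2), and the fitted `model`.
#' @export
fit_alan_gdp_regression <- function(data, folds = 5L, seed = 1L) {
  stopifnot(is.data.frame(data),
            all(c("site", "year", "alan", "gdp") %in% names(data)))
  if (any(data$gdp <= 0)) stop("GDP must be positive (log is taken)")
  n <- nrow(data)
  if (n < folds) stop("need at least `folds` rows")
  alan_mean <- stats::ave(data$alan, data$site)
  df <- data.frame(alan = data$alan, alan_mean = alan_mean,
                   lgdp = log(data$gdp))
  single_site <- length(unique(data$site)) == 1L
  form <- if (single_site) alan ~ lgdp else alan ~ alan_mean + lgdp
  X <- stats::model.matrix(form, df)
  if (qr(X)$rank < ncol(X))
    stop("singular design: ALAN_mean and/or ln(GDP) are collinear ",
         "(constant ln(GDP) within a single site cannot identify b)")
  fit <- stats::lm(form, data = df)
  cf <- stats::coef(fit)
  coefficients <- if (single_site)
    c(a = 0, b = unname(cf["lgdp"]), c = unname(cf["(Intercept)"]))
  else
    c(a = unname(cf["alan_mean"]), b = unname(cf["lgdp"]),
      c = unname(cf["(Intercept)"]))

  set.seed(seed)
  fold_id <- sample(rep(seq_len(folds), length.out = n))
  cv <- do.call(rbind, lapply(seq_len(folds), function(f) {
    train <- df[fold_id != f, , drop = FALSE]
    test <- df[fold_id == f, , drop = FALSE]
    m <- stats::lm(form, data = train)
    pred <- stats::predict(m, newdata = test)
    resid <- test$alan - pred
    ss_tot <- sum((test$alan - mean(test$alan))^2)
    data.frame(fold = f, rmse = sqrt(mean(resid^2)),
               r2 = if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else NA_real_)
  }))
  list(coefficients = coefficients, cv = cv, model = fit)
}

#' Project future annual ALAN from a GDP path
#'
#' Applies the fitted ALAN ~ GDP regression to future GDP, flooring the
#' result at zero (radiance cannot be negative).
#'
#' @param coefficients Named vector (a, b, c) from
#'   [fit_alan_gdp_regression()].
#' @param alan_mean The site's historical mean ALAN.
#' @param gdp_path Positive GDP per future year.
#' @return Projected annual ALAN, same length as `gdp_path`.
#' @export
project_future_alan <- function(coefficients, alan_mean, gdp_path) {
  stopifnot(all(c("a", "b", "c") %in% names(coefficients)))
  if (any(gdp_path <= 0)) stop("GDP path must be positive")
  pmax(0, coefficients[["a"]] * alan_mean +
         coefficients[["b"]] * log(gdp_path) + coefficients[["c"]])
}
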