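# Statistical analysis layer: detrending and standardization, Theil-Sen
# slope with Mann-Kendall significance, partial correlation, the
# preseason-length search, ridge-regression sensitivities, the 11-year
# moving-window modulation of climate sensitivity by ALAN, and the
# Gaussian sensitivity-vs-ALAN response fit.

#' Detrend and standardize an annual series
#'
#' Residuals of an OLS regression on year, scaled to unit standard
#' deviation: the "normalized anomalies" fed to the correlation and ridge
#' analyses, so sensitivities reflect interannual variability rather than
#' shared long-term trends.
#'
#' @param series Numeric values per year, length >= 4.
#' @param years Optional time index (defaults to `seq_along(series)`).
#' @return Standardized anomalies, mean 0 and sd 1.
#' @export
detrend_normalize <- function(series, years = seq_along(series)) {
  ok <- !is.na(series)
  if (sum(ok) < 4L) stop("need at least 4 non-missing years")
  res <- rep(NA_real_, length(series))
  res[ok] <- stats::resid(stats::lm(series[ok] ~ years[ok]))
  s <- stats::sd(res[ok])
  if (s < 1e-12)
    stop("zero residual variance after detrending; series is exactly linear")
  res / s
}

#' Theil-Sen slope with Mann-Kendall test
#'
#' The slope estimate is the median of all pairwise slopes
#' (y_j - y_i)/(t_j - t_i), robust to outliers. Significance comes from
#' the Mann-Kendall S statistic under the tie-corrected normal
#' approximation with continuity correction (no pre-whitening).
#'
#' @param series Numeric values per year (NA dropped), length >= 4.
#' @param years Optional time index.
#' @return List with `slope` (units per year), `intercept` (median of
#'   y - slope*t), `mk_s`, `mk_z`, and `p_value`.
#' @export
theil_sen <- function(series, years = seq_along(series)) {
  ok <- !is.na(series) & !is.na(years)
  y <- series[ok]; t <- years[ok]
  n <- length(y)
  if (n < 4L) stop("need at least 4 non-missing years")
  pairs <- utils::combn(n, 2L)
  dt <- t[pairs[2, ]] - t[pairs[1, ]]
  dy <- y[pairs[2, ]] - y[pairs[1, ]]
  slope <- stats::median(dy[dt != 0] / dt[dt != 0])

  s <- sum(sign(dy))
  ties <- table(y)
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  z <- if (var_s <= 0) 0 else if (s > 0) (s - 1) / sqrt(var_s)
       else if (s < 0) (s + 1) / sqrt(var_s) else 0
  p <- 2 * stats::pnorm(-abs(z))
  list(slope = slope, intercept = stats::median(y - slope * t),
       mk_s = s, mk_z = z, p_value = p)
}

#' Partial correlation by double residualization
#'
#' Pearson correlation of the residuals of `x` and `y` after each is
#' regressed (OLS, with intercept) on the control variables; significance
#' from a two-sided t-test with n - n_controls - 2 degrees of freedom.
#' With no controls this is the plain Pearson correlation.
#'
#' @param x,y Numeric vectors of equal length.
#' @param controls Optional matrix/data.frame of control variables
#'   (columns), or NULL.
#' @return List with `r`, `p_value`, `df`, `n`.
#' @export
partial_correlation <- function(x, y, controls = NULL) {
  stopifnot(length(x) == length(y))
  if (!is.null(controls)) {
    controls <- as.matrix(controls)
    stopifnot(nrow(controls) == length(x))
  }
  ok <- !is.na(x) & !is.na(y)
  if (!is.null(controls)) ok <- ok & stats::complete.cases(controls)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  q <- if (is.null(controls)) 0L else ncol(controls)
  if (n <= q + 2L) stop("need n > n_controls + 2 observations")
  if (q > 0L) {
    Z <- cbind(1, controls[ok, , drop = FALSE])
    if (qr(Z)$rank < ncol(Z)) stop("collinear control variables")
    x <- stats::resid(stats::lm.fit(Z, x))
    y <- stats::resid(stats::lm.fit(Z, y))
  }
  r <- stats::cor(x, y)
  df <- n - q - 2L
  tval <- r * sqrt(df / (1 - r^2))
  list(r = r, p_value = 2 * stats::pt(-abs(tval), df), df = df, n = n)
}

# Window mean of a monthly driver ending at `anchor_month` (inclusive),
# spanning `len` months backwards; months before January come from the
# previous calendar year. `monthly` is a years x 12 matrix with rownames
# set to years; `target_years` selects the rows to return.
preseason_window_mean <- function(monthly, target_years, anchor_month, len) {
  yrs_avail <- as.integer(rownames(monthly))
  months <- (anchor_month - len + 1L):anchor_month
  vapply(target_years, function(y) {
    vals <- vapply(months, function(m) {
      yy <- y; mm <- m
      while (mm < 1L) { mm <- mm + 12L; yy <- yy - 1L }
      row <- match(yy, yrs_avail)
      if (is.na(row)) return(NA_real_)
      monthly[row, mm]
    }, numeric(1))
    mean(vals)
  }, numeric(1))
}

#' Optimal preseason length for one driver
#'
#' Starting from the calendar month of the multi-year mean senescence
#' date (the anchor, included in every window), candidate preseason
#' windows extend backwards 1..`max_months` months. For each length the
#' driver (and each control driver, over the same window) is averaged,
#' all series are detrended and standardized, and the driver's partial
#' correlation with DFS is computed controlling for the other drivers.
#' The length maximizing |partial r| wins; ties break toward the shorter
#' window.
#'
#' @param dfs Observed DFS (day of year) per year.
#' @param years Integer years matching `dfs`.
#' @param driver_monthly years x 12 matrix (rownames = years) of the
#'   driver of interest; must also cover the year before `years[1]` when
#'   windows cross the year boundary.
#' @param other_drivers Named list of years x 12 matrices used as
#'   controls (possibly empty).
#' @param max_months Maximum window length in months (default 6).
#' @return A `sensitivity_estimate` list: `preseason_length`,
#'   `anchor_month`, `partial_r`, `p_value`, and `candidates` (one row
#'   per length).
#' @export
optimal_preseason <- function(dfs, years, driver_monthly,
                              other_drivers = list(), max_months = 6L) {
  ok <- !is.na(dfs)
  if (sum(ok) < 5L) stop("need at least 5 non-missing DFS years")
  anchor <- doy_to_month(round(mean(dfs[ok])))
  cand <- data.frame(length = seq_len(max_months), partial_r = NA_real_,
                     p_value = NA_real_)
  for (len in seq_len(max_months)) {
    x <- preseason_window_mean(driver_monthly, years, anchor, len)
    if (anyNA(x[ok]))
      stop("insufficient monthly coverage for a ", len,
           "-month window anchored at month ", anchor)
    ctrl <- NULL
    if (length(other_drivers)) {
      ctrl <- sapply(other_drivers, preseason_window_mean,
                     target_years = years, anchor_month = anchor, len = len)
      ctrl <- apply(as.matrix(ctrl), 2, detrend_normalize)
    }
    pc <- partial_correlation(detrend_normalize(x), detrend_normalize(dfs),
                              controls = ctrl)
    cand$partial_r[len] <- pc$r
    cand$p_value[len] <- pc$p_value
  }
  best <- which.max(abs(cand$partial_r))  # which.max takes the first max: ties
                                          # break toward the shorter window
  structure(list(preseason_length = cand$length[best], anchor_month = anchor,
                 partial_r = cand$partial_r[best],
                 p_value = cand$p_value[best], candidates = cand),
            class = "sensitivity_estimate")
}

#' Ridge-regression sensitivities
#'
#' Coefficients of an L2-penalized least squares of standardized DFS
#' anomalies on standardized preseason driver anomalies, the intercept
#' left unpenalized (all variables are centered, so it vanishes). With
#' lambda = 0 this is OLS; each coefficient is the sensitivity of DFS to
#' that driver in days-per-standardized-unit times the DFS scaling.
#'
#' @param dfs Standardized DFS anomalies.
#' @param drivers Matrix of standardized driver anomalies (named columns).
#' @param penalty Ridge penalty lambda >= 0 (default 1).
#' @return Named coefficient vector, one per driver column.
#' @export
ridge_sensitivities <- function(dfs, drivers, penalty = 1) {
  drivers <- as.matrix(drivers)
  stopifnot(nrow(drivers) == length(dfs), penalty >= 0)
  ok <- !is.na(dfs) & stats::complete.cases(drivers)
  if (sum(ok) <= 2L) stop("need more than 2 complete years")
  y <- dfs[ok] - mean(dfs[ok])
  X <- scale(drivers[ok, , drop = FALSE], center = TRUE, scale = FALSE)
  p <- ncol(X)
  beta <- solve(crossprod(X) + penalty * diag(p), crossprod(X, y))
  stats::setNames(as.numeric(beta),
                  colnames(drivers) %||% paste0("driver", seq_len(p)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Moving-window modulation of climate sensitivity by ALAN
#'
#' Means of annual ALAN and of a climate-sensitivity series over sliding
#' windows (default 11 years, 1-year step), correlated across windows. A
#' 22-year record yields 12 windows.
#'
#' @param annual_alan ALAN per year.
#' @param climate_sensitivity Sensitivity value per year (same length).
#' @param window Window width in years (default 11).
#' @param step Step between windows in years (default 1).
#' @return List with `n_windows`, `alan_means`, `sens_means`, `r`,
#'   `p_value`.
#' @export
moving_window_modulation <- function(annual_alan, climate_sensitivity,
                                     window = 11L, step = 1L) {
  n <- length(annual_alan)
  stopifnot(length(climate_sensitivity) == n, window >= 2L, step >= 1L)
  if (n < window) stop("series shorter than the window")
  starts <- seq.int(1L, n - window + 1L, by = step)
  if (length(starts) < 2L)
    stop("only one window: correlation across windows is undefined")
  am <- vapply(starts, function(s) mean(annual_alan[s:(s + window - 1L)]),
               numeric(1))
  sm <- vapply(starts, function(s)
    mean(climate_sensitivity[s:(s + window - 1L)]), numeric(1))
  ct <- stats::cor.test(am, sm)
  list(n_windows = length(starts), alan_means = am, sens_means = sm,
       r = unname(ct$estimate), p_value = ct$p.value)
}

#' Gaussian response fit of sensitivity vs ALAN intensity
#'
#' Nonlinear least squares of \eqn{y = A \exp(-(x - x_0)^2 / w)},
#' the hump-shaped response of the ALAN sensitivity of DFS to ALAN
#' intensity across cities. Deterministic initialization: A = y at
#' max |y|, x0 = corresponding x, w = (x-range)^2 / 4; fitted by
#' `nls(algorithm = "port")` with w bounded positive, falling back to
#' Nelder-Mead on non-convergence.
#'
#' @param sv_values Sensitivity values per city.
#' @param alan_values ALAN intensity per city (non-constant, >= 10 pairs).
#' @return A `gaussian_response_fit` list: `amplitude`, `center`, `width`,
#'   `goodness` (correlation of fitted vs observed), `fitted`,
#'   `converged`.
#' @export
fit_gaussian_response <- function(sv_values, alan_values) {
  ok <- !is.na(sv_values) & !is.na(alan_values)
  y <- sv_values[ok]; x <- alan_values[ok]
  if (length(y) < 10L) stop("need at least 10 (ALAN, sensitivity) pairs")
  if (stats::sd(x) < 1e-12) stop("ALAN values are constant; fit is degenerate")
  if (stats::sd(y) < 1e-12)
    stop("sensitivity values are constant; width is unidentifiable")
  i0 <- which.max(abs(y))
  start <- list(A = y[i0], x0 = x[i0], w = (diff(range(x)))^2 / 4)
  df <- data.frame(x = x, y = y)
  fit <- tryCatch(
    stats::nls(y ~ A * exp(-(x - x0)^2 / w), data = df, start = start,
               algorithm = "port",
               lower = c(A = -Inf, x0 = -Inf, w = 1e-8),
               control = stats::nls.control(maxiter = 500, warnOnly = FALSE)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    fitted_y <- stats::fitted(fit)
    converged <- TRUE
  } else {
    obj <- function(p) sum((y - p[1] * exp(-(x - p[2])^2 / max(p[3], 1e-8)))^2)
    op <- stats::optim(unlist(start), obj, method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-12))
    cf <- c(A = op$par[[1]], x0 = op$par[[2]], w = max(op$par[[3]], 1e-8))
    fitted_y <- cf[["A"]] * exp(-(x - cf[["x0"]])^2 / cf[["w"]])
    converged <- op$convergence == 0
    if (!converged)
      warning("Gaussian response fit did not converge (optim code ",
              op$convergence, ")")
  }
  structure(list(amplitude = unname(cf[["A"]]), center = unname(cf[["x0"]]),
                 width = unname(cf[["w"]]),
                 goodness = stats::cor(fitted_y, y),
                 fitted = fitted_y, converged = converged),
            class = "gaussian_response_fit")
}

#' @export
print.gaussian_response_fit <- function(x, ...) {
  cat(sprintf("<gaussian_response_fit> y = %.4f * exp(-(x - %.4f)^2 / %.4f), fit r = %.3f\n",
              x$amplitude, x$center, x$width, x$goodness))
  invisible(x)
}
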