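# Parameter calibration by particle swarm optimization, prediction
# scoring (Pearson r, RMSE, AIC), base-vs-ALAN model comparison, and
# century-scale projection.

#' Default particle swarm settings
#'
#' Standard constriction-coefficient values: inertia 0.729 and
#' cognitive = social = 1.49445.
#'
#' @param particles Swarm size (default 40).
#' @param iterations Iteration count per restart (default 200).
#' @param inertia Velocity inertia weight.
#' @param cognitive Personal-best attraction.
#' @param social Global-best attraction.
#' @param restarts Independent swarm restarts; the best result over all
#'   restarts is kept (default 5). The threshold-crossing objective is
#'   piecewise constant in the parameters, so a single swarm can stall on
#'   a plateau; restarts make the search robustly global.
#' @return A named list of settings.
#' @export
pso_config <- function(particles = 40L, iterations = 200L, inertia = 0.729,
                       cognitive = 1.49445, social = 1.49445,
                       restarts = 5L) {
  stopifnot(particles >= 2L, iterations >= 1L, inertia >= 0,
            cognitive >= 0, social >= 0, restarts >= 1L)
  list(particles = as.integer(particles), iterations = as.integer(iterations),
       inertia = inertia, cognitive = cognitive, social = social,
       restarts = as.integer(restarts))
}

# Calibration objective: RMSE over years where both the observation and
# the model crossing exist, plus a fixed 100-day penalty for each year the
# model fails to cross while an observation exists. Infinite when no year
# yields a prediction.
calibration_objective <- function(pred, obs, missing_penalty = 100) {
  usable <- !is.na(obs)
  pred <- pred[usable]; obs <- obs[usable]
  crossed <- !is.na(pred)
  if (!any(crossed)) return(Inf)
  rmse <- sqrt(mean((pred[crossed] - obs[crossed])^2))
  rmse + missing_penalty * sum(!crossed)
}

# Precomputed per-site quantities shared by every objective evaluation:
# photoperiod and onset eligibility depend only on latitude, the ALAN
# normalized gap, LUD anomalies and spring-summer temperatures only on
# the data. Lets the swarm evaluate thousands of parameter vectors
# without re-deriving them.
precompute_site <- function(spec, site) {
  doy <- seq_len(365L)
  ser <- alan_series(site$years, site$alan)
  list(temps = site$daily_temp,
       photoperiod = day_length(site$latitude, doy),
       eligible = doy >= SOLSTICE_DOY,
       alan_gap = (ser$alan - ser$alan_max) / ser$alan_max,
       lud_a = if (spec$family == "SIAM") lud_anomaly(site$lud) else NULL,
       tss = if (spec$family == "DMT")
         apply(site$daily_temp, 1, spring_summer_mean_temp,
               months = spec$tss_months) else NULL,
       ny = length(site$years))
}

# Fast crossing-day computation over all years from precomputed inputs.
# Must agree exactly with predict_dfs_site(); tested against it.
fast_predict_site <- function(spec, theta, pre) {
  ny <- pre$ny
  out <- rep(NA_real_, ny)
  alanin <- if (spec$alan_enabled) exp(theta[["k"]] * pre$alan_gap)
            else rep(1, ny)
  cdd <- spec$family == "CDD"
  if (cdd) {
    T_th <- theta[["T_th"]]
    thr_all <- rep(theta[["CDD_th"]], ny)
  } else {
    T_b <- theta[["T_b"]]; P_s <- theta[["P_s"]]
    x <- theta[["x"]]; y <- theta[["y"]]
    fP <- if (spec$photoperiod_variant == "ratio") pre$photoperiod / P_s
          else pmax(1 - pre$photoperiod / P_s, 0)
    ppart <- ifelse(fP > 0, fP^y, 0)
    pcond <- pre$photoperiod <= P_s
    thr_all <- switch(spec$family,
      DM = rep(theta[["Y_crit"]], ny),
      SIAM = theta[["a"]] + theta[["b"]] * pre$lud_a,
      DMT = theta[["a"]] + theta[["b"]] * pre$tss)
  }
  for (i in seq_len(ny)) {
    thr <- thr_all[i]
    if (!is.finite(thr) || thr <= 0) next
    temps <- pre$temps[i, ]
    if (cdd) {
      cond <- pre$eligible & (temps < T_th)
      o <- which.max(cond)
      if (!cond[o]) next
      rate <- pmax(T_th - temps[o:365L], 0)
    } else {
      cond <- pre$eligible & (temps <= T_b) & pcond
      o <- which.max(cond)
      if (!cond[o]) next
      base <- pmax(T_b - temps[o:365L], 0)
      rate <- ifelse(base > 0, base^x, 0) * ppart[o:365L]
    }
    cross <- which(cumsum(rate * alanin[i]) >= thr)
    if (length(cross)) out[i] <- o + cross[1L] - 1L
  }
  out
}

#' Calibrate a senescence model by particle swarm optimization
#'
#' Minimizes the RMSE between predicted and observed DFS over the site's
#' usable years (years where the model never crosses the threshold incur
#' a fixed 100-day penalty each). Particles move under the standard
#' inertia/cognitive/social update; positions leaving a bound are
#' reflected back inside and the corresponding velocity component is
#' reversed. Fully deterministic given `seed`.
#'
#' @param spec A [senescence_spec()].
#' @param site A `site_dataset` with `dfs_observed` filled.
#' @param bounds Optional data.frame (param, lower, upper); defaults to
#'   [param_bounds()].
#' @param config PSO settings from [pso_config()].
#' @param seed Integer seed.
#' @return A `calibration_result`: `spec`, `best_params` (named),
#'   `objective` (days), `n_years_used`, `convergence` (best objective
#'   per iteration, non-increasing), `seed`.
#' @export
pso_calibrate <- function(spec, site, bounds = NULL, config = pso_config(),
                          seed = 1L) {
  if (is.null(bounds)) bounds <- param_bounds(spec)
  obs <- site$dfs_observed
  usable <- sum(!is.na(obs))
  if (usable < 8L) stop("need at least 8 usable observed years")
  lower <- bounds$lower; upper <- bounds$upper
  d <- nrow(bounds)

  pre <- precompute_site(spec, site)
  obj_fun <- function(theta) {
    names(theta) <- bounds$param
    calibration_objective(fast_predict_site(spec, theta, pre), obs)
  }

  np <- config$particles
  run_swarm <- function(swarm_seed) {
    set.seed(swarm_seed)
    pos <- matrix(stats::runif(np * d, rep(lower, each = np),
                               rep(upper, each = np)), np, d)
    vel <- matrix(stats::runif(np * d, -1, 1), np, d) *
      rep((upper - lower) * 0.1, each = np)
    pbest <- pos
    pbest_val <- apply(pos, 1, obj_fun)
    g <- which.min(pbest_val)
    gbest <- pbest[g, ]; gbest_val <- pbest_val[g]
    history <- numeric(config$iterations)

    for (it in seq_len(config$iterations)) {
      r1 <- matrix(stats::runif(np * d), np, d)
      r2 <- matrix(stats::runif(np * d), np, d)
      vel <- config$inertia * vel +
        config$cognitive * r1 * (pbest - pos) +
        config$social * r2 * sweep(-pos, 2, gbest, `+`)
      pos <- pos + vel
      # reflective bound handling
      for (j in seq_len(d)) {
        below <- pos[, j] < lower[j]
        above <- pos[, j] > upper[j]
        pos[below, j] <- pmin(upper[j], 2 * lower[j] - pos[below, j])
        pos[above, j] <- pmax(lower[j], 2 * upper[j] - pos[above, j])
        vel[below | above, j] <- -vel[below | above, j]
        pos[, j] <- pmin(upper[j], pmax(lower[j], pos[, j]))
      }
      vals <- apply(pos, 1, obj_fun)
      improved <- vals < pbest_val
      pbest[improved, ] <- pos[improved, , drop = FALSE]
      pbest_val[improved] <- vals[improved]
      g <- which.min(pbest_val)
      if (pbest_val[g] < gbest_val) {
        gbest <- pbest[g, ]; gbest_val <- pbest_val[g]
      }
      history[it] <- gbest_val
    }
    list(gbest = gbest, gbest_val = gbest_val, history = history)
  }

  runs <- lapply(seq_len(config$restarts), function(r)
    run_swarm(derive_seed(seed, r)))
  best_run <- which.min(vapply(runs, `[[`, numeric(1), "gbest_val"))
  gbest <- runs[[best_run]]$gbest
  gbest_val <- runs[[best_run]]$gbest_val
  # running best across restarts keeps the trace non-increasing
  convergence <- cummin(unlist(lapply(runs, `[[`, "history")))
  if (!is.finite(gbest_val))
    stop("calibration failure: no particle produced any threshold crossing")
  best <- stats::setNames(as.numeric(gbest), bounds$param)
  structure(list(spec = spec, best_params = best, objective = gbest_val,
                 n_years_used = usable, convergence = convergence,
                 seed = seed),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> %s: objective %.3f days over %d years\n",
              model_name(x$spec), x$objective, x$n_years_used))
  print(round(x$best_params, 4))
  invisible(x)
}

#' Score predicted against observed senescence dates
#'
#' Pearson correlation with its two-sided t-test p-value, RMSE, and
#' \eqn{AIC = n \ln(\sum_i (p_i - o_i)^2 / n) + 2k}. Zero variance in
#' either series makes r undefined (returned NA with a reason); a perfect
#' fit (SSE = 0) returns -Inf AIC with a warning.
#'
#' @param predicted,observed Day-of-year vectors per year (NA allowed).
#' @param k_params Number of model parameters (AIC penalty).
#' @return An `evaluation_metrics` list: `r`, `p_value`, `rmse`, `aic`,
#'   `n`, `k_params`, `r_reason`.
#' @export
evaluate_predictions <- function(predicted, observed, k_params) {
  stopifnot(length(predicted) == length(observed), k_params >= 0)
  ok <- !is.na(predicted) & !is.na(observed)
  n <- sum(ok)
  if (n < 3L) stop("need at least 3 paired non-missing years")
  p <- predicted[ok]; o <- observed[ok]
  sse <- sum((p - o)^2)
  rmse <- sqrt(sse / n)
  if (sse == 0) {
    warning("perfect fit: SSE = 0, AIC reported as -Inf")
    aic <- -Inf
  } else aic <- n * log(sse / n) + 2 * k_params
  r <- NA_real_; pv <- NA_real_; reason <- NA_character_
  if (stats::sd(p) < 1e-12 || stats::sd(o) < 1e-12) {
    reason <- "zero variance in predicted or observed series"
  } else {
    ct <- stats::cor.test(p, o)
    r <- unname(ct$estimate); pv <- ct$p.value
  }
  structure(list(r = r, p_value = pv, rmse = rmse, aic = aic, n = n,
                 k_params = k_params, r_reason = reason),
            class = "evaluation_metrics")
}

#' @export
print.evaluation_metrics <- function(x, ...) {
  cat(sprintf("<evaluation_metrics> n=%d k=%d  r=%.3f (p=%.3g)  RMSE=%.2f  AIC=%.2f\n",
              x$n, x$k_params, x$r, x$p_value, x$rmse, x$aic))
  invisible(x)
}

#' Compare model variants across sites
#'
#' Aggregates per-site evaluation metrics for each model into the
#' comparison table used to judge whether the ALAN term earns its extra
#' parameter: mean r, share of sites with a significant positive-df
#' correlation at the given level, mean RMSE, and mean AIC.
#'
#' @param evaluations Named list (one element per model name) of lists of
#'   `evaluation_metrics` (one per site).
#' @param sig_level Significance level for the share (default 0.05).
#' @return data.frame with one row per model: `model`, `n_sites`,
#'   `mean_r`, `sig_share`, `mean_rmse`, `mean_aic`.
#' @export
compare_models <- function(evaluations, sig_level = 0.05) {
  stopifnot(length(evaluations) >= 1L)
  rows <- lapply(names(evaluations), function(nm) {
    ev <- evaluations[[nm]]
    r <- vapply(ev, `[[`, numeric(1), "r")
    pv <- vapply(ev, `[[`, numeric(1), "p_value")
    data.frame(model = nm, n_sites = length(ev),
               mean_r = mean(r, na.rm = TRUE),
               sig_share = mean(!is.na(pv) & pv < sig_level),
               mean_rmse = mean(vapply(ev, `[[`, numeric(1), "rmse")),
               mean_aic = mean(vapply(ev, `[[`, numeric(1), "aic")))
  })
  do.call(rbind, rows)
}

#' Century-scale senescence projection
#'
#' Runs a calibrated model over a multi-decade scenario (daily
#' temperature, projected annual ALAN, latitude) and summarizes the
#' trajectory with a Theil-Sen slope (Mann-Kendall significance); years
#' with no crossing are excluded from the trend.
#'
#' @param spec A [senescence_spec()].
#' @param params Calibrated named parameter vector.
#' @param scenario List with `years`, `daily_temp` (years x 365 matrix),
#'   `alan` (per year), `latitude`, and optionally `lud` (per year,
#'   required for SIAM).
#' @return List with `years`, `dfs` (predicted per year), `trend`
#'   (the [theil_sen()] result).
#' @export
run_projection <- function(spec, params, scenario) {
  stopifnot(all(c("years", "daily_temp", "alan", "latitude") %in%
                  names(scenario)))
  site <- structure(list(site_id = "scenario", latitude = scenario$latitude,
                         years = scenario$years,
                         daily_temp = scenario$daily_temp,
                         alan = scenario$alan,
                         lud = scenario$lud %||% rep(NA_real_,
                                                     length(scenario$years)),
                         gdp = rep(NA_real_, length(scenario$years)),
                         dfs_true = NA, dfs_observed = NA),
                    class = "site_dataset")
  dfs <- predict_dfs_site(spec, params, site)
  list(years = scenario$years, dfs = dfs,
       trend = theil_sen(dfs, scenario$years))
}
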