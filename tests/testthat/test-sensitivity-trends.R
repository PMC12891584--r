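test_that("detrend/normalize produces standardized anomalies", {
  expect_error(detrend_normalize(2 * (1:10) + 3), "zero residual variance")
  # alternating noise built orthogonal to both intercept and trend so the
  # residuals reproduce it exactly up to scale
  e <- c(rep(c(1, -1), 5), rep(c(-1, 1), 5))
  x <- 2 * (1:20) + 3 + e
  z <- detrend_normalize(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-9)
  expect_equal(z, e / sd(e), tolerance = 1e-9)
  set.seed(3)
  y <- rnorm(15) + 0.3 * (1:15)
  zy <- detrend_normalize(y)
  expect_equal(mean(zy), 0, tolerance = 1e-12)
  expect_equal(sd(zy), 1, tolerance = 1e-9)
})

test_that("Theil-Sen equals the exhaustive pairwise median oracle", {
  ts <- theil_sen(2 * (1:22) + 1)
  expect_equal(ts$slope, 2)
  expect_lt(ts$p_value, 0.05)

  const <- theil_sen(rep(5, 10))
  expect_equal(const$slope, 0)
  expect_equal(const$p_value, 1)

  set.seed(13)
  for (rep in 1:10) {
    n <- sample(5:10, 1)
    y <- rnorm(n)
    # brute-force oracle: double loop over all pairs
    slopes <- c()
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      slopes <- c(slopes, (y[j] - y[i]) / (j - i))
    expect_equal(theil_sen(y)$slope, median(slopes))
  }
})

test_that("partial correlation matches the precision-matrix formula", {
  set.seed(17)
  # no controls: plain Pearson
  x <- rnorm(25); y <- 0.6 * x + rnorm(25)
  pc <- partial_correlation(x, y)
  expect_equal(pc$r, cor(x, y))
  expect_equal(pc$p_value, cor.test(x, y)$p.value, tolerance = 1e-12)

  # y = x with an orthogonal control: r stays ~1
  ctrl <- rnorm(25)
  expect_gt(partial_correlation(x, x + 1e-8 * rnorm(25), ctrl)$r, 0.999)

  # 3-variable oracle: r_xy.z = -P_xy / sqrt(P_xx P_yy), P = inverse corr
  for (rep in 1:20) {
    z <- rnorm(30)
    a <- 0.5 * z + rnorm(30)
    b <- -0.4 * z + 0.3 * a + rnorm(30)
    P <- solve(cor(cbind(a, b, z)))
    oracle <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
    expect_equal(partial_correlation(a, b, z)$r, oracle, tolerance = 1e-9)
  }

  # invariance to affine rescaling of controls
  z2 <- cbind(rnorm(30), rnorm(30))
  a <- rnorm(30); b <- rnorm(30)
  r1 <- partial_correlation(a, b, z2)$r
  r2 <- partial_correlation(a, b, cbind(3 * z2[, 1] - 7, -0.5 * z2[, 2]))$r
  expect_equal(r1, r2, tolerance = 1e-12)

  expect_error(partial_correlation(a, b, cbind(z2[, 1], 2 * z2[, 1])),
               "collinear")
  expect_error(partial_correlation(rnorm(4), rnorm(4), cbind(rnorm(4), rnorm(4))),
               "n_controls")
})

test_that("optimal preseason finds a planted window and is an argmax", {
  years <- 2001:2022
  ny <- length(years)
  anchor <- 10  # mean DFS around day 288 -> October
  set.seed(23)
  dfs_anom <- rnorm(ny, 0, 1)
  dfs <- round(288 + 4 * dfs_anom)
  # plant the signal: only the full 3-month mean (months 8-10) equals the
  # DFS anomaly -- each single month is corrupted by a disturbance that
  # cancels across the window, so shorter windows correlate worse
  monthly <- matrix(rnorm(ny * 12), ny, 12, dimnames = list(years, NULL))
  d <- rnorm(ny, 0, 1)
  monthly[, 10] <- dfs_anom + d
  monthly[, 9] <- dfs_anom - 2 * d
  monthly[, 8] <- dfs_anom + d
  est <- optimal_preseason(dfs, years, monthly, max_months = 6)
  expect_equal(est$anchor_month, 10L)
  expect_equal(est$preseason_length, 3L)
  expect_gt(abs(est$partial_r), 0.95)
  # argmax property over all candidate lengths
  expect_true(all(abs(est$partial_r) >= abs(est$candidates$partial_r)))

  # max_months = 1 reduces to the single anchored window
  est1 <- optimal_preseason(dfs, years, monthly, max_months = 1)
  expect_equal(est1$preseason_length, 1L)
  pc <- partial_correlation(detrend_normalize(monthly[, 10]),
                            detrend_normalize(dfs))
  expect_equal(est1$partial_r, pc$r, tolerance = 1e-12)
})

test_that("selection over window lengths inflates |r| like a max statistic", {
  # pure-noise driver: the selected |partial r| must stochastically exceed
  # the fixed single-window |r| because it is a max over 6 correlated tries
  years <- 2001:2022
  ny <- length(years)
  set.seed(29)
  sel <- fixed <- numeric(60)
  for (i in seq_len(60)) {
    dfs <- round(288 + rnorm(ny, 0, 4))
    monthly <- matrix(rnorm(ny * 12), ny, 12, dimnames = list(years, NULL))
    est <- optimal_preseason(dfs, years, monthly, max_months = 6)
    sel[i] <- abs(est$partial_r)
    fixed[i] <- abs(est$candidates$partial_r[1])
  }
  expect_true(all(sel >= fixed))
  expect_gt(mean(sel), mean(fixed))
})

test_that("ridge sensitivities shrink correctly from the OLS limit", {
  set.seed(31)
  n <- 40
  X <- scale(matrix(rnorm(n * 3), n, 3))
  colnames(X) <- c("alan", "temp", "precip")
  y <- as.numeric(scale(X %*% c(0.5, -0.3, 0.2) + rnorm(n, 0, 0.5)))

  b0 <- ridge_sensitivities(y, X, penalty = 0)
  ols <- coef(lm(y ~ X))[-1]
  expect_equal(unname(b0), unname(ols), tolerance = 1e-9)

  bhuge <- ridge_sensitivities(y, X, penalty = 1e9)
  expect_lt(max(abs(bhuge)), 1e-6)

  # orthonormal design: ridge = OLS / (1 + lambda)
  Q <- qr.Q(qr(matrix(rnorm(n * 3), n, 3)))
  Qc <- sweep(Q, 2, colMeans(Q))  # centered and orthogonalized
  Qc <- qr.Q(qr(Qc))
  yq <- Qc %*% c(1, 2, -1) + 0  # exact linear response
  for (lam in c(0.5, 2)) {
    br <- ridge_sensitivities(as.numeric(yq), Qc, penalty = lam)
    b_ols <- ridge_sensitivities(as.numeric(yq), Qc, penalty = 0)
    expect_equal(unname(br), unname(b_ols) / (1 + lam), tolerance = 1e-8)
  }

  # the coefficient path shrinks monotonically in l2 norm
  norms <- vapply(c(0, 0.5, 1, 2, 5, 20),
                  function(l) sqrt(sum(ridge_sensitivities(y, X, l)^2)),
                  numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("moving-window modulation counts windows and finds planted links", {
  alan <- seq(2, 12, length.out = 22) + rnorm(22, 0, 0.1)
  sens <- 0.5 * alan + rnorm(22, 0, 0.01)
  mw <- moving_window_modulation(alan, sens, window = 11, step = 1)
  expect_equal(mw$n_windows, 12L)
  expect_gt(mw$r, 0.99)
  expect_error(moving_window_modulation(alan, sens, window = 22), "one window")
  expect_error(moving_window_modulation(alan[1:5], sens[1:5], window = 11),
               "shorter")
})

test_that("Gaussian response fit recovers parameters under noise", {
  set.seed(37)
  x <- runif(500, 0, 30)
  y <- 0.24 * exp(-(x - 3.39)^2 / 35.36) + rnorm(500, 0, 0.02)
  g <- fit_gaussian_response(y, x)
  expect_true(g$converged)
  expect_lt(abs(g$amplitude - 0.24) / 0.24, 0.05)
  expect_lt(abs(g$center - 3.39), 0.5)
  # curve evaluated at the center equals the amplitude by construction
  expect_equal(g$amplitude * exp(0), g$amplitude)

  expect_error(fit_gaussian_response(rep(0.2, 20), 1:20), "constant")
  expect_error(fit_gaussian_response(rnorm(20), rep(3, 20)), "constant")
  expect_error(fit_gaussian_response(rnorm(5), rnorm(5)), "at least 10")
})
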