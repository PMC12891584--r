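test_that("photoperiod response handles both variants and clamps at zero", {
  expect_equal(photoperiod_response(12, 12, "ratio"), 1)
  expect_equal(photoperiod_response(12, 12, "one_minus_ratio"), 0)
  expect_equal(photoperiod_response(8, 12, "ratio"), 2 / 3)
  expect_equal(photoperiod_response(20, 12, "one_minus_ratio"), 0)  # clamped
  expect_error(photoperiod_response(8, 0, "ratio"), "positive")
})

test_that("spring-summer mean and LUD anomaly are exact slice statistics", {
  expect_equal(spring_summer_mean_temp(rep(15, 365), c(3, 7)), 15)
  tm <- 10 + 12 * sin(2 * pi * ((1:365) - 108.75) / 365)
  expect_equal(spring_summer_mean_temp(tm, 6), mean(tm[152:181]))
  expect_equal(spring_summer_mean_temp(tm, 1:12), mean(tm))

  expect_equal(lud_anomaly(c(100, 110, 120)), c(-10, 0, 10))
  expect_equal(lud_anomaly(rep(107, 4)), rep(0, 4))
  set.seed(2)
  x <- rnorm(15, 110, 6)
  expect_lt(abs(sum(lud_anomaly(x))), 1e-9)
  expect_error(lud_anomaly(c(100, NA)), "2 non-missing")
})

test_that("CDD model reproduces the hand-traced accumulation", {
  temps <- c(rep(25, 172), 18, 15, 22, 10, rep(25, 365 - 176))
  tr <- predict_dfs(senescence_spec("CDD"), c(T_th = 20, CDD_th = 10),
                    temps, latitude = 45)
  expect_equal(tr$onset_day, 173L)               # first post-solstice day < 20
  expect_equal(tr$daily_state[173:176], c(2, 7, 7, 17))
  expect_equal(tr$crossing_day, 176L)            # first day state >= 10
  expect_equal(tr$threshold, 10)
})

test_that("DM with x = y = 0 accumulates one unit per qualifying day", {
  temps <- c(rep(25, 200), rep(10, 165))  # cold from day 201 on
  spec <- senescence_spec("DM", photoperiod_variant = "ratio")
  tr <- predict_dfs(spec, c(T_b = 15, P_s = 24, x = 0, y = 0, Y_crit = 5.5),
                    temps, latitude = 45)
  expect_equal(tr$onset_day, 201L)
  expect_equal(tr$crossing_day, 201L + ceiling(5.5) - 1L)
})

test_that("trace invariants: monotone state, replay, missing crossing", {
  spec <- senescence_spec("DM")
  params <- c(T_b = 18, P_s = 14, x = 1, y = 1, Y_crit = 40)
  cfg <- synthetic_config(seed = 17)
  site <- generate_site_dataset(cfg, 1)
  for (i in c(1, 5, 10)) {
    tr <- predict_dfs(spec, params, site$daily_temp[i, ], site$latitude)
    expect_true(all(diff(tr$daily_state) >= 0))
    # replay the stored increments
    expect_equal(cumsum(tr$daily_increment), tr$daily_state)
    if (!is.na(tr$crossing_day)) {
      expect_gte(tr$daily_state[tr$crossing_day], tr$threshold)
      if (tr$crossing_day > 1)
        expect_lt(tr$daily_state[tr$crossing_day - 1], tr$threshold)
    }
  }
  # unreachable threshold -> missing, not an error
  tr2 <- predict_dfs(senescence_spec("CDD"), c(T_th = 20, CDD_th = 1e6),
                     site$daily_temp[1, ], site$latitude)
  expect_true(is.na(tr2$crossing_day))
  # non-positive threshold (SIAM with hostile a, b) -> flagged invalid year
  tr3 <- predict_dfs(senescence_spec("SIAM"),
                     c(T_b = 18, P_s = 14, x = 1, y = 1, a = 1, b = 1),
                     site$daily_temp[1, ], site$latitude, lud_anom = -5)
  expect_true(is.na(tr3$crossing_day))
  expect_error(predict_dfs(senescence_spec("SIAM"),
                           c(T_b = 18, P_s = 14, x = 1, y = 1, a = 1, b = 1),
                           site$daily_temp[1, ], site$latitude),
               "LUD")
})

test_that("raising T_th never delays the CDD prediction", {
  cfg <- synthetic_config(seed = 19)
  site <- generate_site_dataset(cfg, 1)
  spec <- senescence_spec("CDD")
  for (yi in c(1, 8)) {
    crossings <- vapply(seq(10, 30, by = 2), function(tth) {
      tr <- predict_dfs(spec, c(T_th = tth, CDD_th = 150),
                        site$daily_temp[yi, ], site$latitude)
      out <- tr$crossing_day
      if (is.na(out)) 400 else out
    }, numeric(1))
    expect_true(all(diff(crossings) <= 0))
  }
})

test_that("ALAN modulation shifts predictions with the sign of k", {
  cfg <- synthetic_config(alan_noise_sd = 0, seed = 23)
  site <- generate_site_dataset(cfg, 1)
  base <- list(
    CDD = c(T_th = 20, CDD_th = 300),
    DM = c(T_b = 18, P_s = 14, x = 1, y = 1, Y_crit = 40),
    SIAM = c(T_b = 18, P_s = 14, x = 1, y = 1, a = 40, b = 1),
    DMT = c(T_b = 18, P_s = 14, x = 1, y = 1, a = 10, b = 2))
  for (fam in names(base)) {
    sp0 <- senescence_spec(fam)
    spA <- senescence_spec(fam, alan_enabled = TRUE)
    p0 <- predict_dfs_site(sp0, base[[fam]], site)
    # k = 0: ALANin is identically 1, trace identical to the base model
    expect_identical(predict_dfs_site(spA, c(base[[fam]], k = 0), site), p0)
    # alan_i < alan_max everywhere except the max year, so the exponent
    # k*(alan_i - alan_max)/alan_max is positive for k < 0: the multiplier
    # exceeds 1, accumulation speeds up, and DFS comes no later than the
    # base model. For k > 0 the multiplier is below 1 and DFS no earlier.
    pneg <- predict_dfs_site(spA, c(base[[fam]], k = -2), site)
    ppos <- predict_dfs_site(spA, c(base[[fam]], k = 2), site)
    ok <- !is.na(p0)
    expect_true(all(pneg[ok] <= p0[ok], na.rm = TRUE), label = fam)
    expect_true(all(ppos[ok] >= p0[ok], na.rm = TRUE), label = fam)
  }
})

test_that("parameter bookkeeping matches the model families", {
  expect_equal(n_params(senescence_spec("CDD")), 2L)
  expect_equal(n_params(senescence_spec("DM")), 5L)
  expect_equal(n_params(senescence_spec("SIAM")), 6L)
  expect_equal(n_params(senescence_spec("DMT")), 6L)
  expect_equal(n_params(senescence_spec("DMT", alan_enabled = TRUE)), 7L)
  b <- param_bounds(senescence_spec("CDD", alan_enabled = TRUE))
  expect_equal(b$param, c("T_th", "CDD_th", "k"))
  expect_equal(b$lower[b$param == "T_th"], 0)
  expect_equal(b$upper[b$param == "T_th"], 50)
  expect_equal(b[b$param == "k", c("lower", "upper")],
               data.frame(lower = -10, upper = 10, row.names = 3L))
  expect_error(predict_dfs(senescence_spec("CDD"), c(T_th = 20),
                           rep(10, 365), 45), "missing parameter")
})
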