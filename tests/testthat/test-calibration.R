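# Random-effect calibration, the eight mean predictors and the
# prediction-quality indexes.

test_that("calibration exactly inverts noise-free stand means", {
  phi <- c(2.5, -1.0)
  tr <- noise_free_stand(ref$params, ref$init, phi, c(35, 60, 90, 140))
  cs <- calibrate_stand(ref$params, ref$init, tr)
  expect_equal(cs$phi_d, 2.5, tolerance = 1e-10)
  expect_equal(cs$phi_h, -1.0, tolerance = 1e-10)
  expect_equal(cs$m_trees, 4L)
  # single very old tree: the exponential washes out, phi-hat -> x - alpha
  old <- data.frame(age_years = 5000, dbh_cm = 40, height_m = 27)
  cs2 <- calibrate_stand(ref$params, ref$init, old)
  expect_equal(cs2$phi_d, 40 - ref$params$alpha_d, tolerance = 1e-8)
  expect_equal(cs2$phi_h, 27 - ref$params$alpha_h, tolerance = 1e-8)
  expect_error(calibrate_stand(ref$params, ref$init,
                               data.frame(age_years = 5, dbh_cm = 1,
                                          height_m = 2)),
               class = "standsde_data_error")
  expect_error(calibrate_stand(ref$params, ref$init, tr[0, ]),
               class = "standsde_data_error")
})

test_that("calibrated effects track the true effects without shrinkage", {
  fd <- simulate_forest(500, trees_per_stand = 8, age_range = c(30, 160),
                        seed = 61)
  cal <- calibrate_all(ref$params, ref$init, fd)
  truth <- attr(fd, "true_effects")
  merged <- merge(cal, truth, by = "plot_id", suffixes = c("_hat", "_true"))
  slope_d <- stats::coef(stats::lm(phi_d_hat ~ phi_d_true, merged))[[2]]
  slope_h <- stats::coef(stats::lm(phi_h_hat ~ phi_h_true, merged))[[2]]
  expect_gt(slope_d, 0.9); expect_lt(slope_d, 1.05)
  expect_gt(slope_h, 0.9); expect_lt(slope_h, 1.05)
  # spread of calibrated effects approaches the population SD as m grows
  fd_big <- simulate_forest(300, trees_per_stand = 25, age_range = c(60, 160),
                            seed = 62)
  cal_big <- calibrate_all(ref$params, ref$init, fd_big)
  expect_equal(stats::sd(cal_big$phi_d), ref$re_vars$sigma_d, tolerance = 0.1)
})

test_that("predictor variants nest exactly", {
  t <- 65
  phi <- c(3, -1.5)
  st <- transition_state(ref$params, t, phi, ref$init)
  # conditioning at the stand's own mean collapses 4 -> 2
  expect_equal(predict_mean("h4", ref$params, t, effects = phi,
                            init = ref$init, d = st$mu_d),
               predict_mean("h2", ref$params, t, effects = phi,
                            init = ref$init), tolerance = 1e-12)
  expect_equal(predict_mean("d4", ref$params, t, effects = phi,
                            init = ref$init, h = st$mu_h),
               predict_mean("d2", ref$params, t, effects = phi,
                            init = ref$init), tolerance = 1e-12)
  # zero effects collapse 4 -> 3 and 2 -> 1 for any conditioning value
  for (d in c(18, 27.24, 41)) {
    expect_equal(predict_mean("h4", ref$params, t, effects = c(0, 0),
                              init = ref$init, d = d),
                 predict_mean("h3", ref$params, t, init = ref$init, d = d),
                 tolerance = 1e-12)
  }
  expect_equal(predict_mean("d2", ref$params, t, effects = c(0, 0),
                            init = ref$init),
               predict_mean("d1", ref$params, t, init = ref$init),
               tolerance = 1e-12)
  # the mixed conditional predictor is the conditional-law mean
  v <- transition_cov(ref$params, t, ref$init)
  m <- transition_mean(ref$params, t, phi, ref$init)
  expect_equal(predict_mean("h4", ref$params, t, effects = phi,
                            init = ref$init, d = 27.24),
               m$mu_h + (v$nu_dh2 / v$nu_d2) * (27.24 - m$mu_d),
               tolerance = 1e-12)
  expect_error(predict_mean("h4", ref$params, t, init = ref$init, d = 27),
               class = "standsde_validation_error")
  expect_error(predict_mean("h3", ref$params, t, init = ref$init),
               class = "standsde_validation_error")
})

test_that("prediction indexes match hand-computed values", {
  perfect <- prediction_indexes(c(3, 7, 11), c(3, 7, 11), p = 0)
  expect_equal(perfect$B, 0); expect_equal(perfect$AB, 0)
  expect_equal(perfect$AE, 0); expect_equal(perfect$R2, 1)
  # observed (10, 20), predicted (11, 19): errors -1, +1
  ix <- prediction_indexes(c(10, 20), c(11, 19), p = 0)
  expect_equal(ix$B, 0)
  expect_equal(ix$AB, 1)
  expect_equal(ix$AE, sqrt(2))
  expect_equal(ix$PB, -2.5)      # mean(-1/10, 1/20) * 100
  expect_equal(ix$PAB, 7.5)      # mean(1/10, 1/20) * 100
  expect_equal(ix$R2, 0.98)      # 1 - (1/2) * 2/50
  # constant predictor: R2 = 1 - (n-1)/n under p = 0
  y <- c(4, 8, 12, 16)
  ic <- prediction_indexes(y, rep(mean(y), 4), p = 0)
  expect_equal(ic$R2, 1 - 3 / 4)
  expect_true(ix$AB >= abs(ix$B))
  expect_error(prediction_indexes(c(0, 1), c(1, 1), p = 0),
               class = "standsde_data_error")
  expect_error(prediction_indexes(1:3, 1:2, p = 0),
               class = "standsde_data_error")
})

test_that("calibrated conditional predictors beat the marginal fixed ones", {
  wins_d <- 0; wins_h <- 0
  n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    fd <- simulate_forest(25, trees_per_stand = 6, age_range = c(40, 160),
                          seed = 300 + s)
    split <- as.data.frame(fd)
    cal_rows <- unlist(lapply(split(seq_len(nrow(split)), split$plot_id),
                              function(i) i[1:3]))
    cal_set <- forest_dataset(split[cal_rows, ])
    val_set <- split[-cal_rows, ]
    cal <- calibrate_all(ref$params, ref$init, cal_set)
    ab <- function(obs, pred) mean(abs(obs - pred))
    pred_d1 <- transition_mean(ref$params, val_set$age_years,
                               init = ref$init)$mu_d
    pred_h1 <- transition_mean(ref$params, val_set$age_years,
                               init = ref$init)$mu_h
    pred_d4 <- pred_h4 <- numeric(nrow(val_set))
    for (i in seq_len(nrow(val_set))) {
      eff <- cal[cal$plot_id == val_set$plot_id[i], c("phi_d", "phi_h")]
      eff <- c(eff$phi_d, eff$phi_h)
      pred_d4[i] <- predict_mean("d4", ref$params, val_set$age_years[i],
                                 effects = eff, init = ref$init,
                                 h = val_set$height_m[i])
      pred_h4[i] <- predict_mean("h4", ref$params, val_set$age_years[i],
                                 effects = eff, init = ref$init,
                                 d = val_set$dbh_cm[i])
    }
    if (ab(val_set$dbh_cm, pred_d4) <= ab(val_set$dbh_cm, pred_d1))
      wins_d <- wins_d + 1
    if (ab(val_set$height_m, pred_h4) <= ab(val_set$height_m, pred_h1))
      wins_h <- wins_h + 1
  }
  expect_gte(wins_d, 16)
  expect_gte(wins_h, 16)
})
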