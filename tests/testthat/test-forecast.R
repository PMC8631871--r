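test_that("design row counts follow the window arithmetic", {
  rec <- simulate_growth_curves(growth_sim_config(n_plants = 2, noise_sd = 0,
                                                  seed = 1))
  cfg <- forecast_config(horizons = 1, lookback = 1, learner = "linear")
  d <- build_design(rec, table1_windows()$T3, cfg)
  # T3 spans steps 84..140; base steps 84..139 have a valid lag and target
  expect_equal(length(d$designs[["1"]][["1"]]$y), 56)
  expect_equal(d$designs[["1"]][["1"]]$bases, 84:139)
})

test_that("design rows never reference steps beyond their base", {
  rec <- simulate_growth_curves(growth_sim_config(n_plants = 1, noise_sd = 0,
                                                  seed = 2))
  cfg <- forecast_config(horizons = c(6, 24), lookback = 10,
                         learner = "linear")
  d <- build_design(rec, table1_windows()$T1, cfg)
  dd <- d$designs[["1"]][["6"]]
  pa <- rec$pa[rec$plant_id == 1]
  for (k in c(1, nrow(dd$X))) {
    b <- dd$bases[k]
    expect_equal(unname(dd$X[k, paste0("pa_lag", 0:9)]), pa[b - 0:9])
    expect_equal(dd$y[k], pa[b + 6])
  }
})

test_that("missing interior steps are a named error", {
  rec <- simulate_growth_curves(growth_sim_config(n_plants = 2, seed = 3))
  rec <- rec[!(rec$plant_id == 2 & rec$time_step %in% 100:102), ]
  cfg <- forecast_config(horizons = 1, lookback = 2, learner = "linear")
  expect_error(build_design(rec, table1_windows()$T1, cfg),
               "plant 2 is missing interior steps 100, 101, 102")
})

test_that("uncapped lookback that does not fit the window errors early", {
  rec <- simulate_growth_curves(growth_sim_config(n_plants = 1, seed = 4))
  cfg <- forecast_config(lookback = 60, learner = "linear",
                         cap_lookback = FALSE)
  expect_error(build_design(rec, table1_windows()$T3, cfg),
               "does not fit")
  cfg2 <- forecast_config(horizons = 120, learner = "linear")
  expect_error(build_design(rec, table1_windows()$T1, cfg2),
               "max horizon")
})

test_that("error summary matches direct substitution and RMSE >= MAE", {
  expect_equal(error_summary(c(1, 2), c(1, 2)), list(mae = 0, rmse = 0, n = 2))
  expect_equal(error_summary(c(1, -1), c(0, 0)), list(mae = 1, rmse = 1, n = 2))
  es <- error_summary(c(0, 2), c(0, 0))
  expect_equal(es$mae, 1)
  expect_equal(es$rmse, sqrt(2))
  expect_gte(es$rmse, es$mae)
  expect_error(error_summary(1:3, 1:2), "length mismatch")
})

test_that("linear learner is exact on noiseless linear growth", {
  rec <- simulate_growth_curves(growth_sim_config(n_plants = 3, noise_sd = 0,
                                                  law = "linear", seed = 5))
  cfg <- forecast_config(learner = "linear", seed = 9)
  for (wn in c("T1", "T5")) {
    d <- build_design(rec, table1_windows()[[wn]], cfg)
    m <- suppressWarnings(fit_forecaster(d))
    r <- predict_window(m, rec)
    rel <- abs(r$predicted - r$observed) / pmax(abs(r$observed), 1e-12)
    expect_lt(max(rel), 1e-6)
  }
})

test_that("prediction bases respect the observation cutoff", {
  rec <- simulate_growth_curves(growth_sim_config(n_plants = 1, noise_sd = 0,
                                                  seed = 6))
  cfg <- forecast_config(learner = "linear", seed = 1)
  w <- table1_windows()$T5
  d <- build_design(rec, w, cfg)
  m <- suppressWarnings(fit_forecaster(d))
  r <- predict_window(m, rec)
  # every issued prediction has its base inside the observed training period
  expect_true(all(r$time_step - r$horizon <= w$train_end))
  expect_true(all(r$time_step - r$horizon >= w$train_start))
  # horizon 1 exists only for the first test step
  expect_equal(r$time_step[r$horizon == 1], w$test_start)
  # the last test step (23 DAS) is reachable only at horizons >= 42
  last <- r[r$time_step == w$test_end, ]
  expect_true(all(last$horizon >= 42))
  expect_setequal(unique(last$horizon), c(42, 48))
})

test_that("predictions ignore future values (no leakage)", {
  rec <- simulate_growth_curves(growth_sim_config(n_plants = 1, seed = 7))
  cfg <- forecast_config(learner = "gbt", params = list(nrounds = 10),
                         seed = 2)
  w <- table1_windows()$T3
  m <- suppressWarnings(fit_forecaster(build_design(rec, w, cfg)))
  r1 <- predict_window(m, rec)
  # corrupt everything after the training window; predictions cannot change
  rec2 <- rec
  sel <- rec2$time_step > w$train_end
  rec2$pa[sel] <- rec2$pa[sel] * 100
  rec2$hull_area[sel] <- rec2$hull_area[sel] * 100
  r2 <- predict_window(m, rec2)
  expect_equal(r1$predicted, r2$predicted, tolerance = 1e-12)
})

test_that("gbt forecasts are seed-deterministic", {
  rec <- simulate_growth_curves(growth_sim_config(n_plants = 2, seed = 8))
  cfg <- forecast_config(learner = "gbt", params = list(nrounds = 15),
                         seed = 3)
  w <- table1_windows()$T3
  r1 <- predict_window(suppressWarnings(
    fit_forecaster(build_design(rec, w, cfg))), rec)
  r2 <- predict_window(suppressWarnings(
    fit_forecaster(build_design(rec, w, cfg))), rec)
  expect_identical(r1$predicted, r2$predicted)
})

test_that("compare_windows covers all six windows with finite errors", {
  rec <- simulate_growth_curves(growth_sim_config(n_plants = 4, seed = 9))
  cfg <- forecast_config(learner = "linear", seed = 4)
  cmp <- suppressWarnings(compare_windows(rec, config = cfg))
  expect_equal(cmp$summary$window, paste0("T", 1:6))
  expect_true(all(is.finite(cmp$summary$global_mae)))
  expect_true(all(is.finite(cmp$summary$global_rmse)))
  expect_true(all(cmp$summary$global_rmse >= cmp$summary$global_mae - 1e-12))
  expect_setequal(unique(cmp$checkpoints$time_step), c(154, 165))
  ce <- checkpoint_error(cmp$checkpoints, 165)
  expect_equal(nrow(ce), 6)
  expect_true(all(is.finite(ce$mae)))
})
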