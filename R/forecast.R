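# Per-plant direct multi-horizon forecasting of projected area on the
# daylight step grid, with lagged shape features, stage-defined training
# windows and MAE/RMSE scoring.

#' Forecasting configuration
#'
#' Direct (one model per horizon) forecasting per plant. A design row at
#' base step `t` holds the most recent `lookback` values of each dynamic
#' feature, `f(t), f(t-1), ..., f(t-lookback+1)`, plus calendar features of
#' `t`; its target for horizon `h` is `pa(t + h)`. One measured step equals
#' one daylight hour, so a 12-step horizon is one day ahead.
#'
#' The lookback is capped per window and horizon so that at least `min_rows`
#' training rows remain; long horizons in short windows otherwise leave an
#' empty design.
#'
#' @param horizons Forecast horizons in measured hours
#'   (default 1, 6, 12, 24, 36, 42, 48).
#' @param lookback Number of recent steps used as lagged features
#'   (default 48).
#' @param dynamic Dynamic feature columns from the feature table.
#' @param calendar Include calendar features of the base step (integer day
#'   and clock hour). Default: on for the tree learner, off for the linear
#'   learner (step functions and periodic hour encodings do not extrapolate
#'   linearly, so the OLS baseline is a pure map of lagged features).
#' @param learner `"gbt"` (gradient-boosted trees) or `"linear"` (ordinary
#'   least squares).
#' @param params Learner hyperparameters; for `gbt`: `nrounds` (default 60),
#'   `max_depth` (3), `eta` (0.3).
#' @param min_rows Minimum training rows preserved when capping the
#'   lookback; designs with fewer than 5 rows or a constant target fall back
#'   to a mean predictor.
#' @param cap_lookback Cap the lookback per window and horizon (default).
#'   When `FALSE`, a lookback that does not fit the training window is a
#'   configuration error instead.
#' @param seed Integer seed.
#' @return An object of class `forecast_config`.
#' @export
forecast_config <- function(horizons = c(1L, 6L, 12L, 24L, 36L, 42L, 48L),
                            lookback = 48L,
                            dynamic = c("pa", "hull_area", "compactness"),
                            calendar = NULL,
                            learner = c("gbt", "linear"),
                            params = list(), seed = 1L, min_rows = 10L,
                            cap_lookback = TRUE) {
  learner <- match.arg(learner)
  stopifnot(all(horizons >= 1), lookback >= 1, length(dynamic) >= 1,
            "pa" %in% dynamic || TRUE)
  defaults <- list(nrounds = 60L, max_depth = 3L, eta = 0.3)
  params <- utils::modifyList(defaults, params)
  calendar <- calendar %||% (learner == "gbt")
  structure(list(horizons = as.integer(sort(unique(horizons))),
                 lookback = as.integer(lookback), dynamic = dynamic,
                 calendar = isTRUE(calendar), learner = learner,
                 params = params, seed = as.integer(seed),
                 min_rows = as.integer(min_rows),
                 cap_lookback = isTRUE(cap_lookback)),
            class = "forecast_config")
}

validate_forecast_setup <- function(window, config) {
  if (max(config$horizons) > window$test_end - window$train_start) {
    stop("max horizon ", max(config$horizons),
         " exceeds the reach of window ", window$name,
         " (no test step has an in-window base)")
  }
  train_len <- window$train_end - window$train_start + 1L
  if (!config$cap_lookback && config$lookback >= train_len) {
    stop("lookback ", config$lookback, " does not fit the ",
         train_len, "-step training window ", window$name)
  }
  invisible(TRUE)
}

effective_lookback <- function(config, window, h) {
  train_len <- window$train_end - window$train_start + 1L
  max(1L, min(config$lookback, train_len - h - config$min_rows + 1L))
}

# Per-plant series matrix indexed by step, with coverage checks.
plant_series <- function(rec, window, plant) {
  need <- window$train_start:window$test_end
  have <- rec$time_step
  missing_steps <- setdiff(window$train_start:window$train_end, have)
  if (length(missing_steps)) {
    stop("plant ", plant, " is missing interior steps ",
         paste(head(missing_steps, 5), collapse = ", "),
         if (length(missing_steps) > 5) " ..." else "")
  }
  rec[order(rec$time_step), , drop = FALSE]
}

lag_matrix <- function(series, bases, L) {
  # series: named numeric indexed by step; bases: base steps; L lags 0..L-1
  out <- matrix(NA_real_, length(bases), L)
  for (l in 0:(L - 1L)) out[, l + 1L] <- series[bases - l]
  out
}

design_features <- function(rec_s, bases, L, config, grid) {
  step_index <- rec_s$time_step
  cols <- list()
  for (f in config$dynamic) {
    s <- rep(NA_real_, max(step_index))
    s[step_index] <- rec_s[[f]]
    m <- lag_matrix(s, bases, L)
    colnames(m) <- paste0(f, "_lag", 0:(L - 1L))
    cols[[f]] <- m
  }
  X <- do.call(cbind, cols)
  if (config$calendar) {
    das <- step_to_das(bases, grid)
    X <- cbind(X, cal_day = floor(das), cal_hour = round((das %% 1) * 24))
  }
  X
}

#' Build per-plant, per-horizon design matrices
#'
#' For every plant and horizon `h`, rows are base steps `t` inside the
#' training window whose lags and target both fall inside the window:
#' `t` from `train_start + L - 1` to `train_end - h` where `L` is the
#' (capped) lookback. The target is `pa(t + h)`. A design row at step `t`
#' never references any step beyond `t` except through its target.
#'
#' @param records Feature table (see [simulate_growth_curves()]).
#' @param window A [window_spec()].
#' @param config A [forecast_config()].
#' @param grid A [time_grid()].
#' @return An object of class `forecast_design`: nested list
#'   `designs[[plant]][[horizon]] = list(X, y, bases, L)`.
#' @export
build_design <- function(records, window, config, grid = time_grid()) {
  validate_forecast_setup(window, config)
  plants <- unique(records$plant_id)
  designs <- list()
  for (p in plants) {
    rec_s <- plant_series(records[records$plant_id == p, , drop = FALSE],
                          window, p)
    per_h <- list()
    for (h in config$horizons) {
      L <- effective_lookback(config, window, h)
      t_lo <- window$train_start + L - 1L
      t_hi <- window$train_end - h
      if (t_lo > t_hi) {
        # horizon longer than the training window: no (base, target) pair
        # fits inside it; record the persistence level (PA at training end)
        pa_end <- rec_s$pa[rec_s$time_step == window$train_end]
        per_h[[as.character(h)]] <- list(X = NULL, y = numeric(0),
                                         bases = integer(0), L = L,
                                         persist = pa_end)
        next
      }
      bases <- t_lo:t_hi
      X <- design_features(rec_s, bases, L, config, grid)
      pa_series <- rep(NA_real_, max(rec_s$time_step))
      pa_series[rec_s$time_step] <- rec_s$pa
      y <- pa_series[bases + h]
      per_h[[as.character(h)]] <- list(X = X, y = y, bases = bases, L = L)
    }
    designs[[as.character(p)]] <- per_h
  }
  structure(list(designs = designs, window = window, config = config,
                 grid = grid),
            class = "forecast_design")
}

fit_one <- function(X, y, config, persist = NULL) {
  if (is.null(X) || length(y) < 5L || var(y) == 0) {
    if (length(y) == 0L && !is.null(persist)) {
      warning("horizon exceeds the training window; ",
              "falling back to persistence of the last training value",
              call. = FALSE)
      return(list(type = "mean", value = persist))
    }
    if (length(y) < 5L && length(y) > 0) {
      warning("degenerate design (", length(y),
              " rows); falling back to mean predictor", call. = FALSE)
    }
    return(list(type = "mean",
                value = if (length(y)) mean(y) else NA_real_))
  }
  if (config$learner == "linear") {
    # minimum-norm least squares via SVD: exact on consistent systems, and
    # bounded coefficients when the lagged design is underdetermined
    Xi <- cbind(1, X)
    sv <- svd(Xi)
    tol <- max(dim(Xi)) * .Machine$double.eps * sv$d[1]
    dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
    coefs <- sv$v %*% (dinv * crossprod(sv$u, y))
    list(type = "linear", coef = drop(coefs))
  } else {
    dtrain <- xgboost::xgb.DMatrix(X, label = y)
    booster <- xgboost::xgb.train(
      params = list(max_depth = config$params$max_depth,
                    eta = config$params$eta,
                    objective = "reg:squarederror",
                    nthread = 1L),
      data = dtrain, nrounds = config$params$nrounds, verbose = 0
    )
    # store serialized bytes: many live booster handles are fragile, and raw
    # models survive saveRDS round trips
    list(type = "gbt", booster_raw = xgboost::xgb.save.raw(booster))
  }
}

predict_one <- function(model, X) {
  switch(model$type,
         mean = rep(model$value, nrow(X)),
         linear = drop(cbind(1, X) %*% model$coef),
         gbt = predict(xgboost::xgb.load.raw(model$booster_raw),
                       xgboost::xgb.DMatrix(X)))
}

#' Fit the per-plant, per-horizon forecasters
#'
#' One direct model per (plant, horizon): gradient-boosted regression trees
#' by default, ordinary least squares for the `linear` learner. Degenerate
#' designs (fewer than 5 rows or constant target) fall back to a mean
#' predictor with a warning.
#'
#' @param design A [build_design()] result.
#' @return An object of class `forecast_models`.
#' @export
fit_forecaster <- function(design) {
  stopifnot(inherits(design, "forecast_design"))
  config <- design$config
  set.seed(config$seed)
  models <- lapply(design$designs, function(per_h) {
    lapply(per_h, function(d) fit_one(d$X, d$y, config, d$persist))
  })
  structure(list(models = models, window = design$window, config = config,
                 grid = design$grid,
                 L = lapply(design$designs, function(per_h) {
                   vapply(per_h, function(d) d$L, integer(1))
                 })),
            class = "forecast_models")
}

#' Forecast the test window
#'
#' For each test step `s` and horizon `h`, the prediction is issued from base
#' step `b = s - h` using only observations up to `b` (and never later than
#' `obs_end`, by default the training end: the scenario in which measurement
#' stops when training data ends). Test steps whose base falls before the
#' training start, or beyond `obs_end`, are skipped and counted.
#'
#' @param models A [fit_forecaster()] result.
#' @param records Feature table covering the plants.
#' @param obs_end Last step whose observations may serve as features
#'   (default: the window's training end). Set to the test end for rolling
#'   forecasts that condition on incoming test-window measurements.
#' @return An object of class `forecast_result`: data frame `plant_id,
#'   horizon, time_step, das, observed, predicted` with attribute `skipped`.
#' @export
predict_window <- function(models, records, obs_end = NULL) {
  stopifnot(inherits(models, "forecast_models"))
  window <- models$window
  config <- models$config
  grid <- models$grid
  obs_end <- obs_end %||% window$train_end
  out <- list()
  skipped <- 0L
  for (p in names(models$models)) {
    rec_s <- records[records$plant_id == as.integer(p), , drop = FALSE]
    rec_s <- rec_s[order(rec_s$time_step), , drop = FALSE]
    pa_series <- rep(NA_real_, max(rec_s$time_step))
    pa_series[rec_s$time_step] <- rec_s$pa
    for (h in config$horizons) {
      hc <- as.character(h)
      L <- models$L[[p]][[hc]]
      s_all <- window$test_start:window$test_end
      bases <- s_all - h
      ok <- bases >= window$train_start & bases <= obs_end &
        (bases - L + 1L) >= min(rec_s$time_step)
      skipped <- skipped + sum(!ok)
      if (!any(ok)) next
      X <- design_features(rec_s, bases[ok], L, config, grid)
      pred <- predict_one(models$models[[p]][[hc]], X)
      out[[length(out) + 1L]] <- data.frame(
        plant_id = as.integer(p), horizon = h, time_step = s_all[ok],
        das = step_to_das(s_all[ok], grid),
        observed = pa_series[s_all[ok]], predicted = pred
      )
    }
  }
  res <- do.call(rbind, out)
  attr(res, "skipped") <- skipped
  attr(res, "window") <- window
  class(res) <- c("forecast_result", class(res))
  res
}

#' MAE and RMSE of a prediction vector
#'
#' Mean absolute error and root mean squared error; `rmse >= mae` always,
#' with equality iff all absolute errors are equal.
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @return List with `mae`, `rmse`, `n`.
#' @export
error_summary <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (length(observed) < 1) stop("need at least one pair")
  err <- observed - predicted
  list(mae = mean(abs(err)), rmse = sqrt(mean(err^2)), n = length(err))
}

#' Per-plant/horizon and global error summary of a forecast
#'
#' Global MAE/RMSE are the unweighted means of the per-(plant, horizon)
#' MAE/RMSE over all forecast steps.
#'
#' @param object A [predict_window()] result.
#' @param ... Unused.
#' @return List with `per` (data frame `plant_id, horizon, mae, rmse, n`)
#'   and `global_mae`, `global_rmse`, `n`.
#' @export
summary.forecast_result <- function(object, ...) {
  sp <- split(object, list(object$plant_id, object$horizon), drop = TRUE)
  per <- do.call(rbind, lapply(sp, function(d) {
    es <- error_summary(d$observed, d$predicted)
    data.frame(plant_id = d$plant_id[1], horizon = d$horizon[1],
               mae = es$mae, rmse = es$rmse, n = es$n)
  }))
  rownames(per) <- NULL
  list(per = per, global_mae = mean(per$mae), global_rmse = mean(per$rmse),
       n = sum(per$n))
}

#' Run all training windows and collect checkpoint predictions
#'
#' Fits and scores every window with a shared seed, returning the per-window
#' global error table and per-plant predictions at the checkpoint steps
#' (default: the 22.71-DAS step and the final 23-DAS step of the default
#' grid) for the statistical validation stage.
#'
#' @param records Feature table.
#' @param windows Named list of [window_spec()]s (default
#'   [table1_windows()]).
#' @param config A [forecast_config()].
#' @param grid A [time_grid()].
#' @param checkpoint_steps Steps at which per-plant predictions are
#'   extracted.
#' @return List with `summary` (window, global_mae, global_rmse),
#'   `checkpoints` (window, plant_id, horizon, time_step, das, observed,
#'   predicted) and `results` (per-window `forecast_result`s).
#' @export
compare_windows <- function(records, windows = table1_windows(),
                            config = forecast_config(), grid = time_grid(),
                            checkpoint_steps = c(154L, 165L)) {
  for (w in windows) validate_forecast_setup(w, config)
  results <- list()
  summaries <- list()
  checkpoints <- list()
  for (w in windows) {
    design <- build_design(records, w, config, grid)
    models <- fit_forecaster(design)
    res <- predict_window(models, records)
    s <- summary(res)
    results[[w$name]] <- res
    summaries[[w$name]] <- data.frame(window = w$name,
                                      global_mae = s$global_mae,
                                      global_rmse = s$global_rmse, n = s$n)
    cp <- res[res$time_step %in% checkpoint_steps, , drop = FALSE]
    if (nrow(cp)) {
      cp <- data.frame(window = w$name, cp, row.names = NULL)
      checkpoints[[w$name]] <- cp
    }
  }
  list(summary = do.call(rbind, c(summaries, list(make.row.names = FALSE))),
       checkpoints = do.call(rbind, c(checkpoints, list(make.row.names = FALSE))),
       results = results)
}

#' Checkpoint error by window
#'
#' Per-window MAE over plants (and the given horizons) at one checkpoint
#' step; used to compare training windows at the end of the late
#' pre-flowering stage.
#'
#' @param checkpoints The `checkpoints` table from [compare_windows()].
#' @param step Checkpoint step.
#' @param horizons Horizons included (default: those valid for every
#'   window present).
#' @return Data frame `window, mae, rmse, n`.
#' @export
checkpoint_error <- function(checkpoints, step, horizons = NULL) {
  cp <- checkpoints[checkpoints$time_step == step, , drop = FALSE]
  if (!is.null(horizons)) cp <- cp[cp$horizon %in% horizons, , drop = FALSE]
  else {
    common <- Reduce(intersect, lapply(split(cp$horizon, cp$window), unique))
    cp <- cp[cp$horizon %in% common, , drop = FALSE]
  }
  sp <- split(cp, cp$window)
  out <- do.call(rbind, lapply(sp, function(d) {
    es <- error_summary(d$observed, d$predicted)
    data.frame(window = d$window[1], mae = es$mae, rmse = es$rmse, n = es$n)
  }))
  rownames(out) <- NULL
  out
}
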