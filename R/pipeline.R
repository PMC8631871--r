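# One reproducible end-to-end run: simulate -> image -> segment -> features
# -> forecast -> fresh-weight chain -> validation, with per-stage derived
# seeds and a checksum manifest.

#' Pipeline configuration
#'
#' All tunables of [run_pipeline()]. One root seed deterministically derives
#' the per-stage seeds, so a completed run can be re-executed bit-identically
#' (with a deterministic learner configuration).
#'
#' The imaging stage renders a small tray at a few grid steps, trains the
#' pixel segmenter on the first tray's ground truth, and verifies that
#' extracted areas match the simulated trajectories; the forecasting stage
#' runs on the full simulated feature table.
#'
#' @param seed Root seed.
#' @param out_dir Output directory.
#' @param n_plants Simulated population size.
#' @param growth Optional [growth_sim_config()] override (its seed is
#'   re-derived from `seed`).
#' @param windows Training windows (default [table1_windows()]).
#' @param forecast A [forecast_config()] (its seed is re-derived).
#' @param allometry An [allometry_params()].
#' @param n_harvest Plants per early harvest day (14, 17, 20 DAS).
#' @param n_chain Plants harvested at the final step for chain scoring.
#' @param imaging List: `enable`, `layout`, `cell_px`, `steps` (grid steps
#'   at which trays are rendered), `epochs` (segmenter epochs).
#' @param checkpoint_steps Validation checkpoint steps.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("rosettecast_run_"),
                            n_plants = 24L, growth = NULL,
                            windows = table1_windows(),
                            forecast = forecast_config(),
                            allometry = allometry_params(),
                            n_harvest = 5L, n_chain = 8L,
                            imaging = list(enable = TRUE, layout = c(2L, 4L),
                                           cell_px = 96L, steps = c(84L, 140L, 165L),
                                           epochs = 8L),
                            checkpoint_steps = c(154L, 165L)) {
  for (w in windows) validate_forecast_setup(w, forecast)
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 n_plants = as.integer(n_plants), growth = growth,
                 windows = windows, forecast = forecast,
                 allometry = allometry, n_harvest = as.integer(n_harvest),
                 n_chain = as.integer(n_chain), imaging = imaging,
                 checkpoint_steps = as.integer(checkpoint_steps)),
            class = "pipeline_config")
}

write_stage_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  path
}

run_stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  message(sprintf("[%s] done in %.1fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full pipeline
#'
#' Executes every stage in order, writing `features.csv`, `imaging_check.csv`
#' (when imaging is enabled), `predictions.csv`, `window_errors.csv`,
#' `fw_harvest.csv`, `chain_report.csv`, `validation.txt` and a `manifest.csv`
#' of MD5 checksums to the configured output directory.
#'
#' @param config A [pipeline_config()].
#' @return The manifest data frame (invisibly also written to disk), with
#'   the stage outputs attached as the `outputs` attribute.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  gcfg <- config$growth %||% growth_sim_config(n_plants = config$n_plants)
  gcfg$seed <- derive_seed(config$seed, 1L)
  records <- run_stage("simulate", simulate_growth_curves(gcfg))
  grid <- gcfg$grid

  harv <- run_stage("fresh-weight", {
    early <- simulate_fresh_weight(records, harvest_das = c(14L, 17L, 20L),
                                   n_per_harvest = config$n_harvest,
                                   params = config$allometry,
                                   seed = derive_seed(config$seed, 2L))
    late <- simulate_fresh_weight(early$records, harvest_das = 23L,
                                  n_per_harvest = config$n_chain,
                                  params = config$allometry,
                                  seed = derive_seed(config$seed, 3L))
    list(early = early$fw, late = late$fw, records = late$records)
  })
  # final-day harvest happens at the last grid step, so those plants keep a
  # complete series and can be forecast
  records <- harv$records
  files["features.csv"] <- write_stage_csv(
    records, file.path(config$out_dir, "features.csv"))
  files["fw_harvest.csv"] <- write_stage_csv(
    rbind(cbind(harv$early, stage = "early"), cbind(harv$late, stage = "late")),
    file.path(config$out_dir, "fw_harvest.csv"))

  if (isTRUE(config$imaging$enable)) {
    check <- run_stage("imaging", {
      imaging_check(records, config, grid)
    })
    files["imaging_check.csv"] <- write_stage_csv(
      check, file.path(config$out_dir, "imaging_check.csv"))
  }

  fcfg <- config$forecast
  fcfg$seed <- derive_seed(config$seed, 4L)
  # forecast the plants with complete series
  full <- names(which(table(records$plant_id) == grid$total_steps))
  rec_fc <- records[records$plant_id %in% as.integer(full), , drop = FALSE]
  cmp <- run_stage("forecast", {
    compare_windows(rec_fc, config$windows, fcfg, grid,
                    checkpoint_steps = config$checkpoint_steps)
  })
  files["window_errors.csv"] <- write_stage_csv(
    cmp$summary, file.path(config$out_dir, "window_errors.csv"))
  files["predictions.csv"] <- write_stage_csv(
    do.call(rbind, lapply(names(cmp$results), function(w) {
      data.frame(window = w, as.data.frame(cmp$results[[w]]),
                 row.names = NULL)
    })), file.path(config$out_dir, "predictions.csv"))

  chain <- run_stage("fw-chain", {
    model <- fit_fw_model(harv$early, das_range = c(14, 20))
    last_step <- max(config$checkpoint_steps)
    cp <- cmp$checkpoints
    cp <- cp[cp$window == "T3" & cp$time_step == last_step &
               cp$plant_id %in% harv$late$plant_id, , drop = FALSE]
    sc <- score_chain(model, cp, harv$late)
    list(model = model, score = sc)
  })
  files["chain_report.csv"] <- write_stage_csv(
    data.frame(slope = chain$model$slope, intercept = chain$model$intercept,
               fit_spearman_r = chain$model$fit_r,
               residual_sd = chain$model$residual_sd,
               n_fit = chain$model$n_fit,
               chain_spearman_r = chain$score$spearman_r,
               chain_mae_fw = chain$score$mae_fw, n_chain = chain$score$n),
    file.path(config$out_dir, "chain_report.csv"))

  report <- run_stage("validate", validation_report(cmp$checkpoints))
  val_path <- file.path(config$out_dir, "validation.txt")
  writeLines(utils::capture.output(print(report)), val_path)
  files["validation.txt"] <- val_path

  manifest <- data.frame(
    file = names(files),
    md5 = unname(tools::md5sum(unlist(files))),
    row.names = NULL
  )
  write.csv(manifest, file.path(config$out_dir, "manifest.csv"),
            row.names = FALSE)
  attr(manifest, "outputs") <- list(records = records, compare = cmp,
                                    chain = chain, report = report)
  manifest
}

# Render trays at selected steps, train the segmenter on the first tray's
# ground truth, segment all trays, and compare extracted PA to the simulated
# trajectory the tray was rendered from.
imaging_check <- function(records, config, grid) {
  layout <- config$imaging$layout
  cell_px <- config$imaging$cell_px
  n_cells <- prod(layout)
  plants <- sort(unique(records$plant_id))[seq_len(n_cells)]
  # area scale: map simulated "area units" onto pixels so a mature rosette
  # fills roughly a third of the cell
  px_per_unit <- 0.3 * cell_px^2 / max(records$pa)
  trays <- list()
  for (i in seq_along(config$imaging$steps)) {
    step <- config$imaging$steps[i]
    sub <- records[records$time_step == step & records$plant_id %in% plants, ]
    sub <- sub[order(sub$plant_id), ]
    crops <- lapply(seq_len(nrow(sub)), function(j) {
      render_rosette(rosette_spec(
        target_pa = max(60, sub$pa[j] * px_per_unit),
        n_leaves = 8L, img_size = cell_px,
        seed = derive_seed(config$seed, 100L + i * n_cells + j)
      ))
    })
    trays[[i]] <- list(
      scene = compose_tray(crops, layout, cell_px, margin_px = 32L,
                           seed = derive_seed(config$seed, 50L + i)),
      sub = sub
    )
  }
  train_pairs <- unlist(lapply(trays, function(tr) {
    sc <- tr$scene
    crops_img <- crop_cells(sc$nominal, layout, cell_px, sc$margin_px)
    lapply(seq_len(n_cells), function(j)
      list(image = crops_img[[j]], mask = sc$masks[[j]]))
  }), recursive = FALSE)
  model <- train_segmenter(train_pairs, epochs = config$imaging$epochs,
                           seed = derive_seed(config$seed, 60L))
  rows <- list()
  for (i in seq_along(trays)) {
    sc <- trays[[i]]$scene
    sub <- trays[[i]]$sub
    corners <- detect_markers(sc$image)
    rect <- rectify_tray(sc$image, corners,
                         tray_nominal(layout, cell_px, sc$margin_px))
    crops_img <- crop_cells(rect$image, layout, cell_px, sc$margin_px)
    for (j in seq_len(nrow(sub))) {
      mask <- segment_image(model, crops_img[[j]])
      pa_px <- projected_area(mask)
      pa_true_px <- projected_area(sc$masks[[j]])
      rows[[length(rows) + 1L]] <- data.frame(
        time_step = sub$time_step[j], plant_id = sub$plant_id[j],
        pa_px = pa_px, pa_true_px = pa_true_px,
        iou = iou(mask, sc$masks[[j]]),
        rel_err = abs(pa_px - pa_true_px) / pa_true_px
      )
    }
  }
  do.call(rbind, rows)
}
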