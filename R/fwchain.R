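# Fresh-weight allometry: fit FW ~ PA on early-stage harvests, convert
# forecast PA into predicted FW, and score the chained prediction.

#' Fit the PA -> fresh-weight regression
#'
#' Ordinary least squares `FW ~ PA` on harvest pairs inside `das_range`,
#' reporting the Spearman rank correlation of the pairs and the residual SD.
#'
#' @param fw_table Data frame with `pa`, `fw` and `das` columns (see
#'   [simulate_fresh_weight()]).
#' @param das_range Inclusive DAS range of pairs used (default 14-20, the
#'   early pre-flowering harvests).
#' @return An object of class `fw_model` with `slope`, `intercept`,
#'   `fit_r` (Spearman), `residual_sd`, `n_fit`, `fit_das_range`.
#' @export
fit_fw_model <- function(fw_table, das_range = c(14, 20)) {
  sel <- fw_table$das >= das_range[1] & fw_table$das < das_range[2] + 1
  tab <- fw_table[sel, , drop = FALSE]
  if (nrow(tab) < 3) stop("need at least 3 (PA, FW) pairs in the DAS range")
  fit <- lm(fw ~ pa, data = tab)
  structure(list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    fit_r = suppressWarnings(cor(tab$pa, tab$fw, method = "spearman")),
    residual_sd = sqrt(sum(residuals(fit)^2) / max(1, nrow(tab) - 2)),
    n_fit = nrow(tab),
    fit_das_range = das_range,
    fit = fit
  ), class = "fw_model")
}

#' Estimate fresh weight from projected area
#'
#' Elementwise `slope * PA + intercept`; negative estimates are clipped to 0
#' and flagged in the `clipped` attribute.
#'
#' @param model An [fit_fw_model()] result.
#' @param pa Numeric PA values.
#' @return FW estimates with attribute `clipped` (logical vector).
#' @export
estimate_fw <- function(model, pa) {
  stopifnot(inherits(model, "fw_model"))
  est <- model$slope * pa + model$intercept
  clipped <- est < 0
  est[clipped] <- 0
  attr(est, "clipped") <- clipped
  est
}

#' Score the forecast -> fresh-weight chain
#'
#' Converts checkpoint *predicted* PA into FW with the early-stage model and
#' scores it against the harvested FW of the same plants: Spearman R and MAE
#' in FW units.
#'
#' @param model An [fit_fw_model()] result.
#' @param predicted_pa Data frame with `plant_id` and `predicted` (PA at the
#'   checkpoint; e.g. a subset of [compare_windows()]'s `checkpoints`).
#' @param fw_truth Data frame with `plant_id` and `fw` at the checkpoint
#'   harvest.
#' @return List with `spearman_r`, `mae_fw`, `n`, and the merged table.
#' @export
score_chain <- function(model, predicted_pa, fw_truth) {
  merged <- merge(
    stats::aggregate(predicted ~ plant_id, data = predicted_pa, FUN = mean),
    fw_truth[, c("plant_id", "fw")], by = "plant_id"
  )
  if (nrow(merged) == 0) stop("no overlap between forecast plants and FW truth")
  merged$fw_pred <- as.numeric(estimate_fw(model, merged$predicted))
  list(
    spearman_r = suppressWarnings(cor(merged$fw, merged$fw_pred,
                                      method = "spearman")),
    mae_fw = mean(abs(merged$fw - merged$fw_pred)),
    n = nrow(merged),
    table = merged
  )
}
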