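# Statistical validation of forecast outputs: one-way ANOVA across training
# windows, Tukey HSD at 95% family confidence, observed-vs-predicted t-tests
# and Spearman correlations. The standard-model machinery is delegated to
# stats::aov / TukeyHSD / t.test; this module wires it to the pipeline's
# checkpoint tables and conventions.

#' One-way ANOVA across groups
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each n >= 2).
#' @return List with `f` and `p`. Zero variance everywhere (all groups
#'   identical constants) yields `f = 0, p = 1` by convention, with a
#'   message.
#' @export
anova_one_way <- function(groups) {
  stopifnot(length(groups) >= 2, all(vapply(groups, length, 1L) >= 2))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  if (var(values) == 0) {
    message("all observations identical; ANOVA defined as F = 0, p = 1")
    return(list(f = 0, p = 1))
  }
  fit <- aov(values ~ g)
  s <- summary(fit)[[1]]
  f <- s[["F value"]][1]
  p <- s[["Pr(>F)"]][1]
  if (!is.finite(f)) {
    message("degenerate within-group variance; ANOVA p defined as 1")
    return(list(f = 0, p = 1))
  }
  list(f = f, p = p)
}

#' Tukey honestly-significant-difference intervals
#'
#' Studentized-range simultaneous intervals and adjusted p-values for all
#' group pairs at the given family-wise confidence level.
#'
#' @param groups Named list of numeric vectors.
#' @param family_conf Family-wise confidence level (default 0.95).
#' @return Data frame `pair, diff, lwr, upr, p_adj`.
#' @export
tukey_hsd <- function(groups, family_conf = 0.95) {
  stopifnot(length(groups) >= 2, all(vapply(groups, length, 1L) >= 2))
  nm <- names(groups) %||% as.character(seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(nm, vapply(groups, length, 1L)), levels = nm)
  fit <- aov(values ~ g)
  tk <- TukeyHSD(fit, conf.level = family_conf)$g
  data.frame(pair = rownames(tk), diff = tk[, "diff"], lwr = tk[, "lwr"],
             upr = tk[, "upr"], p_adj = tk[, "p adj"], row.names = NULL)
}

#' Observed-vs-predicted tests per window
#'
#' For every training window at the checkpoint: a two-sided t-test of
#' observed against predicted PA (paired by plant, by default) and the
#' Spearman rank correlation across plants. Zero-variance differences leave
#' the t statistic undefined; the p-value is then defined as 1 when the
#' constant difference is 0 (identical vectors) and 0 otherwise (an exact
#' nonzero shift).
#'
#' @param checkpoints Checkpoint table (`window, plant_id, observed,
#'   predicted`); multiple horizons per plant are averaged first.
#' @param paired Paired t-test (default) or two-sample.
#' @param alpha Significance level for the `significant` flag
#'   (default 0.01).
#' @return Data frame `window, t_p, spearman_r, n, significant`.
#' @export
observed_vs_predicted_tests <- function(checkpoints, paired = TRUE,
                                        alpha = 0.01) {
  sp <- split(checkpoints, checkpoints$window)
  out <- do.call(rbind, lapply(sp, function(d) {
    agg <- merge(
      stats::aggregate(observed ~ plant_id, data = d, FUN = mean),
      stats::aggregate(predicted ~ plant_id, data = d, FUN = mean),
      by = "plant_id"
    )
    if (nrow(agg) < 3) stop("need at least 3 plants per window")
    p <- tryCatch(
      t.test(agg$observed, agg$predicted, paired = paired)$p.value,
      error = function(e) {
        # degenerate (zero-variance) case
        if (isTRUE(all.equal(agg$observed, agg$predicted))) 1 else 0
      }
    )
    if (is.na(p)) {
      p <- if (isTRUE(all.equal(agg$observed, agg$predicted))) 1 else 0
    }
    r <- suppressWarnings(cor(agg$observed, agg$predicted,
                              method = "spearman"))
    data.frame(window = d$window[1], t_p = p, spearman_r = r, n = nrow(agg),
               significant = p < alpha)
  }))
  rownames(out) <- NULL
  out
}

#' Full validation report at a checkpoint
#'
#' Reproduces the validation protocol on a checkpoint table: one-way ANOVA
#' across the per-window predicted values (plus the observed group), Tukey
#' HSD pairwise intervals at 95% family confidence, per-window paired
#' t-tests and Spearman correlations, with significance flagged at
#' `alpha = 0.01`.
#'
#' @param checkpoints Checkpoint table from [compare_windows()].
#' @param alpha Significance level.
#' @param family_conf Tukey family confidence level.
#' @return An object of class `validation_report`.
#' @export
validation_report <- function(checkpoints, alpha = 0.01, family_conf = 0.95) {
  per_plant <- function(d) {
    a <- stats::aggregate(predicted ~ plant_id, data = d, FUN = mean)
    a$predicted
  }
  sp <- split(checkpoints, checkpoints$window)
  groups <- lapply(sp, per_plant)
  obs <- stats::aggregate(observed ~ plant_id, data = checkpoints, FUN = mean)
  groups <- c(list(observed = obs$observed), groups)
  an <- anova_one_way(groups)
  tk <- tukey_hsd(groups, family_conf)
  tests <- observed_vs_predicted_tests(checkpoints, alpha = alpha)
  structure(list(
    checkpoint_steps = sort(unique(checkpoints$time_step)),
    anova_f = an$f, anova_p = an$p,
    tukey = tk, tests = tests, alpha = alpha
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation at step(s)",
      paste(x$checkpoint_steps, collapse = ", "), "\n")
  cat(sprintf("ANOVA across groups: F = %.4f, p = %.4g\n", x$anova_f,
              x$anova_p))
  cat("\nObserved vs predicted per window:\n")
  print(transform(x$tests, t_p = signif(t_p, 4),
                  spearman_r = round(spearman_r, 4)), row.names = FALSE)
  cat("\nTukey HSD (adjusted p):\n")
  print(transform(x$tukey[, c("pair", "diff", "p_adj")],
                  diff = round(diff, 4), p_adj = signif(p_adj, 4)),
        row.names = FALSE)
  invisible(x)
}
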