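# CPU-trainable segmentation harness. The default learner is a compact
# encoder-decoder: a fixed multi-scale smoothing encoder (Gaussian pyramid of
# the RGB channels) feeding a learned pixel-wise logistic decoder, trained
# with the combined dice + focal loss by full-batch Adam. It is deliberately
# small so that training on synthetic crops completes in seconds on one CPU;
# the learner registry lets heavier encoder-decoder models plug into the same
# contract.

#' Registered segmentation learners
#'
#' @return Named list of learner specifications.
#' @export
seg_learners <- function() {
  list(
    pyramid_logistic = list(
      description = "multi-scale Gaussian encoder + pixel-wise logistic decoder",
      sigmas = c(0, 2, 4), lr = 0.15
    )
  )
}

# Encode an RGB image into per-pixel features: each channel at each
# smoothing scale, flattened to (n_pixels x n_features).
encode_pixels <- function(img, sigmas) {
  feats <- lapply(sigmas, function(s) {
    vapply(1:3, function(ch) as.numeric(gauss_blur(img[, , ch], s)),
           numeric(prod(dim(img)[1:2])))
  })
  do.call(cbind, feats)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Gradient of the combined loss w.r.t. the logits z, for probabilities
# p = sigmoid(z) and labels y in {0,1}. The dice term is the global soft
# dice over the batch; the focal term is the per-pixel mean.
combined_loss_grad <- function(p, y, config, eps = 1e-7) {
  n <- length(p)
  beta2 <- config$beta^2
  tp <- sum(p * y); fp <- sum(p * (1 - y)); fn <- sum((1 - p) * y)
  den <- (1 + beta2) * tp + beta2 * fn + fp
  # d dice / d p_i: quotient rule on 1 - (1+b^2) tp / den
  d_dice <- if (den == 0) rep(0, n) else {
    num_i <- (1 + beta2) * y
    den_i <- (1 + beta2) * y + beta2 * (-y) + (1 - y)  # d den / d p_i
    -(num_i * den - (1 + beta2) * tp * den_i) / den^2
  }
  pc <- clamp(p, eps, 1 - eps)
  pt <- ifelse(y == 1, pc, 1 - pc)
  at <- if (config$alpha == 1) rep(1, n) else
    ifelse(y == 1, config$alpha, 1 - config$alpha)
  g <- config$gamma
  # d/dpt of -at (1-pt)^g log(pt)
  d_pt <- at * (g * (1 - pt)^(pmax(g - 1, 0)) * log(pt) - (1 - pt)^g / pt)
  d_focal <- ifelse(y == 1, d_pt, -d_pt) / n
  dp <- d_dice + d_focal
  dp * p * (1 - p)  # chain through the sigmoid
}

combined_loss_flat <- function(p, y, config) {
  beta2 <- config$beta^2
  tp <- sum(p * y); fp <- sum(p * (1 - y)); fn <- sum((1 - p) * y)
  den <- (1 + beta2) * tp + beta2 * fn + fp
  dice <- if (den == 0) 0 else 1 - (1 + beta2) * tp / den
  eps <- 1e-7
  pc <- clamp(p, eps, 1 - eps)
  pt <- ifelse(y == 1, pc, 1 - pc)
  at <- if (config$alpha == 1) 1 else
    ifelse(y == 1, config$alpha, 1 - config$alpha)
  dice + mean(-at * (1 - pt)^config$gamma * log(pt))
}

#' Train the segmentation model
#'
#' Randomly splits the pairs 90/10 (by `val_fraction`) into training and
#' validation, trains the selected learner with the combined dice + focal
#' loss, evaluates IoU and F1 on the validation split at the end of every
#' epoch, and returns the parameters of the best-validation-F1 epoch.
#' Training is deterministic given the seed.
#'
#' @param pairs List of `list(image, mask)` pairs.
#' @param val_fraction Validation fraction (default 0.1).
#' @param epochs Training epochs; 0 returns the untrained model.
#' @param learner Name of a registered learner (see [seg_learners()]).
#' @param config A [loss_config()].
#' @param seed Integer seed (split + any stochastic learner state).
#' @return An object of class `rosette_segmenter` with the fitted decoder
#'   weights, feature normalisation, per-epoch validation log (`epoch, loss,
#'   iou, f1`) and the index of the best epoch.
#' @export
train_segmenter <- function(pairs, val_fraction = 0.1, epochs = 20L,
                            learner = "pyramid_logistic",
                            config = loss_config(), seed = 1L) {
  spec <- seg_learners()[[learner]]
  if (is.null(spec)) stop("unknown learner: ", learner)
  if (length(pairs) < 10) stop("need at least 10 image/mask pairs")
  with_rng(seed, {
    n <- length(pairs)
    n_val <- max(1L, round(val_fraction * n))
    val_idx <- sort(sample(n, n_val))
    train_idx <- setdiff(seq_len(n), val_idx)
    X <- do.call(rbind, lapply(pairs[train_idx],
                               function(p) encode_pixels(p$image, spec$sigmas)))
    y <- unlist(lapply(pairs[train_idx], function(p) as.numeric(p$mask)))
    mu <- colMeans(X)
    sdv <- pmax(apply(X, 2, sd), 1e-8)
    Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
    w <- rep(0, ncol(X))
    b <- 0
    model <- list(learner = learner, sigmas = spec$sigmas, mu = mu, sd = sdv,
                  w = w, b = b, config = config)
    class(model) <- "rosette_segmenter"
    log <- data.frame(epoch = integer(0), loss = numeric(0),
                      iou = numeric(0), f1 = numeric(0))
    if (epochs == 0L) {
      model$log <- log
      model$best_epoch <- NA_integer_
      model$val_idx <- val_idx
      return(model)
    }
    # Adam state
    mw <- vw <- rep(0, length(w)); mb <- vb <- 0
    b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
    lr <- spec$lr
    best <- list(f1 = -Inf, w = w, b = b, epoch = NA_integer_)
    steps_per_epoch <- 5L  # a few full-batch steps per logged epoch
    tstep <- 0
    for (ep in seq_len(epochs)) {
      for (it in seq_len(steps_per_epoch)) {
        z <- drop(Xs %*% w) + b
        p <- sigmoid(z)
        gz <- combined_loss_grad(p, y, config)
        if (any(!is.finite(gz))) stop("non-finite training gradient; aborting")
        gw <- drop(crossprod(Xs, gz))
        gb <- sum(gz)
        tstep <- tstep + 1
        mw <- b1 * mw + (1 - b1) * gw; vw <- b2 * vw + (1 - b2) * gw^2
        mb <- b1 * mb + (1 - b1) * gb; vb <- b2 * vb + (1 - b2) * gb^2
        w <- w - lr * (mw / (1 - b1^tstep)) / (sqrt(vw / (1 - b2^tstep)) + adam_eps)
        b <- b - lr * (mb / (1 - b1^tstep)) / (sqrt(vb / (1 - b2^tstep)) + adam_eps)
      }
      model$w <- w; model$b <- b
      z <- drop(Xs %*% w) + b
      train_loss <- combined_loss_flat(sigmoid(z), y, config)
      if (!is.finite(train_loss)) stop("non-finite training loss; aborting")
      scores <- vapply(pairs[val_idx], function(pr) {
        pm <- predict(model, pr$image) >= 0.5
        s <- seg_score(pm, pr$mask)
        c(s$iou, s$fbeta)
      }, numeric(2))
      ep_iou <- mean(scores[1, ]); ep_f1 <- mean(scores[2, ])
      log <- rbind(log, data.frame(epoch = ep, loss = train_loss,
                                   iou = ep_iou, f1 = ep_f1))
      # ties resolve to the later (further-trained) epoch
      if (ep_f1 >= best$f1) best <- list(f1 = ep_f1, w = w, b = b, epoch = ep)
    }
    model$w <- best$w
    model$b <- best$b
    model$log <- log
    model$best_epoch <- best$epoch
    model$val_idx <- val_idx
    model
  })
}

#' Predict a foreground probability map
#'
#' @param object A trained `rosette_segmenter`.
#' @param image h x w x 3 array.
#' @param ... Unused.
#' @return Matrix of foreground probabilities.
#' @export
predict.rosette_segmenter <- function(object, image, ...) {
  X <- encode_pixels(image, object$sigmas)
  Xs <- sweep(sweep(X, 2, object$mu), 2, object$sd, "/")
  matrix(sigmoid(drop(Xs %*% object$w) + object$b),
         dim(image)[1], dim(image)[2])
}

#' Segment an image into a refined binary mask
#'
#' Convenience wrapper: probability map, 0.5 threshold, then
#' [refine_mask()].
#'
#' @param model A trained `rosette_segmenter`.
#' @param image h x w x 3 array.
#' @param refine Apply morphological refinement (default TRUE).
#' @param ... Passed to [refine_mask()].
#' @return Logical mask.
#' @export
segment_image <- function(model, image, refine = TRUE, ...) {
  prob <- predict(model, image)
  if (refine) refine_mask(prob, ...) else prob >= 0.5
}
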