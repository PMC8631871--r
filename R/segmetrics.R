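# Segmentation evaluation metrics, training losses, augmentation and mask
# refinement.

#' Pixel confusion counts between two binary masks
#'
#' @param pred,truth Logical matrices of equal shape.
#' @return List with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(pred, truth) {
  stop_if_shape_mismatch(pred, truth)
  pred <- as_mask(pred); truth <- as_mask(truth)
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  tn <- sum(!pred & !truth)
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Intersection over union of two masks
#'
#' `|A intersect B| / |A union B|`. Two empty masks agree that there is no
#' plant, so the empty-vs-empty case is defined as 1 (with a message).
#'
#' @param pred,truth Logical matrices of equal shape.
#' @return IoU in [0, 1].
#' @export
iou <- function(pred, truth) {
  cc <- confusion_counts(pred, truth)
  union <- cc$tp + cc$fp + cc$fn
  if (union == 0) {
    message("both masks empty; IoU defined as 1")
    return(1)
  }
  cc$tp / union
}

#' Precision, recall and the F-beta score
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and
#' `F_beta = (1+beta^2) P R / (beta^2 P + R)`. When both masks are empty all
#' scores are defined as 1 (the prediction correctly finds no plant,
#' matching the IoU convention); otherwise undefined ratios (empty
#' denominator) are defined as 0 with a message.
#'
#' @param pred,truth Logical matrices of equal shape.
#' @param beta F-score weight (default 1).
#' @return List of class `seg_score` with `iou`, `precision`, `recall`,
#'   `fbeta`, `beta` and the confusion counts.
#' @export
seg_score <- function(pred, truth, beta = 1) {
  cc <- confusion_counts(pred, truth)
  if (cc$tp + cc$fp + cc$fn == 0) {
    message("both masks empty; scores defined as 1")
    return(structure(list(iou = 1, precision = 1, recall = 1, fbeta = 1,
                          beta = beta, counts = cc),
                     class = "seg_score"))
  }
  ratio0 <- function(num, den, what) {
    if (den == 0) {
      message(what, " undefined (empty denominator); defined as 0")
      0
    } else num / den
  }
  p <- ratio0(cc$tp, cc$tp + cc$fp, "precision")
  r <- ratio0(cc$tp, cc$tp + cc$fn, "recall")
  fb <- if (p + r == 0) 0 else (1 + beta^2) * p * r / (beta^2 * p + r)
  union <- cc$tp + cc$fp + cc$fn
  structure(list(iou = if (union == 0) 1 else cc$tp / union,
                 precision = p, recall = r, fbeta = fb, beta = beta,
                 counts = cc),
            class = "seg_score")
}

check_prob_map <- function(prob) {
  if (any(prob < 0 | prob > 1)) stop("probability map values outside [0, 1]")
}

#' Soft dice loss
#'
#' `1 - soft F_beta`, where soft confusion counts replace the indicator of a
#' predicted pixel with its predicted probability: `TP = sum(p * y)`,
#' `FP = sum(p * (1 - y))`, `FN = sum((1 - p) * y)`.
#'
#' @param prob Predicted probability map in [0, 1].
#' @param truth Logical ground-truth mask.
#' @param beta F-score weight (default 1).
#' @return Loss in [0, 1].
#' @export
dice_loss <- function(prob, truth, beta = 1) {
  stop_if_shape_mismatch(prob, truth)
  check_prob_map(prob)
  y <- as.numeric(truth)
  p <- as.numeric(prob)
  tp <- sum(p * y)
  fp <- sum(p * (1 - y))
  fn <- sum((1 - p) * y)
  den <- (1 + beta^2) * tp + beta^2 * fn + fp
  if (den == 0) return(0)  # empty truth, confidently empty prediction
  1 - (1 + beta^2) * tp / den
}

#' Focal loss
#'
#' Mean over pixels of `-alpha_t (1 - p_t)^gamma log(p_t)` with
#' `p_t = p` for foreground pixels and `1 - p` for background, and
#' `alpha_t = alpha` for foreground and `1 - alpha` for background
#' (the class-balance convention of the focal-loss literature).
#' `alpha = 1` disables class weighting (`alpha_t = 1` everywhere), so
#' `alpha = 1, gamma = 0` reduces to mean binary cross-entropy.
#' Probabilities are clipped to `[eps, 1 - eps]` before the logarithm.
#'
#' @param prob Predicted probability map in [0, 1].
#' @param truth Logical ground-truth mask.
#' @param alpha Class-balance weight (default 0.25).
#' @param gamma Focusing exponent (default 2).
#' @param eps Clipping epsilon.
#' @return Nonnegative loss.
#' @export
focal_loss <- function(prob, truth, alpha = 0.25, gamma = 2, eps = 1e-7) {
  stop_if_shape_mismatch(prob, truth)
  check_prob_map(prob)
  stopifnot(alpha > 0, alpha <= 1, gamma >= 0)
  y <- as.numeric(truth)
  p <- clamp(as.numeric(prob), eps, 1 - eps)
  pt <- ifelse(y == 1, p, 1 - p)
  at <- if (alpha == 1) 1 else ifelse(y == 1, alpha, 1 - alpha)
  mean(-at * (1 - pt)^gamma * log(pt))
}

#' Loss configuration
#'
#' @param beta Dice F-score weight (default 1).
#' @param alpha Focal class-balance weight (default 0.25).
#' @param gamma Focal focusing exponent (default 2).
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(beta = 1, alpha = 0.25, gamma = 2) {
  stopifnot(alpha > 0, alpha <= 1, gamma >= 0)
  structure(list(beta = beta, alpha = alpha, gamma = gamma),
            class = "loss_config")
}

#' Combined segmentation training loss
#'
#' Exactly `dice_loss + focal_loss`.
#'
#' @param prob Predicted probability map.
#' @param truth Logical ground-truth mask.
#' @param config A [loss_config()].
#' @return Nonnegative loss.
#' @export
combined_loss <- function(prob, truth, config = loss_config()) {
  dice_loss(prob, truth, beta = config$beta) +
    focal_loss(prob, truth, alpha = config$alpha, gamma = config$gamma)
}

#' Augment an image/mask pair
#'
#' Applies each requested op to the pair: geometric ops (`flip_h`, `flip_v`,
#' `pad`) transform image and mask identically; photometric ops (`blur`,
#' `sharpen`) touch the image only.
#'
#' @param image h x w x 3 array.
#' @param mask Logical matrix.
#' @param ops Character subset of `flip_h, flip_v, pad, blur, sharpen`.
#' @param seed Integer seed (reserved for randomized op parameters).
#' @param pad_px Border width for `pad`.
#' @param blur_sigma Gaussian sigma for `blur`.
#' @param sharpen_amount Unsharp-mask strength.
#' @return Named list of `(image, mask)` pairs, one per op.
#' @export
augment <- function(image, mask, ops, seed = 1L, pad_px = 4L,
                    blur_sigma = 1.5, sharpen_amount = 1) {
  known <- c("flip_h", "flip_v", "pad", "blur", "sharpen")
  bad <- setdiff(ops, known)
  if (length(bad)) stop("unknown augmentation op(s): ", paste(bad, collapse = ", "))
  stop_if_shape_mismatch(image, mask)
  flip_cols <- function(x) map_channels(x, function(m) m[, rev(seq_len(ncol(m)))])
  flip_rows <- function(x) map_channels(x, function(m) m[rev(seq_len(nrow(m))), ])
  pad_it <- function(x, fill) {
    d <- dim(x)
    if (length(d) == 2L) {
      out <- matrix(fill, d[1] + 2 * pad_px, d[2] + 2 * pad_px)
      out[pad_px + seq_len(d[1]), pad_px + seq_len(d[2])] <- x
      out
    } else {
      out <- array(fill, c(d[1] + 2 * pad_px, d[2] + 2 * pad_px, d[3]))
      out[pad_px + seq_len(d[1]), pad_px + seq_len(d[2]), ] <- x
      out
    }
  }
  with_rng(seed, {
    out <- list()
    for (op in ops) {
      out[[op]] <- switch(op,
        flip_h = list(image = flip_cols(image), mask = flip_cols(mask)),
        flip_v = list(image = flip_rows(image), mask = flip_rows(mask)),
        pad = list(image = pad_it(image, 0),
                   mask = pad_it(mask, FALSE) > 0),
        blur = list(image = map_channels(image,
                                         function(m) gauss_blur(m, blur_sigma)),
                    mask = mask),
        sharpen = {
          blurred <- map_channels(image, function(m) gauss_blur(m, blur_sigma))
          list(image = clamp(image + sharpen_amount * (image - blurred), 0, 1),
               mask = mask)
        }
      )
    }
    out
  })
}

#' Refine a segmentation mask
#'
#' Deterministic morphological refinement: threshold a probability map at
#' 0.5, drop connected components smaller than `min_area` pixels, and fill
#' interior holes of at most `max_hole_area` pixels. Components use
#' 4-connectivity. The refiner contract (probability map or mask in, binary
#' mask out) is pluggable, so a dense-CRF refiner can be substituted.
#'
#' @param x Probability map or binary mask.
#' @param min_area Minimum surviving component area (pixels).
#' @param max_hole_area Largest hole that gets filled (pixels).
#' @return Logical mask.
#' @export
refine_mask <- function(x, min_area = 9L, max_hole_area = 25L) {
  mask <- if (is.logical(x)) x else x >= 0.5
  lab <- bwlabel(mask * 1)
  areas <- component_areas(lab)
  if (length(areas)) {
    small <- which(areas < min_area)
    if (length(small)) mask[lab %in% small] <- FALSE
  }
  # fill small interior holes: background components not touching the border
  bg_lab <- bwlabel((!mask) * 1)
  border_labels <- unique(c(bg_lab[1, ], bg_lab[nrow(bg_lab), ],
                            bg_lab[, 1], bg_lab[, ncol(bg_lab)]))
  bg_areas <- component_areas(bg_lab)
  holes <- setdiff(which(bg_areas <= max_hole_area), border_labels)
  holes <- setdiff(holes, 0L)
  if (length(holes)) mask[bg_lab %in% holes] <- TRUE
  mask
}
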