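test_that("confusion counts and scores match a brute-force pixel loop", {
  set.seed(42)
  for (i in 1:25) {
    a <- random_mask(16, 16)
    b <- random_mask(16, 16)
    cc <- confusion_counts(a, b)
    oracle <- loop_confusion(a, b)
    expect_identical(cc, oracle)
    s <- suppressMessages(seg_score(a, b))
    expect_identical(s$iou, if (oracle$tp + oracle$fp + oracle$fn == 0) 1
                     else oracle$tp / (oracle$tp + oracle$fp + oracle$fn))
    expect_identical(s$precision, oracle$tp / (oracle$tp + oracle$fp))
    expect_identical(s$recall, oracle$tp / (oracle$tp + oracle$fn))
  }
  expect_error(confusion_counts(random_mask(4, 4), random_mask(4, 5)),
               "shape mismatch")
})

test_that("iou handles identical, disjoint, shifted and empty masks", {
  m <- random_mask(8, 8)
  expect_equal(iou(m, m), 1)
  a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE
  b <- matrix(FALSE, 4, 4); b[3:4, 3:4] <- TRUE
  expect_equal(iou(a, b), 0)
  shifted <- matrix(FALSE, 4, 4); shifted[1:2, 2:3] <- TRUE
  expect_equal(iou(a, shifted), 1 / 3)  # overlap 2, union 6
  expect_message(v <- iou(matrix(FALSE, 3, 3), matrix(FALSE, 3, 3)), "empty")
  expect_equal(v, 1)
})

test_that("seg_score substitutes the documented precision/recall cases", {
  # TP=2, FP=2, FN=2 on a 3x3 grid
  pred <- matrix(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE), 3)
  truth <- matrix(c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE), 3)
  s <- seg_score(pred, truth)
  expect_equal(s$precision, 0.5)
  expect_equal(s$recall, 0.5)
  expect_equal(s$fbeta, 0.5)
  perfect <- seg_score(truth, truth)
  expect_equal(perfect$fbeta, 1)
  # beta -> 0 recovers precision
  s0 <- seg_score(pred, truth, beta = 1e-8)
  expect_equal(s0$fbeta, s$precision, tolerance = 1e-6)
  expect_message(seg_score(matrix(FALSE, 2, 2), matrix(TRUE, 2, 2)),
                 "precision undefined")
})

test_that("F1 and IoU satisfy the exact count identity", {
  set.seed(7)
  for (i in 1:50) {
    a <- random_mask(12, 12); b <- random_mask(12, 12)
    s <- suppressMessages(seg_score(a, b))
    expect_equal(s$fbeta, 2 * s$iou / (1 + s$iou), tolerance = 1e-12)
  }
})

test_that("dice loss matches hand-computed soft counts", {
  truth <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
  expect_equal(dice_loss(truth * 1, truth), 0)
  expect_equal(dice_loss(1 - truth, truth), 1)
  # uniform 0.5 on 4 px, half foreground: soft TP=FP=FN=1 -> 0.5
  expect_equal(dice_loss(matrix(0.5, 2, 2), truth), 0.5)
  expect_error(dice_loss(matrix(1.5, 2, 2), truth), "outside")
})

test_that("focal loss evaluates its closed form and limits", {
  truth1 <- matrix(TRUE)
  expect_equal(focal_loss(matrix(0.5), truth1),
               0.25 * 0.25 * log(2), tolerance = 1e-12)
  # pt -> 1 drives the loss to 0
  expect_lt(focal_loss(matrix(1), truth1), 1e-10)
  # gamma = 0, alpha = 1 reduces to mean cross-entropy
  set.seed(3)
  p <- matrix(runif(64, 0.05, 0.95), 8)
  y <- random_mask(8, 8)
  ce <- mean(-ifelse(y, log(p), log(1 - p)))
  expect_equal(focal_loss(p, y, alpha = 1, gamma = 0), ce, tolerance = 1e-10)
})

test_that("combined loss is exactly additive and zero when perfect", {
  set.seed(9)
  p <- matrix(runif(64), 8)
  y <- random_mask(8, 8)
  cfg <- loss_config()
  expect_equal(combined_loss(p, y, cfg),
               dice_loss(p, y) + focal_loss(p, y), tolerance = 1e-12)
  expect_lt(combined_loss(y * 1, y, cfg), 1e-6)
})

test_that("augmentation ops transform image and mask coherently", {
  pr <- render_rosette(rosette_spec(300, img_size = 32, seed = 4))
  out <- augment(pr$image, pr$mask, c("flip_h", "flip_v", "pad", "blur",
                                      "sharpen"), seed = 1, pad_px = 3)
  # flip twice is the identity
  back <- augment(out$flip_h$image, out$flip_h$mask, "flip_h", seed = 1)
  expect_identical(back$flip_h$image, pr$image)
  expect_identical(back$flip_h$mask, pr$mask)
  # photometric ops leave the mask alone
  expect_identical(out$blur$mask, pr$mask)
  expect_identical(out$sharpen$mask, pr$mask)
  expect_false(identical(out$blur$image, pr$image))
  # pad then crop back recovers the original
  expect_identical(out$pad$image[4:35, 4:35, ], pr$image)
  expect_equal(dim(out$pad$mask), c(38, 38))
  expect_error(augment(pr$image, pr$mask, "rotate"), "unknown")
})

test_that("mask refinement removes speckles, fills pinholes, idempotent", {
  clean <- disc_mask(10)
  expect_identical(refine_mask(clean, min_area = 3), clean)
  speckled <- clean
  pts <- cbind(c(1, 1, 25, 25, 13), c(1, 25, 1, 25, 1))
  speckled[pts] <- TRUE
  ref <- refine_mask(speckled, min_area = 3)
  expect_identical(ref, clean)
  expect_equal(sum(speckled) - sum(ref), 5)
  holey <- clean
  holey[13, 13] <- FALSE
  expect_identical(refine_mask(holey, min_area = 3, max_hole_area = 4), clean)
  big_hole <- clean
  big_hole[10:16, 10:16] <- FALSE
  expect_identical(refine_mask(big_hole, min_area = 3, max_hole_area = 4),
                   big_hole)
  expect_identical(refine_mask(ref), refine_mask(refine_mask(ref)))
})
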