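test_that("rendered rosettes hit the target area and are reproducible", {
  spec <- rosette_spec(400, n_leaves = 6, img_size = 64, seed = 3)
  out <- render_rosette(spec)
  expect_true(sum(out$mask) >= 380 && sum(out$mask) <= 420)
  expect_identical(out, render_rosette(spec))
  # single leaf with aspect 1 is one ellipse: convex, hull ~ PA
  one <- render_rosette(rosette_spec(500, n_leaves = 1, aspect = 1,
                                     img_size = 64, seed = 2))
  expect_lt(convex_hull_area(one$mask) / sum(one$mask), 1.06)
  expect_error(rosette_spec(3000, img_size = 64), "half the canvas")
})

test_that("tray composition stores consistent ground truth", {
  crops <- tray_fixture(n_cells = 4, cell = 64, target_pa = 1200)
  sc <- compose_tray(crops, layout = c(2, 2), cell_px = 64, margin_px = 32,
                     marker_radius = 5, seed = 1)
  expect_equal(sc$markers_warped, sc$markers)  # identity homography
  expect_equal(length(sc$masks), 4)
  expect_equal(sum(sc$tray_mask), sum(vapply(sc$masks, sum, 1)))
  # known warp: warped marker ground truth equals the applied transform
  H <- random_perspective(sc$dims, strength = 0.02, seed = 5)
  sc2 <- compose_tray(crops, layout = c(2, 2), cell_px = 64, margin_px = 32,
                      marker_radius = 5, H = H, seed = 1)
  expect_equal(sc2$markers_warped, apply_homography(sc2$H, sc2$markers),
               tolerance = 1e-12)
  expect_error(compose_tray(crops, layout = c(2, 2), cell_px = 64,
                            marker_color = c(0.2, 0.8, 0.2)),
               "marker color")
  expect_error(compose_tray(crops, layout = c(1, 2), cell_px = 64),
               "more crops")
})

test_that("marker detection is subpixel-accurate and fails without markers", {
  crops <- tray_fixture(n_cells = 4, cell = 64, target_pa = 1200)
  sc <- compose_tray(crops, layout = c(2, 2), cell_px = 64, margin_px = 32,
                     marker_radius = 5, seed = 2)
  det <- detect_markers(sc$image)
  expect_lt(max(abs(det - sc$markers)), 1)
  gray <- array(0.5, c(64, 64, 3))
  expect_error(detect_markers(gray), "marker")
})

test_that("homography fit/apply round-trips and rejects degenerate input", {
  src <- rbind(c(1, 1), c(100, 1), c(100, 80), c(1, 80))
  dst <- src + matrix(rnorm(8, 0, 3), 4, 2)
  H <- fit_homography(src, dst)
  expect_equal(apply_homography(H, src), dst, tolerance = 1e-9)
  expect_equal(apply_homography(solve(H), dst), src, tolerance = 1e-9)
  collinear <- rbind(c(1, 1), c(2, 2), c(3, 3), c(4, 4))
  expect_error(fit_homography(collinear, dst), "degenerate")
})

test_that("rectification is idempotent and recovers warped cell masks", {
  crops <- tray_fixture(n_cells = 8, cell = 96, target_pa = 3500)
  layout <- c(2, 4); cell <- 96L; margin <- 32L
  nom <- tray_nominal(layout, cell, margin)
  H <- random_perspective(nom$dims, strength = 0.03, seed = 17)
  sc <- compose_tray(crops, layout, cell, margin, marker_radius = 5, H = H,
                     seed = 3)
  det <- detect_markers(sc$image)
  expect_lt(max(sqrt(rowSums((det - sc$markers_warped)^2))), 2)
  rect <- rectify_tray(sc$image, det, nom)
  # masks warped with the scene homography, then rectified, overlap truth
  warped <- warp_image(sc$tray_mask * 1, sc$H, out_dim = dim(sc$image)[1:2])
  back <- warp_image(warped, rect$H, out_dim = nom$dims) >= 0.5
  per_cell <- mapply(iou, crop_cells(back, layout, cell, margin),
                     crop_cells(sc$tray_mask, layout, cell, margin))
  expect_gte(min(per_cell), 0.99)
  # rectifying an already-rectified tray changes nearly nothing
  det2 <- detect_markers(rect$image)
  rect2 <- rectify_tray(rect$image, det2, nom)
  expect_lt(mean(abs(rect2$image - rect$image)), 0.01)
  expect_error(rectify_tray(sc$image, rbind(c(1, 1), c(2, 2), c(3, 3),
                                            c(4, 4)), nom), "degenerate")
})

test_that("cell cropping partitions the grid region exactly", {
  crops <- tray_fixture(n_cells = 8, cell = 64, target_pa = 1200)
  sc <- compose_tray(crops, layout = c(2, 4), cell_px = 64, margin_px = 32,
                     marker_radius = 5, seed = 1)
  cc <- crop_cells(sc$nominal, c(2, 4), 64, 32)
  expect_length(cc, 8)
  # reassemble and compare to the grid region of the tray
  rebuilt <- array(0, c(128, 256, 3))
  idx <- 0
  for (r in 1:2) for (c in 1:4) {
    idx <- idx + 1
    rebuilt[(r - 1) * 64 + 1:64, (c - 1) * 64 + 1:64, ] <- cc[[idx]]
  }
  expect_identical(rebuilt, sc$nominal[33:160, 33:288, ])
})

test_that("PNG round trip preserves masks exactly and images closely", {
  out <- render_rosette(rosette_spec(300, img_size = 32, seed = 9))
  mp <- withr::local_tempfile(fileext = ".png")
  ip <- withr::local_tempfile(fileext = ".png")
  write_mask_png(out$mask, mp)
  expect_identical(read_mask_png(mp), out$mask)
  write_image_png(out$image, ip)
  expect_lt(max(abs(png::readPNG(ip) - out$image)), 1 / 255)
})

test_that("standard 32- and 50-cell tray layouts crop completely", {
  for (layout in list(c(8L, 4L), c(10L, 5L))) {
    tray <- array(0, c(layout[1] * 32 + 32, layout[2] * 32 + 32, 3))
    cc <- crop_cells(tray, layout, 32, 16)
    expect_length(cc, prod(layout))
    expect_true(all(vapply(cc, function(x) all(dim(x)[1:2] == 32), TRUE)))
  }
})

test_that("scale_and_pad is aspect-preserving with exact inverse mapping", {
  img <- array(runif(256 * 128 * 3), c(128, 256, 3))
  sp <- scale_and_pad(img, 512)
  expect_equal(dim(sp$image), c(512, 512, 3))
  expect_equal(sp$scale, 2)
  expect_equal(unname(sp$pad), c(128, 128, 0, 0))  # top/bottom padding
  same <- scale_and_pad(array(runif(512 * 512 * 3), c(512, 512, 3)), 512)
  expect_equal(same$scale, 1)
  expect_equal(unname(same$pad), c(0, 0, 0, 0))
  pts <- cbind(x = c(1, 100, 256), y = c(1, 60, 128))
  expect_equal(unname(unmap_points(map_points(pts, sp$scale, sp$pad),
                                   sp$scale, sp$pad)),
               unname(pts))
})
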