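# Tray preprocessing: marker detection, projective rectification, cell
# cropping and network-size scaling.

#' Detect the four red fiducial markers
#'
#' HSV-range thresholding followed by connected-component labelling; the
#' centroids of the four largest red components are returned in fixed corner
#' order (top-left, top-right, bottom-right, bottom-left), assigned by
#' angular position around the component mean. Centroids are weighted by
#' red-channel excess, which recovers sub-pixel positions of anti-aliased
#' markers.
#'
#' @param img h x w x 3 RGB array in [0, 1].
#' @param color_spec List with `h_lo`, `h_hi` (hue interval wrapping through
#'   red), `s_min`, `v_min`.
#' @param min_area Minimum component area in pixels.
#' @return 4x2 matrix of (x, y) marker centroids, ordered TL, TR, BR, BL.
#' @export
detect_markers <- function(img,
                           color_spec = list(h_lo = 0.95, h_hi = 0.04,
                                             s_min = 0.55, v_min = 0.25),
                           min_area = 9L) {
  stopifnot(length(dim(img)) == 3)
  h <- dim(img)[1]; w <- dim(img)[2]
  rgb <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
               as.vector(img[, , 3]))
  hsv <- rgb2hsv(rgb, maxColorValue = 1)
  red <- (hsv[1, ] >= color_spec$h_lo | hsv[1, ] <= color_spec$h_hi) &
    hsv[2, ] >= color_spec$s_min & hsv[3, ] >= color_spec$v_min
  red_m <- matrix(red, h, w)
  lab <- bwlabel(red_m * 1)
  areas <- component_areas(lab)
  areas[areas < min_area] <- 0L
  n_found <- sum(areas > 0)
  if (n_found < 4) {
    stop("found only ", n_found, " marker component(s); need 4 (no markers?)")
  }
  if (n_found > 4) {
    message("found ", n_found, " red components; keeping the 4 largest")
  }
  keep <- order(areas, decreasing = TRUE)[1:4]
  weight <- pmax(0, img[, , 1] - pmax(img[, , 2], img[, , 3]))
  cent <- t(vapply(keep, function(k) {
    sel <- which(lab == k)
    wsel <- weight[sel]
    if (sum(wsel) <= 0) wsel <- rep(1, length(sel))
    rr <- (sel - 1) %% h + 1
    cc <- (sel - 1) %/% h + 1
    c(sum(cc * wsel) / sum(wsel), sum(rr * wsel) / sum(wsel))
  }, numeric(2)))
  ang <- atan2(cent[, 2] - mean(cent[, 2]), cent[, 1] - mean(cent[, 1]))
  cent[order(ang), , drop = FALSE]  # TL, TR, BR, BL
}

#' Rectify a distorted tray image
#'
#' Fits the homography mapping the detected corner markers onto their nominal
#' positions and warps the tray onto the nominal canvas (bilinear).
#'
#' @param img Distorted tray image.
#' @param corners 4x2 detected marker coordinates (TL, TR, BR, BL).
#' @param nominal [tray_nominal()] geometry.
#' @param refine Number of refinement passes: after an initial rectification
#'   the markers are re-detected in the rectified image (where they are
#'   nearly circular, so their centroids are unbiased) and the residual
#'   correction is composed into the homography. 1 pass (the default)
#'   removes the centroid bias that perspective introduces on disc markers.
#' @return List with `image` (rectified tray) and `H` (the rectifying
#'   homography, distorted -> nominal).
#' @export
rectify_tray <- function(img, corners, nominal, refine = 1L) {
  stopifnot(nrow(corners) == 4)
  # collinearity check: area of the corner quadrilateral
  a <- abs(polygon_area(corners))
  if (a < 1e-6 * prod(nominal$dims)) stop("degenerate (collinear) corners")
  H <- fit_homography(corners, nominal$markers)
  out <- warp_image(img, H, out_dim = nominal$dims)
  for (i in seq_len(refine)) {
    det <- tryCatch(detect_markers(out), error = function(e) NULL)
    if (is.null(det)) break
    H <- fit_homography(det, nominal$markers) %*% H
    out <- warp_image(img, H, out_dim = nominal$dims)
  }
  list(image = out, H = H)
}

#' Crop a rectified tray into per-cell images
#'
#' Splits the grid region (inside the margin) into `rows * cols` crops in
#' row-major order. Coordinates are 1-based with inclusive cell intervals of
#' exactly `cell_px` pixels; empty cells yield background-only crops.
#'
#' @param img Rectified tray image (matrix or 3-channel array).
#' @param layout `c(rows, cols)`.
#' @param cell_px Cell side in pixels.
#' @param margin_px Margin width.
#' @return List of crops, row-major.
#' @export
crop_cells <- function(img, layout, cell_px, margin_px) {
  rows <- layout[1]; cols <- layout[2]
  d <- dim(img)
  stopifnot(d[1] == rows * cell_px + 2 * margin_px,
            d[2] == cols * cell_px + 2 * margin_px)
  out <- vector("list", rows * cols)
  idx <- 0L
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      idx <- idx + 1L
      rr <- margin_px + (r - 1L) * cell_px + seq_len(cell_px)
      cc <- margin_px + (c - 1L) * cell_px + seq_len(cell_px)
      out[[idx]] <- if (length(d) == 2L) img[rr, cc] else img[rr, cc, , drop = FALSE]
    }
  }
  out
}

#' Bilinear image resize
#'
#' @param img Matrix or h x w x 3 array.
#' @param out_dim `c(height, width)`.
#' @return Resized image.
#' @export
resize_bilinear <- function(img, out_dim) {
  d <- dim(img)
  sx <- (seq_len(out_dim[2]) - 0.5) * d[2] / out_dim[2] + 0.5
  sy <- (seq_len(out_dim[1]) - 0.5) * d[1] / out_dim[1] + 0.5
  sx <- clamp(sx, 1, d[2]); sy <- clamp(sy, 1, d[1])
  gx <- rep(sx, each = out_dim[1])
  gy <- rep(sy, out_dim[2])
  sample_mat <- function(mat) {
    # clamp-to-edge: pad one pixel on each side so bilinear never falls out

    padded <- rbind(mat[1, , drop = FALSE], mat, mat[nrow(mat), , drop = FALSE])
    padded <- cbind(padded[, 1, drop = FALSE], padded, padded[, ncol(padded), drop = FALSE])
    matrix(bilinear_sample(padded, gx + 1, gy + 1, 0), out_dim[1], out_dim[2])
  }
  if (length(d) == 2L) return(sample_mat(img))
  arr <- array(0, c(out_dim, d[3]))
  for (ch in seq_len(d[3])) arr[, , ch] <- sample_mat(img[, , ch])
  arr
}

#' Scale and pad a crop to the network input size
#'
#' Aspect-preserving scale so the larger side equals `target`, then symmetric
#' zero padding to a `target x target` square. The recorded scale and padding
#' allow exact inverse mapping of mask coordinates via [unmap_points()].
#'
#' @param img Crop (matrix or 3-channel array).
#' @param target Network input side (e.g. 512).
#' @return List with `image`, `scale`, and `pad` (`top, bottom, left, right`).
#' @export
scale_and_pad <- function(img, target) {
  stopifnot(target >= 1)
  d <- dim(img)
  h <- d[1]; w <- d[2]
  s <- target / max(h, w)
  h2 <- if (h >= w) as.integer(target) else as.integer(round(h * s))
  w2 <- if (w > h) as.integer(target) else as.integer(round(w * s))
  scaled <- if (s == 1) img else resize_bilinear(img, c(h2, w2))
  top <- (target - h2) %/% 2L
  bottom <- target - h2 - top
  left <- (target - w2) %/% 2L
  right <- target - w2 - left
  out <- if (length(d) == 2L) {
    m <- matrix(0, target, target)
    m[top + seq_len(h2), left + seq_len(w2)] <- scaled
    m
  } else {
    a <- array(0, c(target, target, d[3]))
    a[top + seq_len(h2), left + seq_len(w2), ] <- scaled
    a
  }
  list(image = out, scale = s,
       pad = c(top = top, bottom = bottom, left = left, right = right))
}

#' Map padded-square coordinates back to the original crop
#'
#' Inverse of the [scale_and_pad()] coordinate transform.
#'
#' @param pts n x 2 matrix of (x, y) in the padded square.
#' @param scale,pad As returned by [scale_and_pad()].
#' @return n x 2 matrix in original crop coordinates.
#' @export
unmap_points <- function(pts, scale, pad) {
  cbind((pts[, 1] - pad["left"] - 0.5) / scale + 0.5,
        (pts[, 2] - pad["top"] - 0.5) / scale + 0.5)
}

#' Forward-map crop coordinates into the padded square
#'
#' @param pts n x 2 matrix of (x, y) in crop coordinates.
#' @param scale,pad As returned by [scale_and_pad()].
#' @return n x 2 matrix in padded-square coordinates.
#' @export
map_points <- function(pts, scale, pad) {
  cbind((pts[, 1] - 0.5) * scale + 0.5 + pad["left"],
        (pts[, 2] - 0.5) * scale + 0.5 + pad["top"])
}

# Shoelace area of a polygon given as n x 2 (x, y).
polygon_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  n <- nrow(pts)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}
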