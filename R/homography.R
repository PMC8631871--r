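# Projective (3x3 homography) geometry used by tray composition and
# rectification. Point coordinates are (x = column, y = row), 1-based pixel
# centers.

#' Fit a homography from four point correspondences
#'
#' Direct linear solve of the eight homography parameters (h33 = 1) mapping
#' `src` points onto `dst` points.
#'
#' @param src,dst 4x2 matrices of (x, y) coordinates.
#' @return A 3x3 homography matrix.
#' @export
fit_homography <- function(src, dst) {
  stopifnot(nrow(src) == 4, nrow(dst) == 4, ncol(src) == 2, ncol(dst) == 2)
  A <- matrix(0, 8, 8)
  b <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]
    xp <- dst[i, 1]; yp <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -x * xp, -y * xp)
    A[2 * i, ]     <- c(0, 0, 0, x, y, 1, -x * yp, -y * yp)
    b[2 * i - 1] <- xp
    b[2 * i] <- yp
  }
  h <- tryCatch(solve(A, b), error = function(e) {
    stop("degenerate point configuration (collinear corners?)", call. = FALSE)
  })
  matrix(c(h, 1), 3, 3, byrow = TRUE)
}

#' Apply a homography to points
#'
#' @param H 3x3 homography.
#' @param pts n x 2 matrix of (x, y).
#' @return n x 2 matrix of mapped points.
#' @export
apply_homography <- function(H, pts) {
  pts <- rbind(t(as.matrix(pts)), 1)
  out <- H %*% pts
  t(out[1:2, , drop = FALSE] / rep(out[3, ], each = 2))
}

# Bilinear sampling of matrix `mat` at continuous coords (sx, sy);
# out-of-range samples return `fill`.
bilinear_sample <- function(mat, sx, sy, fill = 0) {
  h <- nrow(mat); w <- ncol(mat)
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  ok <- x0 >= 1 & x0 + 1 <= w & y0 >= 1 & y0 + 1 <= h
  out <- rep(fill, length(sx))
  if (any(ok)) {
    x0k <- x0[ok]; y0k <- y0[ok]; fxk <- fx[ok]; fyk <- fy[ok]
    i00 <- (x0k - 1) * h + y0k
    v <- mat[i00] * (1 - fxk) * (1 - fyk) +
      mat[i00 + h] * fxk * (1 - fyk) +
      mat[i00 + 1] * (1 - fxk) * fyk +
      mat[i00 + h + 1] * fxk * fyk
    out[ok] <- v
  }
  out
}

#' Warp an image or mask by a homography
#'
#' Produces the destination image: each output pixel is sampled from the
#' source at the inverse-mapped location (bilinear for images, or nearest
#' neighbour). Logical masks are warped bilinearly on their 0/1 values and
#' re-thresholded at 0.5.
#'
#' @param img Matrix (grayscale/mask) or h x w x 3 array.
#' @param H Homography mapping source coords to destination coords.
#' @param out_dim `c(height, width)` of the output (default: input size).
#' @param fill Fill value outside the source.
#' @return Warped image of the same kind as the input.
#' @export
warp_image <- function(img, H, out_dim = NULL, fill = 0) {
  was_mask <- is.matrix(img) && is.logical(img)
  if (was_mask) img <- img * 1
  d <- dim(img)
  out_dim <- out_dim %||% d[1:2]
  Hi <- solve(H)
  xs <- rep(seq_len(out_dim[2]), each = out_dim[1])
  ys <- rep(seq_len(out_dim[1]), out_dim[2])
  src <- apply_homography(Hi, cbind(xs, ys))
  sample_one <- function(mat) {
    matrix(bilinear_sample(mat, src[, 1], src[, 2], fill), out_dim[1], out_dim[2])
  }
  out <- if (length(d) == 2L) {
    sample_one(img)
  } else {
    arr <- array(0, c(out_dim, d[3]))
    for (ch in seq_len(d[3])) arr[, , ch] <- sample_one(img[, , ch])
    arr
  }
  if (was_mask) out >= 0.5 else out
}

#' Random mild perspective homography
#'
#' Perturbs the four corners of a `dims = c(height, width)` frame by up to
#' `strength` of the frame diagonal and fits the induced homography; used to
#' emulate camera perspective distortion of trays.
#'
#' @param dims `c(height, width)`.
#' @param strength Relative perturbation (default 0.03).
#' @param seed Integer seed.
#' @return 3x3 homography.
#' @export
random_perspective <- function(dims, strength = 0.03, seed = 1L) {
  with_rng(seed, {
    w <- dims[2]; h <- dims[1]
    corners <- rbind(c(1, 1), c(w, 1), c(w, h), c(1, h))
    amp <- strength * sqrt(w^2 + h^2)
    jitter <- matrix(runif(8, -amp, amp), 4, 2)
    fit_homography(corners, corners + jitter)
  })
}
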