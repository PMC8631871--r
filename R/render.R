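# Synthetic rosette and tray rendering. Images are h x w x 3 arrays in
# [0, 1]; masks are logical matrices of the same height/width.

#' Rosette rendering specification
#'
#' A rosette is the union of `n_leaves` rotated ellipses arranged around a
#' center at the phyllotaxis angle; leaf size is solved so the rendered mask
#' hits `target_pa` (pixel count) within 5%.
#'
#' @param target_pa Target projected area in pixels^2.
#' @param n_leaves Leaf count.
#' @param aspect Leaf width / length ratio.
#' @param phyllotaxis Angle between consecutive leaves, degrees.
#' @param img_size Square canvas side in pixels.
#' @param center Rosette center `c(x, y)` (default canvas center).
#' @param seed Integer seed controlling leaf jitter and hues.
#' @return An object of class `rosette_spec`.
#' @export
rosette_spec <- function(target_pa, n_leaves = 8L, aspect = 0.6,
                         phyllotaxis = 137.5, img_size = 128L,
                         center = NULL, seed = 1L) {
  stopifnot(target_pa > 0, n_leaves >= 1)
  if (target_pa > 0.5 * img_size^2) {
    stop("target_pa exceeds half the canvas area")
  }
  structure(list(target_pa = target_pa, n_leaves = as.integer(n_leaves),
                 aspect = aspect, phyllotaxis = phyllotaxis,
                 img_size = as.integer(img_size),
                 center = center %||% rep((img_size + 1) / 2, 2),
                 seed = as.integer(seed)),
            class = "rosette_spec")
}

# Rasterize the union of leaves at scale `len` (leaf length in px).
rosette_mask_at <- function(spec, len, angles, asp) {
  n <- spec$img_size
  xs <- matrix(rep(seq_len(n), each = n), n, n)   # column index
  ys <- matrix(rep(seq_len(n), n), n, n)          # row index
  mask <- matrix(FALSE, n, n)
  cx <- spec$center[1]; cy <- spec$center[2]
  for (i in seq_along(angles)) {
    a <- angles[i] * pi / 180
    L <- len[i]
    # leaf ellipse centered at distance L/2 from rosette center
    ex <- cx + cos(a) * L / 2
    ey <- cy + sin(a) * L / 2
    dx <- xs - ex; dy <- ys - ey
    u <- dx * cos(a) + dy * sin(a)
    v <- -dx * sin(a) + dy * cos(a)
    mask <- mask | (u / (L / 2))^2 + (v / (asp[i] * L / 2))^2 <= 1
  }
  mask
}

#' Render a synthetic rosette crop
#'
#' Renders the leaf-union mask, bisecting the leaf length until the mask's
#' pixel count is within 5% of `target_pa`, then paints foreground leaves in
#' green hues over a soil-textured background.
#'
#' @param spec A [rosette_spec()].
#' @return List with `image` (h x w x 3 array) and `mask` (logical matrix).
#' @export
render_rosette <- function(spec) {
  stopifnot(inherits(spec, "rosette_spec"))
  with_rng(spec$seed, {
    k <- seq_len(spec$n_leaves)
    angles <- (k - 1) * spec$phyllotaxis + runif(spec$n_leaves, -8, 8)
    # outer leaves slightly longer, as in real rosettes
    rel_len <- 0.75 + 0.25 * k / spec$n_leaves
    asp <- spec$aspect * runif(spec$n_leaves, 0.9, 1.1)
    # initial guess from the disjoint-ellipse area, then bisection
    area_one <- pi / 4 * spec$aspect * mean(rel_len)^2
    len0 <- sqrt(spec$target_pa / (spec$n_leaves * area_one * 0.7))
    lo <- len0 * 0.3
    hi <- min(len0 * 3, spec$img_size * 0.95)
    mask <- NULL
    for (iter in 1:40) {
      mid <- (lo + hi) / 2
      mask <- rosette_mask_at(spec, mid * rel_len, angles, asp)
      pa <- sum(mask)
      if (abs(pa - spec$target_pa) <= 0.025 * spec$target_pa) break
      if (pa < spec$target_pa) lo <- mid else hi <- mid
    }
    pa <- sum(mask)
    if (abs(pa - spec$target_pa) > 0.05 * spec$target_pa) {
      stop("could not reach target_pa = ", spec$target_pa,
           " (achieved ", pa, "); relax leaf constraints")
    }
    img <- soil_texture(c(spec$img_size, spec$img_size),
                        seed = derive_seed(spec$seed, 11L))
    # green foreground with a radial shade gradient
    n <- spec$img_size
    xs <- matrix(rep(seq_len(n), each = n), n, n)
    ys <- matrix(rep(seq_len(n), n), n, n)
    dist <- sqrt((xs - spec$center[1])^2 + (ys - spec$center[2])^2)
    shade <- 0.75 + 0.25 * clamp(dist / (n / 2), 0, 1)
    g <- 0.55 * shade
    r <- 0.18 * shade
    b <- 0.12 * shade
    img[, , 1][mask] <- r[mask]
    img[, , 2][mask] <- g[mask]
    img[, , 3][mask] <- b[mask]
    list(image = img, mask = mask)
  })
}

#' Soil-textured background
#'
#' Multi-octave value noise in brown hues; optionally adds moss-like green
#' speckles to stress-test mask refinement.
#'
#' @param dims `c(height, width)`.
#' @param moss_frac Fraction of pixels turned into green speckles.
#' @param seed Integer seed.
#' @return h x w x 3 array.
#' @export
soil_texture <- function(dims, moss_frac = 0, seed = 1L) {
  with_rng(seed, {
    h <- dims[1]; w <- dims[2]
    noise <- matrix(0, h, w)
    for (octave in c(8, 16, 32)) {
      coarse <- matrix(runif(ceiling(h / octave + 2) * ceiling(w / octave + 2)),
                       ceiling(h / octave + 2))
      big <- resize_bilinear(coarse, c(h, w))
      noise <- noise + big / (octave / 8)
    }
    noise <- (noise - min(noise)) / (max(noise) - min(noise) + 1e-12)
    img <- array(0, c(h, w, 3))
    img[, , 1] <- 0.32 + 0.18 * noise
    img[, , 2] <- 0.22 + 0.12 * noise
    img[, , 3] <- 0.12 + 0.08 * noise
    if (moss_frac > 0) {
      n_speck <- round(moss_frac * h * w)
      idx <- sample(h * w, n_speck)
      img[, , 1][idx] <- 0.20
      img[, , 2][idx] <- 0.50
      img[, , 3][idx] <- 0.15
    }
    img
  })
}

#' Compose a marked tray image from cell crops
#'
#' Lays the crops onto a soil background in row-major grid order, stamps four
#' anti-aliased red disc markers at the corner insets, and warps the whole
#' tray by the given homography (camera perspective). Ground truth (cell
#' masks, marker coordinates pre- and post-warp) is retained for evaluation.
#'
#' @param crops List of [render_rosette()] outputs, length <= rows*cols.
#' @param layout `c(rows, cols)`.
#' @param cell_px Cell side in pixels.
#' @param margin_px Margin around the grid (markers live here).
#' @param marker_radius Marker disc radius in pixels.
#' @param marker_color RGB triplet of the markers.
#' @param H Homography applied to the finished tray (default identity).
#' @param out_pad Extra border (pixels) on the warped canvas so mild
#'   perspective never clips the tray; the stored `H` includes the implied
#'   translation.
#' @param seed Integer seed for the background.
#' @return An object of class `tray_scene`: `image` (warped tray), `nominal`
#'   (pre-warp tray), `tray_mask` (pre-warp foreground), `masks` (per-cell
#'   logical masks, row-major), `markers` / `markers_warped` (4x2, ordered
#'   TL, TR, BR, BL), plus the geometry fields.
#' @export
compose_tray <- function(crops, layout = c(8L, 4L), cell_px = 128L,
                         margin_px = 48L, marker_radius = 9L,
                         marker_color = c(0.85, 0.08, 0.08),
                         H = diag(3), out_pad = 24L, seed = 1L) {
  rows <- layout[1]; cols <- layout[2]
  if (length(crops) > rows * cols) stop("more crops than cells")
  if (marker_color[1] < max(marker_color[2], marker_color[3]) + 0.3) {
    stop("marker color too close to foliage/soil hues; choose a red marker")
  }
  hgt <- rows * cell_px + 2L * margin_px
  wdt <- cols * cell_px + 2L * margin_px
  tray <- soil_texture(c(hgt, wdt), seed = seed)
  tray_mask <- matrix(FALSE, hgt, wdt)
  masks <- vector("list", rows * cols)
  idx <- 0L
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      idx <- idx + 1L
      masks[[idx]] <- matrix(FALSE, cell_px, cell_px)
      if (idx <= length(crops)) {
        crop <- crops[[idx]]
        stopifnot(nrow(crop$mask) == cell_px)
        rr <- margin_px + (r - 1L) * cell_px + seq_len(cell_px)
        cc <- margin_px + (c - 1L) * cell_px + seq_len(cell_px)
        for (ch in 1:3) {
          tile <- tray[rr, cc, ch]
          tile[crop$mask] <- crop$image[, , ch][crop$mask]
          tray[rr, cc, ch] <- tile
        }
        tray_mask[rr, cc] <- crop$mask
        masks[[idx]] <- crop$mask
      }
    }
  }
  inset <- margin_px / 2
  markers <- rbind(
    c(inset, inset), c(wdt - inset, inset),
    c(wdt - inset, hgt - inset), c(inset, hgt - inset)
  )
  xs <- matrix(rep(seq_len(wdt), each = hgt), hgt, wdt)
  ys <- matrix(rep(seq_len(hgt), wdt), hgt, wdt)
  for (m in 1:4) {
    d <- sqrt((xs - markers[m, 1])^2 + (ys - markers[m, 2])^2)
    cov <- clamp(marker_radius + 0.5 - d, 0, 1)  # anti-aliased coverage
    for (ch in 1:3) {
      tray[, , ch] <- tray[, , ch] * (1 - cov) + marker_color[ch] * cov
    }
  }
  if (identical(H, diag(3))) {
    warped <- tray
    H_eff <- H
  } else {
    shift <- rbind(c(1, 0, out_pad), c(0, 1, out_pad), c(0, 0, 1))
    H_eff <- shift %*% H
    warped <- warp_image(tray, H_eff,
                         out_dim = c(hgt + 2L * out_pad, wdt + 2L * out_pad))
  }
  structure(list(
    image = warped, nominal = tray, tray_mask = tray_mask, masks = masks,
    markers = markers, markers_warped = apply_homography(H_eff, markers),
    H = H_eff, layout = as.integer(layout), cell_px = as.integer(cell_px),
    margin_px = as.integer(margin_px), dims = c(hgt, wdt)
  ), class = "tray_scene")
}

#' Nominal tray geometry
#'
#' The reference geometry a rectified tray must match: canvas dimensions and
#' the four marker positions (TL, TR, BR, BL).
#'
#' @param layout `c(rows, cols)`.
#' @param cell_px Cell side.
#' @param margin_px Margin width.
#' @return List with `dims` and `markers`.
#' @export
tray_nominal <- function(layout, cell_px, margin_px) {
  hgt <- layout[1] * cell_px + 2 * margin_px
  wdt <- layout[2] * cell_px + 2 * margin_px
  inset <- margin_px / 2
  list(dims = c(hgt, wdt),
       markers = rbind(c(inset, inset), c(wdt - inset, inset),
                       c(wdt - inset, hgt - inset), c(inset, hgt - inset)))
}
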