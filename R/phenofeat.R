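# Shape features extracted from binary plant masks: projected area, convex
# hull area, perimeter, compactness (solidity), and absolute growth rate.

#' Projected area of a mask
#'
#' Foreground pixel count times the per-pixel area scale. Pixels^2 by
#' default; pass `px_area_scale` (e.g. mm^2 per pixel) to convert.
#'
#' @param mask Logical matrix.
#' @param px_area_scale Area of one pixel (default 1).
#' @return Area (0 for an empty mask).
#' @export
projected_area <- function(mask, px_area_scale = 1) {
  sum(as_mask(mask)) * px_area_scale
}

# Foreground pixels with at least one exposed 4-neighbour edge.
boundary_pixels <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  core <- pad[2:(h + 1), 2:(w + 1)]
  exposed <- core & !(pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
                        pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)])
  which(exposed, arr.ind = TRUE)
}

#' Convex hull area of a mask
#'
#' Area of the convex hull of the foreground pixel *squares*: the hull is
#' taken over the four corners of every boundary pixel, so it always encloses
#' the full rasterised footprint and `hull_area >= projected_area` holds for
#' every mask. Computed by the shoelace formula on the hull polygon.
#'
#' @param mask Logical matrix, nonempty.
#' @return Hull area in pixels^2.
#' @export
convex_hull_area <- function(mask) {
  mask <- as_mask(mask)
  if (!any(mask)) stop("empty mask has no convex hull")
  bp <- boundary_pixels(mask)
  # corners of each boundary pixel square, (x = col +- .5, y = row +- .5)
  x <- c(bp[, 2] - 0.5, bp[, 2] + 0.5, bp[, 2] - 0.5, bp[, 2] + 0.5)
  y <- c(bp[, 1] - 0.5, bp[, 1] - 0.5, bp[, 1] + 0.5, bp[, 1] + 0.5)
  hull <- chull(x, y)
  abs(polygon_area(cbind(x[hull], y[hull])))
}

#' Perimeter of a mask
#'
#' Total exposed-edge length of the largest connected component
#' (4-connectivity): every foreground pixel edge bordering background or the
#' image edge contributes 1. A filled s x s square therefore has perimeter
#' 4s and a single pixel has perimeter 4.
#'
#' @param mask Logical matrix, nonempty.
#' @return Perimeter in pixel edges.
#' @export
perimeter <- function(mask) {
  mask <- as_mask(mask)
  if (!any(mask)) stop("empty mask has no perimeter")
  lab <- bwlabel(mask * 1)
  areas <- component_areas(lab)
  mask <- lab == which.max(areas)
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  core <- pad[2:(h + 1), 2:(w + 1)]
  sum(core & !pad[1:h, 2:(w + 1)]) + sum(core & !pad[3:(h + 2), 2:(w + 1)]) +
    sum(core & !pad[2:(h + 1), 1:w]) + sum(core & !pad[2:(h + 1), 3:(w + 2)])
}

#' Compactness (solidity) of a mask
#'
#' Projected area divided by convex hull area; 1 for convex shapes, small
#' for sprawling rosettes. Always in (0, 1] because the hull encloses the
#' rasterised footprint.
#'
#' @param mask Logical matrix, nonempty.
#' @return Compactness in (0, 1].
#' @export
compactness <- function(mask) {
  min(1, projected_area(mask) / convex_hull_area(mask))
}

#' Absolute growth rate of a PA series
#'
#' Backward finite difference `(PA(t) - PA(t - window)) / window` in area
#' units per step; `NA` for the first `window` entries.
#'
#' @param pa Numeric PA series, time-ordered.
#' @param window_steps Difference window in steps (>= 1).
#' @return Numeric AGR series of the same length.
#' @export
absolute_growth_rate <- function(pa, window_steps = 1L) {
  stopifnot(window_steps >= 1)
  n <- length(pa)
  out <- rep(NA_real_, n)
  if (n > window_steps) {
    idx <- (window_steps + 1):n
    out[idx] <- (pa[idx] - pa[idx - window_steps]) / window_steps
  }
  out
}

#' Extract a feature record from a mask
#'
#' One row of the feature table the forecasting stage consumes.
#'
#' @param mask Logical matrix.
#' @param plant_id,experiment,time_step Identifiers.
#' @param grid A [time_grid()] used to derive decimal DAS.
#' @param px_area_scale Area of one pixel.
#' @return One-row data frame `plant_id, experiment, time_step, das, pa,
#'   hull_area, perimeter, compactness`.
#' @export
extract_features <- function(mask, plant_id, experiment = 1L, time_step = 1L,
                             grid = time_grid(), px_area_scale = 1) {
  pa <- projected_area(mask, px_area_scale)
  if (pa == 0) {
    hull <- NA_real_; per <- NA_real_; comp <- NA_real_
  } else {
    hull <- convex_hull_area(mask) * px_area_scale
    per <- perimeter(mask) * sqrt(px_area_scale)
    comp <- compactness(mask)
  }
  data.frame(plant_id = plant_id, experiment = experiment,
             time_step = time_step, das = step_to_das(time_step, grid),
             pa = pa, hull_area = hull, perimeter = per, compactness = comp)
}
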