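# PNG I/O for images and masks. Images are h x w x 3 arrays in [0, 1];
# masks are written as single-channel PNGs with 0/255 coding.

#' Write an RGB image to PNG
#'
#' @param img h x w x 3 array in [0, 1].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_image_png <- function(img, path) {
  writePNG(clamp(img, 0, 1), path)
  invisible(path)
}

#' Write a binary mask to a single-channel PNG
#'
#' Foreground is 255, background 0.
#'
#' @param mask Logical matrix.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  writePNG(as_mask(mask) * 1, path)
  invisible(path)
}

#' Read a mask PNG back to a logical matrix
#'
#' Any channel value above 0.5 is foreground.
#'
#' @param path PNG path.
#' @return Logical matrix.
#' @export
read_mask_png <- function(path) {
  m <- readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m > 0.5
}
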