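#' Preprocessing parameters
#'
#' Parameters for the fixed preprocessing recipe: automatic border cropping,
#' Gaussian denoising, then CLAHE local contrast enhancement (in that
#' order).
#'
#' @param blur_sigma Gaussian blur sigma in pixels; `0` disables blurring.
#' @param clahe_clip_limit CLAHE clip limit (dimensionless).
#' @param clahe_tile_grid tiles as `c(nx, ny)`, at least `c(1, 1)`.
#' @param border_tol intensity tolerance (on the `[0, 1]` scale) below which
#'   a margin row/column counts as uniform; default 2 units on the 8-bit
#'   scale.
#' @return A `preprocess_params` list.
#' @export
preprocess_params <- function(blur_sigma = 1.5, clahe_clip_limit = 2,
                              clahe_tile_grid = c(8, 8),
                              border_tol = 2 / 255) {
  stopifnot(blur_sigma >= 0, all(clahe_tile_grid >= 1))
  structure(list(blur_sigma = blur_sigma, clahe_clip_limit = clahe_clip_limit,
                 clahe_tile_grid = as.integer(clahe_tile_grid),
                 border_tol = border_tol),
            class = "preprocess_params")
}

#' Crop uniform borders from a frame
#'
#' X-ray exports often carry gray or black letterbox borders; this removes
#' the maximal margin of rows and columns whose intensity range is within
#' `tol`, from each of the four edges. The operation is idempotent.
#'
#' @param image numeric grayscale matrix.
#' @param tol uniformity tolerance in intensity units (same scale as the
#'   image).
#' @return A list with `image` (cropped matrix) and `offset = c(row, col)`:
#'   the number of rows/columns removed at the top/left, so that
#'   `cropped[r, c]` is `original[r + offset[1], c + offset[2]]`.
#' @examples
#' img <- matrix(runif(400), 20, 20); img[, 1:4] <- 0
#' crop_borders(img, tol = 0)$offset
#' @export
crop_borders <- function(image, tol = 2 / 255) {
  assert_gray_image(image)
  uniform_run <- function(ranges) {
    n <- 0
    for (r in ranges) { if (r <= tol) n <- n + 1 else break }
    n
  }
  row_rng <- apply(image, 1, function(x) diff(range(x)))
  col_rng <- apply(image, 2, function(x) diff(range(x)))
  top <- uniform_run(row_rng); bottom <- uniform_run(rev(row_rng))
  left <- uniform_run(col_rng); right <- uniform_run(rev(col_rng))
  if (top + bottom >= nrow(image) || left + right >= ncol(image))
    abort("image is fully uniform: no content to crop to")
  out <- image[(1 + top):(nrow(image) - bottom),
               (1 + left):(ncol(image) - right), drop = FALSE]
  list(image = out, offset = c(top, left))
}

#' Denoise and contrast-enhance a frame
#'
#' Applies the fixed enhancement recipe: Gaussian blur (noise removal)
#' followed by CLAHE (local contrast enhancement). The output has the same
#' shape and `[0, 1]` intensity convention as the input. Constant images are
#' returned unchanged (CLAHE is undefined on zero dynamic range).
#'
#' @param image numeric grayscale matrix with values in `[0, 1]`.
#' @param params a [preprocess_params()].
#' @return Enhanced matrix, same dimensions.
#' @export
enhance <- function(image, params = preprocess_params()) {
  assert_gray_image(image)
  x <- image
  if (params$blur_sigma > 0)
    x <- EBImage::gblur(x, sigma = params$blur_sigma)
  if (diff(range(x)) < 1e-12) return(x)
  x <- EBImage::clahe(clamp(x, 0, 1),
                      nx = params$clahe_tile_grid[1],
                      ny = params$clahe_tile_grid[2],
                      limit = params$clahe_clip_limit)
  matrix(as.numeric(x), nrow(image), ncol(image))
}
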