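# Synthetic matching templates: the detector never learns from data; it
# matches programmatically generated sensor patterns (dark soft-edged bars
# on a neutral background) against the preprocessed frames.

new_template <- function(pixels, kind, scale, row_profile = NULL,
                         col_profile = NULL, sign = -1) {
  structure(list(pixels = pixels, kind = kind, scale = scale,
                 anchor = c((nrow(pixels) + 1) / 2, (ncol(pixels) + 1) / 2),
                 row_profile = row_profile, col_profile = col_profile,
                 sign = sign),
            class = "fluoro_template")
}

#' @export
print.fluoro_template <- function(x, ...) {
  cat(sprintf("<template %s/%s> %dx%d px, anchor (%g, %g)\n", x$kind, x$scale,
              nrow(x$pixels), ncol(x$pixels), x$anchor[1], x$anchor[2]))
  invisible(x)
}

# soft-edged vertical bar profile values at offsets `d` with half-width `h`
soft_edge <- function(d, h, softness = 1) plogis((h - abs(d)) / softness)

template_canvas <- function(height, width) {
  matrix(0.5, odd_ceiling(height), odd_ceiling(width))
}

# 1-D bar profiles: every template is 0.5 - depth * outer(row, col) — a
# rank-1 pattern, which the matcher exploits for a separable NCC.
bar_row_profile <- function(h, centers, len) {
  u <- seq_len(h)
  rowSums(vapply(centers, function(cr) soft_edge(u - cr, len / 2),
                 numeric(h)))
}

bar_col_profile <- function(w, width) {
  soft_edge(seq_len(w) - (w + 1) / 2, width / 2)
}

#' Build a single-sensor matching template
#'
#' A dark, soft-edged, vertically oriented sensor bar on a neutral
#' background; the anchor sits at the bar center. Used by the second
#' detection stage (sensor localization along the catheter line).
#'
#' @param sensor_len_px,sensor_width_px bar size in pixels; must be positive.
#' @param scale label for the geometry preset (`"large"`/`"small"`).
#' @return A `fluoro_template`.
#' @export
make_single_template <- function(sensor_len_px, sensor_width_px,
                                 scale = "large") {
  if (sensor_len_px <= 0 || sensor_width_px <= 0)
    abort("template dimensions must be positive")
  px <- template_canvas(sensor_len_px + 0.6 * sensor_len_px + 4,
                        3 * sensor_width_px)
  rp <- bar_row_profile(nrow(px), (nrow(px) + 1) / 2, sensor_len_px)
  cp <- bar_col_profile(ncol(px), sensor_width_px)
  new_template(px - 0.45 * outer(rp, cp), "single", scale, rp, cp)
}

#' Build a three-sensor matching template
#'
#' Three dark bars at the given center-to-center spacing along the vertical
#' axis; the anchor sits at the middle bar's center. Used by the first
#' detection stage (catheter-line detection), where the repeating
#' three-sensor pattern is far more specific than a single blob.
#'
#' @param sensor_len_px bar length, px.
#' @param spacing_px center-to-center bar spacing, px; must exceed the bar
#'   length (sensors never overlap).
#' @param sensor_width_px bar width, px.
#' @param scale label for the geometry preset.
#' @return A `fluoro_template`.
#' @export
make_triple_template <- function(sensor_len_px, spacing_px, sensor_width_px,
                                 scale = "large") {
  if (sensor_len_px <= 0 || sensor_width_px <= 0 || spacing_px <= 0)
    abort("template dimensions must be positive")
  if (spacing_px <= sensor_len_px)
    abort("`spacing_px` must exceed `sensor_len_px` (bars would overlap)")
  px <- template_canvas(2 * spacing_px + sensor_len_px + 0.6 * sensor_len_px + 4,
                        3 * sensor_width_px)
  mid <- (nrow(px) + 1) / 2
  rp <- bar_row_profile(nrow(px), mid + c(-spacing_px, 0, spacing_px),
                        sensor_len_px)
  cp <- bar_col_profile(ncol(px), sensor_width_px)
  new_template(px - 0.45 * outer(rp, cp), "triple", scale, rp, cp)
}

#' Build the four-template matching bank
#'
#' Two geometry presets ("large" and "small" sensor size, for robustness to
#' patient- and exposure-dependent sensor appearance) crossed with the two
#' template kinds: triple-sensor templates for catheter-line detection and
#' single-sensor templates for sensor localization.
#'
#' @param large,small lists with `len` and `width` (px) for each preset; the
#'   large preset must have the longer sensor.
#' @param spacing_px bar spacing for the triple templates, px.
#' @return A list of four `fluoro_template`s named
#'   `triple_large`, `triple_small`, `single_large`, `single_small`.
#' @examples
#' length(template_bank())
#' @export
template_bank <- function(large = list(len = 30, width = 12),
                          small = list(len = 24, width = 9),
                          spacing_px = 38) {
  stopifnot(large$len > small$len)
  list(
    triple_large = make_triple_template(large$len, spacing_px, large$width, "large"),
    triple_small = make_triple_template(small$len, spacing_px, small$width, "small"),
    single_large = make_single_template(large$len, large$width, "large"),
    single_small = make_single_template(small$len, small$width, "small")
  )
}

bank_subset <- function(bank, kind) {
  bank[map_lgl(bank, function(t) t$kind == kind)]
}
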