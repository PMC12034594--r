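#' Synchronized physio sample for a frame time
#'
#' Frames and physiological recordings share a time origin; the sample
#' shown on a frame is the nearest one. Returns the number of elapsed
#' samples since the origin (0 for the sample at `t0`), clipped to the
#' record length with a warning. At 50 Hz versus at most 15 fps the
#' nearest-sample error is below 10 ms, so no temporal interpolation of the
#' physio signal is performed.
#'
#' @param frame_time frame timestamp, seconds (`>= 0`).
#' @param physio_rate sampling rate, Hz.
#' @param n_samples record length; when given, the index is clipped to
#'   `n_samples - 1` elapsed samples.
#' @return Integer sample offset (0-based count of elapsed samples; add 1
#'   to index an R matrix column).
#' @examples
#' sync_sample_index(1.0, 50)  # 50
#' @export
sync_sample_index <- function(frame_time, physio_rate, n_samples = Inf) {
  if (any(frame_time < 0)) abort("`frame_time` must be non-negative")
  idx <- round(frame_time * physio_rate)
  if (any(idx > n_samples - 1)) {
    warn("frame time beyond the physio record: using the last sample")
    idx <- pmin(idx, n_samples - 1)
  }
  as.integer(idx)
}

#' Sensor pair spanned by an impedance channel
#'
#' The 15 impedance values are measured between every second sensor
#' starting from the fourth: channel *k* spans sensors `2 + 2k` and
#' `4 + 2k`, so channel 1 spans (4, 6) and channel 15 spans (32, 34) —
#' 15 span-two intervals exactly tiling sensors 4..34.
#'
#' @param channel impedance channel, 1..15.
#' @return Integer vector `c(sensor_a, sensor_b)`.
#' @examples
#' impedance_span(1)
#' @export
impedance_span <- function(channel) {
  if (any(channel < 1 | channel > 15 | channel != round(channel)))
    abort("impedance `channel` must be an integer in 1..15")
  cbind(a = as.integer(2 + 2 * channel), b = as.integer(4 + 2 * channel))[
    , , drop = TRUE]
}

#' Color scale for projected physiological values
#'
#' A Clouse-plot-style monotone color ramp (blue -> green -> yellow -> red by
#' default). Values are clamped (not dropped) to `[value_min, value_max]`;
#' `log = TRUE` maps on a log scale (used for impedance, whose dynamic range
#' spans orders of magnitude).
#'
#' @param value_min,value_max display range (mmHg or Ohm).
#' @param colors ordered ramp colors.
#' @param log map values on a log scale.
#' @return A `color_scale`; use [scale_colors()] to map values to hex colors.
#' @export
color_scale <- function(value_min, value_max,
                        colors = c("blue", "green", "yellow", "red"),
                        log = FALSE) {
  if (value_min >= value_max) abort("`value_min` must be below `value_max`")
  structure(list(value_min = value_min, value_max = value_max,
                 colors = colors, log = isTRUE(log),
                 ramp = grDevices::colorRamp(colors)),
            class = "color_scale")
}

#' Map values through a color scale
#'
#' @param scale a [color_scale()].
#' @param values numeric values; clamped to the scale range.
#' @return Character vector of hex colors.
#' @export
scale_colors <- function(scale, values) {
  v <- clamp(values, scale$value_min, scale$value_max)
  if (scale$log) {
    u <- (log(v) - log(scale$value_min)) /
      (log(scale$value_max) - log(scale$value_min))
  } else {
    u <- (v - scale$value_min) / (scale$value_max - scale$value_min)
  }
  rgb <- scale$ramp(u)
  grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3], maxColorValue = 255)
}

#' Interpolate per-sensor values along the catheter
#'
#' Linear interpolation in arc length between consecutive valued sensors,
#' producing the continuous colored line the projection draws; no
#' extrapolation beyond the outermost valued sensors.
#'
#' @param sensors a `sensor_set` (needs `arc`).
#' @param values one scalar per sensor row (NA allowed; at least two
#'   non-NA).
#' @return Tibble `arc` (1-px steps spanning the valued sensors), `value`.
#' @export
interpolate_along_catheter <- function(sensors, values) {
  ok <- !is.na(values)
  if (sum(ok) < 2) abort("need at least 2 sensors with values to interpolate")
  arc <- sensors$arc[ok]; val <- values[ok]
  grid <- seq(min(arc), max(arc))
  interp <- approx(arc, val, xout = grid)$y
  tibble(arc = grid, value = interp)
}

#' Default display scales for projected values
#'
#' Manometry: -10..150 mmHg, linear; impedance: 50..2000 Ohm, log-scaled.
#' @return A [color_scale()].
#' @export
default_mano_scale <- function() color_scale(-10, 150)

#' @rdname default_mano_scale
#' @export
default_imped_scale <- function() color_scale(50, 2000, log = TRUE)

#' Render the multimodal overlay for one frame
#'
#' Projects the synchronized manometry and impedance values onto the
#' detected sensor locations: a pressure ribbon is drawn along the catheter
#' line (colored by the per-sensor pressures, interpolated between sensors),
#' and an impedance ribbon is drawn at a lateral offset, spanning the
#' midpoints of each channel's sensor pair. Inferred sensors are rendered
#' exactly like detected ones. Pixels outside the ribbons are bit-identical
#' to the input frame, and the color at each sensor center is exactly
#' `colormap(clamped value)`.
#'
#' @param frame grayscale matrix in `[0, 1]`.
#' @param line the accepted `catheter_line` (unused directly; the ribbon
#'   follows the sensor arc span, kept for API symmetry and clipping).
#' @param sensors a `sensor_set` with `sensor_index`, `arc`.
#' @param physio a `physio_record`.
#' @param frame_time frame timestamp, seconds.
#' @param mano_scale,imped_scale [color_scale()]s; defaults -10..150 mmHg
#'   and 50..2000 Ohm (log).
#' @param ribbon_width manometry ribbon width, px.
#' @param imped_offset_px lateral offset of the impedance ribbon, px.
#' @param imped_width impedance ribbon width, px.
#' @return An `overlay_frame`: numeric array `H x W x 3` (RGB in `[0, 1]`)
#'   with a `legend` attribute describing both scales.
#' @export
render_overlay <- function(frame, line, sensors, physio, frame_time,
                           mano_scale = default_mano_scale(),
                           imped_scale = default_imped_scale(),
                           ribbon_width = 8, imped_offset_px = 12,
                           imped_width = 6) {
  assert_gray_image(frame)
  if (nrow(sensors) < 2) abort("need at least two detected sensors to render")
  idx <- sync_sample_index(frame_time, physio$rate, ncol(physio$mano)) + 1L
  if (nrow(physio$mano) < max(sensors$sensor_index))
    abort(sprintf("missing manometry channel %d", max(sensors$sensor_index)))

  H <- nrow(frame); W <- ncol(frame)
  out <- array(frame, dim = c(H, W, 3))

  paint_band <- function(pts, cols_rgb, width) {
    half <- floor(width / 2)
    for (dw in -half:half) {
      r <- round(pts$row); c <- clamp(round(pts$col) + dw, 1, W)
      keep <- r >= 1 & r <= H
      ij <- cbind(r[keep], c[keep])
      out[cbind(ij, 1)] <<- cols_rgb[keep, 1]
      out[cbind(ij, 2)] <<- cols_rgb[keep, 2]
      out[cbind(ij, 3)] <<- cols_rgb[keep, 3]
    }
  }
  hex_to_rgb <- function(hex) t(grDevices::col2rgb(hex)) / 255

  # manometry ribbon along the catheter
  pvals <- physio$mano[sensors$sensor_index, idx]
  interp <- interpolate_along_catheter(sensors, pvals)
  pts <- point_at_arc(line, interp$arc)
  paint_band(pts, hex_to_rgb(scale_colors(mano_scale, interp$value)), ribbon_width)
  # exact color at each sensor center
  cpts <- tibble(row = sensors$row, col = sensors$col)
  paint_band(cpts, hex_to_rgb(scale_colors(mano_scale, pvals)), ribbon_width)

  # impedance ribbon at a lateral offset, spanning each channel's pair
  span <- map(1:15, impedance_span)
  have <- map_lgl(span, function(s) all(s %in% sensors$sensor_index))
  if (sum(have) >= 2) {
    mid_arc <- map_dbl(span[have], function(s) {
      mean(sensors$arc[match(s, sensors$sensor_index)])
    })
    zvals <- physio$imped[which(have), idx]
    o <- order(mid_arc)
    grid <- seq(min(mid_arc), max(mid_arc))
    zi <- approx(mid_arc[o], zvals[o], xout = grid)$y
    zpts <- point_at_arc(line, grid)
    zpts$col <- zpts$col + imped_offset_px
    paint_band(zpts, hex_to_rgb(scale_colors(imped_scale, zi)), imped_width)
  }

  structure(out, class = "overlay_frame",
            legend = list(mano = mano_scale[c("value_min", "value_max", "log")],
                          imped = imped_scale[c("value_min", "value_max", "log")],
                          frame_time = frame_time, sample_index = idx - 1L))
}
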