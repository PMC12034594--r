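#' Specify a synthetic fluoroscopy phantom
#'
#' Builds the parameter set for the synthetic phantom generator: a smoothly
#' curved, mostly vertical manometry catheter carrying dark (radiopaque)
#' sensor blobs, rendered into grayscale frames over a slowly varying
#' anatomical background, optionally with a moving radiopaque bolus that
#' occludes sensors, plus synchronized manometry/impedance traces.
#'
#' Geometry defaults are derived from the clinical acquisition scale
#' (1024x1024 frames, ~38 px sensor spacing, sensors ~27x12 px) and scale
#' proportionally with `image_size`; the package default of 512x512 keeps
#' test runs fast. Intensities are on `[0, 1]`; the four named noise levels
#' map to Gaussian sigmas 0, 10, 25 and 50 on the 8-bit scale.
#'
#' @param image_size integer vector `c(rows, cols)`.
#' @param n_frames number of frames in the sequence.
#' @param fps frame rate, frames/s; must lie in `[8, 15]`.
#' @param n_sensors_total sensors on the catheter (clinically 36).
#' @param spacing_px center-to-center sensor spacing along the catheter, px.
#' @param sensor_len_px,sensor_width_px sensor blob size, px; the spacing
#'   must exceed the length (sensors never overlap).
#' @param n_visible how many sensors are placed inside the frame.
#' @param visible_end which catheter end is in frame, `"top"` or `"bottom"`;
#'   determines sensor numbering (index 1 at the top for `"top"`, index
#'   `n_sensors_total` at the bottom for `"bottom"`).
#' @param curve_amplitude_px maximal lateral excursion of the catheter curve.
#' @param drift_amplitude_px,drift_period_frames slow lateral anatomical
#'   drift across frames; the defaults bound frame-to-frame displacement of
#'   any catheter point well below 3 px.
#' @param bolus_enabled render a moving radiopaque bolus blob.
#' @param bolus_speed_px_per_frame bolus advance along the catheter per frame.
#' @param bolus_radius_px bolus footprint radius; default `2.6 * spacing_px`
#'   so the footprint covers about five consecutive sensors.
#' @param bolus_start_frac starting bolus position as a fraction of the
#'   catheter arc length.
#' @param noise_level one of `"none"`, `"little"`, `"medium"`, `"most"`.
#' @param noise_sigma optional explicit Gaussian noise sigma on the `[0, 1]`
#'   scale, overriding `noise_level`.
#' @param seed integer seed; identical specs generate bit-identical data.
#'
#' @return An object of class `phantom_spec` (a named list).
#' @examples
#' spec <- phantom_spec(n_frames = 4)
#' spec$spacing_px
#' @export
phantom_spec <- function(image_size = c(512, 512),
                         n_frames = 40,
                         fps = 10,
                         n_sensors_total = 36,
                         spacing_px = NULL,
                         sensor_len_px = NULL,
                         sensor_width_px = NULL,
                         n_visible = NULL,
                         visible_end = c("top", "bottom"),
                         curve_amplitude_px = NULL,
                         drift_amplitude_px = 4,
                         drift_period_frames = 20,
                         bolus_enabled = FALSE,
                         bolus_speed_px_per_frame = 2,
                         bolus_radius_px = NULL,
                         bolus_start_frac = 0.45,
                         noise_level = c("none", "little", "medium", "most"),
                         noise_sigma = NULL,
                         seed = 1L) {
  visible_end <- match.arg(visible_end)
  noise_level <- match.arg(noise_level)
  stopifnot(length(image_size) == 2, all(image_size >= 32), n_frames >= 1)
  if (fps < 8 || fps > 15) abort("`fps` must lie in [8, 15]")
  scale <- image_size[1] / 1024
  spacing_px <- spacing_px %||% max(8, round(38 * scale))
  sensor_len_px <- sensor_len_px %||% max(5, round(27 * scale))
  sensor_width_px <- sensor_width_px %||% max(3, round(12 * scale))
  curve_amplitude_px <- curve_amplitude_px %||% round(80 * scale)
  n_visible <- n_visible %||% min(n_sensors_total,
                                  floor(image_size[1] / spacing_px) - 1)
  bolus_radius_px <- bolus_radius_px %||% (2.6 * spacing_px)
  if (spacing_px <= sensor_len_px)
    abort("`spacing_px` must exceed `sensor_len_px`: sensors never overlap")
  if (n_visible > n_sensors_total)
    abort("`n_visible` cannot exceed `n_sensors_total`")
  structure(list(
    image_size = as.integer(image_size), n_frames = as.integer(n_frames),
    fps = fps, n_sensors_total = as.integer(n_sensors_total),
    spacing_px = spacing_px, sensor_len_px = sensor_len_px,
    sensor_width_px = sensor_width_px, n_visible = as.integer(n_visible),
    visible_end = visible_end, curve_amplitude_px = curve_amplitude_px,
    drift_amplitude_px = drift_amplitude_px,
    drift_period_frames = drift_period_frames,
    bolus_enabled = isTRUE(bolus_enabled),
    bolus_speed_px_per_frame = bolus_speed_px_per_frame,
    bolus_radius_px = bolus_radius_px, bolus_start_frac = bolus_start_frac,
    noise_level = noise_level,
    noise_sigma = noise_sigma %||% noise_sigma_for(noise_level),
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' Gaussian noise sigma for a named phantom noise level
#'
#' The four levels correspond to sigmas 0, 10, 25 and 50 on the 8-bit
#' intensity scale, returned here on the `[0, 1]` scale.
#'
#' @param level `"none"`, `"little"`, `"medium"` or `"most"`.
#' @return Numeric sigma on the `[0, 1]` intensity scale.
#' @export
noise_sigma_for <- function(level) {
  sig <- c(none = 0, little = 10, medium = 25, most = 50) / 255
  unname(sig[match.arg(level, names(sig))])
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> %dx%d px, %d frames @ %g fps, %d/%d sensors visible (%s)\n",
    x$image_size[1], x$image_size[2], x$n_frames, x$fps, x$n_visible,
    x$n_sensors_total, x$visible_end))
  cat(sprintf("  spacing %g px, sensor %gx%g px, curve +/-%g px, noise '%s', seed %d\n",
              x$spacing_px, x$sensor_len_px, x$sensor_width_px,
              x$curve_amplitude_px, x$noise_level, x$seed))
  if (x$bolus_enabled)
    cat(sprintf("  bolus: radius %g px, %g px/frame\n",
                x$bolus_radius_px, x$bolus_speed_px_per_frame))
  invisible(x)
}

#' Generate the catheter center-line for one phantom frame
#'
#' The catheter is a smooth, mostly vertical curve: a fixed two-harmonic
#' lateral profile (phases drawn once from the spec seed) plus a slow
#' sinusoidal whole-curve drift across frames emulating anatomical motion.
#' Frame-to-frame displacement of any point is bounded by
#' `drift_amplitude_px * 2 * pi / drift_period_frames` (about 1.3 px at the
#' defaults).
#'
#' @param spec a [phantom_spec()].
#' @param frame_idx frame index, 1-based, `<= n_frames`.
#' @return A `catheter_line` tibble with columns `row` (1..rows) and `col`.
#' @export
generate_catheter_path <- function(spec, frame_idx) {
  stopifnot(inherits(spec, "phantom_spec"),
            frame_idx >= 1, frame_idx <= spec$n_frames)
  H <- spec$image_size[1]; W <- spec$image_size[2]
  ph <- with_seed(spec$seed, runif(3, 0, 2 * pi))
  r <- seq_len(H)
  # low-order bend: a half-period harmonic plus a mild full-period one, so the
  # local inclination stays realistic for an esophageal catheter (< ~20 deg)
  shape <- 0.8 * sin(pi * r / H + ph[1]) + 0.2 * sin(2 * pi * r / H + ph[2])
  shape <- shape - mean(shape)
  shape <- shape / max(1, max(abs(shape)))   # excursion <= curve_amplitude_px
  drift <- spec$drift_amplitude_px *
    sin(2 * pi * (frame_idx - 1) / spec$drift_period_frames + ph[3])
  margin <- max(8, spec$sensor_width_px)
  col <- clamp(W / 2 + spec$curve_amplitude_px * shape + drift,
               1 + margin, W - margin)
  new_catheter_line(r, col)
}

# cumulative arc length (px) along a catheter line, starting at 0 at its top
arc_cumulative <- function(line) {
  c(0, cumsum(sqrt(1 + diff(line$col)^2)))
}

# (row, col) image points at given arc positions along the line
point_at_arc <- function(line, s) {
  cs <- arc_cumulative(line)
  tibble(
    arc = s,
    row = approx(cs, line$row, xout = s, rule = 2)$y,
    col = approx(cs, line$col, xout = s, rule = 2)$y
  )
}

# local tangent direction (unit d_row, d_col) at given rows of the line
tangent_at_row <- function(line, rows) {
  n <- nrow(line)
  i <- clamp(round(rows), 2, n - 1)
  dr <- line$row[i + 1] - line$row[i - 1]
  dc <- line$col[i + 1] - line$col[i - 1]
  nrm <- sqrt(dr^2 + dc^2)
  cbind(dr / nrm, dc / nrm)
}

# Arc positions and indices of the sensors placed on the phantom catheter.
phantom_sensor_arcs <- function(spec, path) {
  L <- max(arc_cumulative(path))
  s0 <- 0.6 * spec$spacing_px
  s <- s0 + (seq_len(spec$n_visible) - 1) * spec$spacing_px
  pts <- point_at_arc(path, s)
  margin <- spec$sensor_len_px / 2
  keep <- pts$row >= 1 + margin & pts$row <= spec$image_size[1] - margin & s <= L
  pts <- pts[keep, , drop = FALSE]
  n_kept <- nrow(pts)
  idx <- if (spec$visible_end == "top") seq_len(n_kept)
         else spec$n_sensors_total - n_kept + seq_len(n_kept)
  pts$sensor_index <- idx
  pts
}

# bolus center (arc position) at a given frame, or NULL when disabled
bolus_arc_at <- function(spec, path, frame_idx) {
  if (!spec$bolus_enabled) return(NULL)
  L <- max(arc_cumulative(path))
  spec$bolus_start_frac * L + spec$bolus_speed_px_per_frame * (frame_idx - 1)
}

#' Render one phantom frame with its ground truth
#'
#' Draws a smooth background (intensity gradients plus a broad blob,
#' emulating anatomy and varying lighting), a faint catheter line, dark
#' soft-edged sensor blobs oriented along the local tangent at arc-length
#' multiples of the spacing, optionally a radiopaque bolus blob whose hard
#' core saturates the image (occluding any sensor inside it), and finally
#' additive zero-mean Gaussian noise.
#'
#' @param spec a [phantom_spec()].
#' @param path the frame's catheter line from [generate_catheter_path()].
#' @param frame_idx 1-based frame index (drives bolus position and the
#'   per-frame noise stream).
#' @return A list with `image` (numeric matrix in `[0, 1]`) and `truth`
#'   (tibble: `frame`, `sensor_index`, `row`, `col`, `occluded`).
#' @export
render_frame <- function(spec, path, frame_idx) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$image_size[1]; W <- spec$image_size[2]
  if (spec$sensor_len_px >= min(H, W))
    abort("phantom geometry does not fit a single sensor in the frame")

  bgp <- with_seed(spec$seed + 1, {
    list(g = runif(2, -0.08, 0.08),
         blob = c(runif(1, 0.25, 0.75) * H, runif(1, 0.25, 0.75) * W),
         blob_sigma = runif(1, 0.25, 0.5) * H,
         blob_amp = runif(1, -0.10, 0.10))
  })
  rr <- seq_len(H) / H - 0.5; cc <- seq_len(W) / W - 0.5
  img <- 0.72 + outer(rr * bgp$g[1], rep(1, W)) + outer(rep(1, H), cc * bgp$g[2])
  d2 <- outer((seq_len(H) - bgp$blob[1])^2, rep(1, W)) +
        outer(rep(1, H), (seq_len(W) - bgp$blob[2])^2)
  img <- img + bgp$blob_amp * exp(-d2 / (2 * bgp$blob_sigma^2))

  # faint catheter shaft
  for (dw in -3:3) {
    j <- clamp(round(path$col) + dw, 1, W)
    img[cbind(path$row, j)] <- img[cbind(path$row, j)] -
      0.06 * exp(-(dw / 1.5)^2 / 2)
  }

  sensors <- phantom_sensor_arcs(spec, path)
  tang <- tangent_at_row(path, sensors$row)
  hl <- spec$sensor_len_px / 2; hw <- spec$sensor_width_px / 2
  reach <- ceiling(hl + hw + 4)
  for (k in seq_len(nrow(sensors))) {
    r0 <- sensors$row[k]; c0 <- sensors$col[k]
    ri <- max(1, floor(r0 - reach)):min(H, ceiling(r0 + reach))
    ci <- max(1, floor(c0 - reach)):min(W, ceiling(c0 + reach))
    dr <- outer(ri - r0, rep(1, length(ci)))
    dc <- outer(rep(1, length(ri)), ci - c0)
    u <- dr * tang[k, 1] + dc * tang[k, 2]   # along the catheter
    v <- -dr * tang[k, 2] + dc * tang[k, 1]  # across it
    dip <- 0.40 * plogis((hl - abs(u)) / 1.0) * plogis((hw - abs(v)) / 1.0)
    img[ri, ci] <- img[ri, ci] - dip
  }

  occluded <- rep(FALSE, nrow(sensors))
  s_b <- bolus_arc_at(spec, path, frame_idx)
  if (!is.null(s_b)) {
    bc <- point_at_arc(path, s_b)
    rad <- spec$bolus_radius_px
    ri <- max(1, floor(bc$row - rad - 8)):min(H, ceiling(bc$row + rad + 8))
    ci <- max(1, floor(bc$col - rad - 8)):min(W, ceiling(bc$col + rad + 8))
    dist <- sqrt(outer((ri - bc$row)^2, rep(1, length(ci))) +
                 outer(rep(1, length(ri)), (ci - bc$col)^2))
    sub <- img[ri, ci]
    sub[dist <= rad] <- 0.05                          # saturated core
    rim <- dist > rad & dist <= rad + 6
    blend <- plogis((rad + 3 - dist[rim]) / 1.5)
    sub[rim] <- sub[rim] * (1 - blend) + 0.05 * blend
    img[ri, ci] <- sub
    # occluded = the whole sensor lies inside the saturated core (a sensor
    # at the rim is still partly visible and is not flagged)
    occluded <- sqrt((sensors$row - bc$row)^2 + (sensors$col - bc$col)^2) <=
      rad - spec$sensor_len_px / 2
  }

  if (spec$noise_sigma > 0) {
    img <- img + with_seed(child_seed(spec$seed, frame_idx),
                           matrix(rnorm(H * W, 0, spec$noise_sigma), H, W))
  }
  img <- clamp(img, 0, 1)

  truth <- tibble(
    frame = as.integer(frame_idx),
    sensor_index = as.integer(sensors$sensor_index),
    row = sensors$row, col = sensors$col, occluded = occluded
  )
  list(image = img, truth = truth)
}

#' Generate synchronized propagating-wave manometry and impedance traces
#'
#' Emulates a peristaltic swallow: each of the 36 manometry channels carries
#' a Gaussian-profile pressure wave whose peak time increases strictly from
#' channel 1 to 36 over the sequence duration (the structure a Clouse plot
#' displays), on a noisy baseline. The 15 impedance channels show a
#' transient conductivity drop co-propagating with the wave at the midpoint
#' of each channel's sensor pair.
#'
#' @param spec a [phantom_spec()]; duration is `n_frames / fps` and sampling
#'   is 50 Hz.
#' @return A `physio_record`: list with `mano` (36 x T, mmHg), `imped`
#'   (15 x T, Ohm), `rate` (Hz), `t0` and `time` (s).
#' @export
generate_physio <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  rate <- 50
  duration <- spec$n_frames / spec$fps
  Tn <- round(duration * rate)
  time <- (seq_len(Tn) - 1) / rate
  n_m <- spec$n_sensors_total
  lead <- 0.1 * duration
  peak_t <- lead + (seq_len(n_m) - 1) / (n_m - 1) * (duration - 2 * lead)
  tau <- duration / 25
  mano <- with_seed(spec$seed + 2, {
    m <- matrix(rnorm(n_m * Tn, 0, 0.8), n_m, Tn) + 8
    for (k in seq_len(n_m))
      m[k, ] <- m[k, ] + 110 * exp(-(time - peak_t[k])^2 / (2 * tau^2))
    m
  })
  imped <- with_seed(spec$seed + 3, {
    z <- matrix(rnorm(15 * Tn, 0, 20), 15, Tn) + 1600
    tau2 <- duration / 18
    for (k in 1:15) {
      mid <- 3 + 2 * k   # sensor midway between the channel's pair
      z[k, ] <- z[k, ] - 1400 * exp(-(time - peak_t[mid])^2 / (2 * tau2^2))
    }
    pmax(z, 50)
  })
  structure(list(mano = mano, imped = imped, rate = rate, t0 = 0, time = time),
            class = "physio_record")
}

#' @export
print.physio_record <- function(x, ...) {
  cat(sprintf("<physio_record> %d manometry + %d impedance channels, %d samples @ %g Hz\n",
              nrow(x$mano), nrow(x$imped), ncol(x$mano), x$rate))
  invisible(x)
}

#' @export
as_tibble.physio_record <- function(x, ...) {
  m <- t(x$mano); colnames(m) <- sprintf("mano_%02d", seq_len(nrow(x$mano)))
  z <- t(x$imped); colnames(z) <- sprintf("imp_%02d", seq_len(nrow(x$imped)))
  bind_cols(tibble(time = x$time), as_tibble(m), as_tibble(z))
}

#' Generate a complete phantom dataset
#'
#' Renders all frames with their ground truth and the synchronized
#' physiological record sharing the same time origin (frame `i` is at
#' `(i - 1) / fps` seconds).
#'
#' @param spec a [phantom_spec()].
#' @return A `phantom_dataset`: list with `frames` (list of matrices),
#'   `timestamps` (s), `truth` (tibble over all frames), `physio`
#'   (a `physio_record`) and the `spec`.
#' @examples
#' ds <- generate_dataset(phantom_spec(image_size = c(128, 128), n_frames = 2,
#'                                     spacing_px = 12, sensor_len_px = 8,
#'                                     sensor_width_px = 4, n_visible = 8))
#' dim(ds$frames[[1]])
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  out <- map(seq_len(spec$n_frames), function(f) {
    path <- generate_catheter_path(spec, f)
    render_frame(spec, path, f)
  })
  structure(list(
    frames = map(out, "image"),
    timestamps = (seq_len(spec$n_frames) - 1) / spec$fps,
    truth = list_rbind(map(out, "truth")),
    physio = generate_physio(spec),
    spec = spec
  ), class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf("<phantom_dataset> %d frames %dx%d, %d truth points, seed %d\n",
              length(x$frames), x$spec$image_size[1], x$spec$image_size[2],
              nrow(x$truth), x$spec$seed))
  invisible(x)
}
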