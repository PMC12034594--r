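#' Detection parameters for a sequence
#'
#' Bundles every tunable of the two-stage detector. When a [phantom_spec()]
#' is given, the template geometry is taken from it; otherwise pass the
#' sensor geometry observed in the data (at the clinical scale: spacing
#' ~38 px, sensors ~27x12 px).
#'
#' @param spec optional [phantom_spec()] supplying geometry and
#'   `visible_end`.
#' @param spacing_px,sensor_len_px,sensor_width_px sensor geometry, px.
#' @param visible_end which catheter end is in frame (`"top"`/`"bottom"`);
#'   a dataset-level property, not auto-detected.
#' @param preprocess a [preprocess_params()].
#' @param score_floor,max_slope,gap_max,min_span_frac catheter-line
#'   extraction parameters, see [extract_line()].
#' @param dev_thresh_px temporal-correction threshold, see
#'   [temporal_correct()].
#' @param peak_floor,extend_floor sensor-peak parameters, see
#'   [detect_peaks()] and [regularize_and_number()].
#' @param n_sensors_total sensors on the catheter.
#' @return A `detect_config` list (includes the generated template `bank`).
#' @export
detect_config <- function(spec = NULL,
                          spacing_px = 38, sensor_len_px = 27,
                          sensor_width_px = 12,
                          visible_end = c("top", "bottom"),
                          preprocess = preprocess_params(),
                          score_floor = 0.3, max_slope = 3, gap_max = NULL,
                          min_span_frac = 0.5, dev_thresh_px = 25,
                          peak_floor = 0.25, extend_floor = 0.15,
                          n_sensors_total = 36) {
  if (!is.null(spec)) {
    stopifnot(inherits(spec, "phantom_spec"))
    spacing_px <- spec$spacing_px
    sensor_len_px <- spec$sensor_len_px
    sensor_width_px <- spec$sensor_width_px
    visible_end <- spec$visible_end
    n_sensors_total <- spec$n_sensors_total
  } else visible_end <- match.arg(visible_end)
  # a bolus can blank several sensor spacings plus the rows where the tall
  # triple template cannot anchor; the bridgeable gap must cover that
  gap_max <- gap_max %||% (12 * spacing_px)
  large <- list(len = max(3, round(sensor_len_px * 30 / 27)),
                width = max(2, sensor_width_px))
  small <- list(len = max(2, round(sensor_len_px * 24 / 27)),
                width = max(1, round(sensor_width_px * 0.75)))
  structure(list(
    spacing_px = spacing_px, sensor_len_px = sensor_len_px,
    sensor_width_px = sensor_width_px, visible_end = visible_end,
    preprocess = preprocess,
    bank = template_bank(large, small, spacing_px),
    score_floor = score_floor, max_slope = max_slope, gap_max = gap_max,
    min_span_frac = min_span_frac, dev_thresh_px = dev_thresh_px,
    peak_floor = peak_floor, extend_floor = extend_floor,
    n_sensors_total = n_sensors_total
  ), class = "detect_config")
}

#' Run the two-stage sensor detector over a frame sequence
#'
#' Per frame: enhance (blur + CLAHE), triple-template heatmap, catheter-line
#' extraction, temporal error correction against the previous three
#' accepted lines, single-template heatmap, peak detection along the line,
#' and grid regularization with occluded-sensor inference and numbering.
#'
#' @param frames list of grayscale matrices (already cropped), or a
#'   `frame_sequence`.
#' @param config a [detect_config()].
#' @return List with `detections` (tibble `frame`, `sensor_index`, `row`,
#'   `col`, `arc`, `confidence`, `inferred`), `lines` (tibble `frame`,
#'   `row`, `col`), and `events` (per frame: `corrected`,
#'   `low_confidence`, `quality`).
#' @export
detect_sequence <- function(frames, config = detect_config()) {
  if (inherits(frames, "frame_sequence")) frames <- frames$frames
  stopifnot(length(frames) >= 1)
  hist <- list()
  detections <- list(); lines <- list(); events <- list()
  for (f in seq_along(frames)) {
    res <- tryCatch(
      detect_frame(frames[[f]], config, hist),
      error = function(e) abort(sprintf("frame %d: %s", f, conditionMessage(e))))
    hist <- res$hist
    detections[[f]] <- mutate(res$sensors, frame = as.integer(f), .before = 1)
    lines[[f]] <- tibble(frame = as.integer(f),
                         row = res$line$row, col = res$line$col)
    events[[f]] <- tibble(frame = as.integer(f), corrected = res$corrected,
                          low_confidence = attr(res$sensors, "low_confidence"),
                          quality = attr(res$line, "quality") %||% NA_real_)
  }
  list(detections = list_rbind(detections), lines = list_rbind(lines),
       events = list_rbind(events))
}

# single-frame detection step given the temporal history
detect_frame <- function(image, config, hist = list()) {
  img <- enhance(image, config$preprocess)
  lhm <- line_heatmap(img, config$bank)
  cur <- extract_line(lhm, score_floor = config$score_floor,
                      max_slope = config$max_slope, gap_max = config$gap_max,
                      min_span_frac = config$min_span_frac)
  tc <- temporal_correct(cur, hist, dev_thresh_px = config$dev_thresh_px)
  shm <- sensor_heatmap(img, config$bank)
  prof <- profile_along_line(shm, tc$line)
  peaks <- detect_peaks(prof, config$spacing_px, peak_floor = config$peak_floor)
  sensors <- regularize_and_number(
    peaks, tc$line, config$spacing_px, visible_end = config$visible_end,
    profile = prof, n_sensors_total = config$n_sensors_total,
    extend_floor = config$extend_floor)
  list(sensors = sensors, line = tc$line, hist = tc$hist,
       corrected = tc$corrected)
}

#' Assemble a run configuration
#'
#' The serializable configuration the pipeline and command-line interface
#' consume: input/output paths and the per-stage parameter sections.
#' Unknown section entries are rejected; missing ones get defaults.
#'
#' @param frames path to the frame directory or multi-page TIFF.
#' @param physio optional physio CSV path.
#' @param truth optional ground-truth CSV path (enables evaluation).
#' @param out_dir output directory.
#' @param fps frame rate, frames/s.
#' @param visible_end `"top"` or `"bottom"` (dataset-level, required).
#' @param preprocess,templates,catheter,sensors,fusion named lists
#'   overriding the per-stage defaults (see [preprocess_params()],
#'   [detect_config()], [render_overlay()]). `preprocess$crop` toggles
#'   border cropping; `fusion$write_overlays` toggles overlay PNG output.
#' @param seed integer seed (only phantom generation is stochastic; the
#'   detection pipeline itself is deterministic).
#' @return A `run_config` list.
#' @export
run_config <- function(frames = NULL, physio = NULL, truth = NULL,
                       out_dir = "fluorocath_out", fps = 10,
                       visible_end = "top",
                       preprocess = list(), templates = list(),
                       catheter = list(), sensors = list(), fusion = list(),
                       seed = 1L) {
  merge_section <- function(defaults, user, name) {
    bad <- setdiff(names(user), names(defaults))
    if (length(bad))
      abort(sprintf("unknown `%s` config entries: %s", name,
                    paste(bad, collapse = ", ")))
    utils::modifyList(defaults, user)
  }
  structure(list(
    frames = frames, physio = physio, truth = truth, out_dir = out_dir,
    fps = fps, visible_end = visible_end,
    preprocess = merge_section(
      list(crop = TRUE, blur_sigma = 1.5, clahe_clip_limit = 2,
           clahe_tile_grid = c(8L, 8L), border_tol = 2 / 255),
      preprocess, "preprocess"),
    templates = merge_section(
      list(spacing_px = 38, sensor_len_px = 27, sensor_width_px = 12),
      templates, "templates"),
    catheter = merge_section(
      list(score_floor = 0.3, max_slope = 3, gap_max = -1,
           min_span_frac = 0.5, dev_thresh_px = 25),
      catheter, "catheter"),
    sensors = merge_section(
      list(peak_floor = 0.25, extend_floor = 0.15, n_sensors_total = 36L),
      sensors, "sensors"),
    fusion = merge_section(
      list(mano_min = -10, mano_max = 150, imped_min = 50, imped_max = 2000,
           ribbon_width = 8, imped_offset_px = 12, imped_width = 6,
           write_overlays = FALSE),
      fusion, "fusion"),
    seed = as.integer(seed)
  ), class = "run_config")
}

detect_config_from_run <- function(cfg) {
  detect_config(
    spacing_px = cfg$templates$spacing_px,
    sensor_len_px = cfg$templates$sensor_len_px,
    sensor_width_px = cfg$templates$sensor_width_px,
    visible_end = cfg$visible_end,
    preprocess = preprocess_params(
      blur_sigma = cfg$preprocess$blur_sigma,
      clahe_clip_limit = cfg$preprocess$clahe_clip_limit,
      clahe_tile_grid = cfg$preprocess$clahe_tile_grid,
      border_tol = cfg$preprocess$border_tol),
    score_floor = cfg$catheter$score_floor,
    max_slope = cfg$catheter$max_slope,
    gap_max = if (cfg$catheter$gap_max > 0) cfg$catheter$gap_max else NULL,
    min_span_frac = cfg$catheter$min_span_frac,
    dev_thresh_px = cfg$catheter$dev_thresh_px,
    peak_floor = cfg$sensors$peak_floor,
    extend_floor = cfg$sensors$extend_floor,
    n_sensors_total = cfg$sensors$n_sensors_total)
}

#' Run the full pipeline from a configuration
#'
#' Reads the frames (cropping uniform borders when configured; all output
#' coordinates are mapped back to the original frame), runs the two-stage
#' detector, writes per-frame catheter lines and sensor detections as CSV,
#' optionally renders fused overlays (when a physio CSV is given) and an
#' evaluation report (when a truth CSV is given), and writes a structured
#' log of parameters and per-frame correction events.
#'
#' @param cfg a [run_config()].
#' @return Invisibly, a list with the in-memory `detections`, `lines`,
#'   `events`, optional `report`, and the output file paths.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$frames)) abort("config has no `frames` input")
  seq <- read_frames(cfg$frames, fps = cfg$fps)
  offsets <- map(seq$frames, function(f) c(0, 0))
  frames <- seq$frames
  if (isTRUE(cfg$preprocess$crop)) {
    cropped <- map(frames, crop_borders, tol = cfg$preprocess$border_tol)
    frames <- map(cropped, "image")
    offsets <- map(cropped, "offset")
  }
  dcfg <- detect_config_from_run(cfg)
  res <- detect_sequence(frames, dcfg)
  # map back to original frame coordinates
  off <- list_rbind(imap(offsets, function(o, i)
    tibble(frame = as.integer(i), row_off = o[1], col_off = o[2])))
  res$detections <- res$detections |> left_join(off, by = "frame") |>
    mutate(row = .data$row + .data$row_off, col = .data$col + .data$col_off) |>
    select(-"row_off", -"col_off")
  res$lines <- res$lines |> left_join(off, by = "frame") |>
    mutate(row = .data$row + .data$row_off, col = .data$col + .data$col_off) |>
    select(-"row_off", -"col_off")

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    detections = file.path(cfg$out_dir, "detections.csv"),
    lines = file.path(cfg$out_dir, "lines.csv"),
    log = file.path(cfg$out_dir, "run_log.txt"))
  write_detections(res$detections, paths$detections)
  write_lines_csv(res$lines, paths$lines)

  report <- NULL
  if (!is.null(cfg$truth)) {
    truth <- read_truth(cfg$truth)
    report <- evaluate_detections(res$detections, truth)
    paths$report <- file.path(cfg$out_dir, "eval_report.json")
    jsonlite::write_json(list(summary = tidy(report),
                              by_index = report$misses),
                         paths$report, auto_unbox = TRUE, digits = NA)
    readr::write_csv(tidy(report), file.path(cfg$out_dir, "eval_report.csv"))
  }

  if (!is.null(cfg$physio) && isTRUE(cfg$fusion$write_overlays)) {
    physio <- read_physio(cfg$physio)
    ovl_dir <- file.path(cfg$out_dir, "overlays")
    dir.create(ovl_dir, showWarnings = FALSE)
    mano_scale <- color_scale(cfg$fusion$mano_min, cfg$fusion$mano_max)
    imped_scale <- color_scale(cfg$fusion$imped_min, cfg$fusion$imped_max,
                               log = TRUE)
    for (f in seq_along(seq$frames)) {
      det_f <- filter(res$detections, .data$frame == f)
      line_f <- filter(res$lines, .data$frame == f)
      if (nrow(det_f) < 2) next
      ovl <- render_overlay(seq$frames[[f]],
                            new_catheter_line(line_f$row, line_f$col),
                            det_f, physio, seq$timestamps[f],
                            mano_scale = mano_scale,
                            imped_scale = imped_scale,
                            ribbon_width = cfg$fusion$ribbon_width,
                            imped_offset_px = cfg$fusion$imped_offset_px,
                            imped_width = cfg$fusion$imped_width)
      png::writePNG(unclass(ovl), file.path(ovl_dir, sprintf("overlay_%04d.png", f)))
    }
    paths$overlays <- ovl_dir
  }

  log_lines <- c(
    sprintf("fluorocath run %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    sprintf("frames: %s (%d frames, fps %g)", cfg$frames,
            length(seq$frames), cfg$fps),
    sprintf("visible_end: %s  seed: %d", cfg$visible_end, cfg$seed),
    sprintf("templates: spacing %g len %g width %g", cfg$templates$spacing_px,
            cfg$templates$sensor_len_px, cfg$templates$sensor_width_px),
    sprintf("catheter: floor %g slope %g gap %g span %g dev %g",
            cfg$catheter$score_floor, cfg$catheter$max_slope,
            cfg$catheter$gap_max, cfg$catheter$min_span_frac,
            cfg$catheter$dev_thresh_px),
    sprintf("corrected frames: %s",
            paste(res$events$frame[res$events$corrected], collapse = " ") %||% ""),
    sprintf("low-confidence frames: %s",
            paste(res$events$frame[res$events$low_confidence], collapse = " "))
  )
  writeLines(log_lines, paths$log)

  invisible(c(res, list(report = report, paths = paths)))
}

#' Write a phantom dataset to disk in the pipeline's exchange formats
#'
#' Frames as PNG (or one multi-page TIFF), ground truth and physio as CSV.
#'
#' @param ds a `phantom_dataset` from [generate_dataset()].
#' @param out_dir output directory.
#' @param frame_format `"png"` or `"tiff"`.
#' @return List of written paths, invisibly.
#' @export
write_dataset <- function(ds, out_dir, frame_format = c("png", "tiff")) {
  frame_format <- match.arg(frame_format)
  stopifnot(inherits(ds, "phantom_dataset"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fpath <- if (frame_format == "png") file.path(out_dir, "frames")
           else file.path(out_dir, "frames.tiff")
  write_frames(ds$frames, fpath)
  paths <- list(
    frames = fpath,
    truth = write_truth(ds$truth, file.path(out_dir, "truth.csv")),
    physio = write_physio(ds$physio, file.path(out_dir, "physio.csv")))
  invisible(paths)
}
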