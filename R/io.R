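# Readers and writers for the plain formats the pipeline exchanges:
# PNG / multi-page TIFF frames, wide physio CSV, truth/detections/lines CSV,
# YAML run configuration.

as_gray_matrix <- function(x) {
  if (length(dim(x)) == 3) x <- apply(x[, , 1:min(3, dim(x)[3]), drop = FALSE],
                                      c(1, 2), mean)
  matrix(as.numeric(x), nrow(x), ncol(x))
}

#' Read a fluoroscopy frame sequence
#'
#' Accepts either a directory of lexicographically ordered PNG/TIFF frames
#' or a single multi-page TIFF. Frames are returned as grayscale matrices
#' in `[0, 1]`; timestamps come from `fps`.
#'
#' @param path directory or multi-page TIFF file.
#' @param fps frame rate used for timestamps, frames/s.
#' @return A `frame_sequence`: list with `frames`, `timestamps`, `fps`.
#' @export
read_frames <- function(path, fps = 10) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0) abort(sprintf("no PNG/TIFF frames found in %s", path))
    frames <- map(files, function(f) {
      img <- tryCatch(
        if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
        else tiff::readTIFF(f),
        error = function(e) abort(sprintf("cannot read frame %s: %s",
                                          basename(f), conditionMessage(e))))
      as_gray_matrix(img)
    })
  } else if (file.exists(path)) {
    frames <- map(tiff::readTIFF(path, all = TRUE), as_gray_matrix)
  } else abort(sprintf("no such frame source: %s", path))
  shapes <- unique(map(frames, dim))
  if (length(shapes) > 1)
    abort(sprintf("frames have mixed shapes: %s",
                  paste(map(shapes, paste, collapse = "x"), collapse = ", ")))
  structure(list(frames = frames,
                 timestamps = (seq_along(frames) - 1) / fps, fps = fps),
            class = "frame_sequence")
}

#' Write a frame sequence
#'
#' @param frames list of grayscale matrices in `[0, 1]`.
#' @param path output directory (PNG, files `frame_0001.png`, ...) or a
#'   `.tif`/`.tiff` filename (multi-page TIFF).
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(map(frames, clamp, 0, 1), path, bits.per.sample = 16)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(frames))
      png::writePNG(clamp(frames[[i]], 0, 1),
                    file.path(path, sprintf("frame_%04d.png", i)))
  }
  invisible(path)
}

#' Read a synchronized physio CSV
#'
#' Expects a wide CSV: a monotone `time` column (seconds), 36 manometry
#' columns (`mano_01`..`mano_36`, mmHg) and 15 impedance columns
#' (`imp_01`..`imp_15`, Ohm), sampled at about 50 Hz.
#'
#' @param path CSV file.
#' @return A `physio_record`.
#' @export
read_physio <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  mano_cols <- grep("^mano_", names(df), value = TRUE)
  imp_cols <- grep("^imp_", names(df), value = TRUE)
  if (length(mano_cols) != 36)
    abort(sprintf("expected 36 manometry channels, found %d", length(mano_cols)))
  if (length(imp_cols) != 15)
    abort(sprintf("expected 15 impedance channels, found %d", length(imp_cols)))
  if (!"time" %in% names(df)) abort("physio CSV needs a `time` column")
  if (is.unsorted(df$time, strictly = TRUE))
    abort("physio `time` column must be strictly increasing")
  rate <- 1 / median(diff(df$time))
  if (abs(rate - 50) > 0.5)
    warn(sprintf("physio sampling rate %.2f Hz deviates from the nominal 50 Hz", rate))
  structure(list(mano = t(as.matrix(df[mano_cols])),
                 imped = t(as.matrix(df[imp_cols])),
                 rate = rate, t0 = df$time[1], time = df$time),
            class = "physio_record")
}

#' Write a physio record as a wide CSV
#'
#' @param physio a `physio_record`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_physio <- function(physio, path) {
  readr::write_csv(as_tibble(physio), path)
  invisible(path)
}

#' Read / write ground-truth and detection tables
#'
#' Ground truth: `frame,sensor_index,row,col,occluded`. Detections:
#' `frame,sensor_index,row,col,confidence,inferred`. Lines:
#' `frame,row,col`.
#'
#' @param path CSV file.
#' @return A tibble.
#' @export
read_truth <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(frame = "i", sensor_index = "i",
                                          row = "d", col = "d",
                                          occluded = "l"))
}

#' @rdname read_truth
#' @param truth,detections,lines tibbles as produced by the pipeline.
#' @export
write_truth <- function(truth, path) {
  readr::write_csv(truth, path)
  invisible(path)
}

#' @rdname read_truth
#' @export
read_detections <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(frame = "i", sensor_index = "i",
                                          row = "d", col = "d",
                                          confidence = "d", inferred = "l"))
}

#' @rdname read_truth
#' @export
write_detections <- function(detections, path) {
  readr::write_csv(detections, path)
  invisible(path)
}

#' @rdname read_truth
#' @export
write_lines_csv <- function(lines, path) {
  readr::write_csv(lines, path)
  invisible(path)
}

#' Load / save a run configuration
#'
#' YAML configuration with the path and parameter sections the pipeline
#' reads (`preprocess`, `templates`, `catheter`, `sensors`, `fusion`,
#' `visible_end`, `fps`, `seed`). Loading fills defaults for missing
#' entries; `load_config(save_config(cfg))` is the identity.
#'
#' @param path YAML file.
#' @return A `run_config` list.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' @rdname load_config
#' @param cfg a [run_config()].
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}
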