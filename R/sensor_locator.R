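#' Sample a heatmap along the catheter line
#'
#' Bilinearly samples heatmap scores at 1-px arc-length steps along the
#' line, from its top endpoint, producing the 1-D profile in which the
#' individual sensors appear as regularly spaced peaks.
#'
#' @param hm heatmap from [sensor_heatmap()].
#' @param line an accepted `catheter_line`.
#' @return An `arc_profile` tibble: `arc` (px from the line top), `score`,
#'   `row`, `col` (image point of each sample).
#' @export
profile_along_line <- function(hm, line) {
  assert_gray_image(hm, "hm")
  if (is.null(line) || nrow(line) == 0) abort("empty catheter line")
  L <- max(arc_cumulative(line))
  pts <- point_at_arc(line, seq(0, floor(L)))
  structure(tibble(arc = pts$arc, score = bilinear_at(hm, pts$row, pts$col),
                   row = pts$row, col = pts$col),
            class = c("arc_profile", class(tibble())))
}

#' Detect sensor peaks along an arc profile
#'
#' Finds the score-optimal set of profile peaks subject to a minimum mutual
#' separation of `0.6 * spacing_px` (non-maximum suppression as an optimal
#' weighted selection, solved by dynamic programming): among all local
#' maxima scoring at least `peak_floor`, the subset maximizing the total
#' score under the separation constraint is returned, ordered by arc
#' position.
#'
#' @param profile an `arc_profile` from [profile_along_line()].
#' @param spacing_px expected sensor spacing, px.
#' @param peak_floor minimum score for a local maximum to be a candidate.
#' @return Numeric vector of arc positions (attribute `scores` carries the
#'   profile score at each); empty when nothing qualifies.
#' @export
detect_peaks <- function(profile, spacing_px, peak_floor = 0.25) {
  stopifnot(spacing_px > 0)
  s <- profile$score
  n <- length(s)
  if (n < 3) return(structure(numeric(0), scores = numeric(0)))
  is_max <- c(FALSE, s[2:(n - 1)] >= s[1:(n - 2)] & s[2:(n - 1)] >= s[3:n],
              FALSE) & s >= peak_floor
  # collapse plateaus to their center sample
  idx <- which(is_max)
  if (length(idx) > 1) {
    grp <- cumsum(c(1, diff(idx) > 1 | abs(diff(s[idx])) > 1e-12))
    idx <- as.integer(tapply(idx, grp, function(v) round(mean(v))))
  }
  if (length(idx) == 0) return(structure(numeric(0), scores = numeric(0)))
  pos <- profile$arc[idx]; sc <- s[idx]
  keep <- select_peaks_dp(pos, sc, 0.6 * spacing_px)
  structure(pos[keep], scores = sc[keep])
}

# Optimal subset of candidate peaks maximizing total score with pairwise
# separation >= minsep (weighted-interval-scheduling DP; positions sorted).
select_peaks_dp <- function(pos, score, minsep) {
  n <- length(pos)
  if (n <= 1) return(seq_len(n))
  best <- numeric(n + 1)      # best[i+1]: optimum over first i candidates
  take <- logical(n)
  pred <- integer(n)
  for (i in seq_len(n)) {
    p <- which(pos <= pos[i] - minsep)
    pred[i] <- if (length(p)) max(p) else 0L
    with_i <- score[i] + best[pred[i] + 1]
    if (with_i > best[i]) { best[i + 1] <- with_i; take[i] <- TRUE }
    else best[i + 1] <- best[i]
  }
  keep <- integer(0); i <- n
  while (i >= 1) {
    if (take[i]) { keep <- c(i, keep); i <- pred[i] }
    else i <- i - 1
  }
  keep
}

#' Snap peaks to a regular sensor grid, infer occluded sensors, and number
#'
#' Realizes the occluded-sensor inference the task requires: sensors sit at
#' near-regular arc-length intervals, so (1) the local spacing is estimated
#' as the median inter-peak gap (clipped to `spacing_px` +/- 20%), (2) each
#' peak is snapped to its grid slot, (3) interior slots without a supporting
#' peak receive an inferred sensor at the interpolated arc position
#' (`inferred = TRUE`, confidence = the profile score there), and slots
#' beyond the outermost peaks are added only while the profile lends weak
#' support (`extend_floor`), and (4) sensors are numbered consecutively from
#' the visible catheter end — index 1 at the top for `visible_end = "top"`,
#' index 36 at the bottom counting backward for `"bottom"` — capped at 36.
#'
#' @param peaks arc positions from [detect_peaks()].
#' @param line the accepted `catheter_line`.
#' @param spacing_px nominal sensor spacing, px.
#' @param visible_end `"top"` or `"bottom"`.
#' @param profile the `arc_profile` (for confidences at inferred slots).
#' @param n_sensors_total sensors on the catheter (36 clinically).
#' @param extend_floor minimum profile score for extrapolated edge slots.
#' @return A `sensor_set` tibble: `sensor_index`, `row`, `col`, `arc`,
#'   `confidence`, `inferred`; attribute `low_confidence` is `TRUE` when
#'   fewer than 3 peaks supported the grid (numbering unreliable).
#' @export
regularize_and_number <- function(peaks, line, spacing_px,
                                  visible_end = c("top", "bottom"),
                                  profile = NULL,
                                  n_sensors_total = 36,
                                  extend_floor = 0.15) {
  visible_end <- match.arg(visible_end)
  L <- max(arc_cumulative(line))
  low_confidence <- length(peaks) < 3
  score_at <- function(s) {
    if (is.null(profile)) return(NA_real_)
    approx(profile$arc, profile$score, xout = s, rule = 2)$y
  }
  if (length(peaks) == 0) {
    out <- tibble(sensor_index = integer(0), row = numeric(0),
                  col = numeric(0), arc = numeric(0),
                  confidence = numeric(0), inferred = logical(0))
    return(structure(out, class = c("sensor_set", class(tibble())),
                     low_confidence = TRUE))
  }

  gaps <- diff(peaks)
  gaps <- gaps[gaps <= 1.5 * spacing_px]          # skip missing-sensor gaps
  s_hat <- if (length(gaps)) median(gaps) else spacing_px
  s_hat <- clamp(s_hat, 0.8 * spacing_px, 1.2 * spacing_px)

  k <- round((peaks - peaks[1]) / s_hat)          # grid slot of each peak
  offset <- peaks[1] + median(peaks - peaks[1] - k * s_hat)
  k_all <- seq(ceiling((0 - offset) / s_hat), floor((L - offset) / s_hat))
  slot_pos <- offset + k_all * s_hat

  slot_peak <- map_int(slot_pos, function(p) {
    d <- abs(peaks - p)
    i <- which.min(d)
    if (d[i] <= 0.45 * s_hat) i else NA_integer_
  })
  # a peak supports only its nearest slot
  dup <- duplicated(slot_peak, incomparables = NA)
  slot_peak[dup] <- NA_integer_

  supported <- !is.na(slot_peak)
  arc <- ifelse(supported, peaks[slot_peak], slot_pos)
  conf <- ifelse(supported, attr(peaks, "scores")[slot_peak], score_at(slot_pos))
  inferred <- !supported

  # keep interior inferred slots unconditionally; trim weak edge extrapolation
  if (any(supported)) {
    lo <- min(which(supported)); hi <- max(which(supported))
    keep <- supported
    keep[lo:hi] <- TRUE
    if (lo > 1) for (i in (lo - 1):1) {
      if (!is.na(conf[i]) && conf[i] >= extend_floor) keep[i] <- TRUE else break
    }
    if (hi < length(keep)) for (i in (hi + 1):length(keep)) {
      if (!is.na(conf[i]) && conf[i] >= extend_floor) keep[i] <- TRUE else break
    }
    arc <- arc[keep]; conf <- conf[keep]; inferred <- inferred[keep]
  }

  n <- length(arc)
  if (n > n_sensors_total) {      # cap at the physical sensor count
    keep <- if (visible_end == "top") seq_len(n_sensors_total)
            else (n - n_sensors_total + 1):n
    arc <- arc[keep]; conf <- conf[keep]; inferred <- inferred[keep]
    n <- n_sensors_total
  }
  idx <- if (visible_end == "top") seq_len(n)
         else n_sensors_total - n + seq_len(n)
  pts <- point_at_arc(line, arc)
  out <- tibble(sensor_index = as.integer(idx), row = pts$row, col = pts$col,
                arc = arc, confidence = as.numeric(conf), inferred = inferred)
  structure(out, class = c("sensor_set", class(tibble())),
            low_confidence = low_confidence)
}
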