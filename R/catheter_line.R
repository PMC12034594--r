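#' @rdname extract_line
#' @param row,col equal-length numeric vectors (rows strictly increasing).
#' @param quality mean heatmap score along the supported rows.
#' @param supported_rows rows backed by heatmap evidence (the rest are
#'   interpolated/extrapolated).
#' @export
new_catheter_line <- function(row, col, quality = NA_real_,
                              supported_rows = row) {
  stopifnot(length(row) == length(col), !is.unsorted(row, strictly = TRUE))
  structure(tibble(row = as.numeric(row), col = as.numeric(col)),
            class = c("catheter_line", class(tibble())),
            quality = quality, supported_rows = supported_rows)
}

#' Template-match a frame into a score heatmap
#'
#' Normalized cross-correlation (zero-mean, unit-variance — invariant to
#' affine intensity rescaling, the robust choice under varying X-ray
#' exposure) of each template against the image; the combined heatmap is the
#' elementwise maximum over the templates. Scores sit at the template anchor
#' position and lie in `[-1, 1]`; anchors where a template does not fully
#' fit carry the sentinel `-1`, and zero-variance windows score 0.
#'
#' `line_heatmap()` uses the triple-sensor templates of the bank (stage 1:
#' catheter-line detection), `sensor_heatmap()` the single-sensor templates
#' (stage 2: sensor localization).
#'
#' @param image preprocessed grayscale matrix, larger than every template.
#' @param bank a [template_bank()] (or any list of `fluoro_template`s).
#' @return Numeric matrix of scores, same shape as `image`.
#' @export
line_heatmap <- function(image, bank = template_bank()) {
  match_heatmap(image, bank_subset(bank, "triple"))
}

#' @rdname line_heatmap
#' @export
sensor_heatmap <- function(image, bank = template_bank()) {
  match_heatmap(image, bank_subset(bank, "single"))
}

# Per-row candidate columns: local maxima of each row's score profile at or
# above `floor`, keeping the `per_row` best per row; sorted by row.
row_candidates <- function(hm, floor, per_row = 5L) {
  H <- nrow(hm); W <- ncol(hm)
  left <- cbind(hm[, 1], hm[, -W, drop = FALSE])
  right <- cbind(hm[, -1, drop = FALSE], hm[, W])
  is_max <- hm >= left & hm >= right & hm >= floor
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(tibble(row = integer(0), col = integer(0), score = numeric(0)))
  out <- tibble(row = idx[, 1], col = idx[, 2], score = hm[idx]) |>
    arrange(.data$row, dplyr::desc(.data$score)) |>
    mutate(rank = dplyr::row_number(), .by = "row") |>
    filter(.data$rank <= per_row) |>
    select(-"rank") |>
    arrange(.data$row, .data$col)
  out
}

match_heatmap <- function(image, templates) {
  assert_gray_image(image)
  if (length(templates) == 0) abort("empty template list")
  hm <- NULL
  for (t in templates) {
    px <- t$pixels
    if (nrow(px) > nrow(image) || ncol(px) > ncol(image))
      abort(sprintf("image (%dx%d) smaller than template (%dx%d)",
                    nrow(image), ncol(image), nrow(px), ncol(px)))
    h <- if (!is.null(t$row_profile))
      ncc_valid_sep(image, t$row_profile, t$col_profile,
                    sign = t$sign, fill = -1)
    else ncc_valid(image, px, fill = -1)
    hm <- if (is.null(hm)) h else pmax(hm, h)
  }
  hm
}

#' Extract the catheter line from a heatmap
#'
#' Per image row, the candidate columns are the row's score local maxima at
#' or above `score_floor` (up to the five best). The best slope-feasible
#' chain of candidates (column change at most `max_slope` px per row, gaps
#' up to `gap_max` rows) is selected by dynamic programming, scoring each
#' candidate by its margin above the floor minus a small lateral-jump cost
#' (so spurious off-catheter responses do not drag the line). Interior gaps
#' are bridged by linear interpolation and the line is extended to the full
#' frame height with the end slopes (clamped to `max_slope`) so that
#' sensors near the frame border — where the tall triple template cannot be
#' anchored — still lie on the line.
#'
#' @param hm heatmap from [line_heatmap()].
#' @param score_floor minimum NCC score for a row to count as evidence.
#' @param max_slope maximum column change per row, px.
#' @param gap_max largest bridgeable run of evidence-free rows.
#'   [detect_config()] sets it to ten sensor spacings so that a radiopaque
#'   bolus covering several sensors (plus the rows where the tall triple
#'   template cannot anchor) is bridged within the frame.
#' @param min_span_frac minimum fraction of the image height the supported
#'   rows must span; below it the frame is a detection failure.
#' @return A `catheter_line` (tibble `row`, `col`, one point per image row,
#'   with attributes `quality` and `supported_rows`), or `NULL` on detection
#'   failure (caller falls back to history, see [temporal_correct()]).
#' @export
extract_line <- function(hm, score_floor = 0.3, max_slope = 3,
                         gap_max = 120, min_span_frac = 0.5) {
  assert_gray_image(hm, "hm")
  H <- nrow(hm)
  cand <- row_candidates(hm, score_floor, per_row = 5L)
  if (nrow(cand) < 2) return(NULL)
  rows <- cand$row; cols <- cand$col; scores <- cand$score
  n <- length(rows)

  # Best slope-feasible chain (Viterbi over candidates, windowed by gap_max).
  # Each candidate contributes its margin above the floor; lateral movement
  # beyond a plausible catheter drift (drift_slope px/row) is penalized, so
  # short isolated response islands far off course (e.g. the rim of a
  # radiopaque bolus) cannot drag the line, while weak evidence that stays
  # roughly colinear with the chain is still picked up.
  jump_cost <- 0.1
  drift_slope <- 0.3
  gain <- scores - score_floor
  best <- gain; prev <- rep(0L, n)
  for (i in seq_len(n)[-1]) {
    dr <- rows[i] - rows
    feas <- which(dr > 0 & dr <= gap_max & abs(cols - cols[i]) <= max_slope * dr)
    if (length(feas)) {
      excess <- pmax(0, abs(cols[feas] - cols[i]) - drift_slope * dr[feas])
      w <- best[feas] - jump_cost * excess
      k <- feas[which.max(w)]
      if (max(w) > 0) { best[i] <- gain[i] + max(w); prev[i] <- k }
    }
  }
  chain <- integer(0); i <- which.max(best)
  while (i > 0) { chain <- c(i, chain); i <- prev[i] }
  srows <- rows[chain]; scols <- cols[chain]
  if ((max(srows) - min(srows)) < min_span_frac * H) return(NULL)

  full_col <- approx(srows, scols, xout = seq_len(H), rule = 1)$y
  slope_of <- function(r, c) {
    k <- min(length(r), 15)
    if (k < 2) return(0)
    clamp((c[k] - c[1]) / (r[k] - r[1]), -max_slope, max_slope)
  }
  top <- min(srows); bot <- max(srows)
  if (top > 1) {
    sl <- slope_of(head(srows, 15), head(scols, 15))
    full_col[1:(top - 1)] <- full_col[top] - sl * (top - (1:(top - 1)))
  }
  if (bot < H) {
    sl <- slope_of(tail(srows, 15), tail(scols, 15))
    full_col[(bot + 1):H] <- full_col[bot] + sl * (((bot + 1):H) - bot)
  }
  full_col <- clamp(full_col, 1, ncol(hm))
  new_catheter_line(seq_len(H), full_col,
                    quality = mean(hm[cbind(srows, scols)]),
                    supported_rows = srows)
}

# largest `window`-row moving average of a deviation profile
max_windowed_deviation <- function(dev, window) {
  n <- length(dev)
  w <- min(window, n)
  cs <- c(0, cumsum(dev))
  max((cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w)
}

#' Temporally correct a detected catheter line
#'
#' The error-correction rule: keep the catheter lines accepted in the
#' previous three frames; if the current frame's line deviates too much
#' from their per-row average, or the current frame failed detection
#' outright, replace it with that history average. The accepted line is
#' appended to the history (window of 3). Deviation is the largest 25-row
#' moving average of the per-row column deviation: the typical failure is a
#' localized excursion (a stretch of line pulled onto a bolus rim or other
#' artifact), which a whole-line mean would dilute below any usable
#' threshold, while a windowed mean exposes it without reacting to
#' single-row jitter; a frame-wide displacement trips it just the same.
#'
#' @param current a `catheter_line`, or `NULL` for a detection failure.
#' @param hist list of previously accepted `catheter_line`s (most recent
#'   last), length 0–3; start with `list()`.
#' @param dev_thresh_px deviation threshold in pixels.
#' @return List with `line` (accepted `catheter_line`), `hist` (updated
#'   window) and `corrected` (TRUE when the history average replaced the
#'   detection).
#' @export
temporal_correct <- function(current, hist = list(), dev_thresh_px = 25) {
  if (length(hist) == 0) {
    if (is.null(current))
      abort("detection failed on the first frame: no history to fall back on")
    return(list(line = current, hist = list(current), corrected = FALSE))
  }
  avg_col <- rowMeans(do.call(cbind, map(hist, function(l) l$col)))
  ref <- new_catheter_line(hist[[length(hist)]]$row, avg_col,
                           quality = mean(map_dbl(hist, function(l)
                             attr(l, "quality") %||% NA_real_)))
  corrected <- is.null(current) ||
    max_windowed_deviation(abs(current$col - avg_col), 25) > dev_thresh_px
  accepted <- if (corrected) ref else current
  hist <- c(hist, list(accepted))
  if (length(hist) > 3) hist <- hist[(length(hist) - 2):length(hist)]
  list(line = accepted, hist = hist, corrected = corrected)
}
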