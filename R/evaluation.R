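#' The three detection accuracy radii
#'
#' A detection counts as correct within a 5-px radius of the true sensor
#' position at the "exact" level, 10 px at "good" and 30 px at
#' "acceptable".
#'
#' @return Named numeric vector of radii in pixels.
#' @export
accuracy_levels <- function() c(exact = 5, good = 10, acceptable = 30)

#' Match detections to ground truth within a radius
#'
#' One-to-one, radius-tolerant keypoint matching: candidate pairs within
#' `radius_px` are processed in increasing-distance order and each truth
#' point / detection is used at most once; the greedy pairing is then
#' augmented (alternating paths) to the maximum achievable number of
#' matches, so the TP count always equals the optimal bipartite matching
#' within the radius.
#'
#' @param detections tibble with `row`, `col` (optionally `sensor_index`,
#'   `inferred`); inferred sensors count as detections.
#' @param truth tibble with `row`, `col` (optionally `sensor_index`) for the
#'   same frame.
#' @param radius_px matching radius, px.
#' @return List with `tp` (tibble: detection and truth coordinates,
#'   `truth_index`, `det_index` — the truth/detection `sensor_index` if
#'   present — and `distance`), `fp` (unmatched detections) and `fn`
#'   (unmatched truth rows).
#' @export
match_frame <- function(detections, truth, radius_px) {
  nd <- nrow(detections); nt <- nrow(truth)
  det_idx <- if ("sensor_index" %in% names(detections))
    detections$sensor_index else seq_len(nd)
  tru_idx <- if ("sensor_index" %in% names(truth))
    truth$sensor_index else seq_len(nt)
  if (nd == 0 || nt == 0) {
    tp <- tibble(det_row = numeric(0), det_col = numeric(0),
                 truth_row = numeric(0), truth_col = numeric(0),
                 det_index = integer(0), truth_index = integer(0),
                 distance = numeric(0))
    return(list(tp = tp, fp = detections, fn = truth))
  }
  d <- sqrt(outer(detections$row, truth$row, "-")^2 +
            outer(detections$col, truth$col, "-")^2)
  cand <- which(d <= radius_px, arr.ind = TRUE)
  cand <- cand[order(d[cand]), , drop = FALSE]
  used_d <- logical(nd); used_t <- logical(nt)
  match_of <- rep(NA_integer_, nd)   # truth index matched to each detection
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used_d[i] && !used_t[j]) {
      used_d[i] <- TRUE; used_t[j] <- TRUE
      match_of[i] <- j
    }
  }
  # augment to maximum cardinality (Kuhn's alternating paths)
  adj <- lapply(seq_len(nd), function(i) which(d[i, ] <= radius_px))
  owner <- rep(NA_integer_, nt)
  owner[match_of[!is.na(match_of)]] <- which(!is.na(match_of))
  try_augment <- function(i, seen) {
    for (j in adj[[i]]) {
      if (seen[j]) next
      seen[j] <- TRUE
      if (is.na(owner[j]) || Recall(owner[j], seen)) {
        owner[j] <<- i
        match_of[i] <<- j
        return(TRUE)
      }
    }
    FALSE
  }
  for (i in which(is.na(match_of))) try_augment(i, logical(nt))
  pairs <- cbind(which(!is.na(match_of)), match_of[!is.na(match_of)])
  used_d <- !is.na(match_of)
  used_t <- seq_len(nt) %in% match_of
  tp <- tibble(
    det_row = detections$row[pairs[, 1]], det_col = detections$col[pairs[, 1]],
    truth_row = truth$row[pairs[, 2]], truth_col = truth$col[pairs[, 2]],
    det_index = as.integer(det_idx[pairs[, 1]]),
    truth_index = as.integer(tru_idx[pairs[, 2]]),
    distance = d[pairs]
  )
  list(tp = tp, fp = detections[!used_d, , drop = FALSE],
       fn = truth[!used_t, , drop = FALSE])
}

prf <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  r <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f <- if (!is.na(p) && !is.na(r) && p + r > 0) 2 * p * r / (p + r)
       else if (isTRUE(p == 0) || isTRUE(r == 0)) 0 else NA_real_
  c(precision = p, recall = r, f1 = f)
}

#' Score detections against ground truth at the three accuracy levels
#'
#' Matches every frame at each accuracy radius, aggregates TP/FP/FN per
#' sequence into precision/recall/F1, then averages across sequences with
#' the standard deviation (the per-patient reporting convention). Per-index
#' distance distributions are collected from the matches at the
#' "acceptable" radius.
#'
#' @param detections tibble with `frame`, `row`, `col` (and optionally
#'   `sequence`, `sensor_index`, `inferred`).
#' @param truth tibble with `frame`, `row`, `col` (and optionally
#'   `sequence`, `sensor_index`).
#' @param levels named radii vector, see [accuracy_levels()].
#' @return An `eval_report`: list with `summary` (per level: mean +/- sd
#'   precision/recall/F1 and pooled TP/FP/FN counts), `per_sequence`,
#'   `distances` (per truth sensor index, at the acceptable radius) and
#'   `misses` (per-index FN counts). Frames with zero detections and zero
#'   truth yield NA metrics (flagged, not silently zero).
#' @export
evaluate_detections <- function(detections, truth, levels = accuracy_levels()) {
  stopifnot(length(levels) >= 1, !is.null(names(levels)))
  if (!"sequence" %in% names(detections)) detections$sequence <- 1L
  if (!"sequence" %in% names(truth)) truth$sequence <- 1L
  if (nrow(truth) == 0 && nrow(detections) == 0)
    warn("no detections and no truth: metrics are undefined")

  frames <- distinct(bind_rows(select(detections, "sequence", "frame"),
                               select(truth, "sequence", "frame")))
  if (nrow(frames) == 0) {
    empty_sum <- tibble(level = names(levels), radius_px = unname(levels),
                        precision = NA_real_, recall = NA_real_,
                        f1 = NA_real_, precision_sd = NA_real_,
                        recall_sd = NA_real_, f1_sd = NA_real_,
                        tp = 0L, fp = 0L, fn = 0L, n_sequences = 0L)
    return(structure(list(summary = empty_sum, per_sequence = empty_sum[0, ],
                          per_frame = tibble(), distances = tibble(),
                          misses = tibble(), levels = levels),
                     class = "eval_report"))
  }
  acc_name <- names(levels)[which.max(levels)]
  counts <- list(); dists <- list()
  for (i in seq_len(nrow(frames))) {
    sq <- frames$sequence[i]; fr <- frames$frame[i]
    det_f <- filter(detections, .data$sequence == sq, .data$frame == fr)
    tru_f <- filter(truth, .data$sequence == sq, .data$frame == fr)
    for (lv in names(levels)) {
      m <- match_frame(det_f, tru_f, levels[[lv]])
      counts[[length(counts) + 1]] <- tibble(
        sequence = sq, frame = fr, level = lv, radius_px = levels[[lv]],
        tp = nrow(m$tp), fp = nrow(m$fp), fn = nrow(m$fn))
      if (lv == acc_name) {
        dists[[length(dists) + 1]] <- tibble(
          sequence = sq, frame = fr,
          sensor_index = m$tp$truth_index, distance = m$tp$distance)
        if (nrow(m$fn) > 0 && "sensor_index" %in% names(m$fn))
          dists[[length(dists) + 1]] <- tibble(
            sequence = sq, frame = fr,
            sensor_index = m$fn$sensor_index, distance = NA_real_)
      }
    }
  }
  counts <- list_rbind(counts)
  dists <- if (length(dists)) list_rbind(dists) else
    tibble(sequence = integer(0), frame = integer(0),
           sensor_index = integer(0), distance = numeric(0))

  per_sequence <- counts |>
    summarise(tp = sum(.data$tp), fp = sum(.data$fp), fn = sum(.data$fn),
              .by = c("sequence", "level", "radius_px")) |>
    rowwise() |>
    mutate(metrics = list(prf(.data$tp, .data$fp, .data$fn))) |>
    ungroup() |>
    tidyr::unnest_wider("metrics")

  summary <- per_sequence |>
    summarise(precision_sd = sd(.data$precision), recall_sd = sd(.data$recall),
              f1_sd = sd(.data$f1),
              precision = mean(.data$precision), recall = mean(.data$recall),
              f1 = mean(.data$f1),
              tp = sum(.data$tp), fp = sum(.data$fp), fn = sum(.data$fn),
              n_sequences = n(),
              .by = c("level", "radius_px")) |>
    select("level", "radius_px", "precision", "recall", "f1",
           "precision_sd", "recall_sd", "f1_sd", "tp", "fp", "fn",
           "n_sequences") |>
    arrange(.data$radius_px)

  misses <- dists |>
    summarise(n_matched = sum(!is.na(.data$distance)),
              n_missed = sum(is.na(.data$distance)),
              median_distance = median(.data$distance, na.rm = TRUE),
              .by = "sensor_index") |>
    arrange(.data$sensor_index)

  structure(list(summary = summary, per_sequence = per_sequence,
                 per_frame = counts, distances = filter(dists, !is.na(.data$distance)),
                 misses = misses, levels = levels),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  print(as.data.frame(x$summary |>
    mutate(across(c("precision", "recall", "f1"), ~ round(.x, 4)))),
    row.names = FALSE)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an evaluation report
#'
#' One row per accuracy level with mean +/- sd precision, recall and F1 and
#' pooled counts.
#'
#' @param x an `eval_report`.
#' @param ... unused.
#' @export
tidy.eval_report <- function(x, ...) x$summary

#' One-row summary of an evaluation report (the "acceptable" level)
#'
#' @param x an `eval_report`.
#' @param ... unused.
#' @export
glance.eval_report <- function(x, ...) {
  acc <- x$summary |> filter(.data$radius_px == max(.data$radius_px))
  tibble(precision = acc$precision, recall = acc$recall, f1 = acc$f1,
         tp = acc$tp, fp = acc$fp, fn = acc$fn,
         n_sequences = acc$n_sequences,
         n_frames = length(unique(x$per_frame$frame)))
}

#' Per-sensor-index distance distributions
#'
#' Distances of true-positive matches (at the acceptable radius) grouped by
#' the truth sensor index, top to bottom, plus per-index miss counts —
#' the per-sensor error profile along the catheter.
#'
#' @param report an `eval_report`.
#' @return List with `distances` (tibble `sensor_index`, `distance`) and
#'   `by_index` (per-index match/miss counts and median distance).
#' @export
distance_by_sensor_index <- function(report) {
  stopifnot(inherits(report, "eval_report"))
  list(distances = report$distances |> select("sensor_index", "distance"),
       by_index = report$misses)
}

#' Noise-robustness study on phantom data
#'
#' Renders a clean phantom sequence, then — per named noise level — adds
#' zero-mean Gaussian noise to the acquired images (emulating noise added
#' after acquisition), runs the full two-stage detection pipeline and
#' scores it against the exact phantom truth.
#'
#' @param spec a [phantom_spec()] (its own `noise_level` should be
#'   `"none"`; the study adds noise on top of the clean render).
#' @param levels character vector of named noise levels to test.
#' @param config detection parameters, see [detect_config()].
#' @return A `noise_study`: list of per-level `eval_report`s plus a tidy
#'   `summary` tibble (`noise_level` x accuracy level).
#' @export
noise_study <- function(spec, levels = c("none", "little", "medium", "most"),
                        config = detect_config(spec)) {
  ds <- generate_dataset(spec)
  reports <- list()
  for (lv in levels) {
    sig <- noise_sigma_for(lv)
    frames <- if (sig == 0) ds$frames else
      imap(ds$frames, function(f, i)
        clamp(f + with_seed(child_seed(spec$seed + 17, i),
                            matrix(rnorm(length(f), 0, sig), nrow(f))), 0, 1))
    det <- detect_sequence(frames, config)
    reports[[lv]] <- evaluate_detections(det$detections, ds$truth)
  }
  summary <- imap(reports, function(r, lv)
    mutate(r$summary, noise_level = lv, .before = 1)) |> list_rbind()
  structure(list(reports = reports, summary = summary,
                 levels = levels, spec = spec),
            class = "noise_study")
}

#' @export
print.noise_study <- function(x, ...) {
  cat("<noise_study>\n")
  print(as.data.frame(x$summary |>
    select("noise_level", "level", "precision", "recall", "f1") |>
    mutate(across(where(is.numeric), ~ round(.x, 4)))), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.noise_study <- function(x, ...) x$summary
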