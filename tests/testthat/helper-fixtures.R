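# Shared fixtures, built lazily once per test run and cached in-session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- maker()
  .fixtures[[name]]
}

# compact phantom geometry for fast unit tests
small_spec <- function(...) {
  args <- utils::modifyList(
    list(image_size = c(256, 256), n_frames = 3, spacing_px = 12,
         sensor_len_px = 8, sensor_width_px = 4,
         curve_amplitude_px = 20, n_visible = 18, seed = 5),
    list(...))
  do.call(phantom_spec, args)
}

small_dataset <- function() fixture("small_ds", function() {
  generate_dataset(small_spec())
})

small_detection <- function() fixture("small_det", function() {
  ds <- small_dataset()
  detect_sequence(ds$frames, detect_config(ds$spec))
})

# brute-force maximum bipartite matching size within a radius (oracle for
# the greedy matcher on small instances)
oracle_max_matching <- function(det, tru, radius) {
  nd <- nrow(det); nt <- nrow(tru)
  if (nd == 0 || nt == 0) return(0L)
  d <- sqrt(outer(det$row, tru$row, "-")^2 + outer(det$col, tru$col, "-")^2)
  ok <- d <= radius
  best <- 0L
  recurse <- function(i, used, count) {
    if (count + (nd - i + 1) <= best) return()
    if (i > nd) { best <<- max(best, count); return() }
    for (j in which(ok[i, ] & !used)) {
      used[j] <- TRUE
      recurse(i + 1, used, count + 1L)
      used[j] <- FALSE
    }
    recurse(i + 1, used, count)
  }
  recurse(1L, rep(FALSE, nt), 0L)
  best
}

# exhaustive best-scoring peak subset under a separation constraint (oracle
# for detect_peaks on profiles with few bumps)
oracle_best_subset <- function(pos, score, minsep) {
  n <- length(pos)
  best <- 0
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(sel) > 1 && min(diff(pos[sel])) < minsep) next
    best <- max(best, sum(score[sel]))
  }
  best
}

# synthetic arc profile with Gaussian bumps at given positions
bump_profile <- function(length_px, centers, heights = 0.8, width = 3) {
  arc <- seq(0, length_px)
  heights <- rep_len(heights, length(centers))
  score <- rep(0, length(arc))
  for (k in seq_along(centers))
    score <- score + heights[k] * exp(-(arc - centers[k])^2 / (2 * width^2))
  structure(tibble::tibble(arc = arc, score = score,
                           row = arc + 1, col = rep(50, length(arc))),
            class = c("arc_profile", class(tibble::tibble())))
}
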