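test_that("the accuracy radii are ordered exact < good < acceptable", {
  lv <- accuracy_levels()
  expect_equal(unname(lv), c(5, 10, 30))
  expect_true(all(diff(lv) > 0))
})

test_that("identical detections and truth match perfectly at every radius", {
  tr <- tibble::tibble(row = c(10, 50, 90), col = c(20, 22, 24),
                       sensor_index = 1:3)
  for (r in accuracy_levels()) {
    m <- match_frame(tr, tr, r)
    expect_equal(nrow(m$tp), 3)
    expect_equal(nrow(m$fp), 0)
    expect_equal(nrow(m$fn), 0)
    expect_true(all(m$tp$distance == 0))
  }
})

test_that("a 7-px offset straddles the exact and good thresholds", {
  tr <- tibble::tibble(row = 50, col = 50, sensor_index = 1L)
  det <- tibble::tibble(row = 50, col = 57, sensor_index = 1L)
  m5 <- match_frame(det, tr, 5)
  expect_equal(c(nrow(m5$tp), nrow(m5$fp), nrow(m5$fn)), c(0, 1, 1))
  for (r in c(10, 30)) {
    m <- match_frame(det, tr, r)
    expect_equal(c(nrow(m$tp), nrow(m$fp), nrow(m$fn)), c(1, 0, 0))
  }
})

test_that("greedy matching equals brute-force optimum on small instances", {
  set.seed(123)
  for (rep in 1:60) {
    nd <- sample(0:6, 1); nt <- sample(0:6, 1)
    det <- tibble::tibble(row = runif(nd, 0, 60), col = runif(nd, 0, 60))
    tru <- tibble::tibble(row = runif(nt, 0, 60), col = runif(nt, 0, 60))
    m <- match_frame(det, tru, 15)
    expect_equal(nrow(m$tp), oracle_max_matching(det, tru, 15))
    # conservation in every frame
    expect_equal(nrow(m$tp) + nrow(m$fn), nt)
    expect_equal(nrow(m$tp) + nrow(m$fp), nd)
  }
})

test_that("precision, recall and F1 follow their formulas", {
  # one TP, one FP, one FN -> all metrics 0.5
  tr <- tibble::tibble(frame = 1L, row = c(10, 200), col = c(10, 200),
                       sensor_index = 1:2)
  det <- tibble::tibble(frame = 1L, row = c(10, 400), col = c(10, 400),
                        sensor_index = 1:2)
  rep1 <- evaluate_detections(det, tr, levels = c(acceptable = 30))
  expect_equal(rep1$summary$precision, 0.5)
  expect_equal(rep1$summary$recall, 0.5)
  expect_equal(rep1$summary$f1, 0.5)

  # TP=85, FP=15, FN=12
  grid <- expand.grid(row = seq(0, 900, by = 100), col = seq(0, 900, by = 100))
  tru97 <- tibble::tibble(frame = 1L, row = grid$row[1:97], col = grid$col[1:97])
  det100 <- tibble::tibble(frame = 1L,
                           row = c(grid$row[1:85], seq_len(15) * 7 + 5000),
                           col = c(grid$col[1:85], rep(5000, 15)))
  rep2 <- evaluate_detections(det100, tru97, levels = c(acceptable = 30))
  expect_equal(rep2$summary$precision, 0.85)
  expect_equal(rep2$summary$recall, 85 / 97, tolerance = 1e-9)
  expect_equal(rep2$summary$f1, 2 * 0.85 * (85 / 97) / (0.85 + 85 / 97),
               tolerance = 1e-9)
  expect_equal(rep2$summary$f1, 0.863, tolerance = 1e-3)
})

test_that("reports conserve counts and are monotone in the radius", {
  ds <- small_dataset()
  res <- small_detection()
  rep <- evaluate_detections(res$detections, ds$truth)
  s <- rep$summary
  n_truth <- nrow(ds$truth)
  n_det <- nrow(res$detections)
  for (i in seq_len(nrow(s))) {
    expect_equal(s$tp[i] + s$fn[i], n_truth)
    expect_equal(s$tp[i] + s$fp[i], n_det)
  }
  s <- dplyr::arrange(s, radius_px)
  expect_true(all(diff(s$tp) >= 0))
  expect_true(all(diff(s$f1) >= -1e-12))
  # tidy/glance accessors
  expect_identical(tidy(rep), rep$summary)
  g <- glance(rep)
  expect_equal(g$f1, s$f1[which.max(s$radius_px)])
})

test_that("degenerate empty input is flagged, not silently zero", {
  empty <- tibble::tibble(frame = integer(0), row = numeric(0),
                          col = numeric(0))
  expect_warning(rep <- evaluate_detections(empty, empty), "undefined")
  expect_true(all(is.na(rep$summary$precision)) || nrow(rep$summary) == 0)
})

test_that("per-index distances localize a parked bolus", {
  spec <- small_spec(n_frames = 4, bolus_enabled = TRUE,
                     bolus_speed_px_per_frame = 0, bolus_radius_px = 30,
                     bolus_start_frac = 0.55)
  ds <- generate_dataset(spec)
  res <- detect_sequence(ds$frames, detect_config(spec))
  rep <- evaluate_detections(res$detections, ds$truth)
  d <- distance_by_sensor_index(rep)
  occ_idx <- unique(dplyr::filter(ds$truth, occluded)$sensor_index)
  expect_gt(length(occ_idx), 0)
  by_idx <- d$distances |>
    dplyr::summarise(med = median(distance), .by = sensor_index)
  med_occ <- median(dplyr::filter(by_idx, sensor_index %in% occ_idx)$med)
  med_clean <- median(dplyr::filter(by_idx, !sensor_index %in% occ_idx)$med)
  expect_gt(med_occ, med_clean)
  # perfect detections give degenerate zero distributions
  tr <- dplyr::mutate(ds$truth, sensor_index = as.integer(sensor_index))
  rep0 <- evaluate_detections(tr, tr)
  expect_true(all(distance_by_sensor_index(rep0)$distances$distance == 0))
})

test_that("the noise study reports four levels with a no-op baseline", {
  spec <- small_spec(n_frames = 2)
  st <- noise_study(spec, levels = c("none", "little"))
  expect_length(st$reports, 2)
  base <- detect_sequence(generate_dataset(spec)$frames, detect_config(spec))
  rep_base <- evaluate_detections(base$detections, generate_dataset(spec)$truth)
  expect_equal(st$reports$none$summary$f1, rep_base$summary$f1)
})
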