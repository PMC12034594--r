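test_that("profiles along an axis-aligned line reproduce the column", {
  hm <- matrix(rep(seq(0, 1, length.out = 100), 60), 100, 60)
  line <- new_catheter_line(1:100, rep(25, 100))
  prof <- profile_along_line(hm, line)
  expect_equal(nrow(prof), 100)          # arc length +/- 1
  expect_equal(prof$score, hm[, 25], tolerance = 1e-9)
  expect_error(profile_along_line(hm, NULL), "empty")
})

test_that("profile peaks map back to 2-D heatmap maxima", {
  ds <- small_dataset()
  cfg <- detect_config(ds$spec)
  img <- enhance(ds$frames[[1]], cfg$preprocess)
  shm <- sensor_heatmap(img, cfg$bank)
  line <- extract_line(line_heatmap(img, cfg$bank), gap_max = cfg$gap_max)
  prof <- profile_along_line(shm, line)
  pk <- detect_peaks(prof, cfg$spacing_px)
  expect_gt(length(pk), 10)
  tr <- dplyr::filter(ds$truth, frame == 1)
  pts <- prof[match(round(pk), round(prof$arc)), ]
  for (i in seq_len(nrow(pts))) {
    d <- sqrt((tr$row - pts$row[i])^2 + (tr$col - pts$col[i])^2)
    expect_lte(min(d), 3)
  }
})

test_that("detect_peaks finds one peak per bump within 2 px", {
  centers <- seq(38, 38 * 6, by = 38)
  prof <- bump_profile(300, centers)
  pk <- detect_peaks(prof, 38)
  expect_length(pk, 6)
  expect_true(all(abs(pk - centers) <= 2))
  # flat profile: nothing
  expect_length(detect_peaks(bump_profile(300, numeric(0)), 38), 0)
})

test_that("non-maximum suppression keeps the higher of two close bumps", {
  prof <- bump_profile(120, c(50, 60), heights = c(0.5, 0.9))
  pk <- detect_peaks(prof, 38)           # min separation 22.8 px
  expect_length(pk, 1)
  expect_lt(abs(pk - 60), 3)
})

test_that("peak selection matches the exhaustive subset oracle", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(3:8, 1)
    pos <- sort(runif(n, 0, 260))
    prof <- bump_profile(300, pos, heights = runif(n, 0.3, 1))
    pk <- detect_peaks(prof, 38, peak_floor = 0.1)
    sc <- attr(pk, "scores")
    # candidate local maxima the detector saw
    cand_pk <- detect_peaks(prof, 0.1, peak_floor = 0.1)  # tiny sep: all maxima
    best <- oracle_best_subset(cand_pk, attr(cand_pk, "scores"), 0.6 * 38)
    expect_equal(sum(sc), best, tolerance = 1e-6)
  }
})

test_that("missing interior sensors are inferred on the regular grid", {
  line <- new_catheter_line(1:240, rep(60, 240))
  peaks <- structure(c(38, 76, 114, 190), scores = c(0.8, 0.7, 0.8, 0.75))
  sens <- regularize_and_number(peaks, line, 38, "top")
  expect_equal(nrow(sens), 5)
  expect_equal(sens$sensor_index, 1:5)
  inf <- dplyr::filter(sens, inferred)
  expect_equal(nrow(inf), 1)
  expect_lt(abs(inf$arc - 152), 4)
  expect_true(all(diff(sens$arc) >= 0.8 * 38 & diff(sens$arc) <= 1.2 * 38))
})

test_that("clean phantoms need no inferred sensors and number from the top", {
  ds <- small_dataset()
  det <- small_detection()$detections
  d1 <- dplyr::filter(det, frame == 1)
  expect_equal(sum(d1$inferred), 0)
  expect_equal(d1$sensor_index[which.min(d1$arc)], 1L)
  expect_lte(nrow(d1), 36)
  # spacing invariant on the emitted set
  gaps <- diff(sort(d1$arc))
  expect_true(all(gaps >= 0.8 * ds$spec$spacing_px &
                    gaps <= 1.2 * ds$spec$spacing_px))
})

test_that("bottom-visible sequences number backward from 36", {
  spec <- small_spec(visible_end = "bottom", n_frames = 1)
  ds <- generate_dataset(spec)
  res <- detect_sequence(ds$frames, detect_config(spec))
  d1 <- res$detections
  expect_equal(d1$sensor_index[which.max(d1$arc)], 36L)
  m <- match_frame(d1, dplyr::filter(ds$truth, frame == 1), 10)
  expect_true(all(m$tp$det_index == m$tp$truth_index))
})

test_that("fewer than three peaks flags numbering as unreliable", {
  line <- new_catheter_line(1:240, rep(60, 240))
  peaks <- structure(c(76, 114), scores = c(0.8, 0.7))
  sens <- regularize_and_number(peaks, line, 38, "top")
  expect_true(attr(sens, "low_confidence"))
  expect_gt(nrow(sens), 0)               # sensors still emitted
})
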