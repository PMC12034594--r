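test_that("heatmaps handle degenerate and undersized inputs", {
  bank <- template_bank(large = list(len = 9, width = 4),
                        small = list(len = 7, width = 3), spacing_px = 12)
  const <- matrix(0.5, 64, 64)
  hm <- line_heatmap(const, bank)
  valid <- hm[hm > -1]
  expect_true(all(valid == 0))            # zero-variance convention
  expect_error(line_heatmap(matrix(0.5, 10, 10), bank), "smaller")
})

test_that("the combined heatmap is the elementwise template maximum", {
  ds <- small_dataset()
  img <- enhance(ds$frames[[1]], preprocess_params())
  bank <- detect_config(ds$spec)$bank
  combined <- line_heatmap(img, bank)
  h1 <- line_heatmap(img, bank["triple_large"])
  h2 <- line_heatmap(img, bank["triple_small"])
  expect_equal(combined, pmax(h1, h2))
})

test_that("heatmap scores are invariant to affine intensity rescaling", {
  ds <- small_dataset()
  img <- enhance(ds$frames[[1]], preprocess_params())
  bank <- detect_config(ds$spec)$bank["triple_large"]
  h1 <- line_heatmap(img, bank)
  h2 <- line_heatmap(0.4 * img + 0.2, bank)
  expect_lt(max(abs(h1 - h2)), 1e-6)
})

test_that("a single bright column yields a straight line there", {
  hm <- matrix(-0.2, 120, 80)
  hm[, 37] <- 0.9
  line <- extract_line(hm)
  expect_s3_class(line, "catheter_line")
  expect_equal(nrow(line), 120)
  expect_true(all(line$col == 37))
})

test_that("scores below the floor give a detection failure", {
  hm <- matrix(0.1, 120, 80)
  expect_null(extract_line(hm, score_floor = 0.3))
})

test_that("the extracted line tracks the phantom catheter closely", {
  ds <- small_dataset()
  cfg <- detect_config(ds$spec)
  img <- enhance(ds$frames[[1]], cfg$preprocess)
  line <- extract_line(line_heatmap(img, cfg$bank), gap_max = cfg$gap_max)
  path <- generate_catheter_path(ds$spec, 1)
  expect_lte(mean(abs(line$col - path$col)), 3)
  # invariants: one point per row, slope-bounded
  expect_equal(line$row, seq_len(256))
  expect_true(all(abs(diff(line$col)) <= 3 + 1e-9))
})

test_that("temporal correction accepts consistent lines unchanged", {
  l <- new_catheter_line(1:100, rep(40, 100))
  hist <- list(l, l, l)
  out <- temporal_correct(l, hist, dev_thresh_px = 25)
  expect_false(out$corrected)
  expect_equal(out$line$col, l$col)
  expect_length(out$hist, 3)
})

test_that("temporal correction replaces displaced or failed detections", {
  l <- new_catheter_line(1:100, rep(40, 100))
  hist <- list(l, l, l)
  displaced <- new_catheter_line(1:100, rep(140, 100))
  out <- temporal_correct(displaced, hist, dev_thresh_px = 30)
  expect_true(out$corrected)
  expect_equal(out$line$col, l$col)
  # detection failure falls back to the history average
  out2 <- temporal_correct(NULL, hist)
  expect_true(out2$corrected)
  expect_equal(out2$line$col, l$col)
  # window stays at three
  expect_length(out2$hist, 3)
})

test_that("a failure on the very first frame is unrecoverable", {
  expect_error(temporal_correct(NULL, list()), "first frame")
})

test_that("a fully occluded frame between clean frames stays on course", {
  spec <- small_spec(n_frames = 5)
  ds <- generate_dataset(spec)
  cfg <- detect_config(spec)
  frames <- ds$frames
  frames[[4]] <- matrix(0.05, 256, 256)    # bolus blanks the whole frame
  res <- detect_sequence(frames, cfg)
  expect_true(res$events$corrected[4])
  path <- generate_catheter_path(spec, 4)
  l4 <- dplyr::filter(res$lines, frame == 4)
  expect_lte(sqrt(mean((l4$col - path$col)^2)), 10)
})
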