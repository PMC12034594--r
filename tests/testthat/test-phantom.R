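test_that("phantom_spec validates geometry and rates", {
  expect_error(phantom_spec(fps = 20), "fps")
  expect_error(phantom_spec(spacing_px = 10, sensor_len_px = 12), "overlap")
  expect_error(phantom_spec(n_visible = 40), "n_visible")
  spec <- phantom_spec()
  expect_gt(spec$spacing_px, spec$sensor_len_px)
  expect_true(spec$n_frames >= 40 && spec$n_frames <= 180)
})

test_that("named noise levels map to fixed sigmas on the 8-bit scale", {
  expect_equal(noise_sigma_for("none"), 0)
  expect_equal(noise_sigma_for("most"), 50 / 255)
  expect_lt(noise_sigma_for("little"), noise_sigma_for("medium"))
})

test_that("catheter path is smooth, bounded, and drifts slowly", {
  spec <- small_spec(curve_amplitude_px = 80)
  p0 <- generate_catheter_path(spec, 1)
  p1 <- generate_catheter_path(spec, 2)
  expect_equal(p0$row, seq_len(256))
  expect_lte(max(abs(p0$col - 128)), 80 + spec$drift_amplitude_px + 1)
  # frame-to-frame displacement of any point is slow anatomical drift
  expect_lte(max(abs(p1$col - p0$col)), 3)
  # zero amplitude (and zero drift): a vertical straight line
  spec0 <- small_spec(curve_amplitude_px = 0, drift_amplitude_px = 0)
  v <- generate_catheter_path(spec0, 1)
  expect_equal(diff(range(v$col)), 0)
  # determinism
  expect_identical(generate_catheter_path(spec, 2), p1)
})

test_that("rendered ground truth respects spacing and the sensor count", {
  ds <- small_dataset()
  spec <- ds$spec
  for (f in unique(ds$truth$frame)) {
    tr <- dplyr::filter(ds$truth, frame == f)
    expect_equal(nrow(tr), spec$n_visible)
    expect_identical(tr$sensor_index, seq_len(nrow(tr)))
    gaps <- sqrt(diff(tr$row)^2 + diff(tr$col)^2)
    expect_true(all(gaps >= 0.9 * spec$spacing_px &
                      gaps <= 1.1 * spec$spacing_px))
  }
})

test_that("sensor centers are local intensity minima along the catheter", {
  spec <- small_spec()
  path <- generate_catheter_path(spec, 1)
  fr <- render_frame(spec, path, 1)
  for (i in seq_len(nrow(fr$truth))) {
    r <- round(fr$truth$row[i]); c <- round(fr$truth$col[i])
    rr <- pmin(pmax(r + (-4:4), 1), 256)
    along <- fr$image[cbind(rr, round(approx(path$row, path$col,
                                             xout = rr)$y))]
    expect_lte(fr$image[r, c], min(along) + 0.02)
  }
})

test_that("noise changes pixels but never the ground truth", {
  spec_a <- small_spec(noise_level = "none")
  spec_b <- small_spec(noise_level = "most")
  fa <- render_frame(spec_a, generate_catheter_path(spec_a, 1), 1)
  fb <- render_frame(spec_b, generate_catheter_path(spec_b, 1), 1)
  expect_identical(fa$truth, fb$truth)
  expect_gt(mean(abs(fa$image - fb$image)), 0.01)
})

test_that("a requested number of visible sensors is rendered when it fits", {
  spec <- phantom_spec(image_size = c(1024, 1024), n_frames = 1,
                      spacing_px = 33, sensor_len_px = 24, n_visible = 30)
  fr <- render_frame(spec, generate_catheter_path(spec, 1), 1)
  expect_equal(nrow(fr$truth), 30)
})

test_that("impossible sensor geometry is rejected with a sizing error", {
  spec <- small_spec()
  spec$sensor_len_px <- 400
  expect_error(render_frame(spec, generate_catheter_path(small_spec(), 1), 1),
               "fit")
})

test_that("physio record has the right shape and a propagating wave", {
  spec <- small_spec(n_frames = 40, fps = 10)   # 4 s
  ph <- generate_physio(spec)
  expect_equal(dim(ph$mano), c(36, 200))        # 4 s x 50 Hz
  expect_equal(dim(ph$imped), c(15, 200))
  expect_true(all(is.finite(ph$mano)), all(is.finite(ph$imped)))
  peaks <- apply(ph$mano, 1, which.max)
  expect_true(all(diff(peaks) > 0))             # wave propagates 1 -> 36
  drop_t <- apply(ph$imped, 1, which.min)
  expect_true(all(diff(drop_t) > 0))
  expect_identical(generate_physio(spec), ph)   # determinism
})

test_that("datasets are bit-identical under the same seed and share a clock", {
  spec <- small_spec(n_frames = 2)
  a <- generate_dataset(spec)
  b <- generate_dataset(spec)
  expect_identical(a$frames, b$frames)
  expect_identical(a$truth, b$truth)
  expect_identical(a$physio, b$physio)
  expect_equal(a$timestamps, c(0, 0.1))
  c <- generate_dataset(small_spec(n_frames = 2, seed = 99))
  expect_false(identical(a$frames, c$frames))
})

test_that("occluded sensors lie inside the rendered bolus footprint", {
  spec <- small_spec(n_frames = 2, bolus_enabled = TRUE,
                     bolus_radius_px = 3 * 12)
  path <- generate_catheter_path(spec, 1)
  fr <- render_frame(spec, path, 1)
  occ <- dplyr::filter(fr$truth, occluded)
  expect_gt(nrow(occ), 0)
  # the image at an occluded center is saturated to the bolus core value
  for (i in seq_len(nrow(occ)))
    expect_lt(fr$image[round(occ$row[i]), round(occ$col[i])], 0.1)
})
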