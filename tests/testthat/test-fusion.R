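test_that("frame-to-sample synchronization rounds, clips and validates", {
  expect_equal(sync_sample_index(0, 50), 0L)
  expect_equal(sync_sample_index(1.0, 50), 50L)
  expect_equal(sync_sample_index(0.503, 50), 25L)
  expect_warning(idx <- sync_sample_index(10, 50, n_samples = 200), "last")
  expect_equal(idx, 199L)
  expect_error(sync_sample_index(-0.1, 50), "non-negative")
})

test_that("impedance channels span every second sensor from the fourth", {
  expect_equal(unname(impedance_span(1)), c(4L, 6L))
  expect_equal(unname(impedance_span(15)), c(32L, 34L))
  spans <- t(sapply(1:15, impedance_span))
  expect_equal(spans[, 1], seq(4L, 32L, by = 2L))
  expect_equal(spans[, 2] - spans[, 1], rep(2L, 15))
  expect_error(impedance_span(0), "1..15")
  expect_error(impedance_span(16), "1..15")
})

test_that("color scales clamp and map monotonically on the ramp", {
  sc <- color_scale(0, 100)
  expect_identical(scale_colors(sc, -5), scale_colors(sc, 0))
  expect_identical(scale_colors(sc, 500), scale_colors(sc, 100))
  expect_identical(scale_colors(sc, 0), "#0000FF")
  expect_identical(scale_colors(sc, 100), "#FF0000")
  expect_error(color_scale(10, 10), "below")
})

test_that("interpolation along the catheter is piecewise linear", {
  sens <- tibble::tibble(arc = c(0, 38, 76), row = 1:3, col = 1:3)
  out <- interpolate_along_catheter(sens, c(0, 38, 76))
  expect_equal(out$value, out$arc)               # identity profile
  mid <- interpolate_along_catheter(sens[1:2, ], c(0, 100))
  expect_equal(mid$value[mid$arc == 19], 50)
  flat <- interpolate_along_catheter(sens, c(7, 7, 7))
  expect_true(all(flat$value == 7))
  expect_equal(range(out$arc), c(0, 76))         # no extrapolation
  expect_error(interpolate_along_catheter(sens, c(1, NA, NA)), "at least 2")
})

test_that("overlays only paint the ribbons and color centers exactly", {
  ds <- small_dataset()
  res <- small_detection()
  d1 <- dplyr::filter(res$detections, frame == 1)
  l1 <- dplyr::filter(res$lines, frame == 1)
  line <- new_catheter_line(l1$row, l1$col)
  ovl <- render_overlay(ds$frames[[1]], line, d1, ds$physio, 0)
  expect_equal(dim(ovl), c(256, 256, 3))
  base <- array(ds$frames[[1]], dim = c(256, 256, 3))
  changed <- which(apply(ovl != base, c(1, 2), any), arr.ind = TRUE)
  # off-ribbon pixels bit-identical; ribbon pixels near the line
  line_col <- approx(l1$row, l1$col, xout = changed[, 1], rule = 2)$y
  expect_lte(max(abs(changed[, 2] - line_col)), 20)
  # color at each sensor center is exactly colormap(value)
  sc <- default_mano_scale()
  idx <- sync_sample_index(0, ds$physio$rate) + 1
  for (i in c(1, 5, 10)) {
    v <- ds$physio$mano[d1$sensor_index[i], idx]
    got <- grDevices::rgb(ovl[round(d1$row[i]), round(d1$col[i]), 1],
                          ovl[round(d1$row[i]), round(d1$col[i]), 2],
                          ovl[round(d1$row[i]), round(d1$col[i]), 3])
    expect_identical(got, scale_colors(sc, v))
  }
  # pure function: re-rendering is bit-identical
  ovl2 <- render_overlay(ds$frames[[1]], line, d1, ds$physio, 0)
  expect_identical(unclass(ovl), unclass(ovl2))
})

test_that("equal pressures give a single-color manometry ribbon", {
  ds <- small_dataset()
  res <- small_detection()
  d1 <- dplyr::filter(res$detections, frame == 1)
  l1 <- dplyr::filter(res$lines, frame == 1)
  physio <- ds$physio
  physio$mano[] <- 80
  physio$imped[] <- 800
  ovl <- render_overlay(ds$frames[[1]], new_catheter_line(l1$row, l1$col),
                        d1, physio, 0)
  base <- array(ds$frames[[1]], dim = c(256, 256, 3))
  changed <- which(apply(ovl != base, c(1, 2), any), arr.ind = TRUE)
  mano_px <- changed[abs(changed[, 2] -
    approx(l1$row, l1$col, xout = changed[, 1], rule = 2)$y) <= 4, ]
  cols <- unique(grDevices::rgb(ovl[cbind(mano_px, 1)],
                                ovl[cbind(mano_px, 2)],
                                ovl[cbind(mano_px, 3)]))
  expect_identical(cols, scale_colors(default_mano_scale(), 80))
})

test_that("missing manometry channels are reported by name", {
  ds <- small_dataset()
  res <- small_detection()
  d1 <- dplyr::filter(res$detections, frame == 1)
  l1 <- dplyr::filter(res$lines, frame == 1)
  physio <- ds$physio
  physio$mano <- physio$mano[1:10, , drop = FALSE]
  expect_error(render_overlay(ds$frames[[1]],
                              new_catheter_line(l1$row, l1$col),
                              d1, physio, 0), "channel")
})
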