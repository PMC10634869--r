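test_that("8-bit conversion maps the global range and flags constants", {
  raw <- array(0, dim = c(2, 2, 4, 4))
  raw[1, 1, , ] <- 100; raw[2, 1, , ] <- 612
  raw[1, 1, 1, 1] <- 356
  raw[, 2, , ] <- 7  # constant channel
  expect_warning(m <- to_eight_bit(raw), "constant")
  expect_equal(m$frames[1, 1, 2, 2], 0)
  expect_equal(m$frames[2, 1, 2, 2], 255)
  expect_equal(m$frames[1, 1, 1, 1], 128)  # midpoint rounds half up
  expect_true(all(m$frames[, 2, , ] == 0))
  expect_equal(m$constant_channels, 2L)

  # already 0..255 stays put
  raw2 <- array(rep(c(0, 255), each = 16), dim = c(2, 1, 4, 4))
  m2 <- to_eight_bit(raw2, channels = c(spindle = 1))
  expect_equal(as.vector(m2$frames), as.vector(raw2))
  expect_error(to_eight_bit(raw - 200), "non-negative")
})

test_that("top-fraction bands reproduce the printed 8-bit thresholds", {
  expect_identical(top_fraction_band(0.25), c(low = 191L, high = 255L))
  expect_identical(top_fraction_band(0.5), c(low = 127L, high = 255L))
  expect_identical(top_fraction_band(1), c(low = 0L, high = 255L))
  expect_error(top_fraction_band(0), "0, 1")
  expect_error(top_fraction_band(1.2), "0, 1")
})

test_that("embryo segmentation covers the true ellipse and rejects blanks", {
  gen <- make_mitosis_movie(n_frames = 10, seed = 21)
  mask <- segment_embryo(gen$movie)
  d <- dim(gen$movie$frames)
  ctr <- c((d[4] + 1) / 2, (d[3] + 1) / 2)
  truth <- (col(mask) - ctr[1])^2 / (0.45 * d[4])^2 +
    (row(mask) - ctr[2])^2 / (0.45 * d[3])^2 < 1
  overlap <- sum(mask > 0 & truth) / sum(truth)
  expect_gt(overlap, 0.95)

  blank <- array(0, dim = c(2, 2, 20, 20))
  blank_movie <- suppressWarnings(to_eight_bit(blank + 1e-9))
  expect_error(segment_embryo(blank_movie), "empty mask")
})

test_that("two non-touching embryos get two labels", {
  gen <- make_mitosis_movie(n_frames = 6, dims = c(120, 200),
                            pole_dist0 = 10, seed = 3)
  half <- gen$movie$frames
  two <- array(0, dim = c(6, 2, 120, 420))
  two[, , , 1:200] <- half
  two[, , , 221:420] <- half
  movie2 <- embryo_movie(two, pixel_size = 0.2)
  mask <- segment_embryo(movie2)
  expect_equal(max(mask), 2)
})

test_that("pole detection finds blob centroids and flags failures", {
  img <- matrix(0, 80, 120)
  add_blob <- function(img, cx, cy, amp, sd = 2) {
    img + amp * exp(-((col(img) - cx)^2 + (row(img) - cy)^2) / (2 * sd^2))
  }
  frame <- add_blob(add_blob(img, 30, 40, 255), 90, 40, 255)
  p <- detect_poles(frame, mask = NULL)
  expect_true(p$valid)
  expect_within(p$a, c(30, 40), 0.5)
  expect_within(p$b, c(90, 40), 0.5)

  # third, smaller blob is ignored
  frame3 <- add_blob(frame, 60, 20, 230, sd = 1)
  p3 <- detect_poles(frame3, mask = NULL)
  expect_within(p3$a, c(30, 40), 0.5)
  expect_within(p3$b, c(90, 40), 0.5)

  dim_img <- matrix(100, 80, 120)
  expect_false(detect_poles(dim_img, mask = NULL)$valid)
})

test_that("chromatin edges are symmetric before anaphase", {
  img <- matrix(0, 80, 120)
  bar <- 255 * exp(-((col(img) - 60)^2 / (2 * 3^2) +
                       (row(img) - 40)^2 / (2 * 10^2)))
  poles <- list(a = c(20, 40), b = c(100, 40), valid = TRUE)
  ch <- detect_chromatids(bar, mask = NULL, poles = poles)
  expect_true(ch$valid)
  expect_equal(ch$n_comp, 1L)
  expect_within(abs(ch$edge_a), abs(ch$edge_b), 0.1)

  expect_false(detect_chromatids(matrix(0, 80, 120), NULL, poles)$valid)
})

test_that("anaphase onset calling requires persistence", {
  mk_trace <- function(gap) {
    tr <- tibble::tibble(
      frame = seq_along(gap), time_s = seq_along(gap) - 1, valid = TRUE,
      n_chrom_comp = ifelse(is.na(gap), 1L, 2L),
      chrom_gap_um = gap
    )
    attr(tr, "frame_interval") <- 1
    class(tr) <- c("spindle_trace", class(tr))
    tr
  }
  gap <- c(rep(NA, 10), rep(2, 5))
  expect_equal(detect_anaphase_onset(mk_trace(gap)), 10L)
  # single-frame split is ignored
  noisy <- c(rep(NA, 4), 2, rep(NA, 6), rep(2, 4))
  expect_equal(detect_anaphase_onset(mk_trace(noisy)), 11L)
  # never-separating trace
  expect_true(is.na(detect_anaphase_onset(mk_trace(rep(NA_real_, 8)))))
})

test_that("segregation rates follow the kinematics", {
  mk_trace <- function(sep, pole) {
    tr <- tibble::tibble(
      frame = seq_along(sep), time_s = seq_along(sep) - 1, valid = TRUE,
      chrom_sep_um = sep, pole_dist_um = pole
    )
    attr(tr, "frame_interval") <- 1
    class(tr) <- c("spindle_trace", class(tr))
    tr
  }
  t <- 0:59
  tr <- mk_trace(pmax(0, (t - 10) * 0.13), 15 + pmax(0, (t - 10)) * 0.09)
  expect_equal(segregation_rate(tr, onset = 11), 0.13, tolerance = 1e-9)
  expect_equal(segregation_rate(tr, what = "pole", onset = 11), 0.09,
               tolerance = 1e-9)
  # constant distance -> 0
  expect_equal(segregation_rate(mk_trace(rep(3, 60), rep(15, 60)), onset = 5), 0)
  # piecewise fast-then-slow equals net displacement / window
  sep <- pmax(0, pmin(t - 10, 10) * 0.3) + pmax(0, t - 20) * 0.05
  expect_equal(segregation_rate(mk_trace(sep, rep(15, 60)), onset = 11),
               (sep[51] - sep[11]) / 40, tolerance = 1e-9)
  expect_error(segregation_rate(mk_trace(rep(3, 20), rep(15, 20)), onset = 5),
               "insufficient frames")
})

test_that("full pipeline recovers the generator kinematics", {
  gen <- make_mitosis_movie(seed = 31)
  tr <- track_spindle(gen$movie)
  px <- gen$movie$pixel_size
  expect_true(all(tr$valid))
  expect_within(tr$pole_dist_um, gen$truth$frames$pole_dist_um, 1 * px)
  onset <- detect_anaphase_onset(tr)
  expect_lte(abs(onset - gen$truth$onset_frame), 1)
  seg <- segregation_rate(tr, onset = onset)
  elo <- segregation_rate(tr, what = "pole", onset = onset)
  expect_within(seg / gen$truth$segregation_rate, 1, 0.05)
  expect_within(elo / gen$truth$elongation_rate, 1, 0.05)
})

test_that("kymograph of a horizontal spindle equals direct band sums", {
  gen <- make_mitosis_movie(n_frames = 8, oscillation = c(0, 30), seed = 41)
  tr <- track_spindle(gen$movie)
  k <- build_kymograph(gen$movie, tr, band_halfwidth = 5)
  t <- 4
  yc <- round((tr$pole_a_y[t] + tr$pole_b_y[t]) / 2)
  direct <- colSums(movie_channel_for_test(gen$movie, "spindle", t)[(yc - 5):(yc + 5), ])
  expect_within(k$image[t, ], direct, 0.01 * max(direct))
})

test_that("kymograph is invariant under rigid rotation of the movie", {
  gen <- make_mitosis_movie(n_frames = 12, noise_sd = 0, shot_scale = 0,
                            seed = 51)
  tr <- track_spindle(gen$movie)
  k0 <- build_kymograph(gen$movie, tr)
  rot <- rotate_movie(gen$movie, 30)
  trr <- track_spindle(rot, mask = NA)
  kr <- build_kymograph(rot, trr)
  expect_true(all(trr$valid))
  # distances are rotation invariant
  expect_within(trr$pole_dist_um, tr$pole_dist_um, 1 * gen$movie$pixel_size)
  # kymograph rows agree within interpolation tolerance (2% of range)
  rng <- diff(range(k0$image, na.rm = TRUE))
  expect_lt(mean(abs(kr$image - k0$image), na.rm = TRUE), 0.02 * rng)
})

test_that("kymograph enhancement skeletonizes trajectories", {
  gen <- make_mitosis_movie(n_frames = 20, noise_sd = 0, shot_scale = 0,
                            seed = 61)
  tr <- track_spindle(gen$movie)
  k <- build_kymograph(gen$movie, tr)
  sk <- enhance_kymograph(k)
  expect_equal(dim(sk), dim(k$image))
  expect_gt(sum(sk), 0)
  # two pole traces -> at least 2 skeleton pixels per row, near the poles
  row_counts <- rowSums(sk)
  expect_true(all(row_counts[5:15] >= 2))

  blank <- structure(list(image = matrix(0, 10, 20), band_halfwidth = 5,
                          valid = rep(TRUE, 10), pixel_size = 0.2,
                          frame_interval = 1), class = "kymograph")
  expect_equal(sum(enhance_kymograph(blank)), 0)

  # skeleton of a thick straight line lies on its medial axis
  bw <- matrix(FALSE, 21, 40); bw[9:13, 5:35] <- TRUE
  sk2 <- skeletonize(bw)
  expect_true(all(which(rowSums(sk2) > 0) %in% 10:12))
  expect_true(all(sk2[, setdiff(1:40, 5:35)] == 0))
})

test_that("pole oscillation is measured against the reference axis", {
  tr <- tibble::tibble(
    frame = 1:20, time_s = 0:19, valid = TRUE,
    pole_a_x = seq(10, 50, length.out = 20),
    pole_a_y = rep(40, 20),
    pole_b_x = seq(60, 100, length.out = 20),
    pole_b_y = 40 + 3 * sin(2 * pi * (0:19) / 10)
  )
  attr(tr, "pixel_size") <- 0.2
  class(tr) <- c("spindle_trace", class(tr))
  axis <- list(point = c(0, 40), direction = c(1, 0))
  osc <- pole_oscillation(tr, axis)
  # pole A moves parallel to the axis -> zero displacement
  expect_within(osc$pole_a_perp_um, 0, 1e-12)
  # pole B oscillates with amplitude 3 px = 0.6 um
  expect_within(max(abs(osc$pole_b_perp_um)), 0.6, 0.5 * 0.2)
  # axis override changes the result accordingly
  osc2 <- pole_oscillation(tr, list(point = c(0, 0), direction = c(0, 1)))
  expect_within(osc2$pole_a_perp_um, tr$pole_a_x * 0.2, 1e-9)
})

test_that("movies survive a TIFF round trip", {
  skip_if_not_installed("tiff")
  gen <- make_mitosis_movie(n_frames = 4, seed = 71)
  f <- withr::local_tempfile(fileext = ".tif")
  write_movie_tiff(gen$movie, f)
  back <- read_movie_tiff(f, pixel_size = gen$movie$pixel_size)
  expect_equal(dim(back$frames), dim(gen$movie$frames))
  expect_equal(back$frames, gen$movie$frames, tolerance = 1e-6)
})
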