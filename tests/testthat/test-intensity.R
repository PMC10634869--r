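test_that("midzone intensity is background-ratio normalized", {
  img <- matrix(10, 50, 80)
  img[20:30, 35:45] <- 20
  roi <- c(xmin = 35, xmax = 45, ymin = 20, ymax = 30)
  bg <- c(xmin = 1, xmax = 10, ymin = 1, ymax = 10)
  expect_equal(midzone_intensity(img, roi, bg), 1)
  expect_equal(midzone_intensity(img, bg, bg), 0)
  expect_error(midzone_intensity(img, roi, bg * 0 + c(1, 200, 1, 10)),
               "outside")
  expect_error(midzone_intensity(img * 0, roi, bg), "zero")
  # known enrichment factor f -> f - 1
  img2 <- matrix(8, 50, 80); img2[20:30, 35:45] <- 8 * 3.5
  expect_equal(midzone_intensity(img2, roi, bg), 2.5)
})

test_that("half-intensity width matches closed forms and is affine invariant", {
  pos <- seq(-6, 6, by = 0.01)
  # triangular peak, base 6 um: half width = 3 um
  tri <- tibble::tibble(position_um = pos,
                        value = pmax(0, 1 - abs(pos) / 3))
  expect_within(half_intensity_width(tri, background = 0), 3, 0.02)
  # Gaussian: 2.355 sigma
  for (sigma in c(0.7, 1.5)) {
    g <- tibble::tibble(position_um = pos,
                        value = exp(-pos^2 / (2 * sigma^2)))
    expect_within(half_intensity_width(g, background = 0),
                  2 * sqrt(2 * log(2)) * sigma, 0.02)
  }
  # affine transform of the intensities and a position shift change nothing
  g <- tibble::tibble(position_um = pos, value = exp(-pos^2 / 2))
  g2 <- tibble::tibble(position_um = pos + 2.3, value = 5 + 40 * g$value)
  expect_equal(half_intensity_width(g, background = 0),
               half_intensity_width(g2, background = 5), tolerance = 1e-9)
  # peak on the edge is an error
  half <- tibble::tibble(position_um = pos, value = pos + 6)
  expect_error(half_intensity_width(half, background = 0), "edge")
})

test_that("profile extraction feeds the width measurement", {
  img <- matrix(0, 40, 200)
  sigma_px <- 15  # 1.5 um at 0.1 um/px
  img <- img + 100 * exp(-(col(img) - 100)^2 / (2 * sigma_px^2))
  prof <- intensity_profile(img, c(xmin = 10, xmax = 190, ymin = 15,
                                   ymax = 25), pixel_size = 0.1)
  expect_within(half_intensity_width(prof, background = 0),
                2 * sqrt(2 * log(2)) * 1.5, 0.05)
})

test_that("seeded noisy profiles recover the designed width", {
  withr::with_seed(99, {
    widths <- vapply(1:50, function(i) {
      pos <- seq(-5, 5, by = 0.1)
      val <- 50 + 200 * exp(-pos^2 / (2 * (1.8 / 2.355)^2)) + rnorm(length(pos), 0, 5)
      half_intensity_width(tibble::tibble(position_um = pos, value = val),
                           background = 50)
    }, numeric(1))
  })
  expect_within(mean(widths), 1.8, 0.1)  # one 0.1 um bin
})

test_that("comet counting is exact for separated events and monotone", {
  for (n in c(3L, 5L, 7L)) {
    ck <- make_comet_kymograph(n_comets = n, seed = n)
    expect_identical(count_comet_events(ck$kymograph), n)
  }
  # noisy case
  ck <- make_comet_kymograph(n_comets = 6, noise_sd = 2, seed = 8)
  expect_identical(count_comet_events(ck$kymograph), 6L)
  # blank kymograph
  blank <- structure(list(image = matrix(5, 100, 45), band_halfwidth = NA,
                          valid = rep(TRUE, 100), pixel_size = 0.1,
                          frame_interval = 1), class = "kymograph")
  expect_identical(count_comet_events(blank), 0L)
  # segment outside the kymograph errors
  ck2 <- make_comet_kymograph(seed = 1)
  expect_error(count_comet_events(ck2$kymograph, segment_start = 10), "outside")
  # infeasible placement errors
  expect_error(make_comet_kymograph(n_comets = 40, min_separation = 10,
                                    seed = 1), "cannot place")
})

test_that("FRAP fit inverts the generating model", {
  g <- make_frap_curve(fraction = 0.34, k = 0.05, noise_sd = 0)
  fit <- frap_recovery_fraction(g$curve)
  expect_within(fit$fraction, 0.34, 1e-6)
  expect_within(fit$k, 0.05, 1e-6)
  glanced <- glance(fit)
  expect_equal(glanced$fraction, fit$fraction)
  expect_equal(nrow(tidy(fit)), 3)

  # flat post-bleach curve -> fraction ~0
  flat <- frap_curve(seq(0, 60, 0.5), rep(0.2, 121), prebleach = 1)
  expect_within(frap_recovery_fraction(flat)$fraction, 0, 1e-6)

  # prebleach must exceed the first post-bleach intensity
  bad <- frap_curve(seq(0, 10, 0.5), rep(2, 21), prebleach = 1)
  expect_error(frap_recovery_fraction(bad), "prebleach")
})

test_that("FRAP recovery is unbiased at 2% noise", {
  ests <- t(vapply(1:50, function(s) {
    g <- make_frap_curve(fraction = 0.34, k = 0.05, noise_sd = 0.02, seed = s)
    fit <- frap_recovery_fraction(g$curve)
    c(fit$fraction, fit$k)
  }, numeric(2)))
  expect_within(mean(ests[, 1]), 0.34, 0.02)
  expect_within(mean(ests[, 2]), 0.05, 0.005)
})
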