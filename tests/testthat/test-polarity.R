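test_that("network polarity reproduces the defining endpoints", {
  all_par <- make_filament_network(n = 20, antiparallel_fraction = 0,
                                   seed = 1)
  expect_identical(network_polarity(all_par$network), 1)

  balanced <- make_filament_network(n = 20, antiparallel_fraction = 0.5,
                                    seed = 1)
  expect_identical(network_polarity(balanced$network), 0)

  # 3 along +x, 1 along -x -> |3 - 1| / 4
  quarter <- make_filament_network(n = 4, antiparallel_fraction = 0.25,
                                   seed = 2)
  expect_equal(network_polarity(quarter$network), 0.5)
})

test_that("network polarity is invariant to axis flip and needs annotations", {
  gen <- make_filament_network(n = 10, antiparallel_fraction = 0.3, seed = 5)
  expect_equal(network_polarity(gen$network, axis = c(1, 0, 0)),
               network_polarity(gen$network, axis = c(-1, 0, 0)))
  # empty region is undefined, not zero
  empty <- c(xmin = 1e6, xmax = 2e6, ymin = 1e6, ymax = 2e6,
             zmin = 1e6, zmax = 2e6)
  expect_true(is.na(network_polarity(gen$network, region = empty)))
  # missing plus ends are an error
  plain <- make_random_filaments(n = 5, seed = 1)
  expect_error(network_polarity(plain), "plus-end")
})

test_that("forward model obeys its defining identities", {
  rho <- matrix(10, 20, 30)
  p1 <- shg_tp_forward(rho, matrix(1, 20, 30), alpha = 2, beta = 3)
  expect_equal(p1$kappa, 3 / 4)
  expect_equal(max(abs(p1$shg / (p1$kappa * p1$tp^2) - 1)), 0)
  p0 <- shg_tp_forward(rho, matrix(0, 20, 30))
  expect_true(all(p0$shg == 0))
  # determinism under a seed
  a <- shg_tp_forward(rho, matrix(0.5, 20, 30), noise_sd = 1, seed = 9)
  b <- shg_tp_forward(rho, matrix(0.5, 20, 30), noise_sd = 1, seed = 9)
  expect_identical(a$shg, b$shg)
  expect_identical(a$tp, b$tp)
  expect_error(shg_tp_forward(-rho, matrix(1, 20, 30)), "non-negative")
})

test_that("noiseless forward -> inverse round trip is the identity", {
  rho <- matrix(runif(600, 5, 20), 20, 30)
  for (p in c(0.3, 0.7, 1)) {
    pair <- shg_tp_forward(rho, matrix(p, 20, 30), alpha = 1.7, beta = 0.4)
    rec <- polarity_from_images(pair)
    expect_within(rec, p, 1e-9)
  }
  # masked where TP is at floor
  rho2 <- rho; rho2[1:5, 1] <- 0
  pair2 <- shg_tp_forward(rho2, matrix(0.5, 20, 30))
  rec2 <- polarity_from_images(pair2, tp_floor = 1)
  expect_true(all(is.na(rec2[1:5, 1])))
  expect_error(polarity_from_images(pair2, kappa = -1), "kappa")
})

test_that("kappa calibration recovers beta / alpha^2", {
  rho <- matrix(50, 40, 40)
  pair <- shg_tp_forward(rho, matrix(1, 40, 40), alpha = 2, beta = 5)
  reg <- c(xmin = 5, xmax = 35, ymin = 5, ymax = 35)
  expect_equal(calibrate_kappa(pair, reg), 5 / 4, tolerance = 1e-12)
  # noisy: within 5% for noise at 5% of signal
  noisy <- shg_tp_forward(rho, matrix(1, 40, 40), alpha = 2, beta = 5,
                          noise_sd = 5, seed = 3)
  expect_within(calibrate_kappa(noisy, reg) / (5 / 4), 1, 0.05)
  blank <- shg_tp_forward(matrix(0, 4, 4), matrix(1, 4, 4))
  expect_error(calibrate_kappa(blank, c(xmin = 1, xmax = 4, ymin = 1, ymax = 4)),
               "no usable pixels")
})

test_that("axial profiles average slabs correctly", {
  flat <- matrix(0.8, 40, 60)
  prof <- axial_profile(flat, axis = list(p1 = c(1, 20), p2 = c(60, 20)),
                        center = c(30, 20), bin = 0.5, pixel_size = 0.1)
  expect_true(all(abs(prof$polarity - 0.8) < 1e-12))
  expect_true(!is.unsorted(prof$position_um, strictly = TRUE))

  dip <- matrix(1, 40, 61)
  dip[, 29:33] <- 0  # central stripe
  prof2 <- axial_profile(dip, axis = list(p1 = c(1, 20), p2 = c(61, 20)),
                         center = c(31, 20), bin = 0.1, pixel_size = 0.1)
  expect_equal(prof2$polarity[which.min(abs(prof2$position_um))], 0)

  # slab-average oracle: direct pixel bucketing on a gradient map
  grad <- matrix(rep(seq(0, 1, length.out = 50), each = 30), 30, 50)
  prof3 <- axial_profile(grad, axis = list(p1 = c(1, 15), p2 = c(50, 15)),
                         center = c(25, 15), bin = 0.2, pixel_size = 0.1)
  xs <- (col(grad) - 25) * 0.1
  oracle <- tapply(grad, floor(xs / 0.2 + 0.5), mean)
  oracle <- oracle[order(as.numeric(names(oracle)))]
  expect_equal(prof3$polarity, as.numeric(oracle))
  expect_error(axial_profile(grad, axis = list(p1 = c(1, 1), p2 = c(1, 1)),
                             center = c(1, 1)), "degenerate")
})

test_that("overlap width matches closed forms", {
  # rectangular dip of width 4 um
  pos_fine <- seq(-8, 8, by = 0.01)
  rect <- ifelse(abs(pos_fine) < 2, 0, 1)
  prof <- tibble::tibble(position_um = pos_fine, polarity = rect)
  expect_within(overlap_width(prof), 4, 0.05)
  pos <- seq(-8, 8, by = 0.1)

  # Gaussian dip: FWHM = 2 sqrt(2 log 2) sigma
  for (sigma in c(0.8, 1.7)) {
    gauss <- tibble::tibble(position_um = pos,
                            polarity = 1 - exp(-pos^2 / (2 * sigma^2)))
    expect_within(overlap_width(gauss), 2 * sqrt(2 * log(2)) * sigma, 0.02)
  }

  # invariance under value scaling and position translation
  g <- tibble::tibble(position_um = pos, polarity = 1 - exp(-pos^2 / 2))
  g_scaled <- tibble::tibble(position_um = pos + 3, polarity = g$polarity * 0.4)
  expect_equal(overlap_width(g), overlap_width(g_scaled), tolerance = 1e-9)

  mono <- tibble::tibble(position_um = pos, polarity = seq(0, 1, length.out = length(pos)))
  expect_error(overlap_width(mono), "no central dip")
})

test_that("designed antiparallel zone width is recovered from noisy images", {
  widths <- vapply(1:25, function(s) {
    g <- make_shg_tp_pair(dip_width_um = 4, noise_sd = 2, seed = s)
    P <- polarity_from_images(g$pair, tp_floor = 10)
    prof <- axial_profile(P, axis = list(p1 = c(1, 40), p2 = c(200, 40)),
                          center = c(100.5, 40.5), bin = 0.2,
                          pixel_size = 0.1)
    overlap_width(prof)
  }, numeric(1))
  expect_within(mean(widths), 4, 0.2)  # within one 0.2 um bin
})

test_that("image-derived polarity agrees with the network statistic", {
  # balanced antiparallel zone -> polarity ~0 in the zone, 1 outside
  gen <- make_filament_network(n = 20, antiparallel_fraction = 0.5, seed = 4)
  expect_identical(network_polarity(gen$network), 0)
  g <- make_shg_tp_pair(dip_width_um = 4, dip_depth = 1, noise_sd = 0)
  P <- polarity_from_images(g$pair, tp_floor = 1)
  prof <- axial_profile(P, axis = list(p1 = c(1, 40), p2 = c(200, 40)),
                        center = c(100.5, 40.5), bin = 0.2, pixel_size = 0.1)
  center_val <- prof$polarity[which.min(abs(prof$position_um))]
  edge_val <- prof$polarity[which.min(abs(prof$position_um - 8))]
  expect_within(center_val, 0, 0.05)
  expect_within(edge_val, 1, 0.05)
})
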