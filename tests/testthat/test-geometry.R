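test_that("segment_min_distance matches closed forms and a sampling oracle", {
  a <- rbind(c(0, 0, 0), c(100, 0, 0))
  expect_equal(segment_min_distance(a, rbind(c(0, 50, 0), c(100, 50, 0))), 50)
  expect_equal(segment_min_distance(a, rbind(c(50, -50, 0), c(50, 50, 0))), 0)
  b <- rbind(c(200, 30, 40), c(300, 30, 40))
  expect_equal(segment_min_distance(a, b), sqrt(100^2 + 30^2 + 40^2),
               tolerance = 1e-9)
  expect_lt(abs(segment_min_distance(a, b) -
                  oracle_seg_seg_sampled(a[1, ], a[2, ], b[1, ], b[2, ])),
            0.2)
  # skew pair against the dense sampling oracle
  c1 <- rbind(c(0, 0, 0), c(120, 40, 10))
  c2 <- rbind(c(60, -30, 90), c(10, 80, 30))
  expect_lt(abs(segment_min_distance(c1, c2) -
                  oracle_seg_seg_sampled(c1[1, ], c1[2, ], c2[1, ], c2[2, ])),
            0.2)
  # degenerate point-segment
  expect_equal(segment_min_distance(rbind(c(0, 0, 0), c(0, 0, 0)),
                                    rbind(c(3, 4, 0), c(3, 4, 0))), 5)
})

test_that("filament_pair_distance equals the brute-force polyline oracle", {
  expect_equal(filament_pair_distance(xline(0, 500), xline(0, 500)), 0)
  expect_equal(filament_pair_distance(xline(0, 500), xline(0, 500, y = 50)), 50)
  withr::with_seed(42, {
    for (i in 1:5) {
      A <- matrix(cumsum(rnorm(30, sd = 40)), ncol = 3)
      B <- matrix(cumsum(rnorm(30, sd = 40)) + 150, ncol = 3)
      expect_equal(filament_pair_distance(A, B),
                   oracle_polyline_pair_distance(A, B, step = 0.25),
                   tolerance = 0.01)
    }
  })
})

test_that("interaction_angle follows the end-to-end line convention", {
  expect_equal(interaction_angle(xline(0, 100), xline(50, 150, y = 30)), 0)
  expect_equal(interaction_angle(rbind(c(0, 0, 0), c(1, 0, 0)),
                                 rbind(c(0, 0, 0), c(0, 1, 0))), 90)
  expect_equal(interaction_angle(rbind(c(0, 0, 0), c(1, 0, 0)),
                                 rbind(c(1, 0, 0), c(0, 0, 0))), 180)
  expect_equal(interaction_angle(rbind(c(0, 0, 0), c(1, 0, 0)),
                                 rbind(c(1, 0, 0), c(0, 0, 0)), fold = TRUE), 0)
  loop <- rbind(c(0, 0, 0), c(100, 0, 0), c(100, 100, 0), c(0, 0, 0))
  expect_error(interaction_angle(loop, xline(0, 100)), "undefined angle")
})

test_that("detect_interactions finds full overlaps and respects d_max", {
  net <- line_network(xline(0, 500), xline(0, 500, y = 50))
  ints <- detect_interactions(net, resample_step = 20)
  expect_equal(nrow(ints), 2)  # one run per ordered pair
  expect_within(ints$length_nm, c(500, 500), 20)
  expect_equal(ints$min_distance_nm, c(50, 50))
  expect_equal(ints$angle_deg, c(0, 0))

  far <- line_network(xline(0, 500), xline(0, 500, y = 150))
  expect_equal(nrow(detect_interactions(far)), 0)

  single <- line_network(xline(0, 500))
  expect_equal(nrow(detect_interactions(single)), 0)
})

test_that("run boundaries are refined to the threshold crossing", {
  # target tracks the source at 80 nm for 400 nm of arc, then diverges
  target <- rbind(c(0, 80, 0), c(400, 80, 0), c(700, 380, 0))
  net <- line_network(xline(0, 700, n = 15), target)
  ints <- detect_interactions(net, resample_step = 20)
  run <- ints[ints$source_id == 1, ]
  expect_equal(nrow(run), 1)
  oracle <- oracle_interactions(net, step = 1)
  o_run <- oracle[oracle$source_id == 1, ]
  expect_within(run$length_nm, o_run$length_nm, 2 * 20)
  expect_within(run$min_distance_nm, 80, 0.5)
})

test_that("short in-threshold stretches are discarded by l_min", {
  # only ~80 nm of the source stays within 100 nm of the target
  target <- rbind(c(240, 95, 0), c(260, 95, 0))
  net <- line_network(xline(0, 500, n = 26), target)
  expect_equal(nrow(detect_interactions(net, l_min = 100)), 0)
  ints0 <- detect_interactions(net, l_min = 0)
  expect_gt(nrow(ints0), 0)
})

test_that("grid-accelerated detection equals the brute-force path exactly", {
  for (seed in c(1, 2, 3)) {
    net <- make_random_filaments(n = 18, box = 1200, seed = seed)
    plain <- detect_interactions(net, index = FALSE)
    grid <- detect_interactions(net, index = TRUE)
    grid_small <- detect_interactions(net, index = grid_index(net, cell = 60))
    expect_equal(as.data.frame(grid), as.data.frame(plain))
    expect_equal(as.data.frame(grid_small), as.data.frame(plain))
    expect_identical(nearest_neighbor_distances(net, index = TRUE),
                     nearest_neighbor_distances(net))
  }
})

test_that("interactions are monotone in d_max and l_min", {
  for (seed in 4:6) {
    net <- make_random_filaments(n = 15, box = 1000, seed = seed)
    base <- detect_interactions(net, d_max = 100, l_min = 100)
    wider <- detect_interactions(net, d_max = 130, l_min = 100)
    shorter <- detect_interactions(net, d_max = 100, l_min = 60)
    key <- function(x) paste(x$source_id, x$target_id)
    expect_true(all(key(base) %in% key(wider)))
    expect_true(all(key(base) %in% key(shorter)))
    # per-pair total interaction length never shrinks when d_max grows
    tot <- function(x) tapply(x$length_nm, paste(x$source_id, x$target_id), sum)
    common <- intersect(names(tot(base)), names(tot(wider)))
    expect_true(all(tot(wider)[common] >= tot(base)[common] - 1e-6))
  }
})

test_that("interaction existence is symmetric for clearly interacting pairs", {
  for (seed in 7:9) {
    net <- make_random_filaments(n = 15, box = 1000, seed = seed)
    ints <- detect_interactions(net, l_min = 0)
    strong <- ints[ints$min_distance_nm <= 95, ]
    fwd <- unique(paste(strong$source_id, strong$target_id))
    rev <- unique(paste(ints$target_id, ints$source_id))
    expect_true(all(fwd %in% rev))
  }
})

test_that("designed spacing and overlap are recovered from synthetic pairs", {
  for (s in c(40, 60, 80)) {
    for (L in c(300, 500, 800)) {
      gen <- make_filament_network(n = 10, length_dist = c(L, 0),
                                   spacing = s, seed = s + L)
      ints <- detect_interactions(gen$network, resample_step = 20)
      expect_within(mean(ints$min_distance_nm), s, 1)
      expect_within(mean(ints$length_nm), L, 2 * 20)
    }
  }
})

test_that("all reported interactions satisfy the declared bounds", {
  net <- make_random_filaments(n = 20, box = 1200, seed = 10)
  ints <- detect_interactions(net, d_max = 100, l_min = 100)
  if (nrow(ints) > 0) {
    expect_true(all(ints$min_distance_nm <= 100))
    expect_true(all(ints$length_nm >= 100))
    expect_true(all(ints$angle_deg >= 0 & ints$angle_deg <= 180))
    expect_true(all(ints$start_nm >= 0 & ints$end_nm > ints$start_nm))
  }
})

test_that("symmetric mode deduplicates ordered runs", {
  net <- line_network(xline(0, 500), xline(0, 500, y = 50))
  sym <- detect_interactions(net, mode = "symmetric")
  expect_equal(nrow(sym), 1)
  expect_equal(sym$source_id, 1)
  expect_equal(sym$target_id, 2)
  expect_within(sym$length_nm, 500, 20)
})

test_that("nearest neighbors match hand-built and oracle tables", {
  net <- line_network(xline(0, 400), xline(0, 400, y = 60),
                      xline(0, 400, y = 200))
  nn <- nearest_neighbor_distances(net)
  expect_equal(nn$distance_nm, c(60, 60, 140))
  expect_equal(nn$nearest_id, c(2L, 1L, 2L))
  expect_error(nearest_neighbor_distances(line_network(xline(0, 100))),
               "at least 2")

  rnd <- make_random_filaments(n = 12, box = 900, seed = 12)
  got <- nearest_neighbor_distances(rnd)
  want <- oracle_nearest_neighbors(rnd, step = 0.5)
  expect_equal(got$nearest_id, want$nearest_id)
  expect_within(got$distance_nm, want$distance_nm, 0.5)
})

test_that("network_stats computes density, SDs and bin fractions", {
  # 31 filaments of 400 nm in a 10 um^3 volume
  pts <- do.call(rbind, lapply(1:31, function(i) {
    data.frame(filament_id = i, x = c(0, 400), y = i * 60, z = 500)
  }))
  vol <- c(xmin = -300, xmax = 700, ymin = 0, ymax = 2000, zmin = 0, zmax = 5000)
  # 1000 x 2000 x 5000 nm = 10 um^3
  net <- filament_network(pts, volume = vol)
  st <- network_stats(net, detect_interactions(net))
  expect_equal(st$volume_um3, 10)
  expect_equal(st$density_per_um3, 3.1)
  expect_equal(st$mean_length_nm, 400)
  expect_equal(st$sd_length_nm, 0)

  fake <- tibble::tibble(source_id = 1:4, target_id = 2:5,
                         start_nm = 0, end_nm = 100, length_nm = 100,
                         min_distance_nm = c(30, 60, 90, 120),
                         angle_deg = 0)
  st2 <- network_stats(net, fake, bins = 100)
  expect_equal(unname(st2$distance_bin_fractions), c(0.75, 0.25))
  expect_equal(sum(st2$distance_bin_fractions), 1, tolerance = 1e-9)

  # zero interactions: stats absent, not zero
  empty <- detect_interactions(line_network(xline(0, 400),
                                            xline(0, 400, y = 900)))
  st3 <- network_stats(net, empty)
  expect_true(is.na(st3$mean_interaction_length_nm))
  expect_equal(st3$n_interactions, 0)
})
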