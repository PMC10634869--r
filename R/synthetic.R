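#' Synthetic filament networks with designed overlap geometry
#'
#' Generates straight, spindle-axis-parallel microtubule pairs on a jittered
#' lattice. The two members of a pair share the same axial span (designed
#' full overlap) and sit at an exact lateral spacing, so interaction
#' detection on the synthetic network has a closed-form expected result:
#' every ordered pair yields one interaction of length equal to the pair's
#' overlap length, at minimum distance equal to the designed spacing.
#' Plus-end orientations are antiparallel for an exact count
#' `round(antiparallel_fraction * n_zone)` of the filaments whose midpoint
#' falls inside the overlap zone, and parallel (+x) elsewhere.
#'
#' @param n Number of filaments (laid out in pairs; one unpaired filament
#'   is allowed when `n` is odd).
#' @param length_dist `c(mean, sd)` of filament length in nm; one length is
#'   drawn per pair (both members share it, giving full designed overlap).
#' @param spacing Designed lateral center-to-center spacing within a pair
#'   (nm).
#' @param overlap_zone `c(center, half_width)` along the x (spindle) axis,
#'   nm: filaments whose midpoint lies inside get the antiparallel
#'   assignment.
#' @param antiparallel_fraction Fraction of in-zone filaments whose plus
#'   end points along -x (assigned as an exact count, shuffled by seed).
#' @param volume Optional bounding box `c(xmin, xmax, ymin, ymax, zmin,
#'   zmax)` (nm); defaults to a tight box with 50 nm margins. An error is
#'   raised if the requested layout cannot fit.
#' @param jitter SD (nm) of the lattice jitter applied to pair base
#'   positions (not to the exact intra-pair spacing).
#' @param pair_pitch Lattice pitch between pair bases (nm); keep well above
#'   the interaction threshold so pairs do not interact across the lattice.
#' @param point_step Spacing of traced points along each filament (nm).
#' @param seed Integer seed; regeneration is bit-identical.
#' @return List with `network` (a [filament_network()]) and `truth` (list
#'   with the generator name, seed, parameters and a per-filament tibble of
#'   directions, pair ids, designed spacings and overlap lengths).
#' @export
make_filament_network <- function(n = 20, length_dist = c(800, 100),
                                  spacing = 50,
                                  overlap_zone = c(0, 1000),
                                  antiparallel_fraction = 0.5,
                                  volume = NULL, jitter = 0,
                                  pair_pitch = 500, point_step = 100,
                                  seed = 1) {
  stopifnot(spacing > 0, length_dist[1] > 0, n >= 1)
  withr::with_seed(seed, {
    n_pairs <- ceiling(n / 2)
    side <- ceiling(sqrt(n_pairs))
    base_y <- rep(seq_len(side), length.out = n_pairs) * pair_pitch
    base_z <- rep(seq_len(side), each = side)[seq_len(n_pairs)] * pair_pitch
    base_y <- base_y + stats::rnorm(n_pairs, 0, jitter)
    base_z <- base_z + stats::rnorm(n_pairs, 0, jitter)
    lens <- pmax(abs(stats::rnorm(n_pairs, length_dist[1], length_dist[2])),
                 point_step)
    phi <- stats::runif(n_pairs, 0, 2 * pi)  # intra-pair offset direction

    pts <- list()
    fil <- 0L
    truth_rows <- list()
    for (p in seq_len(n_pairs)) {
      x0 <- overlap_zone[1] - lens[p] / 2
      xs <- seq(x0, x0 + lens[p], by = point_step)
      if (xs[length(xs)] < x0 + lens[p]) xs <- c(xs, x0 + lens[p])
      members <- if (2L * p <= n) 1:2 else 1L
      for (m in members) {
        fil <- fil + 1L
        off <- if (m == 1) c(0, 0) else spacing * c(cos(phi[p]), sin(phi[p]))
        pts[[fil]] <- tibble::tibble(
          filament_id = fil, x = xs,
          y = base_y[p] + off[1], z = base_z[p] + off[2]
        )
        truth_rows[[fil]] <- tibble::tibble(
          filament_id = fil, pair_id = p,
          designed_spacing_nm = if (length(members) == 2) spacing else NA_real_,
          designed_overlap_nm = if (length(members) == 2) lens[p] else NA_real_
        )
      }
    }
    pts <- dplyr::bind_rows(pts)
    truth_fil <- dplyr::bind_rows(truth_rows)

    mid_x <- (overlap_zone[1])  # all filaments are centered on the zone center
    in_zone <- rep(abs(mid_x - overlap_zone[1]) <= overlap_zone[2], fil)
    n_zone <- sum(in_zone)
    n_flip <- round(antiparallel_fraction * n_zone)
    flip <- rep(FALSE, fil)
    if (n_zone > 0 && n_flip > 0) {
      flip[sample(which(in_zone), n_flip)] <- TRUE
    }
    # plus end at the traced end (+x) for parallel, at the start for flipped
    plus_end <- tibble::tibble(
      filament_id = seq_len(fil),
      plus_end = ifelse(flip, "start", "end")
    )
    truth_fil$direction <- ifelse(flip, -1, 1)

    if (is.null(volume)) {
      volume <- c(xmin = min(pts$x) - 50, xmax = max(pts$x) + 50,
                  ymin = min(pts$y) - 50, ymax = max(pts$y) + 50,
                  zmin = min(pts$z) - 50, zmax = max(pts$z) + 50)
    } else {
      fits <- min(pts$x) >= volume["xmin"] & max(pts$x) <= volume["xmax"] &
        min(pts$y) >= volume["ymin"] & max(pts$y) <= volume["ymax"] &
        min(pts$z) >= volume["zmin"] & max(pts$z) <= volume["zmax"]
      if (!fits) {
        rlang::abort("volume too small for the requested layout (n, spacing, lengths)")
      }
    }
    net <- filament_network(pts, volume = volume, plus_end = plus_end,
                            label = "synthetic")
    list(network = net,
         truth = list(generator = "make_filament_network", seed = seed,
                      parameters = list(n = n, length_dist = length_dist,
                                        spacing = spacing,
                                        overlap_zone = overlap_zone,
                                        antiparallel_fraction = antiparallel_fraction,
                                        jitter = jitter,
                                        pair_pitch = pair_pitch,
                                        point_step = point_step),
                      filaments = truth_fil))
  })
}

#' Random straight-filament benchmark networks
#'
#' Uniformly placed straight filaments with isotropic random orientations,
#' used to exercise the interaction and nearest-neighbor machinery against
#' brute-force oracles.
#'
#' @param n Number of filaments.
#' @param box Edge length of the cubic volume (nm) holding the filament
#'   midpoints.
#' @param length_dist `c(mean, sd)` of filament length (nm).
#' @param point_step Traced point spacing (nm).
#' @param seed Integer seed.
#' @return A [filament_network()].
#' @export
make_random_filaments <- function(n = 20, box = 1500,
                                  length_dist = c(500, 150),
                                  point_step = 60, seed = 1) {
  withr::with_seed(seed, {
    pts <- list()
    for (i in seq_len(n)) {
      len <- max(abs(stats::rnorm(1, length_dist[1], length_dist[2])), 2 * point_step)
      ctr <- stats::runif(3, 0, box)
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      s <- seq(-len / 2, len / 2, by = point_step)
      if (s[length(s)] < len / 2) s <- c(s, len / 2)
      pts[[i]] <- tibble::tibble(
        filament_id = i,
        x = ctr[1] + s * u[1], y = ctr[2] + s * u[2], z = ctr[3] + s * u[3]
      )
    }
    pts <- dplyr::bind_rows(pts)
    filament_network(pts, label = "random benchmark")
  })
}

#' Synthetic two-channel mitosis movie with kinematic ground truth
#'
#' Renders a one-cell embryo movie: a dim elliptical embryo plus two
#' Gaussian spindle-pole blobs (spindle channel) and chromatin masses (dna
#' channel). Before anaphase onset the chromatin is a single plate at the
#' midzone; at onset it splits into two masses whose center separation
#' starts at `initial_sep` and grows at `segregation_rate`, while the
#' pole-pole distance grows at `elongation_rate`. Poles oscillate
#' transversely in antiphase. Noise is Gaussian read noise plus
#' signal-proportional (shot-like) noise. All trajectories and the onset
#' frame are recorded as ground truth.
#'
#' @param n_frames Number of frames.
#' @param dt Frame interval (s).
#' @param px Pixel size (um/px).
#' @param dims Image size `c(ny, nx)` in px.
#' @param pole_dist0 Metaphase pole-pole distance (um).
#' @param elongation_rate Pole-separation rate after onset (um/s).
#' @param segregation_rate Chromosome-separation rate after onset (um/s).
#' @param onset_frame Last frame (1-based) before chromosome segregation.
#' @param initial_sep Chromatid center separation in the first segregating
#'   frame (um); anaphase onset is abrupt.
#' @param oscillation `c(amplitude_um, period_s)` of transverse pole
#'   oscillation.
#' @param angle_deg Orientation of the spindle axis in the image plane.
#' @param psf_sd Pole blob SD (px).
#' @param chrom_sd `c(axial, transverse)` chromatin mass SD (um).
#' @param noise_sd Read-noise SD (counts).
#' @param shot_scale Scale of the signal-proportional noise component.
#' @param seed Integer seed.
#' @return List with `movie` (an 8-bit [embryo_movie()]) and `truth` (pole
#'   and chromatin trajectories per frame, rates, onset frame, parameters).
#' @export
make_mitosis_movie <- function(n_frames = 80, dt = 1, px = 0.2,
                               dims = c(160, 280), pole_dist0 = 15.4,
                               elongation_rate = 0.09,
                               segregation_rate = 0.13,
                               onset_frame = 25, initial_sep = 2,
                               oscillation = c(0.3, 30), angle_deg = 0,
                               psf_sd = 2, chrom_sd = c(0.5, 1.5),
                               noise_sd = 2, shot_scale = 0.05, seed = 1) {
  ny <- dims[1]; nx <- dims[2]
  ctr <- c(x = (nx + 1) / 2, y = (ny + 1) / 2)
  theta <- angle_deg * pi / 180
  u <- c(cos(theta), sin(theta))       # spindle axis, px coords
  v <- c(-sin(theta), cos(theta))      # transverse
  times <- (seq_len(n_frames) - 1) * dt
  t_on <- (onset_frame - 1) * dt       # time of the last pre-anaphase frame

  pole_dist <- pole_dist0 + elongation_rate * pmax(0, times - t_on)
  chrom_sep <- ifelse(times > t_on,
                      initial_sep + segregation_rate * (times - t_on), 0)
  osc <- oscillation[1] * sin(2 * pi * times / oscillation[2])

  # trajectories in um relative to the image center
  half <- pole_dist / 2
  pa <- cbind(-half * u[1] + osc * v[1], -half * u[2] + osc * v[2])
  pb <- cbind(half * u[1] - osc * v[1], half * u[2] - osc * v[2])
  ca <- cbind(-chrom_sep / 2 * u[1], -chrom_sep / 2 * u[2])
  cb <- cbind(chrom_sep / 2 * u[1], chrom_sep / 2 * u[2])

  to_px <- function(m) cbind(ctr["x"] + m[, 1] / px, ctr["y"] + m[, 2] / px)
  pa_px <- to_px(pa); pb_px <- to_px(pb)
  ca_px <- to_px(ca); cb_px <- to_px(cb)
  if (any(c(pa_px[, 1], pb_px[, 1]) < 3 | c(pa_px[, 1], pb_px[, 1]) > nx - 2) ||
      any(c(pa_px[, 2], pb_px[, 2]) < 3 | c(pa_px[, 2], pb_px[, 2]) > ny - 2)) {
    rlang::abort("poles leave the field of view; enlarge `dims` or shorten the movie")
  }

  X <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  Y <- matrix(rep(seq_len(ny), times = nx), ny, nx)
  blob <- function(cx, cy, sdx_px, sdy_px, amp, ux = u, vx = v) {
    dx <- X - cx; dy <- Y - cy
    along <- dx * ux[1] + dy * ux[2]
    across <- dx * vx[1] + dy * vx[2]
    amp * exp(-along^2 / (2 * sdx_px^2) - across^2 / (2 * sdy_px^2))
  }
  ell <- 30 * ((X - ctr["x"])^2 / (0.45 * nx)^2 +
                 (Y - ctr["y"])^2 / (0.45 * ny)^2 < 1)

  raw <- array(0, dim = c(n_frames, 2, ny, nx))
  withr::with_seed(seed, {
    for (t in seq_len(n_frames)) {
      sp <- ell +
        blob(pa_px[t, 1], pa_px[t, 2], psf_sd, psf_sd, 230) +
        blob(pb_px[t, 1], pb_px[t, 2], psf_sd, psf_sd, 230)
      if (chrom_sep[t] > 0) {
        dn <- blob(ca_px[t, 1], ca_px[t, 2], chrom_sd[1] / px, chrom_sd[2] / px, 220) +
          blob(cb_px[t, 1], cb_px[t, 2], chrom_sd[1] / px, chrom_sd[2] / px, 220)
      } else {
        dn <- blob(ctr["x"], ctr["y"], chrom_sd[1] / px, chrom_sd[2] / px, 220)
      }
      if (noise_sd > 0 || shot_scale > 0) {
        sp <- sp + stats::rnorm(length(sp), 0, noise_sd + shot_scale * sqrt(pmax(sp, 0)))
        dn <- dn + stats::rnorm(length(dn), 0, noise_sd + shot_scale * sqrt(pmax(dn, 0)))
      }
      raw[t, 1, , ] <- pmax(sp, 0)
      raw[t, 2, , ] <- pmax(dn, 0)
    }
  })
  movie <- suppressWarnings(
    to_eight_bit(raw, channels = c(spindle = 1, dna = 2), pixel_size = px,
                 frame_interval = dt)
  )
  truth <- list(
    generator = "make_mitosis_movie", seed = seed,
    parameters = list(n_frames = n_frames, dt = dt, px = px, dims = dims,
                      pole_dist0 = pole_dist0,
                      elongation_rate = elongation_rate,
                      segregation_rate = segregation_rate,
                      onset_frame = onset_frame, initial_sep = initial_sep,
                      oscillation = oscillation, angle_deg = angle_deg),
    onset_frame = onset_frame,
    elongation_rate = elongation_rate,
    segregation_rate = segregation_rate,
    frames = tibble::tibble(
      frame = seq_len(n_frames), time_s = times,
      pole_dist_um = pole_dist, chrom_sep_um = chrom_sep,
      pole_a_x = pa_px[, 1], pole_a_y = pa_px[, 2],
      pole_b_x = pb_px[, 1], pole_b_y = pb_px[, 2],
      osc_um = osc
    )
  )
  list(movie = movie, truth = truth)
}

#' Synthetic SHG/TP image pair from a designed spindle
#'
#' Builds a density map (an elongated spindle between two poles) and a
#' polarity map with a designed central antiparallel dip, then renders the
#' image pair through [shg_tp_forward()].
#'
#' @param dims Image size `c(ny, nx)` px.
#' @param pixel_size Pixel size (um/px).
#' @param density_peak Peak density (arbitrary units).
#' @param spindle_halflength Axial half-length of the density envelope (um).
#' @param spindle_sd_um Transverse density SD (um).
#' @param dip_width_um Full width at half depth of the central polarity dip
#'   (um).
#' @param dip_depth Depth of the dip (1 = polarity reaches 0 at center).
#' @param dip_shape `"gaussian"` or `"rect"`.
#' @param alpha,beta,noise_sd,seed Passed to [shg_tp_forward()].
#' @return List with `pair` (an `shg_tp_pair`), `density`, `polarity`
#'   (ground-truth maps) and `truth` (parameters incl. the designed width).
#' @export
make_shg_tp_pair <- function(dims = c(80, 200), pixel_size = 0.1,
                             density_peak = 100, spindle_halflength = 7,
                             spindle_sd_um = 1.5, dip_width_um = 4,
                             dip_depth = 1, dip_shape = c("gaussian", "rect"),
                             alpha = 1, beta = 1, noise_sd = 0, seed = 1) {
  dip_shape <- match.arg(dip_shape)
  ny <- dims[1]; nx <- dims[2]
  xc <- (nx + 1) / 2; yc <- (ny + 1) / 2
  x_um <- (matrix(rep(seq_len(nx), each = ny), ny, nx) - xc) * pixel_size
  y_um <- (matrix(rep(seq_len(ny), times = nx), ny, nx) - yc) * pixel_size
  axial <- exp(-pmax(0, abs(x_um) - spindle_halflength)^2 / (2 * 1^2))
  density <- density_peak * axial * exp(-y_um^2 / (2 * spindle_sd_um^2))
  if (dip_shape == "gaussian") {
    sigma <- dip_width_um / (2 * sqrt(2 * log(2)))
    polarity <- 1 - dip_depth * exp(-x_um^2 / (2 * sigma^2))
  } else {
    polarity <- ifelse(abs(x_um) < dip_width_um / 2, 1 - dip_depth, 1)
  }
  pair <- shg_tp_forward(density, polarity, alpha = alpha, beta = beta,
                         noise_sd = noise_sd, seed = seed,
                         pixel_size = pixel_size)
  list(pair = pair, density = density, polarity = polarity,
       truth = list(generator = "make_shg_tp_pair", seed = seed,
                    parameters = list(dims = dims, pixel_size = pixel_size,
                                      dip_width_um = dip_width_um,
                                      dip_depth = dip_depth,
                                      dip_shape = dip_shape,
                                      alpha = alpha, beta = beta,
                                      noise_sd = noise_sd),
                    dip_width_um = dip_width_um,
                    center_px = c(x = xc, y = yc)))
}

#' Synthetic EB-comet kymograph with a known event count
#'
#' Draws `n_comets` diagonal comet traces (constant growth speed) on a
#' space-time image, enforcing a minimum separation between traces, plus
#' background and Gaussian noise.
#'
#' @param n_comets Number of comet traces.
#' @param n_frames,length_px Kymograph size (rows = time, cols = space);
#'   the defaults span exactly the standard 4.5 um x 100 s analysis window
#'   (45 px at 0.1 um/px, 100 rows at 1 s), so every generated comet falls
#'   inside the counted segment.
#' @param pixel_size um/px; `frame_interval` s/row.
#' @param frame_interval Frame interval (s).
#' @param speed Comet speed (px/frame).
#' @param comet_frames Lifetime of each comet (frames).
#' @param min_separation Minimum separation between any two trace points
#'   (px, in the kymograph plane).
#' @param amplitude,background,noise_sd Intensity parameters.
#' @param seed Integer seed.
#' @return List with `kymograph` (a `kymograph` object) and `truth`
#'   (`n_comets`, trace start points, parameters). Errors if the requested
#'   count cannot be placed at the requested separation.
#' @export
make_comet_kymograph <- function(n_comets = 7, n_frames = 100,
                                 length_px = 45, pixel_size = 0.1,
                                 frame_interval = 1, speed = 0.3,
                                 comet_frames = 15, min_separation = 5,
                                 amplitude = 100, background = 10,
                                 noise_sd = 0, seed = 1) {
  withr::with_seed(seed, {
    starts <- matrix(numeric(0), 0, 2)  # (t0, x0)
    tries <- 0
    while (nrow(starts) < n_comets) {
      tries <- tries + 1
      if (tries > 2000) {
        rlang::abort("cannot place the requested comets at this separation")
      }
      t0 <- stats::runif(1, 1, n_frames - comet_frames)
      x0 <- stats::runif(1, 2, length_px - speed * comet_frames - 2)
      if (nrow(starts) > 0) {
        # conservative separation check on sampled trace points
        tt <- seq(0, comet_frames, by = 0.5)
        new_pts <- cbind(t0 + tt, x0 + speed * tt)
        ok <- TRUE
        for (j in seq_len(nrow(starts))) {
          old_pts <- cbind(starts[j, 1] + tt, starts[j, 2] + speed * tt)
          dmin <- min(sqrt(outer(new_pts[, 1], old_pts[, 1], "-")^2 +
                             outer(new_pts[, 2], old_pts[, 2], "-")^2))
          if (dmin < min_separation) { ok <- FALSE; break }
        }
        if (!ok) next
      }
      starts <- rbind(starts, c(t0, x0))
    }
    img <- matrix(background, n_frames, length_px)
    for (j in seq_len(nrow(starts))) {
      for (f in 0:comet_frames) {
        t <- round(starts[j, 1] + f)
        x <- starts[j, 2] + speed * f
        if (t < 1 || t > n_frames) next
        xs <- max(1, floor(x)):min(length_px, ceiling(x))
        img[t, xs] <- img[t, xs] + amplitude * exp(-(xs - x)^2 / (2 * 0.6^2))
      }
    }
    if (noise_sd > 0) {
      img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                          n_frames, length_px)
    }
  })
  k <- structure(list(image = img, band_halfwidth = NA_integer_,
                      valid = rep(TRUE, n_frames), pixel_size = pixel_size,
                      frame_interval = frame_interval),
                 class = "kymograph")
  list(kymograph = k,
       truth = list(generator = "make_comet_kymograph", seed = seed,
                    n_comets = n_comets, starts = starts,
                    parameters = list(n_frames = n_frames,
                                      length_px = length_px, speed = speed,
                                      comet_frames = comet_frames,
                                      min_separation = min_separation,
                                      amplitude = amplitude,
                                      background = background,
                                      noise_sd = noise_sd)))
}

#' Synthetic FRAP curve with known recovery fraction and rate
#'
#' @param fraction True mobile (recovery) fraction.
#' @param k True recovery rate (1/s).
#' @param prebleach Prebleach intensity.
#' @param bleach_depth Fraction of the prebleach signal removed by the
#'   bleach (`F0 = prebleach * (1 - bleach_depth)`).
#' @param t_max,dt Post-bleach sampling (s).
#' @param n_pre Number of prebleach points.
#' @param noise_sd Gaussian noise SD (same units as intensity).
#' @param seed Integer seed.
#' @return List with `curve` (a [frap_curve()]) and `truth`.
#' @export
make_frap_curve <- function(fraction = 0.34, k = 0.05, prebleach = 1,
                            bleach_depth = 0.8, t_max = 120, dt = 0.25,
                            n_pre = 8, noise_sd = 0, seed = 1) {
  f0 <- prebleach * (1 - bleach_depth)
  finf <- f0 + fraction * (prebleach - f0)
  t_post <- seq(0, t_max, by = dt)
  t_pre <- seq(-n_pre * dt, -dt, by = dt)
  val <- c(rep(prebleach, length(t_pre)),
           f0 + (finf - f0) * (1 - exp(-k * t_post)))
  if (noise_sd > 0) {
    withr::with_seed(seed, {
      val <- val + stats::rnorm(length(val), 0, noise_sd)
    })
  }
  curve <- frap_curve(c(t_pre, t_post), val, prebleach = prebleach)
  list(curve = curve,
       truth = list(generator = "make_frap_curve", seed = seed,
                    fraction = fraction, k = k,
                    parameters = list(prebleach = prebleach,
                                      bleach_depth = bleach_depth,
                                      t_max = t_max, dt = dt,
                                      noise_sd = noise_sd)))
}

#' Synthetic single-particle track table
#'
#' Directed tracks with per-track speeds and exponentially distributed run
#' lengths, mimicking processive motor particles on immobilized
#' microtubules.
#'
#' @param n_tracks Number of tracks.
#' @param mean_speed,speed_sd Per-track speed distribution (um/s; truncated
#'   normal).
#' @param mean_run Mean run length (um; exponential).
#' @param dt Frame interval (s).
#' @param mean_intensity,intensity_sd Per-track brightness distribution
#'   (independent of speed).
#' @param transverse_sd Localization jitter perpendicular to the run
#'   direction (um).
#' @param seed Integer seed.
#' @return List with `tracks` (a [track_table()]) and `truth` (per-track
#'   true speeds and run lengths).
#' @export
make_track_table <- function(n_tracks = 200, mean_speed = 0.2,
                             speed_sd = 0.04, mean_run = 2, dt = 0.25,
                             mean_intensity = 1000, intensity_sd = 150,
                             transverse_sd = 0, seed = 1) {
  withr::with_seed(seed, {
    speeds <- pmax(stats::rnorm(n_tracks, mean_speed, speed_sd), 0.02)
    runs <- stats::rexp(n_tracks, 1 / mean_run)
    runs <- pmax(runs, 2 * dt * speeds)  # at least two localizations
    bright <- pmax(stats::rnorm(n_tracks, mean_intensity, intensity_sd), 1)
    rows <- vector("list", n_tracks)
    for (i in seq_len(n_tracks)) {
      n_steps <- max(2, round(runs[i] / (speeds[i] * dt)) + 1)
      ang <- stats::runif(1, 0, 2 * pi)
      s <- (seq_len(n_steps) - 1) * speeds[i] * dt
      perp <- if (transverse_sd > 0) stats::rnorm(n_steps, 0, transverse_sd) else 0
      x0 <- stats::runif(1, 0, 50); y0 <- stats::runif(1, 0, 50)
      rows[[i]] <- tibble::tibble(
        track_id = i,
        frame = seq_len(n_steps),
        time_s = (seq_len(n_steps) - 1) * dt,
        x_um = x0 + s * cos(ang) - perp * sin(ang),
        y_um = y0 + s * sin(ang) + perp * cos(ang),
        intensity = bright[i] + stats::rnorm(n_steps, 0, 0.02 * bright[i])
      )
    }
    tracks <- track_table(dplyr::bind_rows(rows))
  })
  list(tracks = tracks,
       truth = list(generator = "make_track_table", seed = seed,
                    speeds = speeds, run_lengths = runs,
                    parameters = list(n_tracks = n_tracks,
                                      mean_speed = mean_speed,
                                      speed_sd = speed_sd,
                                      mean_run = mean_run, dt = dt)))
}

#' Synthetic bait-prey co-appearance log
#'
#' @param n_bait Number of captured bait molecules.
#' @param fraction True co-appearance probability (not percent).
#' @param seed Integer seed.
#' @return List with `log` (tibble with `bait_event_id`, `has_prey`) and
#'   `truth`.
#' @export
make_coappearance_log <- function(n_bait = 10000, fraction = 0.01, seed = 1) {
  stopifnot(n_bait > 0, fraction >= 0, fraction <= 1)
  withr::with_seed(seed, {
    log <- tibble::tibble(
      bait_event_id = seq_len(n_bait),
      has_prey = stats::runif(n_bait) < fraction
    )
  })
  list(log = log,
       truth = list(generator = "make_coappearance_log", seed = seed,
                    fraction = fraction,
                    parameters = list(n_bait = n_bait, fraction = fraction)))
}

#' Published condition presets
#'
#' Condition-level summary scales (control and RNAi depletions) carried as
#' documented defaults for the synthetic generators: midzone microtubule
#' density and mean length, mean inter-microtubule distance, overlap
#' length, spindle elongation and chromosome segregation rates, and FRAP
#' recovery fraction. These are preset scales for simulation design, not
#' data; recovering a preset from synthetic data never validates the preset
#' itself.
#'
#' @return A tibble, one row per condition.
#' @export
midzone_presets <- function() {
  tibble::tribble(
    ~condition,      ~density_per_um3, ~mean_length_um, ~mean_distance_nm,
    ~overlap_um, ~elongation_um_s, ~segregation_um_s, ~frap_fraction,
    "control",       3.1,  0.88, 71, 0.42, 0.09,  0.13, 0.34,
    "klp-19",        4.3,  1.15, 62, 0.50, 0.07,  0.08, 0.23,
    "spd-1",         NA,   NA,   NA, NA,   0.30,  0.23, NA,
    "spd-1/gpr-1/2", NA,   NA,   NA, NA,   0.059, 0.11, NA,
    "klp-19/spd-1",  NA,   NA,   NA, NA,   0.08,  0.10, NA
  )
}
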