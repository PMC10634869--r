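#' Microtubule polarity of a network region
#'
#' Polarity of an array of oriented microtubules in a focal region:
#' `|n_plus - n_minus| / (n_plus + n_minus)`, where `n_plus` counts
#' filaments whose plus end points along the reference axis (positive dot
#' product) and `n_minus` the rest. 1 = all plus ends parallel, 0 = balanced
#' antiparallel. Invariant under a sign flip of the axis and under filament
#' permutation.
#'
#' @param network A [filament_network()]; every filament intersecting the
#'   region must carry a plus-end annotation.
#' @param region Optional named vector `c(xmin, xmax, ymin, ymax, zmin,
#'   zmax)` (nm); filaments with any point inside are counted. `NULL` uses
#'   the whole network.
#' @param axis Reference axis direction (length-3), default +x (the spindle
#'   axis convention).
#' @return Polarity in \[0, 1\], or `NA` if the region contains no
#'   filaments (undefined, not 0).
#' @export
network_polarity <- function(network, region = NULL, axis = c(1, 0, 0)) {
  ids <- network$filaments$filament_id
  if (!is.null(region)) {
    pts <- network$points
    inside <- pts$x >= region["xmin"] & pts$x <= region["xmax"] &
      pts$y >= region["ymin"] & pts$y <= region["ymax"] &
      pts$z >= region["zmin"] & pts$z <= region["zmax"]
    ids <- unique(pts$filament_id[inside])
  }
  if (length(ids) == 0) return(NA_real_)
  ori <- filament_orientations(network)
  ori <- ori[ori$filament_id %in% ids, ]
  if (anyNA(ori$px)) {
    rlang::abort("all filaments in the region must carry a plus-end annotation")
  }
  dot <- ori$px * axis[1] + ori$py * axis[2] + ori$pz * axis[3]
  n_plus <- sum(dot > 0)
  n_minus <- sum(dot <= 0)
  abs(n_plus - n_minus) / (n_plus + n_minus)
}

#' Forward model: SHG and two-photon images from density and polarity
#'
#' A declared minimal forward model for simultaneous second-harmonic
#' generation (SHG) and two-photon (TP) imaging of a microtubule array: the
#' TP fluorescence reads out density, `TP = alpha * rho`, while the coherent
#' SHG signal depends on both density and polarity, `SHG = beta * (rho *
#' P)^2`. Gaussian noise of standard deviation `noise_sd` is added to both
#' images. The calibration constant `kappa = beta / alpha^2` makes the
#' inversion `P = sqrt(SHG / (kappa * TP^2))` exact on noiseless input. The
#' quadratic law is an assumption of this package, isolated here so a
#' different calibration can be substituted.
#'
#' @param density_map Matrix of non-negative densities (rows = y, cols = x).
#' @param polarity_map Matrix of polarities in \[0, 1\], same shape.
#' @param alpha,beta Positive gain constants.
#' @param noise_sd Gaussian noise SD added to both images (0 = noiseless).
#' @param seed Integer seed; the call is deterministic given the seed.
#' @param pixel_size Pixel size in um.
#' @return An object of class `shg_tp_pair`: list with `shg`, `tp`,
#'   `pixel_size` and `kappa`.
#' @export
shg_tp_forward <- function(density_map, polarity_map, alpha = 1, beta = 1,
                           noise_sd = 0, seed = 1, pixel_size = 0.1) {
  stopifnot(all(dim(density_map) == dim(polarity_map)),
            alpha > 0, beta > 0, pixel_size > 0)
  if (any(density_map < 0)) rlang::abort("density must be non-negative")
  if (any(polarity_map < 0 | polarity_map > 1)) {
    rlang::abort("polarity must lie in [0, 1]")
  }
  tp <- alpha * density_map
  shg <- beta * (density_map * polarity_map)^2
  if (noise_sd > 0) {
    withr::with_seed(seed, {
      tp <- tp + matrix(stats::rnorm(length(tp), 0, noise_sd), nrow(tp))
      shg <- shg + matrix(stats::rnorm(length(shg), 0, noise_sd), nrow(shg))
    })
  }
  structure(list(shg = shg, tp = tp, pixel_size = pixel_size,
                 kappa = beta / alpha^2),
            class = "shg_tp_pair")
}

#' Invert an SHG/TP image pair to a polarity map
#'
#' `P = clip(sqrt(SHG / (kappa * TP^2)), 0, 1)` wherever the TP (density)
#' signal exceeds `tp_floor`; pixels at or below the floor are masked
#' (`NA`) rather than zero-filled, to avoid spurious polarity where there is
#' no microtubule density.
#'
#' @param pair An `shg_tp_pair` (from [shg_tp_forward()] or built from
#'   measured images).
#' @param tp_floor Positive TP intensity floor.
#' @param kappa Calibration constant; defaults to the one stored on the
#'   pair (see [calibrate_kappa()]).
#' @return Matrix of polarities in \[0, 1\] with `NA` where masked.
#' @export
polarity_from_images <- function(pair, tp_floor = 1e-3, kappa = pair$kappa) {
  if (is.null(kappa) || !is.finite(kappa) || kappa <= 0) {
    rlang::abort("`kappa` must be a positive scalar; calibrate it first")
  }
  if (tp_floor <= 0) rlang::abort("`tp_floor` must be > 0")
  p <- sqrt(pmax(pair$shg, 0) / (kappa * pair$tp^2))
  p <- pmin(pmax(p, 0), 1)
  p[pair$tp <= tp_floor] <- NA_real_
  p
}

#' Calibrate the SHG/TP constant from a fully parallel reference region
#'
#' Assuming the reference region contains fully parallel microtubules
#' (P = 1), `kappa` is the median of `SHG / TP^2` over the unmasked pixels
#' of the region; the median is robust to outliers.
#'
#' @param pair An `shg_tp_pair`.
#' @param reference_region Named vector `c(xmin, xmax, ymin, ymax)` in pixel
#'   indices (1-based, inclusive).
#' @param tp_floor TP floor below which pixels are ignored.
#' @return The scalar kappa.
#' @export
calibrate_kappa <- function(pair, reference_region, tp_floor = 1e-3) {
  r <- reference_region
  rows <- seq(max(1, r["ymin"]), min(nrow(pair$tp), r["ymax"]))
  cols <- seq(max(1, r["xmin"]), min(ncol(pair$tp), r["xmax"]))
  tp <- pair$tp[rows, cols]
  shg <- pair$shg[rows, cols]
  ok <- tp > tp_floor
  if (!any(ok)) rlang::abort("reference region contains no usable pixels")
  stats::median(shg[ok] / tp[ok]^2)
}

#' Axial polarity (or intensity) profile
#'
#' Averages a 2D map over slabs perpendicular to the spindle axis. Pixel
#' centers are projected onto the axis; positions are reported in um
#' relative to the given center (0 = spindle center). Masked (`NA`) pixels
#' are excluded from slab averages.
#'
#' @param map Matrix (rows = y, cols = x), e.g. from
#'   [polarity_from_images()].
#' @param axis Two distinct points `list(p1 = c(x, y), p2 = c(x, y))` in
#'   pixel coordinates defining the axis (e.g. the pole centers).
#' @param center Point `c(x, y)` in pixel coordinates projected to position
#'   0 (e.g. the spindle center).
#' @param bin Slab width in um.
#' @param pixel_size Pixel size in um.
#' @return A tibble of class `polarity_profile` with `position_um` (slab
#'   centers, strictly increasing) and `polarity` (slab means; `NaN` slabs
#'   are dropped).
#' @export
axial_profile <- function(map, axis, center, bin = 0.2, pixel_size = 0.1) {
  stopifnot(bin > 0, pixel_size > 0)
  u <- axis$p2 - axis$p1
  if (sqrt(sum(u^2)) == 0) rlang::abort("degenerate axis: the two points coincide")
  u <- u / sqrt(sum(u^2))
  xc <- (col(map) - center[1]) * pixel_size
  yc <- (row(map) - center[2]) * pixel_size
  pos <- xc * u[1] + yc * u[2]
  keep <- !is.na(map)
  idx <- floor(pos[keep] / bin + 0.5)
  vals <- map[keep]
  agg <- tapply(vals, idx, mean)
  out <- tibble::tibble(
    position_um = as.numeric(names(agg)) * bin,
    polarity = as.numeric(agg)
  )
  out <- out[order(out$position_um), ]
  class(out) <- c("polarity_profile", class(out))
  out
}

#' Width of the central polarity dip
#'
#' The antiparallel overlap region appears as a central dip in the axial
#' polarity profile. Its width is measured as the full width of the dip at
#' a depth fraction `level` between the flanking plateau value and the
#' minimum (level 0.5 = full width at half depth), with linear interpolation
#' between samples. The plateau is the smaller of the maxima on the two
#' flanks of the minimum. Invariant under uniform scaling of the polarity
#' values and translation of the positions.
#'
#' @param profile A `polarity_profile` (tibble with `position_um`,
#'   `polarity`), or any data frame with those columns.
#' @param level Depth fraction in (0, 1) at which the width is read off.
#' @return Width in um.
#' @export
overlap_width <- function(profile, level = 0.5) {
  pos <- profile$position_um
  val <- profile$polarity
  ok <- is.finite(val)
  pos <- pos[ok]; val <- val[ok]
  if (length(val) < 3) rlang::abort("profile too short to measure a width")
  imin <- which.min(val)
  if (imin == 1 || imin == length(val)) {
    rlang::abort("no central dip: the profile minimum lies on the boundary")
  }
  plateau <- min(max(val[1:imin]), max(val[imin:length(val)]))
  depth <- plateau - val[imin]
  if (depth <= 0) rlang::abort("no central dip: the profile is flat or monotone")
  target <- plateau - level * depth
  left <- crossing_position(pos, val, target, seq(imin, 1), rising = TRUE)
  right <- crossing_position(pos, val, target, seq(imin, length(val)), rising = TRUE)
  right - left
}

# first position, walking outward from the dip along `order_idx`, where the
# profile crosses `target` (linear interpolation between samples)
crossing_position <- function(pos, val, target, order_idx, rising = TRUE) {
  prev <- order_idx[1]
  for (i in order_idx[-1]) {
    if (val[i] >= target && val[prev] < target) {
      f <- (target - val[prev]) / (val[i] - val[prev])
      return(pos[prev] + f * (pos[i] - pos[prev]))
    }
    prev <- i
  }
  pos[order_idx[length(order_idx)]]
}

#' Export a polarity (or intensity) profile as CSV
#'
#' @param profile A profile tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}
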