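#' Minimum distance between two 3D segments
#'
#' Exact (analytic) minimum Euclidean distance between two closed segments;
#' degenerate point-segments are handled as points.
#'
#' @param a,b 2 x 3 matrices (rows = the two segment endpoints, nm).
#' @return Distance in nm.
#' @export
segment_min_distance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  cpp_seg_seg_dist(a[1, ], a[2, ], b[1, ], b[2, ])
}

#' Minimum distance between two filaments
#'
#' The distance between two microtubules is the minimum over all pairs of
#' their line segments of the exact segment-segment distance.
#'
#' @param f,g Point matrices (n x 3, nm) or single-filament point tibbles
#'   with columns `x`, `y`, `z`.
#' @return Distance in nm.
#' @export
filament_pair_distance <- function(f, g) {
  cpp_polyline_min_dist(as_point_matrix(f), as_point_matrix(g))
}

as_point_matrix <- function(f) {
  if (is.matrix(f)) return(f)
  if (is.data.frame(f)) return(cbind(f$x, f$y, f$z))
  rlang::abort("expected an n x 3 matrix or a data frame with x,y,z")
}

#' Angle between two filaments
#'
#' To be robust to local tracing distortions the angle is measured between
#' the end-to-end lines (start point to end point) of the two filaments, in
#' degrees in \[0, 180\]: 0 = parallel with the same traced orientation,
#' 180 = antiparallel. Use `fold = TRUE` for an orientation-agnostic angle
#' in \[0, 90\].
#'
#' @param f,g Point matrices (n x 3, nm) or data frames with `x,y,z`.
#' @param fold Fold the angle into \[0, 90\] (orientation-agnostic)?
#' @return Angle in degrees.
#' @export
interaction_angle <- function(f, g, fold = FALSE) {
  u <- end_to_end(as_point_matrix(f))
  v <- end_to_end(as_point_matrix(g))
  cosang <- sum(u * v)
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  if (fold && ang > 90) ang <- 180 - ang
  ang
}

end_to_end <- function(m) {
  d <- m[nrow(m), ] - m[1, ]
  n <- sqrt(sum(d^2))
  if (n == 0) rlang::abort("undefined angle: filament start and end points coincide")
  d / n
}

#' Resample a polyline at uniform arc-length steps
#'
#' @param m Point matrix (n x 3).
#' @param step Arc-length step (nm). The end point is always included.
#' @return List with `points` (matrix) and `arc` (arc-length positions, nm).
#' @keywords internal
resample_polyline <- function(m, step) {
  seg <- sqrt(rowSums((m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2))
  arc <- c(0, cumsum(seg))
  total <- arc[length(arc)]
  s <- seq(0, total, by = step)
  if (total - s[length(s)] > 1e-9) s <- c(s, total)
  pts <- cbind(
    stats::approx(arc, m[, 1], xout = s)$y,
    stats::approx(arc, m[, 2], xout = s)$y,
    stats::approx(arc, m[, 3], xout = s)$y
  )
  list(points = pts, arc = s, total = total)
}

#' Build a spatial grid index over a filament network
#'
#' A uniform 3D grid over the network's segments. Queries within the cell
#' size only need to touch the 27-neighborhood of a cell, so interaction
#' detection and nearest-neighbor searches return results identical to the
#' brute-force scan while visiting far fewer segment pairs.
#'
#' @param network A [filament_network()].
#' @param cell Cell edge length in nm; choose `cell >= d_max` for
#'   interaction queries (the detection routine enlarges it if needed).
#' @return An object of class `grid_index` carrying the cell size; the grid
#'   itself is rebuilt inside the C++ kernels from the same parameters.
#' @export
grid_index <- function(network, cell = 120) {
  if (cell <= 0) rlang::abort("`cell` must be > 0")
  structure(list(cell = cell, n_filaments = nrow(network$filaments)),
            class = "grid_index")
}

#' Detect interactions between filaments
#'
#' An interaction is a contiguous stretch of one microtubule (the source)
#' lying within a maximum center-to-center distance `d_max` of another (the
#' target), maintained over a minimum arc length `l_min`. Each filament is
#' resampled at a uniform arc step; maximal runs of in-threshold samples
#' become interactions, with run boundaries refined by linear interpolation
#' between the last in-threshold and first out-of-threshold samples. A
#' single out-of-threshold sample splits a run (no gap bridging). No angle
#' restriction is applied.
#'
#' @param network A [filament_network()]; filter with [filter_short()]
#'   first for statistics comparable across reconstructions.
#' @param d_max Maximum center-to-center distance (nm), default 100.
#' @param l_min Minimum interaction length (nm), default 100.
#' @param resample_step Arc resampling step (nm), default 20 (well below the
#'   100 nm thresholds).
#' @param index A [grid_index()], `TRUE` (build one), or `NULL`/`FALSE` for
#'   the brute-force scan. Both paths give identical results.
#' @param mode `"ordered"` (default) reports one record per ordered
#'   (source, target) run, matching a per-microtubule parts analysis;
#'   `"symmetric"` deduplicates to unordered pairs, averaging the two
#'   directions' total run lengths.
#' @return A tibble of class `interaction_table` with columns `source_id`,
#'   `target_id`, `start_nm`, `end_nm`, `length_nm`, `min_distance_nm`,
#'   `angle_deg`.
#' @export
detect_interactions <- function(network, d_max = 100, l_min = 100,
                                resample_step = 20, index = NULL,
                                mode = c("ordered", "symmetric")) {
  mode <- match.arg(mode)
  stopifnot(d_max > 0, l_min >= 0, resample_step > 0)
  empty <- tibble::tibble(
    source_id = integer(), target_id = integer(), start_nm = numeric(),
    end_nm = numeric(), length_nm = numeric(), min_distance_nm = numeric(),
    angle_deg = numeric()
  )
  class(empty) <- c("interaction_table", class(empty))
  ids <- network$filaments$filament_id
  if (length(ids) < 2) return(empty)

  polys <- network_polyline_list(network)
  res <- lapply(polys, resample_polyline, step = resample_step)
  pts <- do.call(rbind, lapply(res, `[[`, "points"))
  pt_fil <- rep.int(seq_along(res), vapply(res, function(r) length(r$arc), integer(1)))
  arcs <- lapply(res, `[[`, "arc")

  use_grid <- !is.null(index) && !isFALSE(index)
  cell <- if (inherits(index, "grid_index")) index$cell else d_max + resample_step
  # reach covers the first out-of-threshold sample next to any in-threshold
  # one (distance along the arc is 1-Lipschitz in the chord), so boundary
  # interpolation sees exact distances in both modes
  reach <- d_max + resample_step + 1e-9
  sp <- cpp_point_filament_dists(pts, pt_fil - 1L, polys, reach,
                                 max(cell, reach), use_grid)

  offsets <- c(0, cumsum(vapply(arcs, length, integer(1))))
  rows <- list()
  if (nrow(sp) > 0) {
    key <- paste(pt_fil[sp$point], sp$filament)
    for (grp in split(seq_len(nrow(sp)), key)) {
      si <- pt_fil[sp$point[grp[1]]]
      ti <- sp$filament[grp[1]]
      arc <- arcs[[si]]
      d <- rep(Inf, length(arc))
      local_idx <- sp$point[grp] - offsets[si]
      d[local_idx] <- sp$distance[grp]
      inside <- d <= d_max
      if (!any(inside)) next
      r <- rle(inside)
      ends_run <- cumsum(r$lengths)
      starts_run <- ends_run - r$lengths + 1
      for (k in which(r$values)) {
        a <- starts_run[k]; b <- ends_run[k]
        if (a > 1 && is.finite(d[a - 1])) {
          t0 <- (d[a - 1] - d_max) / (d[a - 1] - d[a])
          start <- arc[a - 1] + t0 * (arc[a] - arc[a - 1])
        } else start <- arc[a]
        if (b < length(arc) && is.finite(d[b + 1])) {
          t1 <- (d_max - d[b]) / (d[b + 1] - d[b])
          end <- arc[b] + t1 * (arc[b + 1] - arc[b])
        } else end <- arc[b]
        len <- end - start
        if (len < l_min) next
        rows[[length(rows) + 1]] <- tibble::tibble(
          source_id = ids[si], target_id = ids[ti],
          start_nm = start, end_nm = end, length_nm = len,
          min_distance_nm = min(d[a:b]),
          angle_deg = interaction_angle(polys[[si]], polys[[ti]])
        )
      }
    }
  }
  out <- if (length(rows) > 0) dplyr::bind_rows(rows) else empty
  out <- dplyr::arrange(out, .data$source_id, .data$target_id, .data$start_nm)
  if (mode == "symmetric" && nrow(out) > 0) {
    out <- out |>
      dplyr::mutate(
        a = pmin(.data$source_id, .data$target_id),
        b = pmax(.data$source_id, .data$target_id),
        dir_total = 0
      ) |>
      dplyr::group_by(.data$a, .data$b, .data$source_id) |>
      dplyr::mutate(dir_total = sum(.data$length_nm)) |>
      dplyr::group_by(.data$a, .data$b) |>
      dplyr::summarise(
        start_nm = NA_real_, end_nm = NA_real_,
        length_nm = mean(unique_pair_totals(.data$source_id, .data$dir_total)),
        min_distance_nm = min(.data$min_distance_nm),
        angle_deg = .data$angle_deg[1],
        .groups = "drop"
      ) |>
      dplyr::rename(source_id = "a", target_id = "b") |>
      dplyr::select("source_id", "target_id", "start_nm", "end_nm",
                    "length_nm", "min_distance_nm", "angle_deg")
  }
  class(out) <- c("interaction_table", setdiff(class(out), "interaction_table"))
  out
}

unique_pair_totals <- function(source_id, dir_total) {
  vapply(split(dir_total, source_id), `[[`, numeric(1), 1)
}

#' Nearest-neighbor filament distances
#'
#' For each filament, the closest other filament (exact minimum over all
#' segment pairs) and its distance; ties broken toward the smaller id.
#'
#' @param network A [filament_network()] with at least 2 filaments.
#' @param index A [grid_index()], `TRUE`, or `NULL`/`FALSE` (brute force).
#'   The indexed search expands its reach until every filament has found a
#'   neighbour, so both paths return identical tables.
#' @return Tibble with `filament_id`, `nearest_id`, `distance_nm`.
#' @export
nearest_neighbor_distances <- function(network, index = NULL) {
  ids <- network$filaments$filament_id
  if (length(ids) < 2) rlang::abort("need at least 2 filaments")
  polys <- network_polyline_list(network)
  use_grid <- !is.null(index) && !isFALSE(index)
  if (!use_grid) {
    dm <- cpp_pairwise_filament_dists(polys, Inf, FALSE)
  } else {
    reach <- if (inherits(index, "grid_index")) index$cell else 200
    repeat {
      dm <- cpp_pairwise_filament_dists(polys, reach, TRUE)
      dm_off <- dm
      diag(dm_off) <- Inf
      if (all(is.finite(apply(dm_off, 1, min)))) break
      reach <- reach * 2
    }
  }
  diag(dm) <- Inf
  nn <- apply(dm, 1, which.min)  # which.min takes the first (smallest id) on ties
  tibble::tibble(
    filament_id = ids,
    nearest_id = ids[nn],
    distance_nm = dm[cbind(seq_along(ids), nn)]
  )
}

#' Summary statistics for a filament network
#'
#' Density (filaments per um^3 of the bounding volume), length statistics,
#' nearest-neighbor distance statistics, interaction-length statistics and
#' the fraction of interactions falling into center-to-center distance bins.
#' Standard deviations are population SDs (divisor N). The network should
#' already be filtered with [filter_short()].
#'
#' @param network A [filament_network()].
#' @param interactions An `interaction_table` from [detect_interactions()],
#'   or `NULL` to compute one with default parameters.
#' @param bins Upper edges (nm) of the distance bins for interaction
#'   min-distances; an open overflow bin is appended. The default mirrors a
#'   25-100 nm color scale in 15 steps.
#' @return A list of class `network_stats`.
#' @export
network_stats <- function(network, interactions = NULL,
                          bins = seq(25, 100, length.out = 15)) {
  if (is.null(interactions)) interactions <- detect_interactions(network)
  lens <- filament_lengths(network)$length_nm
  n <- length(lens)
  vol <- network_volume_um3(network)
  nn <- if (n >= 2) nearest_neighbor_distances(network)$distance_nm else numeric(0)
  has_int <- nrow(interactions) > 0
  edges <- sort(unique(bins))
  fractions <- NULL
  if (has_int) {
    cuts <- cut(interactions$min_distance_nm, breaks = c(-Inf, edges, Inf))
    fractions <- as.numeric(table(cuts)) / nrow(interactions)
    names(fractions) <- c(sprintf("<=%g", edges), sprintf(">%g", edges[length(edges)]))
  }
  structure(list(
    n_filaments = n,
    volume_um3 = vol,
    density_per_um3 = n / vol,
    mean_length_nm = mean_or_na(lens),
    sd_length_nm = pop_sd(lens),
    mean_nn_distance_nm = mean_or_na(nn),
    sd_nn_distance_nm = pop_sd(nn),
    n_interactions = nrow(interactions),
    mean_interaction_length_nm = if (has_int) mean(interactions$length_nm) else NA_real_,
    sd_interaction_length_nm = if (has_int) pop_sd(interactions$length_nm) else NA_real_,
    distance_bin_fractions = fractions
  ), class = "network_stats")
}

mean_or_na <- function(x) if (length(x) > 0) mean(x) else NA_real_
pop_sd <- function(x) {
  if (length(x) == 0) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

#' @export
print.network_stats <- function(x, ...) {
  cat(sprintf("<network_stats> %d filaments, %.3g MT/um^3 in %.3g um^3\n",
              x$n_filaments, x$density_per_um3, x$volume_um3))
  cat(sprintf("  length: %.0f +/- %.0f nm; nn distance: %.1f +/- %.1f nm\n",
              x$mean_length_nm, x$sd_length_nm,
              x$mean_nn_distance_nm, x$sd_nn_distance_nm))
  if (x$n_interactions > 0) {
    cat(sprintf("  interactions: n = %d, length %.0f +/- %.0f nm\n",
                x$n_interactions, x$mean_interaction_length_nm,
                x$sd_interaction_length_nm))
  } else {
    cat("  interactions: none detected\n")
  }
  invisible(x)
}

#' @export
tidy.network_stats <- function(x, ...) {
  tibble::tibble(
    n_filaments = x$n_filaments,
    volume_um3 = x$volume_um3,
    density_per_um3 = x$density_per_um3,
    mean_length_nm = x$mean_length_nm,
    sd_length_nm = x$sd_length_nm,
    mean_nn_distance_nm = x$mean_nn_distance_nm,
    sd_nn_distance_nm = x$sd_nn_distance_nm,
    n_interactions = x$n_interactions,
    mean_interaction_length_nm = x$mean_interaction_length_nm,
    sd_interaction_length_nm = x$sd_interaction_length_nm
  )
}

#' Export an interaction table as CSV
#'
#' Writes the per-interaction spreadsheet (one row per ordered-pair run).
#'
#' @param interactions An `interaction_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interactions_csv <- function(interactions, path) {
  utils::write.csv(as.data.frame(interactions), path, row.names = FALSE)
  invisible(path)
}

#' Export network statistics as JSON
#'
#' @param stats A `network_stats` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stats_json <- function(stats, path) {
  obj <- unclass(stats)
  obj$distance_bin_fractions <- as.list(obj$distance_bin_fractions)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
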