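# Independent brute-force oracles, written in plain R against the raw data
# model (not via the package's C++ kernels), used to pin down expected
# values for the geometry machinery.

# distances from points P (n x 3) to one segment a-b
oracle_point_seg <- function(P, a, b) {
  d <- b - a
  len2 <- sum(d^2)
  if (len2 == 0) {
    return(sqrt(rowSums(sweep(P, 2, a)^2)))
  }
  t <- pmin(1, pmax(0, (sweep(P, 2, a) %*% d) / len2))
  proj <- cbind(a[1] + t * d[1], a[2] + t * d[2], a[3] + t * d[3])
  sqrt(rowSums((P - proj)^2))
}

# distances from points P to a whole polyline B (min over segments)
oracle_point_polyline <- function(P, B) {
  best <- rep(Inf, nrow(P))
  for (j in seq_len(nrow(B) - 1)) {
    best <- pmin(best, oracle_point_seg(P, B[j, ], B[j + 1, ]))
  }
  best
}

# dense resampling of a polyline at `step` nm arc spacing
oracle_resample <- function(B, step) {
  seg <- sqrt(rowSums((B[-1, , drop = FALSE] - B[-nrow(B), , drop = FALSE])^2))
  arc <- c(0, cumsum(seg))
  s <- unique(c(seq(0, arc[length(arc)], by = step), arc[length(arc)]))
  P <- cbind(approx(arc, B[, 1], xout = s)$y,
             approx(arc, B[, 2], xout = s)$y,
             approx(arc, B[, 3], xout = s)$y)
  list(points = P, arc = s)
}

# segment-segment min distance by dense sampling of both segments
oracle_seg_seg_sampled <- function(a0, a1, b0, b1, step = 0.1) {
  ta <- seq(0, 1, by = step / max(sqrt(sum((a1 - a0)^2)), step))
  tb <- seq(0, 1, by = step / max(sqrt(sum((b1 - b0)^2)), step))
  A <- cbind(a0[1] + ta * (a1[1] - a0[1]), a0[2] + ta * (a1[2] - a0[2]),
             a0[3] + ta * (a1[3] - a0[3]))
  B <- cbind(b0[1] + tb * (b1[1] - b0[1]), b0[2] + tb * (b1[2] - b0[2]),
             b0[3] + tb * (b1[3] - b0[3]))
  min(sqrt(outer(rowSums(A^2), rep(1, nrow(B))) +
             outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)))
}

# exact min distance between two polylines via all-pairs scan over segments,
# each segment pair resolved by 1-D golden-section-free parameter grid plus
# refinement: here we keep it honest and simple with fine sampling
oracle_polyline_pair_distance <- function(A, B, step = 0.5) {
  P <- oracle_resample(A, step)$points
  min(oracle_point_polyline(P, B))
}

# dense-sampling interaction oracle: for each ordered pair, runs of source
# samples (at `step` nm) within d_max of the target; run length measured
# between first and last in-threshold samples; runs >= l_min kept
oracle_interactions <- function(network, d_max = 100, l_min = 100, step = 1) {
  polys <- lapply(split(network$points, network$points$filament_id),
                  function(df) cbind(df$x, df$y, df$z))
  ids <- as.integer(names(polys))
  out <- list()
  bbox <- lapply(polys, function(m) rbind(apply(m, 2, min), apply(m, 2, max)))
  for (i in seq_along(polys)) {
    rs <- oracle_resample(polys[[i]], step)
    for (j in seq_along(polys)) {
      if (i == j) next
      # rigorous AABB lower bound lets far pairs be skipped
      gap <- pmax(0, pmax(bbox[[j]][1, ] - bbox[[i]][2, ],
                          bbox[[i]][1, ] - bbox[[j]][2, ]))
      if (sqrt(sum(gap^2)) > d_max) next
      d <- oracle_point_polyline(rs$points, polys[[j]])
      inside <- d <= d_max
      if (!any(inside)) next
      r <- rle(inside)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (k in which(r$values)) {
        len <- rs$arc[ends[k]] - rs$arc[starts[k]]
        if (len >= l_min) {
          out[[length(out) + 1]] <- data.frame(
            source_id = ids[i], target_id = ids[j],
            length_nm = len, min_distance_nm = min(d[starts[k]:ends[k]])
          )
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(source_id = integer(), target_id = integer(),
                      length_nm = numeric(), min_distance_nm = numeric()))
  }
  do.call(rbind, out)
}

# nearest-neighbor oracle via fine-sampled pair distances
oracle_nearest_neighbors <- function(network, step = 1) {
  polys <- lapply(split(network$points, network$points$filament_id),
                  function(df) cbind(df$x, df$y, df$z))
  ids <- as.integer(names(polys))
  n <- length(polys)
  dm <- matrix(Inf, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dm[i, j] <- dm[j, i] <- oracle_polyline_pair_distance(polys[[i]], polys[[j]], step)
  }
  nn <- apply(dm, 1, which.min)
  data.frame(filament_id = ids, nearest_id = ids[nn],
             distance_nm = dm[cbind(seq_len(n), nn)])
}

# simple straight-line network builder for hand-constructed cases
line_network <- function(..., volume = NULL) {
  segs <- list(...)
  pts <- do.call(rbind, lapply(seq_along(segs), function(i) {
    m <- segs[[i]]
    data.frame(filament_id = i, x = m[, 1], y = m[, 2], z = m[, 3])
  }))
  filament_network(pts, volume = volume)
}

# straight filament along x as a point matrix
xline <- function(x0, x1, y = 0, z = 0, n = 6) {
  cbind(seq(x0, x1, length.out = n), y, z)
}

# absolute-tolerance comparison helper
expect_within <- function(x, y, tol) {
  testthat::expect_lt(max(abs(x - y)), tol)
}

# direct channel access for movies (mirrors the package's internal accessor)
movie_channel_for_test <- function(movie, role, t) {
  movie$frames[t, movie$channels[[role]], , ]
}
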