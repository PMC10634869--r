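#' Embryo time-lapse movies
#'
#' An `embryo_movie` wraps a T x C x Y x X intensity array (8-bit after
#' [to_eight_bit()]) with channel roles, pixel size and frame interval.
#'
#' @param frames 4D numeric array `[frame, channel, y, x]`.
#' @param channels Named integer vector mapping roles to channel indices,
#'   e.g. `c(spindle = 1, dna = 2)`; roles must be distinct.
#' @param pixel_size Pixel size in um/px.
#' @param frame_interval Frame interval in s.
#' @return An object of class `embryo_movie`.
#' @export
embryo_movie <- function(frames, channels = c(spindle = 1, dna = 2),
                         pixel_size = 0.2, frame_interval = 1) {
  stopifnot(length(dim(frames)) == 4, dim(frames)[1] >= 2,
            pixel_size > 0, frame_interval > 0,
            !anyDuplicated(channels), all(channels <= dim(frames)[2]))
  structure(list(frames = frames, channels = channels,
                 pixel_size = pixel_size, frame_interval = frame_interval,
                 constant_channels = integer(0)),
            class = "embryo_movie")
}

#' @export
print.embryo_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<embryo_movie> %d frames, %d channel(s), %d x %d px (%.3g um/px, %.3g s/frame)\n",
              d[1], d[2], d[4], d[3], x$pixel_size, x$frame_interval))
  invisible(x)
}

movie_channel <- function(movie, role, frame = NULL) {
  ch <- movie$channels[[role]]
  if (is.null(frame)) movie$frames[, ch, , , drop = TRUE]
  else movie$frames[frame, ch, , ]
}

#' Convert a raw multi-channel movie to 8-bit
#'
#' Per channel, the global (whole-movie) minimum and maximum are linearly
#' mapped to 0..255 and values are rounded half away from zero. Global
#' rather than per-frame scaling keeps the fixed 8-bit threshold bands
#' (191-255, 127-255) stationary over time. A constant channel maps to all
#' zeros and is flagged in `$constant_channels`.
#'
#' @param raw 4D numeric array `[frame, channel, y, x]` of non-negative
#'   intensities.
#' @inheritParams embryo_movie
#' @return An `embryo_movie` with 8-bit frames.
#' @export
to_eight_bit <- function(raw, channels = c(spindle = 1, dna = 2),
                         pixel_size = 0.2, frame_interval = 1) {
  if (any(raw < 0)) rlang::abort("raw intensities must be non-negative")
  out <- raw
  constant <- integer(0)
  for (ch in seq_len(dim(raw)[2])) {
    v <- raw[, ch, , ]
    lo <- min(v); hi <- max(v)
    if (hi == lo) {
      out[, ch, , ] <- 0
      constant <- c(constant, ch)
    } else {
      out[, ch, , ] <- floor((v - lo) / (hi - lo) * 255 + 0.5)
    }
  }
  if (length(constant) > 0) {
    rlang::warn(sprintf("channel(s) %s constant over the movie; mapped to 0",
                        paste(constant, collapse = ", ")))
  }
  m <- embryo_movie(out, channels, pixel_size, frame_interval)
  m$constant_channels <- constant
  m
}

#' 8-bit threshold band for a top intensity fraction
#'
#' The band covering the top fraction `p` of the 8-bit range:
#' `(floor((1 - p) * 255), 255)`. The top 25% band is (191, 255), used for
#' spindle poles; the top 50% band is (127, 255), used for chromatin.
#'
#' @param p Fraction in (0, 1].
#' @return Integer vector `c(low, high)`.
#' @export
top_fraction_band <- function(p) {
  if (!is.numeric(p) || p <= 0 || p > 1) rlang::abort("`p` must lie in (0, 1]")
  c(low = as.integer(floor((1 - p) * 255)), high = 255L)
}

# 3x3 discrete Gaussian kernel; size is fixed at 3x3, sigma configurable
gaussian3x3_kernel <- function(sigma = 0.8) {
  k <- stats::dnorm(-1:1, sd = sigma)
  K <- outer(k, k)
  K / sum(K)
}

# 3x3 convolution with replicated borders (shift-and-add, no FFT wraparound)
blur3x3 <- function(img, sigma = 0.8) {
  K <- gaussian3x3_kernel(sigma)
  ny <- nrow(img); nx <- ncol(img)
  pad <- rbind(img[1, , drop = FALSE], img, img[ny, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, nx, drop = FALSE])
  out <- matrix(0, ny, nx)
  for (dy in -1:1) for (dx in -1:1) {
    out <- out + K[dy + 2, dx + 2] * pad[(2:(ny + 1)) + dy, (2:(nx + 1)) + dx]
  }
  out
}

#' Segment embryo outlines from a movie
#'
#' Builds a temporal median projection of the low-background spindle
#' (tubulin) channel, smooths it, thresholds it (Otsu) and separates
#' touching embryos by watershed on the distance map. The resulting labelled
#' mask is used to zero all signal outside each embryo.
#'
#' @param movie An `embryo_movie`.
#' @param sigma Smoothing sigma (px) for the projection.
#' @param min_area Minimum embryo area in px.
#' @param tolerance Watershed tolerance (larger = less oversegmentation).
#' @return Integer matrix (Y x X) with one label per embryo, 0 = background.
#' @export
segment_embryo <- function(movie, sigma = 2, min_area = 200, tolerance = 10) {
  stack <- movie_channel(movie, "spindle")
  proj <- apply(stack, c(2, 3), stats::median)
  sm <- EBImage::gblur(proj / 255, sigma = sigma)
  th <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  bw <- sm > th
  if (!any(bw)) rlang::abort("empty mask: no foreground found in the spindle channel")
  bw <- EBImage::fillHull(bw)
  lab <- EBImage::watershed(EBImage::distmap(bw), tolerance = tolerance)
  lab <- matrix(as.integer(lab), nrow(proj), ncol(proj))
  keep <- which(tabulate(lab[lab > 0]) >= min_area)
  if (length(keep) == 0) rlang::abort("empty mask: no embryo-sized component found")
  relabel <- integer(max(lab))
  relabel[keep] <- seq_along(keep)
  lab[lab > 0] <- relabel[lab[lab > 0]]
  lab
}

#' Long axis of an embryo mask
#'
#' Principal axis of the pixel coordinates of a labelled mask, used as the
#' default reference axis for pole oscillation.
#'
#' @param mask Integer matrix from [segment_embryo()].
#' @param label Embryo label to use.
#' @return List with `point` (centroid, px) and `direction` (unit vector).
#' @export
embryo_long_axis <- function(mask, label = 1) {
  idx <- which(mask == label, arr.ind = TRUE)
  if (nrow(idx) == 0) rlang::abort("label not present in mask")
  xy <- cbind(x = idx[, 2], y = idx[, 1])
  ctr <- colMeans(xy)
  ev <- eigen(stats::cov(xy))$vectors[, 1]
  if (ev[1] < 0) ev <- -ev
  list(point = ctr, direction = ev)
}

#' Detect the two spindle poles in a frame
#'
#' Gaussian blur (3x3 kernel), binary thresholding on the top-25% 8-bit
#' band (191-255), connected components within the embryo mask; the two
#' largest components are the poles and their positions are
#' intensity-weighted centroids. Anterior (pole A) is the pole with the
#' smaller coordinate along the reference axis.
#'
#' @param frame 8-bit spindle-channel image (Y x X matrix).
#' @param mask Embryo mask (0 = outside); `NULL` for no masking.
#' @param band Threshold band, default [top_fraction_band()] of 0.25.
#' @param sigma Blur sigma (px).
#' @param ref_axis Unit vector used to order the poles (default +x).
#' @return List with `a`, `b` (pole positions `c(x, y)` in px) and
#'   `valid`; `valid = FALSE` with `NA` positions when fewer than two
#'   components are found (the frame is flagged, not an error).
#' @export
detect_poles <- function(frame, mask = NULL, band = top_fraction_band(0.25),
                         sigma = 0.8, ref_axis = c(1, 0)) {
  bl <- blur3x3(frame, sigma)
  bw <- bl >= band[1] & bl <= band[2]
  if (!is.null(mask)) bw <- bw & mask > 0
  invalid <- list(a = c(NA_real_, NA_real_), b = c(NA_real_, NA_real_),
                  valid = FALSE)
  if (!any(bw)) return(invalid)
  lab <- EBImage::bwlabel(bw)
  areas <- tabulate(lab[lab > 0])
  if (length(areas) < 2) return(invalid)
  top2 <- order(areas, decreasing = TRUE)[1:2]
  cent <- lapply(top2, function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    w <- bl[idx]
    c(x = sum(idx[, 2] * w) / sum(w), y = sum(idx[, 1] * w) / sum(w))
  })
  s <- vapply(cent, function(p) sum(p * ref_axis), numeric(1))
  ord <- order(s)
  list(a = unname(cent[[ord[1]]]), b = unname(cent[[ord[2]]]), valid = TRUE)
}

#' Detect chromatin leading edges in a frame
#'
#' Gaussian blur, thresholding on the top-50% band (127-255), connected
#' components within the mask. Chromatin pixel centers are projected onto
#' the pole-pole axis; positions are measured from the midzone (the pole
#' midpoint). The leading edge toward each pole is the outermost chromatin
#' position in that direction. When the chromatin has split, the axial gap
#' between the two largest components is also reported (inner-edge
#' separation), which drives anaphase-onset calling.
#'
#' @param frame 8-bit dna-channel image (Y x X matrix).
#' @param mask Embryo mask or `NULL`.
#' @param poles Pole list from [detect_poles()].
#' @param band Threshold band, default [top_fraction_band()] of 0.5.
#' @param sigma Blur sigma (px).
#' @param min_area Minimum component area in px.
#' @return List with `edge_a`, `edge_b` (signed axial positions of the
#'   leading edges, px, pole A side negative), `n_comp`, `gap` (px, `NA`
#'   when fewer than two components) and `valid`.
#' @export
detect_chromatids <- function(frame, mask = NULL, poles,
                              band = top_fraction_band(0.5), sigma = 0.8,
                              min_area = 4) {
  invalid <- list(edge_a = NA_real_, edge_b = NA_real_, n_comp = 0L,
                  gap = NA_real_, valid = FALSE)
  if (!isTRUE(poles$valid)) return(invalid)
  bl <- blur3x3(frame, sigma)
  bw <- bl >= band[1] & bl <= band[2]
  if (!is.null(mask)) bw <- bw & mask > 0
  if (!any(bw)) return(invalid)
  lab <- EBImage::bwlabel(bw)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area)
  if (length(keep) == 0) return(invalid)
  u <- poles$b - poles$a
  u <- u / sqrt(sum(u^2))
  mid <- (poles$a + poles$b) / 2
  lab <- matrix(as.integer(lab), nrow(bl), ncol(bl))
  idx <- which(matrix(lab %in% keep, nrow(lab)), arr.ind = TRUE)
  s <- (idx[, 2] - mid[1]) * u[1] + (idx[, 1] - mid[2]) * u[2]
  comp <- lab[cbind(idx[, 1], idx[, 2])]
  gap <- NA_real_
  if (length(keep) >= 2) {
    top2 <- keep[order(areas[keep], decreasing = TRUE)[1:2]]
    mean_s <- vapply(top2, function(l) mean(s[comp == l]), numeric(1))
    neg <- top2[which.min(mean_s)]; pos <- top2[which.max(mean_s)]
    gap <- min(s[comp == pos]) - max(s[comp == neg])
  }
  list(edge_a = min(s), edge_b = max(s), n_comp = length(keep), gap = gap,
       valid = TRUE)
}

#' Track spindle poles and chromatin through a movie
#'
#' Runs embryo segmentation, per-frame pole detection (spindle channel) and
#' chromatin edge detection (dna channel), and assembles a per-frame trace.
#' Frames where detection fails are flagged invalid, never interpolated.
#'
#' @param movie An 8-bit `embryo_movie`.
#' @param mask Embryo mask; `NULL` computes one with [segment_embryo()],
#'   `NA` disables masking.
#' @param pole_band,chromatin_band Threshold bands.
#' @param sigma Blur sigma (px).
#' @return A tibble of class `spindle_trace` with per-frame columns:
#'   `frame`, `time_s`, `valid`, pole positions (`pole_a_x` ... px),
#'   `pole_dist_um`, leading-edge positions `chrom_edge_a_um`,
#'   `chrom_edge_b_um` (signed, relative to the midzone),
#'   `chrom_sep_um` (leading-edge separation), `n_chrom_comp` and
#'   `chrom_gap_um`. Attributes carry `pixel_size`, `frame_interval` and
#'   the mask.
#' @export
track_spindle <- function(movie, mask = NULL,
                          pole_band = top_fraction_band(0.25),
                          chromatin_band = top_fraction_band(0.5),
                          sigma = 0.8) {
  if (is.null(mask)) mask <- segment_embryo(movie)
  use_mask <- !(length(mask) == 1 && is.na(mask[1]))
  m <- if (use_mask) mask else NULL
  nT <- dim(movie$frames)[1]
  px <- movie$pixel_size
  rows <- vector("list", nT)
  for (t in seq_len(nT)) {
    sp <- movie_channel(movie, "spindle", t)
    dn <- movie_channel(movie, "dna", t)
    poles <- detect_poles(sp, m, band = pole_band, sigma = sigma)
    chrom <- detect_chromatids(dn, m, poles, band = chromatin_band,
                               sigma = sigma)
    rows[[t]] <- tibble::tibble(
      frame = t,
      time_s = (t - 1) * movie$frame_interval,
      valid = poles$valid && chrom$valid,
      pole_a_x = poles$a[1], pole_a_y = poles$a[2],
      pole_b_x = poles$b[1], pole_b_y = poles$b[2],
      pole_dist_um = sqrt(sum((poles$b - poles$a)^2)) * px,
      chrom_edge_a_um = chrom$edge_a * px,
      chrom_edge_b_um = chrom$edge_b * px,
      chrom_sep_um = (chrom$edge_b - chrom$edge_a) * px,
      n_chrom_comp = chrom$n_comp,
      chrom_gap_um = chrom$gap * px
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "pixel_size") <- px
  attr(out, "frame_interval") <- movie$frame_interval
  attr(out, "mask") <- if (use_mask) mask else NULL
  class(out) <- c("spindle_trace", class(out))
  out
}

#' Call anaphase onset from a spindle trace
#'
#' Anaphase onset is the last frame before visible chromosome segregation:
#' the frame preceding the first run of `persist` consecutive valid frames
#' in which the chromatin has split into two or more components whose axial
#' (inner-edge) separation exceeds `gap_min`. A single-frame split does not
#' trigger onset.
#'
#' @param trace A `spindle_trace`.
#' @param gap_min Minimum axial gap (um) between the separating chromatin
#'   masses.
#' @param persist Number of consecutive frames the gap must persist.
#' @return The onset frame index, or `NA_integer_` if no such run exists.
#' @export
detect_anaphase_onset <- function(trace, gap_min = 1, persist = 3) {
  sep <- trace$valid & trace$n_chrom_comp >= 2 &
    !is.na(trace$chrom_gap_um) & trace$chrom_gap_um > gap_min
  if (sum(trace$valid) < persist) {
    rlang::abort(sprintf("trace has only %d valid frames; need >= %d",
                         sum(trace$valid), persist))
  }
  run <- rle(sep)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1
  hit <- which(run$values & run$lengths >= persist)
  if (length(hit) == 0) return(NA_integer_)
  first <- starts[hit[1]]
  as.integer(trace$frame[first] - 1L)
}

#' Segregation / elongation rate over a fixed window after onset
#'
#' The rate is the displacement during the first `window` seconds after the
#' beginning of anaphase divided by the window: for chromosomes, the change
#' in leading-edge separation; for poles, the change in pole-pole distance.
#'
#' @param trace A `spindle_trace`.
#' @param window Averaging window in s (default 40).
#' @param what `"chromosome"` or `"pole"`.
#' @param onset Onset frame; default [detect_anaphase_onset()] on the trace.
#' @return Rate in um/s.
#' @export
segregation_rate <- function(trace, window = 40,
                             what = c("chromosome", "pole"), onset = NULL) {
  what <- match.arg(what)
  dt <- attr(trace, "frame_interval")
  if (is.null(onset)) onset <- detect_anaphase_onset(trace)
  if (is.na(onset)) rlang::abort("no anaphase onset present in the trace")
  i0 <- match(onset, trace$frame)
  i1 <- match(onset + round(window / dt), trace$frame)
  if (is.na(i1)) {
    rlang::abort(sprintf(
      "insufficient frames: need frame %d (%g s after onset), trace ends at %d",
      onset + round(window / dt), window, max(trace$frame)))
  }
  if (!trace$valid[i0] || !trace$valid[i1]) {
    rlang::abort("onset or window-end frame is invalid")
  }
  col <- if (what == "chromosome") "chrom_sep_um" else "pole_dist_um"
  (trace[[col]][i1] - trace[[col]][i0]) / window
}

# bilinear sample of img at (x, y) pixel coordinates; 0 outside
bilinear_sample <- function(img, x, y) {
  ny <- nrow(img); nx <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  val <- function(xi, yi) {
    ok <- xi >= 1 & xi <= nx & yi >= 1 & yi <= ny
    out <- numeric(length(xi))
    out[ok] <- img[cbind(yi[ok], xi[ok])]
    out
  }
  (1 - fx) * (1 - fy) * val(x0, y0) +
    fx * (1 - fy) * val(x0 + 1, y0) +
    (1 - fx) * fy * val(x0, y0 + 1) +
    fx * fy * val(x0 + 1, y0 + 1)
}

#' Rotation-aligned kymograph of a movie
#'
#' Per frame, the image is rotated about the midzone point (the pole
#' midpoint) so that the pole-pole axis is horizontal, using bilinear
#' interpolation with out-of-bounds pixels contributing 0. Each kymograph
#' row is the sum-intensity projection over the rows within
#' `band_halfwidth` pixels above and below the axis. Invalid frames produce
#' rows of `NA` and are flagged.
#'
#' @param movie An `embryo_movie`.
#' @param trace A `spindle_trace` for the same movie.
#' @param band_halfwidth Half-width of the projection band in px
#'   (default 5: +/- 5 px around the axis).
#' @param channel Channel role to project.
#' @return An object of class `kymograph`: list with `image` (T x X
#'   matrix), `band_halfwidth`, `valid`, `pixel_size`, `frame_interval`.
#' @export
build_kymograph <- function(movie, trace, band_halfwidth = 5,
                            channel = "spindle") {
  nT <- dim(movie$frames)[1]
  nx <- dim(movie$frames)[4]
  img_out <- matrix(NA_real_, nT, nx)
  for (t in seq_len(nT)) {
    if (!trace$valid[t]) next
    img <- movie_channel(movie, channel, t)
    a <- c(trace$pole_a_x[t], trace$pole_a_y[t])
    b <- c(trace$pole_b_x[t], trace$pole_b_y[t])
    ctr <- (a + b) / 2
    theta <- atan2(b[2] - a[2], b[1] - a[1])
    co <- cos(theta); si <- sin(theta)
    yc <- round(ctr[2])
    band_rows <- (yc - band_halfwidth):(yc + band_halfwidth)
    gx <- rep(seq_len(nx), times = length(band_rows))
    gy <- rep(band_rows, each = nx)
    # rotate the sampling grid by +theta about the midzone: equivalent to
    # rotating the image by -theta so the pole axis becomes horizontal
    sx <- ctr[1] + (gx - ctr[1]) * co - (gy - ctr[2]) * si
    sy <- ctr[2] + (gx - ctr[1]) * si + (gy - ctr[2]) * co
    vals <- matrix(bilinear_sample(img, sx, sy), nrow = nx)
    img_out[t, ] <- rowSums(vals)
  }
  structure(list(image = img_out, band_halfwidth = band_halfwidth,
                 valid = trace$valid, pixel_size = movie$pixel_size,
                 frame_interval = movie$frame_interval),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d frames x %d px (band +/- %d px)\n",
              nrow(x$image), ncol(x$image), x$band_halfwidth))
  invisible(x)
}

#' Enhance a kymograph by adaptive thresholding and skeletonization
#'
#' Local-mean adaptive thresholding (box filter of the given block size)
#' followed by morphological skeletonization (Zhang-Suen thinning), to
#' visualize pole and chromatid trajectories as 1-px curves.
#'
#' @param k A `kymograph`.
#' @param block Odd box size (px) for the local mean.
#' @param offset Threshold offset as a fraction of the dynamic range.
#' @return Binary matrix (same shape as the kymograph image).
#' @export
enhance_kymograph <- function(k, block = 15, offset = 0.02) {
  img <- k$image
  img[!is.finite(img)] <- 0
  rng <- diff(range(img))
  if (rng == 0) return(matrix(FALSE, nrow(img), ncol(img)))
  norm <- (img - min(img)) / rng
  half <- max(1, block %/% 2)
  bw <- EBImage::thresh(EBImage::Image(norm), w = half, h = half,
                        offset = offset)
  bw <- matrix(as.logical(bw), nrow(img), ncol(img))
  skeletonize(bw)
}

#' Morphological skeletonization (Zhang-Suen thinning)
#'
#' @param bw Logical matrix.
#' @return Logical matrix: the 1-px-wide skeleton, a subset of the input.
#' @export
skeletonize <- function(bw) {
  img <- matrix(0L, nrow(bw) + 2, ncol(bw) + 2)
  img[2:(nrow(bw) + 1), 2:(ncol(bw) + 1)] <- as.integer(bw)
  nb <- function(m, dy, dx) {
    m[(2:(nrow(img) - 1)) + dy, (2:(ncol(img) - 1)) + dx]
  }
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      p2 <- nb(img, -1, 0); p3 <- nb(img, -1, 1); p4 <- nb(img, 0, 1)
      p5 <- nb(img, 1, 1);  p6 <- nb(img, 1, 0);  p7 <- nb(img, 1, -1)
      p8 <- nb(img, 0, -1); p9 <- nb(img, -1, -1)
      p1 <- nb(img, 0, 0)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      A <- matrix(0L, nrow(p1), ncol(p1))
      for (i in 1:8) A <- A + (seqs[[i]] == 0 & seqs[[i + 1]] == 1)
      if (phase == 1) {
        cond <- p1 == 1 & B >= 2 & B <= 6 & A == 1 &
          (p2 * p4 * p6) == 0 & (p4 * p6 * p8) == 0
      } else {
        cond <- p1 == 1 & B >= 2 & B <= 6 & A == 1 &
          (p2 * p4 * p8) == 0 & (p2 * p6 * p8) == 0
      }
      if (any(cond)) {
        changed <- TRUE
        inner <- img[2:(nrow(img) - 1), 2:(ncol(img) - 1)]
        inner[cond] <- 0L
        img[2:(nrow(img) - 1), 2:(ncol(img) - 1)] <- inner
      }
    }
    if (!changed) break
  }
  img[2:(nrow(img) - 1), 2:(ncol(img) - 1)] == 1L
}

#' Pole oscillation relative to a reference axis
#'
#' Signed perpendicular displacement of each pole from a fixed reference
#' axis, per frame. By default the axis is the embryo long axis from the
#' segmentation mask; any axis can be supplied instead.
#'
#' @param trace A `spindle_trace`.
#' @param reference_axis List with `point` (c(x, y), px) and `direction`
#'   (unit vector); default [embryo_long_axis()] of the trace's mask.
#' @return Tibble with `frame`, `time_s`, `pole_a_perp_um`,
#'   `pole_b_perp_um`.
#' @export
pole_oscillation <- function(trace, reference_axis = NULL) {
  if (is.null(reference_axis)) {
    mask <- attr(trace, "mask")
    if (is.null(mask)) rlang::abort("no mask on trace; supply `reference_axis`")
    reference_axis <- embryo_long_axis(mask)
  }
  u <- reference_axis$direction
  if (sqrt(sum(u^2)) == 0) rlang::abort("degenerate reference axis")
  u <- u / sqrt(sum(u^2))
  p0 <- reference_axis$point
  px <- attr(trace, "pixel_size")
  perp <- function(x, y) ((x - p0[1]) * u[2] - (y - p0[2]) * u[1]) * px
  tibble::tibble(
    frame = trace$frame,
    time_s = trace$time_s,
    pole_a_perp_um = perp(trace$pole_a_x, trace$pole_a_y),
    pole_b_perp_um = perp(trace$pole_b_x, trace$pole_b_y)
  )
}

#' Rigidly rotate a movie about its center
#'
#' Utility for invariance checks: every frame and channel is rotated by the
#' same angle about the image center with bilinear interpolation
#' (out-of-bounds pixels become 0).
#'
#' @param movie An `embryo_movie`.
#' @param angle_deg Rotation angle, degrees counter-clockwise.
#' @return An `embryo_movie`.
#' @export
rotate_movie <- function(movie, angle_deg) {
  d <- dim(movie$frames)
  out <- movie$frames
  theta <- angle_deg * pi / 180
  co <- cos(theta); si <- sin(theta)
  ctr <- c((d[4] + 1) / 2, (d[3] + 1) / 2)
  gx <- rep(seq_len(d[4]), each = d[3])
  gy <- rep(seq_len(d[3]), times = d[4])
  sx <- ctr[1] + (gx - ctr[1]) * co + (gy - ctr[2]) * si
  sy <- ctr[2] - (gx - ctr[1]) * si + (gy - ctr[2]) * co
  for (t in seq_len(d[1])) for (ch in seq_len(d[2])) {
    out[t, ch, , ] <- matrix(bilinear_sample(movie$frames[t, ch, , ], sx, sy),
                             d[3], d[4])
  }
  movie$frames <- out
  movie
}

#' Export a spindle trace as CSV
#'
#' @param trace A `spindle_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
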