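#' Background-normalized midzone intensity
#'
#' Mean intensity of a fixed-size ROI in the midzone, normalized against a
#' background ROI: `(mean(roi) - mean(background)) / mean(background)`.
#' Serves both tubulin and EB-comet midzone intensity measurements.
#'
#' @param frame Intensity image (Y x X matrix).
#' @param roi,background_roi Named vectors `c(xmin, xmax, ymin, ymax)` in
#'   pixel indices (1-based, inclusive), inside the image.
#' @return Normalized scalar (0 = no enrichment over background).
#' @export
midzone_intensity <- function(frame, roi, background_roi) {
  roi_mean <- function(r) {
    if (r["xmin"] < 1 || r["ymin"] < 1 || r["xmax"] > ncol(frame) ||
        r["ymax"] > nrow(frame)) {
      rlang::abort("ROI extends outside the image")
    }
    mean(frame[r["ymin"]:r["ymax"], r["xmin"]:r["xmax"]])
  }
  bg <- roi_mean(background_roi)
  if (bg == 0) rlang::abort("background mean is zero; cannot normalize")
  (roi_mean(roi) - bg) / bg
}

#' Axial intensity profile over an ROI box
#'
#' Mean intensity per axial bin across the height of an ROI box spanning
#' the spindle, the standard way midzone protein distributions (e.g. a
#' bundler or a plus-end tracker) are profiled.
#'
#' @param frame Intensity image (Y x X matrix).
#' @param roi Named vector `c(xmin, xmax, ymin, ymax)` (px); the x-range is
#'   the axial direction, the y-range the box height.
#' @param pixel_size Pixel size in um.
#' @param center_x Axial pixel coordinate mapped to position 0 (default:
#'   ROI center).
#' @param background Scalar background to record with the profile.
#' @return A tibble of class `intensity_profile` with `position_um` and
#'   `value`; the background is stored as an attribute.
#' @export
intensity_profile <- function(frame, roi, pixel_size = 0.1,
                              center_x = NULL, background = 0) {
  sub <- frame[roi["ymin"]:roi["ymax"], roi["xmin"]:roi["xmax"], drop = FALSE]
  if (is.null(center_x)) center_x <- (roi["xmin"] + roi["xmax"]) / 2
  out <- tibble::tibble(
    position_um = (seq(roi["xmin"], roi["xmax"]) - center_x) * pixel_size,
    value = colMeans(sub)
  )
  attr(out, "background") <- background
  class(out) <- c("intensity_profile", class(out))
  out
}

#' Full width at half intensity of a peaked profile
#'
#' Full width of a profile peak at half of (peak - background), with linear
#' interpolation at the two crossings. Invariant under affine intensity
#' transforms and axial translation. The half-intensity width of a midzone
#' protein profile is the standard summary of its axial spread.
#'
#' @param profile An `intensity_profile` or data frame with `position_um`
#'   and `value`.
#' @param background Background level; default the attribute stored on the
#'   profile, else the minimum value.
#' @param level Fraction of (peak - background) at which to measure
#'   (default 0.5).
#' @return Width in um.
#' @export
half_intensity_width <- function(profile, background = NULL, level = 0.5) {
  pos <- profile$position_um
  val <- profile$value
  if (is.null(background)) {
    background <- attr(profile, "background")
    if (is.null(background) || identical(background, 0)) background <- min(val)
  }
  imax <- which.max(val)
  if (imax == 1 || imax == length(val)) {
    rlang::abort("peak lies on the profile edge; width is truncated")
  }
  target <- background + level * (val[imax] - background)
  left <- half_cross(pos, val, target, seq(imax, 1))
  right <- half_cross(pos, val, target, seq(imax, length(val)))
  if (is.na(left) || is.na(right)) {
    rlang::abort("profile does not fall to the half level on both sides")
  }
  right - left
}

half_cross <- function(pos, val, target, order_idx) {
  prev <- order_idx[1]
  for (i in order_idx[-1]) {
    if (val[i] <= target && val[prev] > target) {
      f <- (val[prev] - target) / (val[prev] - val[i])
      return(pos[prev] + f * (pos[i] - pos[prev]))
    }
    prev <- i
  }
  NA_real_
}

#' Count EB-comet binding events on a kymograph
#'
#' Crops the kymograph to an axial segment (default 4.5 um) and a stated
#' duration, binarizes at `background + threshold_fraction * (max -
#' background)` (the "10% threshold" convention, taken relative to the
#' background-subtracted maximum) and counts 8-connected components of at
#' least `min_area` pixels as individual binding events. Crossing events
#' merge into one component; this is a documented limitation of
#' component-based counting.
#'
#' @param kymograph A `kymograph` (or plain T x L matrix; then
#'   `pixel_size`/`frame_interval` must be given).
#' @param segment_length Axial segment length in um (default 4.5).
#' @param segment_start Axial start of the segment in um (default 0).
#' @param duration Duration to analyse in s (default 100).
#' @param threshold_fraction Fraction of the background-subtracted maximum.
#' @param background Background level; default the median of the cropped
#'   kymograph.
#' @param min_area Minimum event area in px (default 2, suppressing
#'   single-pixel noise).
#' @param pixel_size,frame_interval Used when a bare matrix is supplied.
#' @return Integer event count.
#' @export
count_comet_events <- function(kymograph, segment_length = 4.5,
                               segment_start = 0, duration = 100,
                               threshold_fraction = 0.10, background = NULL,
                               min_area = 2, pixel_size = NULL,
                               frame_interval = NULL) {
  if (inherits(kymograph, "kymograph")) {
    img <- kymograph$image
    px <- kymograph$pixel_size
    dt <- kymograph$frame_interval
  } else {
    img <- kymograph
    px <- pixel_size %||% rlang::abort("supply `pixel_size` for a bare matrix")
    dt <- frame_interval %||% rlang::abort("supply `frame_interval` for a bare matrix")
  }
  img[!is.finite(img)] <- 0
  cols <- seq(floor(segment_start / px) + 1,
              floor((segment_start + segment_length) / px))
  nrows <- min(nrow(img), ceiling(duration / dt))
  if (max(cols) > ncol(img) || min(cols) < 1) {
    rlang::abort("requested segment lies outside the kymograph")
  }
  crop <- img[seq_len(nrows), cols, drop = FALSE]
  if (is.null(background)) background <- stats::median(crop)
  mx <- max(crop)
  if (mx <= background) return(0L)
  bw <- crop > background + threshold_fraction * (mx - background)
  lab <- EBImage::bwlabel(bw)
  areas <- tabulate(lab[lab > 0])
  sum(areas >= min_area)
}

#' FRAP curves
#'
#' @param times Times in s, 0 = bleach; strictly increasing.
#' @param intensities Normalized intensities.
#' @param prebleach Mean prebleach intensity.
#' @return A tibble of class `frap_curve` with `time_s`, `intensity`;
#'   `prebleach` is stored as an attribute.
#' @export
frap_curve <- function(times, intensities, prebleach = 1) {
  stopifnot(length(times) == length(intensities), !is.unsorted(times))
  if (sum(times >= 0) < 3) rlang::abort("need at least 3 post-bleach points")
  out <- tibble::tibble(time_s = times, intensity = intensities)
  attr(out, "prebleach") <- prebleach
  class(out) <- c("frap_curve", class(out))
  out
}

#' Fit a FRAP recovery curve
#'
#' Least-squares fit of the single-exponential recovery
#' `F(t) = F0 + (Finf - F0) * (1 - exp(-k t))` to the post-bleach points.
#' The mobile (recovery) fraction is `(Finf - F0) / (prebleach - F0)`, the
#' fraction of the bleached signal that returns - here a proxy for
#' microtubule turnover in the midzone.
#'
#' @param curve A [frap_curve()].
#' @return An object of class `frap_fit` with elements `fraction`, `k`,
#'   `F0`, `Finf`, `prebleach`, `residuals` and the underlying `nls` fit.
#'   [tidy()] and [glance()] methods are provided.
#' @export
frap_recovery_fraction <- function(curve) {
  pre <- attr(curve, "prebleach")
  post <- curve[curve$time_s >= 0, ]
  if (pre <= post$intensity[1]) {
    rlang::abort("prebleach intensity must exceed the first post-bleach point")
  }
  if (diff(range(post$intensity)) < 1e-12) {
    # no recovery at all: the exponential model degenerates to a constant
    return(structure(list(fraction = 0, k = NA_real_,
                          F0 = post$intensity[1], Finf = post$intensity[1],
                          prebleach = pre,
                          residuals = rep(0, nrow(post)), fit = NULL),
                     class = "frap_fit"))
  }
  f0_start <- min(post$intensity)
  finf_start <- max(post$intensity)
  span <- max(finf_start - f0_start, 1e-6)
  mid <- post$time_s[which.min(abs(post$intensity - (f0_start + span / 2)))]
  k_start <- log(2) / max(mid, diff(range(post$time_s)) / 20)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      intensity ~ F0 + (Finf - F0) * (1 - exp(-k * time_s)),
      data = post,
      start = list(F0 = f0_start, Finf = finf_start, k = k_start),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) {
      rlang::abort(paste0("FRAP fit did not converge: ", conditionMessage(e)))
    }
  )
  co <- stats::coef(fit)
  structure(list(
    fraction = unname((co["Finf"] - co["F0"]) / (pre - co["F0"])),
    k = unname(co["k"]),
    F0 = unname(co["F0"]),
    Finf = unname(co["Finf"]),
    prebleach = pre,
    residuals = stats::resid(fit),
    fit = fit
  ), class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("<frap_fit> recovery fraction %.3f, k = %.4g /s (t1/2 = %.3g s)\n",
              x$fraction, x$k, log(2) / x$k))
  invisible(x)
}

#' @export
tidy.frap_fit <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble::tibble(term = c("F0", "Finf", "k"),
                          estimate = c(x$F0, x$Finf, x$k),
                          std.error = NA_real_))
  }
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"]
  )
}

#' @export
glance.frap_fit <- function(x, ...) {
  tibble::tibble(
    fraction = x$fraction,
    k = x$k,
    half_time_s = log(2) / x$k,
    sigma = sqrt(mean(x$residuals^2)),
    n = length(x$residuals)
  )
}
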