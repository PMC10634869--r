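#' Plot a polarity or intensity profile
#'
#' @param object A `polarity_profile` or `intensity_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.polarity_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$position_um, .data$polarity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position along spindle axis (μm)",
                  y = "polarity") +
    ggplot2::ylim(0, 1)
}

#' @rdname autoplot.polarity_profile
#' @export
autoplot.intensity_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$position_um, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position along spindle axis (μm)",
                  y = "mean ROI intensity (a.u.)")
}

#' Plot a spindle trace
#'
#' Pole-pole distance and chromosome (leading-edge) separation over time.
#'
#' @param object A `spindle_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spindle_trace <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "time_s", "pole_dist_um",
                  "chrom_sep_um"),
    -"time_s", names_to = "measure", values_to = "um"
  )
  labels <- c(pole_dist_um = "pole-pole distance",
              chrom_sep_um = "chromosome separation")
  df$measure <- labels[df$measure]
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$um,
                                   colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "distance (μm)", colour = NULL)
}

#' Plot a kymograph
#'
#' @param object A `kymograph`.
#' @param ... Unused.
#' @return A ggplot (space horizontal, time down).
#' @export
autoplot.kymograph <- function(object, ...) {
  img <- object$image
  df <- tidyr::expand_grid(frame = seq_len(nrow(img)),
                           x = seq_len(ncol(img)))
  df$intensity <- as.vector(t(img))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$frame,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 na.value = "red") +
    ggplot2::labs(x = "position (px)", y = "frame")
}

#' Plot a FRAP fit
#'
#' Data points and the fitted single-exponential recovery.
#'
#' @param object A `frap_fit`.
#' @param curve The `frap_curve` that was fitted (for the raw points).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.frap_fit <- function(object, curve = NULL, ...) {
  ts <- seq(0, max(if (is.null(curve)) 100 else max(curve$time_s)),
            length.out = 200)
  fitted <- tibble::tibble(
    time_s = ts,
    intensity = object$F0 + (object$Finf - object$F0) * (1 - exp(-object$k * ts))
  )
  p <- ggplot2::ggplot(fitted, ggplot2::aes(.data$time_s, .data$intensity)) +
    ggplot2::geom_line(colour = "red") +
    ggplot2::labs(x = "time after bleach (s)", y = "normalized intensity")
  if (!is.null(curve)) {
    p <- p + ggplot2::geom_point(data = curve[curve$time_s >= 0, ],
                                 alpha = 0.4)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
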