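#' Read a multi-page TIFF movie
#'
#' Reads an interleaved multi-page TIFF (page order frame 1 channel 1,
#' frame 1 channel 2, frame 2 channel 1, ...) into an [embryo_movie()].
#' Requires the `tiff` package.
#'
#' @param path TIFF file path.
#' @param channels Named channel-role map, e.g. `c(spindle = 1, dna = 2)`;
#'   its length sets the number of interleaved channels.
#' @param pixel_size um/px.
#' @param frame_interval s.
#' @param convert Convert to 8-bit with [to_eight_bit()]? If `FALSE` the
#'   raw page values (scaled to 0-255) are kept.
#' @return An `embryo_movie`.
#' @export
read_movie_tiff <- function(path, channels = c(spindle = 1, dna = 2),
                            pixel_size = 0.2, frame_interval = 1,
                            convert = TRUE) {
  rlang::check_installed("tiff")
  pages <- tiff::readTIFF(path, all = TRUE)
  nc <- length(channels)
  if (length(pages) %% nc != 0) {
    rlang::abort(sprintf("page count %d is not a multiple of %d channels",
                         length(pages), nc))
  }
  nT <- length(pages) / nc
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  raw <- array(0, dim = c(nT, nc, ny, nx))
  for (t in seq_len(nT)) for (ch in seq_len(nc)) {
    raw[t, ch, , ] <- pages[[(t - 1) * nc + ch]] * 255
  }
  if (convert) {
    to_eight_bit(raw, channels, pixel_size, frame_interval)
  } else {
    embryo_movie(raw, channels, pixel_size, frame_interval)
  }
}

#' Write an embryo movie (or kymograph) as TIFF
#'
#' @param movie An `embryo_movie`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  rlang::check_installed("tiff")
  d <- dim(movie$frames)
  pages <- vector("list", d[1] * d[2])
  for (t in seq_len(d[1])) for (ch in seq_len(d[2])) {
    pages[[(t - 1) * d[2] + ch]] <- movie$frames[t, ch, , ] / 255
  }
  tiff::writeTIFF(pages, path)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @param k A `kymograph`.
#' @export
write_kymograph_tiff <- function(k, path) {
  rlang::check_installed("tiff")
  img <- k$image
  img[!is.finite(img)] <- 0
  rng <- max(img) - min(img)
  if (rng == 0) rng <- 1
  tiff::writeTIFF((img - min(img)) / rng, path)
  invisible(path)
}
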