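#' Single-particle track tables
#'
#' Track tables are tidy data frames with one row per localization:
#' `track_id`, `frame`, `time_s`, `x_um`, `y_um`, `intensity`. Within a
#' track, frames must be strictly increasing and tracks need at least two
#' points.
#'
#' @param df Data frame with the columns above.
#' @return A validated tibble of class `track_table`.
#' @export
track_table <- function(df) {
  df <- tibble::as_tibble(df)
  required <- c("track_id", "frame", "time_s", "x_um", "y_um", "intensity")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("track table missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  chk <- df |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(n = dplyr::n(),
                     ordered = !is.unsorted(.data$frame, strictly = TRUE),
                     .groups = "drop")
  if (any(chk$n < 2)) rlang::abort("every track needs at least 2 points")
  if (!all(chk$ordered)) rlang::abort("frames must be strictly increasing within a track")
  class(df) <- c("track_table", class(df))
  df
}

#' Read a track table from CSV
#'
#' @param path CSV with header `track_id,frame,time_s,x_um,y_um,intensity`.
#' @return A `track_table`.
#' @export
read_track_csv <- function(path) {
  track_table(utils::read.csv(path))
}

#' Speed of a single track
#'
#' Path length (sum of frame-to-frame displacements) divided by elapsed
#' time: the natural speed estimate for a processive motor. For the net
#' (start-to-end) speed divide [run_length()] by the duration.
#'
#' @param track Data frame of one track's localizations (columns `time_s`,
#'   `x_um`, `y_um`).
#' @return Speed in um/s.
#' @export
track_speed <- function(track) {
  dt <- diff(range(track$time_s))
  if (dt <= 0) rlang::abort("track has zero elapsed time")
  path_length(track) / dt
}

path_length <- function(track) {
  sum(sqrt(diff(track$x_um)^2 + diff(track$y_um)^2))
}

#' Run length of a single track
#'
#' Net start-to-end displacement magnitude of the track, in um. Always at
#' most the path length.
#'
#' @inheritParams track_speed
#' @return Run length in um.
#' @export
run_length <- function(track) {
  n <- nrow(track)
  sqrt((track$x_um[n] - track$x_um[1])^2 + (track$y_um[n] - track$y_um[1])^2)
}

#' Per-track summaries of a track table
#'
#' @param tracks A `track_table` (or any data frame with its columns).
#' @return Tibble with one row per track: `track_id`, `n`, `duration_s`,
#'   `path_um`, `speed_um_s` (path / duration), `run_length_um` (net
#'   displacement), `net_speed_um_s` and `median_intensity`.
#' @export
summarize_tracks <- function(tracks) {
  tracks |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      duration_s = max(.data$time_s) - min(.data$time_s),
      path_um = sum(sqrt(diff(.data$x_um)^2 + diff(.data$y_um)^2)),
      run_length_um = sqrt((dplyr::last(.data$x_um) - dplyr::first(.data$x_um))^2 +
                             (dplyr::last(.data$y_um) - dplyr::first(.data$y_um))^2),
      median_intensity = stats::median(.data$intensity),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      speed_um_s = .data$path_um / .data$duration_s,
      net_speed_um_s = .data$run_length_um / .data$duration_s
    ) |>
    dplyr::select("track_id", "n", "duration_s", "path_um", "speed_um_s",
                  "run_length_um", "net_speed_um_s", "median_intensity")
}

#' Association between particle brightness and speed
#'
#' Pearson correlation between per-track median intensity and speed among
#' moving particles (speed above `speed_floor`), with the two-sided p value
#' from the t distribution. Absence of a correlation argues against
#' higher-order oligomerization affecting motility.
#'
#' @param tracks A `track_table`.
#' @param speed_floor Minimum speed (um/s) for a particle to count as
#'   moving; the conventional display filter is 0.075 um/s. The filter is
#'   used for this association only, never for raw summaries.
#' @return List with `r`, `p_value`, `n` and the per-track `data` tibble
#'   (speed vs median intensity scatter).
#' @export
brightness_speed_association <- function(tracks, speed_floor = 0.075) {
  summ <- summarize_tracks(tracks) |>
    dplyr::filter(.data$speed_um_s > speed_floor)
  if (nrow(summ) < 3) {
    rlang::abort(sprintf("need >= 3 tracks above the speed floor, have %d",
                         nrow(summ)))
  }
  if (stats::sd(summ$median_intensity) == 0 || stats::sd(summ$speed_um_s) == 0) {
    rlang::abort("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(summ$speed_um_s, summ$median_intensity,
                        method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(summ),
       data = dplyr::select(summ, "track_id", "speed_um_s",
                            "median_intensity"))
}

#' Bait-prey co-appearance fraction
#'
#' Percentage of captured bait molecules that appear together with a prey
#' signal in a single-molecule pull-down log. Returned at full precision;
#' display rounding is the caller's concern. (With the published counts of
#' 39 co-appearances among 70,670 baits this evaluates to 0.0552%, which
#' rounds to the printed 0.05% only at one significant digit.)
#'
#' @param log Either a data frame with a logical `has_prey` column (one row
#'   per bait event) or a list/data frame with counts `n_bait` and
#'   `n_coappear`.
#' @return Co-appearance percentage.
#' @export
coappearance_fraction <- function(log) {
  if (is.data.frame(log) && "has_prey" %in% names(log)) {
    n_bait <- nrow(log)
    n_co <- sum(log$has_prey)
  } else {
    n_bait <- log$n_bait
    n_co <- log$n_coappear
  }
  if (is.null(n_bait) || n_bait == 0) rlang::abort("`n_bait` must be > 0")
  if (n_co > n_bait) rlang::abort("`n_coappear` cannot exceed `n_bait`")
  100 * n_co / n_bait
}
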