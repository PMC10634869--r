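#' Traced filament networks
#'
#' A `filament_network` holds a set of traced 3D polyline filaments
#' (microtubules from electron-tomography reconstructions) together with the
#' bounding volume used for density estimates. Coordinates are stored in nm
#' throughout; the volume is reported in both nm and um^3.
#'
#' @param points A data frame with columns `filament_id`, `x`, `y`, `z`
#'   (coordinates in nm), ordered by filament then point index.
#' @param volume Optional named numeric vector
#'   `c(xmin, xmax, ymin, ymax, zmin, zmax)` in nm. Defaults to the tight
#'   axis-aligned bounding box of all points.
#' @param label Free-text label (condition, anaphase stage, ...).
#' @param plus_end Optional data frame with columns `filament_id` and
#'   `plus_end` (`"start"` or `"end"`), marking which traced terminus is the
#'   microtubule plus end.
#' @param chromosome_distance Optional distance between the segregating
#'   chromosome masses (um), used to stage reconstructions.
#'
#' @return An object of class `filament_network`: a list with elements
#'   `points` (tibble), `filaments` (tibble of per-filament metadata),
#'   `volume`, `label` and `chromosome_distance`.
#' @export
#' @examples
#' pts <- tibble::tibble(
#'   filament_id = c(1L, 1L, 2L, 2L),
#'   x = c(0, 500, 0, 500), y = c(0, 0, 50, 50), z = 0
#' )
#' net <- filament_network(pts)
#' filament_lengths(net)
filament_network <- function(points, volume = NULL, label = "",
                             plus_end = NULL, chromosome_distance = NULL) {
  points <- tibble::as_tibble(points)
  required <- c("filament_id", "x", "y", "z")
  missing_cols <- setdiff(required, names(points))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("`points` is missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  points <- dplyr::select(points, dplyr::all_of(required))
  points$filament_id <- as.integer(points$filament_id)
  for (col in c("x", "y", "z")) {
    if (!is.numeric(points[[col]])) {
      rlang::abort(sprintf("coordinate column `%s` must be numeric", col))
    }
  }

  if (is.null(volume)) {
    volume <- if (nrow(points) > 0) {
      c(xmin = min(points$x), xmax = max(points$x),
        ymin = min(points$y), ymax = max(points$y),
        zmin = min(points$z), zmax = max(points$z))
    } else {
      c(xmin = 0, xmax = 1, ymin = 0, ymax = 1, zmin = 0, zmax = 1)
    }
    # a flat network would give a degenerate box; pad such axes minimally
    for (ax in c("x", "y", "z")) {
      lo <- paste0(ax, "min"); hi <- paste0(ax, "max")
      if (volume[hi] - volume[lo] <= 0) {
        volume[lo] <- volume[lo] - 0.5
        volume[hi] <- volume[hi] + 0.5
      }
    }
  }
  volume <- volume[c("xmin", "xmax", "ymin", "ymax", "zmin", "zmax")]
  if (anyNA(volume)) rlang::abort("`volume` must name xmin..zmax")

  fil <- tibble::tibble(filament_id = unique(points$filament_id))
  fil$plus_end <- NA_character_
  if (!is.null(plus_end)) {
    plus_end <- tibble::as_tibble(plus_end)
    bad <- setdiff(plus_end$plus_end, c("start", "end", NA_character_))
    if (length(bad) > 0) rlang::abort("`plus_end` values must be 'start' or 'end'")
    idx <- match(fil$filament_id, plus_end$filament_id)
    fil$plus_end <- plus_end$plus_end[idx]
  }

  net <- structure(
    list(points = points, filaments = fil, volume = volume, label = label,
         chromosome_distance = chromosome_distance),
    class = "filament_network"
  )
  validate_filament_network(net)
}

validate_filament_network <- function(net, tol_nm = 1) {
  pts <- net$points
  if (anyDuplicated(net$filaments$filament_id) > 0) {
    rlang::abort("filament ids must be unique")
  }
  counts <- table(pts$filament_id)
  if (any(counts < 2)) {
    bad <- names(counts)[counts < 2][1]
    rlang::abort(sprintf("filament %s has fewer than 2 points", bad))
  }
  # consecutive points within a filament must be distinct
  step_zero <- pts |>
    dplyr::group_by(.data$filament_id) |>
    dplyr::summarise(
      zero = any(diff(.data$x)^2 + diff(.data$y)^2 + diff(.data$z)^2 == 0),
      .groups = "drop"
    )
  if (any(step_zero$zero)) {
    bad <- step_zero$filament_id[step_zero$zero][1]
    rlang::abort(sprintf("filament %d has coincident consecutive points", bad))
  }
  v <- net$volume
  if (any(c(v["xmax"] - v["xmin"], v["ymax"] - v["ymin"],
            v["zmax"] - v["zmin"]) <= 0)) {
    rlang::abort("bounding volume must have positive extent")
  }
  inside <- pts$x >= v["xmin"] - tol_nm & pts$x <= v["xmax"] + tol_nm &
    pts$y >= v["ymin"] - tol_nm & pts$y <= v["ymax"] + tol_nm &
    pts$z >= v["zmin"] - tol_nm & pts$z <= v["zmax"] + tol_nm
  if (!all(inside)) {
    rlang::abort(sprintf("%d point(s) lie outside the bounding volume",
                         sum(!inside)))
  }
  net
}

#' @export
print.filament_network <- function(x, ...) {
  v <- x$volume
  cat(sprintf("<filament_network> %d filaments, %d points%s\n",
              nrow(x$filaments), nrow(x$points),
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  cat(sprintf("  volume: %.3g um^3 (%.0f x %.0f x %.0f nm)\n",
              network_volume_um3(x),
              v["xmax"] - v["xmin"], v["ymax"] - v["ymin"],
              v["zmax"] - v["zmin"]))
  invisible(x)
}

#' @export
as_tibble.filament_network <- function(x, ...) x$points

#' Bounding-volume size in cubic micrometres
#'
#' @param network A [filament_network()].
#' @return Volume of the bounding box in um^3 (1 um^3 = 1e9 nm^3).
#' @export
network_volume_um3 <- function(network) {
  v <- network$volume
  unname((v["xmax"] - v["xmin"]) * (v["ymax"] - v["ymin"]) *
           (v["zmax"] - v["zmin"]) * 1e-9)
}

polyline_arc_length <- function(x, y, z) {
  if (length(x) < 2) return(0)
  sum(sqrt(diff(x)^2 + diff(y)^2 + diff(z)^2))
}

#' Per-filament arc lengths
#'
#' @param network A [filament_network()].
#' @return A tibble with `filament_id`, `length_nm` and `n_points`.
#' @export
filament_lengths <- function(network) {
  network$points |>
    dplyr::group_by(.data$filament_id) |>
    dplyr::summarise(
      length_nm = polyline_arc_length(.data$x, .data$y, .data$z),
      n_points = dplyr::n(),
      .groups = "drop"
    )
}

#' Drop filaments below a minimum arc length
#'
#' Tracings shorter than the minimal reliable tracing length are removed
#' before any length or interaction statistics; the conventional cutoff for
#' electron-tomography microtubule tracings is 100 nm.
#'
#' @param network A [filament_network()].
#' @param min_length Minimum arc length to retain, in nm.
#' @return A `filament_network` containing only filaments with arc length
#'   `>= min_length`; ids are preserved. Filtering is idempotent and
#'   monotone in `min_length`.
#' @export
filter_short <- function(network, min_length = 100) {
  if (min_length < 0) rlang::abort("`min_length` must be >= 0")
  keep <- filament_lengths(network) |>
    dplyr::filter(.data$length_nm >= min_length) |>
    dplyr::pull("filament_id")
  subset_network(network, keep)
}

subset_network <- function(network, ids) {
  network$points <- dplyr::filter(network$points, .data$filament_id %in% ids)
  network$filaments <- dplyr::filter(network$filaments,
                                     .data$filament_id %in% ids)
  network
}

#' Per-filament end-to-end orientation vectors
#'
#' The orientation is the unit vector from the traced start point to the end
#' point; when a plus-end terminus is recorded, `plus_dir` points from the
#' minus end toward the plus end.
#'
#' @param network A [filament_network()].
#' @return Tibble with `filament_id`, end-to-end unit vector (`ux,uy,uz`),
#'   plus-end direction (`px,py,pz`, `NA` when no plus end is recorded) and
#'   the end-to-end distance `span_nm`.
#' @export
filament_orientations <- function(network) {
  ends <- network$points |>
    dplyr::group_by(.data$filament_id) |>
    dplyr::summarise(
      dx = dplyr::last(.data$x) - dplyr::first(.data$x),
      dy = dplyr::last(.data$y) - dplyr::first(.data$y),
      dz = dplyr::last(.data$z) - dplyr::first(.data$z),
      .groups = "drop"
    )
  span <- sqrt(ends$dx^2 + ends$dy^2 + ends$dz^2)
  out <- tibble::tibble(
    filament_id = ends$filament_id,
    ux = ends$dx / span, uy = ends$dy / span, uz = ends$dz / span,
    span_nm = span
  )
  pe <- network$filaments$plus_end[match(out$filament_id,
                                         network$filaments$filament_id)]
  sign <- ifelse(is.na(pe), NA_real_, ifelse(pe == "end", 1, -1))
  out$px <- out$ux * sign
  out$py <- out$uy * sign
  out$pz <- out$uz * sign
  out
}

# list of per-filament point matrices (n x 3), in filament table order
network_polyline_list <- function(network) {
  ids <- network$filaments$filament_id
  pts <- network$points
  split_idx <- split(seq_len(nrow(pts)), factor(pts$filament_id, levels = ids))
  lapply(split_idx, function(i) {
    cbind(pts$x[i], pts$y[i], pts$z[i])
  })
}
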