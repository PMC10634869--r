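#' Pipeline configuration
#'
#' A validated configuration for [run_pipeline()]. Unknown keys are
#' rejected before any computation; every default is identical to the
#' corresponding function default, so an empty configuration reproduces the
#' documented behaviour of each stage.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A list of class `pipeline_config`.
#' @details Recognized keys: `seed`, `out_dir`, `stages` (character subset
#'   of `"network"`, `"tracking"`, `"frap"`), `d_max`, `l_min`,
#'   `resample_step`, `net_n`, `net_spacing`, `net_length`, `movie_frames`,
#'   `movie_onset`, `elongation_rate`, `segregation_rate`, `rate_window`,
#'   `gap_min`, `persist`, `frap_fraction`, `frap_k`, `frap_noise_sd`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    out_dir = NULL,
    stages = c("network", "tracking", "frap"),
    d_max = 100, l_min = 100, resample_step = 20,
    net_n = 20, net_spacing = 50, net_length = 800,
    movie_frames = 80, movie_onset = 25,
    elongation_rate = 0.09, segregation_rate = 0.13,
    rate_window = 40, gap_min = 1, persist = 3,
    frap_fraction = 0.34, frap_k = 0.05, frap_noise_sd = 0
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown configuration key(s): ",
                        paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, overrides)
  bad_stage <- setdiff(cfg$stages, c("network", "tracking", "frap"))
  if (length(bad_stage) > 0) {
    rlang::abort(paste0("unknown stage(s): ", paste(bad_stage, collapse = ", ")))
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are [pipeline_config()] keys.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Run the synthetic end-to-end analysis pipeline
#'
#' Generates seeded synthetic inputs and runs the corresponding analysis
#' stages: filament network -> interaction statistics; mitosis movie ->
#' tracking -> onset and rates; FRAP curve -> recovery fit. Identical
#' (config, seed) always produce identical outputs; every parameter used is
#' recorded in the returned report (and in `params.json` when `out_dir` is
#' set).
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_report` with one element per stage,
#'   each holding the computed results and the matching ground truth.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) {
    rlang::abort("`config` must be a pipeline_config")
  }
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  report <- list(config = unclass(config))

  if ("network" %in% config$stages) {
    gen <- make_filament_network(
      n = config$net_n, length_dist = c(config$net_length, 0),
      spacing = config$net_spacing, seed = config$seed
    )
    net <- filter_short(gen$network, 100)
    ints <- detect_interactions(net, d_max = config$d_max,
                                l_min = config$l_min,
                                resample_step = config$resample_step,
                                index = TRUE)
    stats <- network_stats(net, ints)
    report$network <- list(stats = tidy(stats), interactions = ints,
                           truth = gen$truth)
    if (!is.null(out_dir)) {
      write_interactions_csv(ints, file.path(out_dir, "interactions.csv"))
      write_stats_json(stats, file.path(out_dir, "network_stats.json"))
    }
  }

  if ("tracking" %in% config$stages) {
    gen <- make_mitosis_movie(
      n_frames = config$movie_frames, onset_frame = config$movie_onset,
      elongation_rate = config$elongation_rate,
      segregation_rate = config$segregation_rate, seed = config$seed
    )
    trace <- track_spindle(gen$movie)
    onset <- detect_anaphase_onset(trace, gap_min = config$gap_min,
                                   persist = config$persist)
    rates <- list(
      onset_frame = onset,
      segregation_um_s = segregation_rate(trace, window = config$rate_window,
                                          what = "chromosome", onset = onset),
      elongation_um_s = segregation_rate(trace, window = config$rate_window,
                                         what = "pole", onset = onset)
    )
    report$tracking <- list(trace = trace, rates = rates, truth = gen$truth)
    if (!is.null(out_dir)) {
      write_trace_csv(trace, file.path(out_dir, "trace.csv"))
      jsonlite::write_json(rates, file.path(out_dir, "rates.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }

  if ("frap" %in% config$stages) {
    gen <- make_frap_curve(fraction = config$frap_fraction,
                           k = config$frap_k,
                           noise_sd = config$frap_noise_sd,
                           seed = config$seed)
    fit <- frap_recovery_fraction(gen$curve)
    report$frap <- list(fit = glance(fit), truth = gen$truth)
    if (!is.null(out_dir)) {
      jsonlite::write_json(as.list(glance(fit)),
                           file.path(out_dir, "frap.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }

  if (!is.null(out_dir)) {
    jsonlite::write_json(unclass(config), file.path(out_dir, "params.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  }
  structure(report, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  if (!is.null(x$network)) {
    cat(sprintf("  network: %d interactions, mean length %.0f nm\n",
                x$network$stats$n_interactions,
                x$network$stats$mean_interaction_length_nm))
  }
  if (!is.null(x$tracking)) {
    cat(sprintf("  tracking: onset frame %s, segregation %.3f um/s, elongation %.3f um/s\n",
                x$tracking$rates$onset_frame,
                x$tracking$rates$segregation_um_s,
                x$tracking$rates$elongation_um_s))
  }
  if (!is.null(x$frap)) {
    cat(sprintf("  frap: fraction %.3f, k %.4g /s\n",
                x$frap$fit$fraction, x$frap$fit$k))
  }
  invisible(x)
}
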