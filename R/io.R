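#' Read a fixed-tissue cell table
#'
#' Reads a CSV of single-cell reporter measurements with required columns
#' `cell_id, gut_id, condition, intensity, esg_pos, delta_pos, ph3_pos`
#' (marker flags as 0/1 or logical). Rows whose intensity is missing,
#' non-numeric or not strictly positive are rejected - intensities must be
#' log-transformable - and reported with their file line numbers in the
#' attribute `"rejected"`.
#'
#' @param path Path to a CSV file.
#' @return A tibble of validated cell records.
#' @export
read_cell_table <- function(path) {
  required <- c("cell_id", "gut_id", "condition", "intensity",
                "esg_pos", "delta_pos", "ph3_pos")
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("cell table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  intensity <- suppressWarnings(as.numeric(df$intensity))
  bad <- !is.finite(intensity) | intensity <= 0
  if (any(bad)) {
    lines <- which(bad) + 1L  # +1 for the header line
    warning(sprintf("rejected %d row(s) with invalid intensity (file line %s)",
                    sum(bad), paste(utils::head(lines, 10), collapse = ", ")),
            call. = FALSE)
  }
  df$intensity <- intensity
  for (flag in c("esg_pos", "delta_pos", "ph3_pos"))
    df[[flag]] <- as.logical(as.integer(as.logical(df[[flag]])) == 1L)
  out <- tibble::as_tibble(df[!bad, , drop = FALSE])
  attr(out, "rejected") <- tibble::tibble(line = which(bad) + 1L,
                                          reason = "non-positive intensity")
  out
}

#' Write a cell table
#'
#' @param records Cell records (tibble).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(records, path) {
  readr::write_csv(tibble::as_tibble(records), path, progress = FALSE)
  invisible(path)
}

#' Read a single-cell track table
#'
#' Reads a CSV of live-imaging traces with required columns
#' `movie_id, cell_id, condition, frame, time_min, gfp, rfp`. Rows are
#' sorted by movie, cell and frame; duplicated (movie, cell, frame)
#' combinations are an error, and frame gaps within a cell are reported in
#' the attribute `"gaps"`.
#'
#' @param path Path to a CSV file.
#' @return A tibble of track rows sorted by movie, cell and frame.
#' @export
read_track_table <- function(path) {
  required <- c("movie_id", "cell_id", "condition", "frame", "time_min",
                "gfp", "rfp")
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("track table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  key <- paste(df$movie_id, df$cell_id, df$frame, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    first <- df[which(dup)[1], ]
    stop(sprintf("duplicate frame %d for cell `%s` in movie `%s`",
                 first$frame, first$cell_id, first$movie_id), call. = FALSE)
  }
  df <- df[order(df$movie_id, df$cell_id, df$frame), , drop = FALSE]
  gaps <- list()
  cells <- unique(df[, c("movie_id", "cell_id")])
  for (i in seq_len(nrow(cells))) {
    sel <- df$movie_id == cells$movie_id[i] & df$cell_id == cells$cell_id[i]
    fr <- df$frame[sel]
    miss <- setdiff(seq(min(fr), max(fr)), fr)
    if (length(miss) > 0)
      gaps[[length(gaps) + 1L]] <- tibble::tibble(
        movie_id = cells$movie_id[i], cell_id = cells$cell_id[i],
        missing_frames = list(miss))
  }
  out <- tibble::as_tibble(df)
  attr(out, "gaps") <- if (length(gaps) > 0) do.call(rbind, gaps) else
    tibble::tibble(movie_id = character(), cell_id = character(),
                   missing_frames = list())
  out
}

#' Write a track table
#'
#' @param tracks Track rows (tibble).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_track_table <- function(tracks, path) {
  readr::write_csv(tibble::as_tibble(tracks), path, progress = FALSE)
  invisible(path)
}

pipeline_defaults <- function() {
  list(
    solver = list(rtol = 1e-8, atol = 1e-10, dt_out = 0.01),
    gmm = list(n_restarts = 20L, seed = 1L, var_floor = 1e-4, min_n = 20L),
    tracks = list(first_half_floor = 0.1, min_points = 8L, off_gfp = 0.1,
                  rfp_present = 0.1, noise_cap = 0.15,
                  rapid_threshold = 0.025, rise_floor = 0.001,
                  fall_floor = 0.001, min_change = 0.08, window = 5L),
    synth = list(preset = "healthy", n_cells = 100L, noise_sd = 0.02)
  )
}

#' Pipeline configuration
#'
#' Builds the configuration list used by [run_pipeline()], starting from
#' package defaults and applying overrides. Unknown sections or keys are
#' rejected. A configuration can also be loaded from a JSON file whose
#' structure mirrors the defaults.
#'
#' @param ... Named sections with named overrides, e.g.
#'   `tracks = list(rapid_threshold = 0.03)`.
#' @param file Optional path to a JSON configuration file.
#' @return A validated configuration list of class `pipeline_config`.
#' @examples
#' cfg <- pipeline_config(gmm = list(n_restarts = 10))
#' cfg$gmm$n_restarts
#' @export
pipeline_config <- function(..., file = NULL) {
  cfg <- pipeline_defaults()
  overrides <- list(...)
  if (!is.null(file)) {
    overrides <- utils::modifyList(jsonlite::read_json(file, simplifyVector = TRUE),
                                   overrides)
  }
  bad_sections <- setdiff(names(overrides), names(cfg))
  if (length(bad_sections) > 0)
    stop("unknown configuration section(s): ",
         paste(bad_sections, collapse = ", "), call. = FALSE)
  for (sec in names(overrides)) {
    bad_keys <- setdiff(names(overrides[[sec]]), names(cfg[[sec]]))
    if (length(bad_keys) > 0)
      stop(sprintf("unknown key(s) in section `%s`: %s", sec,
                   paste(bad_keys, collapse = ", ")), call. = FALSE)
    cfg[[sec]] <- utils::modifyList(cfg[[sec]], overrides[[sec]])
  }
  thresholds <- unlist(cfg$tracks)
  if (any(thresholds <= 0)) stop("track thresholds must be positive", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' Run a pipeline step and write its artifacts
#'
#' Thin orchestration layer over the package's analysis functions: runs
#' one named step with a validated configuration and writes its output
#' CSVs plus a `manifest.json` recording the package version, step,
#' parameters, seed and input-file digests, so a run can be reproduced
#' exactly. Outputs are deterministic given the configuration and seed.
#'
#' Steps:
#' \describe{
#'   \item{`simulate`}{Two- or three-cell circuit simulation; writes
#'     `trajectory.csv` (`time, cell, notch, delta, reporter`). Options:
#'     `kn`, `kd`, `cells` (2 or 3), `t_end`.}
#'   \item{`phasemap`}{Phase map over a (kn, kd) grid; writes `map.csv`
#'     (`kn, kd, value`). Options: `metric`, `kn_values`, `kd_values`.}
#'   \item{`classify`}{Mixture fit + classification of a cell table, per
#'     condition; writes `fits.csv`, `labels.csv`, `crosstab.csv`.
#'     Options: `cells` (path or tibble), `marker`.}
#'   \item{`tracks`}{Track pipeline on a track table; writes `qc.csv`,
#'     `slopes.csv`, `patterns.csv`, `rate_summary.csv`,
#'     `pattern_summary.csv`. Options: `tracks` (path or tibble).}
#'   \item{`synth_population`}{Writes `cells.csv` from a population spec.
#'     Options: `preset` or `spec`, `n_cells`.}
#'   \item{`synth_movie`}{Writes `tracks.csv` and `truth.csv` from the
#'     movie generator. Options: `preset`, `n_cells`.}
#' }
#'
#' @param step Step name (see Details).
#' @param out_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @param seed Integer seed for stochastic steps.
#' @param ... Step options (see Details).
#' @return Named character vector of the files written, invisibly.
#' @export
run_pipeline <- function(step = c("simulate", "phasemap", "classify", "tracks",
                                  "synth_population", "synth_movie"),
                         out_dir, config = pipeline_config(), seed = 1L, ...) {
  step <- match.arg(step)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  opts <- list(...)
  files <- c()
  inputs <- character()
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    readr::write_csv(tibble::as_tibble(df), p, progress = FALSE)
    files[[name]] <<- p
  }

  if (step == "simulate") {
    kn <- opts$kn %||% 0.5; kd <- opts$kd %||% 0.25
    cells <- opts$cells %||% 2L; t_end <- opts$t_end %||% 10
    p <- circuit_params(kn = kn, kd = kd)
    traj <- if (cells == 2L) {
      simulate_pair(p, t_end = t_end, dt_out = config$solver$dt_out,
                    rtol = config$solver$rtol, atol = config$solver$atol)
    } else {
      simulate_triplet(p, t_end = t_end, dt_out = config$solver$dt_out,
                       rtol = config$solver$rtol, atol = config$solver$atol)
    }
    emit(as.data.frame(traj), "trajectory.csv")
  } else if (step == "phasemap") {
    pm <- phase_map(
      kn_values = opts$kn_values %||% 10^seq(-1, 1, length.out = 21),
      kd_values = opts$kd_values %||% seq(0.1, 2, length.out = 20),
      metric = opts$metric %||% "steady_state_delta",
      dt_out = config$solver$dt_out, rtol = config$solver$rtol,
      atol = config$solver$atol
    )
    emit(as.data.frame(pm), "map.csv")
  } else if (step == "classify") {
    cells <- opts$cells
    if (is.character(cells)) { inputs <- cells; cells <- read_cell_table(cells) }
    marker <- opts$marker %||% "delta_pos"
    fits <- list(); labels <- list(); tabs <- list()
    for (cd in unique(cells$condition)) {
      sub <- cells[cells$condition == cd, , drop = FALSE]
      fit <- fit_bimodal_gmm(sub$intensity, seed = config$gmm$seed,
                             n_restarts = config$gmm$n_restarts,
                             min_n = config$gmm$min_n,
                             var_floor = config$gmm$var_floor)
      cls <- classify_cells(sub, fit)
      fits[[cd]] <- tibble::tibble(
        condition = cd, n = fit$n, weight_low = fit$weights[1],
        weight_high = fit$weights[2], mean_low = fit$means[1],
        mean_high = fit$means[2], sd_low = fit$sds[1], sd_high = fit$sds[2],
        boundary_log10 = fit$boundary, loglik = fit$loglik)
      labels[[cd]] <- cls
      tabs[[cd]] <- cbind(condition = cd, subpopulation_proportions(cls, marker))
    }
    emit(do.call(rbind, unname(fits)), "fits.csv")
    emit(do.call(rbind, unname(labels)), "labels.csv")
    emit(do.call(rbind, unname(tabs)), "crosstab.csv")
  } else if (step == "tracks") {
    tracks <- opts$tracks
    if (is.character(tracks)) { inputs <- tracks; tracks <- read_track_table(tracks) }
    tc <- config$tracks
    res <- analyze_tracks(tracks, window = tc$window,
                          rise_floor = tc$rise_floor, fall_floor = tc$fall_floor,
                          min_change = tc$min_change,
                          first_half_floor = tc$first_half_floor,
                          min_points = tc$min_points, off_gfp = tc$off_gfp,
                          rfp_present = tc$rfp_present, noise_cap = tc$noise_cap)
    rs <- rate_summary(res$slopes, rapid_threshold = tc$rapid_threshold)
    emit(res$qc, "qc.csv")
    emit(res$slopes, "slopes.csv")
    emit(res$patterns, "patterns.csv")
    emit(rs$summary, "rate_summary.csv")
    emit(pattern_summary(res$patterns), "pattern_summary.csv")
  } else if (step == "synth_population") {
    spec <- opts$spec %||% population_preset(
      opts$preset %||% config$synth$preset,
      n_cells = opts$n_cells %||% config$synth$n_cells, seed = seed)
    emit(gen_population(spec), "cells.csv")
  } else if (step == "synth_movie") {
    mv <- gen_movie(n_cells = opts$n_cells %||% config$synth$n_cells,
                    preset = opts$preset %||% config$synth$preset,
                    seed = seed, noise_sd = config$synth$noise_sd)
    emit(mv$tracks, "tracks.csv")
    emit(mv$truth, "truth.csv")
  }

  manifest <- list(
    package = "notchspeed",
    version = as.character(utils::packageVersion("notchspeed")),
    step = step, seed = seed,
    config = unclass(config),
    options = opts[!vapply(opts, is.data.frame, logical(1))],
    input_digests = if (length(inputs) > 0)
      as.list(tools::md5sum(inputs)) else list(),
    outputs = names(files)
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  files[["manifest.json"]] <- manifest_path
  invisible(unlist(files))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
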