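# Configuration handling, staged pipeline execution, and trial I/O.

config_schema <- list(
  simulate = c("body_length", "body_halfwidth", "speed", "cast_amplitude",
               "cast_times", "turns", "duration", "dt", "arena_size",
               "mm_per_pixel", "polarity", "background_level", "contrast",
               "noise_sd", "clutter", "start", "heading0", "seed"),
  track = c("polarity", "threshold", "background_threshold", "n_frames",
            "sampling_interval", "margin_factor", "bg_margin"),
  posture = c("smooth_window", "arc_window"),
  identity = c("head_xy", "tail_xy", "tie_tol", "max_jump"),
  calibration = c("mm_per_pixel", "frames_per_second", "landmarks"),
  landscape = c("kind", "slope", "direction", "ref_point", "ref_value",
                "source", "peak", "decay_length", "line_point", "normal",
                "I0", "lit_boundary", "units", "x", "y", "values"),
  events = c("turn_rate", "cast_angle", "min_duration", "run_speed"),
  output = c("dir"),
  input = c("frames_dir"),
  verbosity = NULL
)

#' Read and validate a pipeline configuration
#'
#' A single YAML file (or an equivalent nested list) with per-stage
#' sections (`simulate`, `track`, `posture`, `identity`, `calibration`,
#' `landscape`, `events`, `input`, `output`). The schema is validated
#' before any stage runs; unknown sections or keys are rejected.
#'
#' @param config Path to a YAML file, or a named list.
#' @return The validated configuration list.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stopf("config must be a list or a YAML file path")
  bad <- setdiff(names(config), names(config_schema))
  if (length(bad)) stopf("unknown config section(s): %s",
                         paste(bad, collapse = ", "))
  for (sec in names(config)) {
    allowed <- config_schema[[sec]]
    if (is.null(allowed)) next
    extra <- setdiff(names(config[[sec]]), allowed)
    if (length(extra)) stopf("unknown key(s) in section '%s': %s", sec,
                             paste(extra, collapse = ", "))
  }
  config
}

landscape_from_config <- function(cfg) {
  if (is.null(cfg)) return(NULL)
  kind <- cfg$kind %||% stopf("landscape config needs a 'kind'")
  switch(kind,
    linear = landscape_linear(cfg$slope,
                              unlist(cfg$direction) %||% c(1, 0),
                              unlist(cfg$ref_point) %||% c(0, 0),
                              cfg$ref_value %||% 0,
                              cfg$units %||% "units"),
    radial = landscape_radial(unlist(cfg$source), cfg$peak,
                              cfg$decay_length, cfg$units %||% "units"),
    sideways_light = landscape_sideways_light(
      unlist(cfg$line_point), unlist(cfg$normal) %||% c(1, 0),
      cfg$I0 %||% 1, cfg$decay_length %||% 10,
      cfg$lit_boundary %||% Inf, cfg$units %||% "a.u."),
    grid = landscape_grid(unlist(cfg$x), unlist(cfg$y),
                          do.call(rbind, cfg$values),
                          cfg$units %||% "units"),
    stopf("unknown landscape kind '%s'", kind))
}

#' Write a trial recording to a directory
#'
#' Layout: `background.png`, `crops/0000.png` ..., `offsets.csv`
#' (frame, x0, y0, w, h, timestamp; 0-based offsets) and `trial.json`
#' (sampling interval, stop reason, threshold, polarity).
#'
#' @param trial A `trial_recording`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_trial <- function(trial, dir) {
  dir.create(file.path(dir, "crops"), recursive = TRUE,
             showWarnings = FALSE)
  png::writePNG(trial$background$pixels / 255,
                file.path(dir, "background.png"))
  for (k in seq_along(trial$crops)) {
    png::writePNG(trial$crops[[k]]$img / 255,
                  file.path(dir, "crops", sprintf("%04d.png", k - 1L)))
  }
  utils::write.csv(trial$offsets, file.path(dir, "offsets.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(sampling_interval = trial$sampling_interval,
         n_frames = trial$n_frames, stop_reason = trial$stop_reason,
         threshold = trial$threshold, polarity = trial$polarity,
         background_completed = trial$background$completed),
    file.path(dir, "trial.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

posture_table <- function(trajectory) {
  rows <- lapply(seq_along(trajectory$postures), function(i) {
    p <- trajectory$postures[[i]]
    data.frame(frame = i - 1L,
               head_x = p$head[1], head_y = p$head[2],
               tail_x = p$tail[1], tail_y = p$tail[2],
               centroid_x = p$centroid[1], centroid_y = p$centroid[2],
               midpoint_x = p$midpoint[1], midpoint_y = p$midpoint[2],
               area = p$area, perimeter = p$perimeter,
               skeleton_length = p$skeleton_length,
               flags = paste(p$flags, collapse = ";"))
  })
  do.call(rbind, rows)
}

#' Run the full pipeline on a configuration
#'
#' Staged execution mirroring the tracking workflow: simulate (or read
#' frames), track, per-frame posture analysis, identity labeling and
#' flagging, calibration to arena mm, landscape fusion into sensorimotor
#' records, event detection, and artifact output. A JSON manifest records
#' the configuration, seed and QC fractions so any run is reproducible.
#'
#' @param config A config list or YAML path (see [read_run_config()]).
#' @param out_dir Output directory (overrides `config$output$dir`).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with all stage results (`sim`, `trial`,
#'   `trajectory`, `calibration`, `records`, `events`, `qc`, `out_dir`).
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  config <- read_run_config(config)
  out_dir <- out_dir %||% config$output$dir %||%
    stopf("no output directory configured")
  say <- function(...) if (!quiet) message(sprintf(...))

  # frames: synthetic or from disk
  sim <- NULL
  if (!is.null(config$input$frames_dir)) {
    frames <- read_frames(config$input$frames_dir)
    say("read %d frames from %s", length(frames),
        config$input$frames_dir)
  } else {
    params <- do.call(crawl_params, config$simulate %||% list())
    sim <- simulate_crawl(params)
    frames <- sim$frames
    say("simulated %d frames (seed %d)", length(frames), params$seed)
  }

  trial <- track_stream(frames, config$track %||% list())
  say("tracked %d frames; stop reason: %s", trial$n_frames,
      trial$stop_reason)

  pc <- config$posture %||% list()
  postures <- lapply(seq_along(trial$crops), function(k)
    analyze_posture(crop_mask(trial, k),
                    smooth_window = pc$smooth_window %||% 5,
                    arc_window = pc$arc_window))
  qc <- qc_summary(postures)
  say("postures: %.1f%% spur, %.1f%% blob-like",
      100 * qc$fraction_spur, 100 * qc$fraction_blob_like)

  ic <- config$identity %||% list()
  global_end <- function(p, k, row) {
    c(p$ends[row, 1] + trial$crops[[k]]$c0 - 1L,
      p$ends[row, 2] + trial$crops[[k]]$r0 - 1L)
  }
  head_hint <- unlist(ic$head_xy) %||% global_end(postures[[1]], 1L, 1L)
  tail_hint <- unlist(ic$tail_xy) %||% global_end(postures[[1]], 1L, 2L)
  # label in full-frame pixel coordinates: shift each posture by its crop
  # offset first so hints and the distance rule share one frame of
  # reference
  cal_cfg <- config$calibration %||% list()
  cal <- calibration(
    mm_per_pixel = cal_cfg$mm_per_pixel %||%
      (if (!is.null(cal_cfg$landmarks))
         fit_scale(as.data.frame(cal_cfg$landmarks))
       else if (!is.null(sim)) sim$params$mm_per_pixel
       else 1),
    frames_per_second = cal_cfg$frames_per_second %||%
      (1 / (config$track$sampling_interval %||%
              (if (!is.null(sim)) sim$params$dt else 1))))
  px_cal <- calibration(1, cal$frames_per_second)
  shifted <- lapply(seq_along(postures), function(k)
    to_arena_frame(postures[[k]],
                   c(trial$crops[[k]]$c0 - 1L, trial$crops[[k]]$r0 - 1L),
                   px_cal))
  trajectory <- label_trajectory(shifted, head_hint, tail_hint,
                                 tie_tol = ic$tie_tol %||% 1)
  say("flagged %d frame(s)", nrow(trajectory$flagged_frames))

  # convert the labeled full-frame-pixel trajectory to mm
  trajectory$postures <- lapply(trajectory$postures, function(p)
    to_arena_frame(p, c(0, 0), cal))

  landscape <- landscape_from_config(config$landscape)
  records <- build_records(trajectory, cal, landscape)
  ev <- detect_events(records, config$events %||% list())
  say("events: %d", nrow(ev$events))

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_trial(trial, out_dir)
  utils::write.csv(posture_table(trajectory),
                   file.path(out_dir, "postures.csv"), row.names = FALSE)
  utils::write.csv(trajectory$flagged_frames,
                   file.path(out_dir, "flags.csv"), row.names = FALSE)
  jsonlite::write_json(list(mm_per_pixel = cal$mm_per_pixel,
                            frames_per_second = cal$frames_per_second,
                            landmarks = cal$landmarks),
                       file.path(out_dir, "calibration.json"),
                       auto_unbox = TRUE, digits = NA)
  rec_out <- cbind(records,
                   event_label = ev$labels)
  utils::write.csv(rec_out, file.path(out_dir, "sensorimotor.csv"),
                   row.names = FALSE)
  utils::write.csv(ev$events, file.path(out_dir, "events.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("sensetrackr")),
         config = config, qc = qc, stop_reason = trial$stop_reason),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  say("artifacts written to %s", out_dir)
  invisible(list(sim = sim, trial = trial, trajectory = trajectory,
                 calibration = cal, records = records, events = ev,
                 qc = qc, out_dir = out_dir))
}

#' Apply a corrections file to a trial directory
#'
#' Reads `corrections.csv` (frame, action), applies it to the trajectory
#' and rewrites `postures.csv` and `flags.csv`.
#'
#' @param trajectory A `labeled_trajectory`.
#' @param corrections_csv Path to a CSV with columns frame, action.
#' @return The corrected trajectory.
#' @export
review_trajectory <- function(trajectory, corrections_csv) {
  corr <- utils::read.csv(corrections_csv)
  resolve_flags(trajectory, corr)
}
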