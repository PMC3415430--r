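# Fusion of calibrated trajectories with stimulus landscapes: per-frame
# sensorimotor records, behavioral event detection, trial merging.

#' Relative stimulus change
#'
#' Percentage change of a stimulus increment over its baseline, e.g. a
#' 50 nM concentration change on a 1 uM background is a 5% relative
#' difference.
#'
#' @param delta Stimulus change (same units as `baseline`).
#' @param baseline Non-zero baseline value.
#' @return Percentage, `100 * delta / baseline`.
#' @export
relative_change <- function(delta, baseline) {
  if (any(baseline == 0)) stopf("zero_baseline")
  100 * delta / baseline
}

# Heading time series (degrees) from centroid displacement over a
# centered 3-frame window; NA where the displacement is (numerically)
# zero. Falls back to the tail->head body axis at low speed.
headings_from_centroids <- function(centroids, axes, speeds,
                                    low_speed) {
  n <- nrow(centroids)
  i0 <- pmax(seq_len(n) - 1L, 1L)
  i1 <- pmin(seq_len(n) + 1L, n)
  dx <- centroids[i1, 1] - centroids[i0, 1]
  dy <- centroids[i1, 2] - centroids[i0, 2]
  th <- atan2(dy, dx) * 180 / pi
  slow <- speeds < low_speed | (dx == 0 & dy == 0)
  th[slow] <- atan2(axes[slow, 2], axes[slow, 1]) * 180 / pi
  th
}

unwrap_deg <- function(th) {
  d <- diff(th)
  d <- (d + 180) %% 360 - 180
  cumsum(c(th[1], d))
}

#' Build per-frame sensorimotor records
#'
#' Fuses an arena-calibrated labeled trajectory with a stimulus landscape:
#' per retained (non-discarded) frame it records the body landmark
#' positions, the stimulus at the head, its time derivative (central
#' difference; one-sided at the ends), the bearing of the heading to the
#' local gradient, skeleton-resolved field differences, and — for
#' sideways light with a shadow boundary — the lit contour fraction.
#'
#' @param trajectory A `labeled_trajectory` with postures in arena mm
#'   (see [to_arena_frame()]).
#' @param cal A `calibration` (provides frames per second).
#' @param landscape A `landscape`, or `NULL` for plain kinematics.
#' @param smooth_derivative If `TRUE`, boxcar-smooth (width 3) the head
#'   value before differentiating; off by default.
#' @return A `sensorimotor_records` data.frame (one row per frame) with
#'   attributes `units`, `skeleton_values` (list of per-frame skeleton
#'   field series) and `body_length` (median skeleton length, mm).
#' @export
build_records <- function(trajectory, cal, landscape = NULL,
                          smooth_derivative = FALSE) {
  postures <- if (inherits(trajectory, "labeled_trajectory"))
    trajectory$postures else trajectory
  keep <- !vapply(postures, function(p) "discarded" %in% p$flags,
                  logical(1))
  postures <- postures[keep]
  n <- length(postures)
  if (!n) stopf("no retained frames")
  fps <- cal$frames_per_second
  t <- (which(keep) - 1L) / fps
  get_pts <- function(field)
    t(vapply(postures, function(p) as.numeric(p[[field]]), numeric(2)))
  head <- get_pts("head"); tail <- get_pts("tail")
  centroid <- get_pts("centroid"); midpoint <- get_pts("midpoint")
  skl <- vapply(postures, function(p) p$skeleton_length, numeric(1))
  body_length <- stats::median(skl)

  # centroid speed (central difference)
  i0 <- pmax(seq_len(n) - 1L, 1L); i1 <- pmin(seq_len(n) + 1L, n)
  span <- t[i1] - t[i0]
  speed <- sqrt((centroid[i1, 1] - centroid[i0, 1])^2 +
                (centroid[i1, 2] - centroid[i0, 2])^2) / span
  axes <- head - tail
  heading <- headings_from_centroids(centroid, axes, speed,
                                     low_speed = 0.05 * body_length)

  head_value <- rep(NA_real_, n)
  bearing <- rep(NA_real_, n)
  light_fraction <- rep(NA_real_, n)
  skeleton_values <- vector("list", n)
  if (!is.null(landscape)) {
    head_value <- field_at(landscape, head)
    for (i in seq_len(n)) {
      g <- tryCatch(gradient_at(landscape, head[i, ]),
                    error = function(e) c(0, 0))
      hv <- c(cos(heading[i] * pi / 180), sin(heading[i] * pi / 180))
      bearing[i] <- if (sqrt(sum(g^2)) < 1e-12) NA_real_
        else angle_between_deg(hv, g)
      if (!is.null(postures[[i]]$skeleton))
        skeleton_values[[i]] <-
          sample_along_skeleton(landscape, postures[[i]]$skeleton)
      if (inherits(landscape, "landscape_sideways_light") &&
          is.finite(landscape$lit_boundary) &&
          !is.null(postures[[i]]$contour))
        light_fraction[i] <-
          contour_light_fraction(landscape, postures[[i]]$contour)
    }
  }
  hv_s <- head_value
  if (smooth_derivative && n >= 3)
    hv_s <- stats::filter(head_value, rep(1 / 3, 3), sides = 2) |>
      as.numeric() |> (\(x) ifelse(is.na(x), head_value, x))()
  deriv <- rep(NA_real_, n)
  if (n >= 2) {
    deriv <- (hv_s[i1] - hv_s[i0]) / span
  }
  rec <- data.frame(frame = which(keep), t = t,
                    head_x = head[, 1], head_y = head[, 2],
                    tail_x = tail[, 1], tail_y = tail[, 2],
                    centroid_x = centroid[, 1], centroid_y = centroid[, 2],
                    midpoint_x = midpoint[, 1], midpoint_y = midpoint[, 2],
                    skeleton_length = skl, speed = speed,
                    heading = heading, head_value = head_value,
                    head_value_derivative = deriv, bearing = bearing,
                    light_fraction = light_fraction)
  attr(rec, "units") <- if (is.null(landscape)) NA_character_
    else landscape$units
  attr(rec, "skeleton_values") <- skeleton_values
  attr(rec, "body_length") <- body_length
  class(rec) <- c("sensorimotor_records", "data.frame")
  rec
}

runs_of <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  data.frame(value = r$values, start = ends - r$lengths + 1L, end = ends)
}

#' Detect behavioral events (runs, turns, head casts)
#'
#' Labels every frame as exactly one of run/turn/cast:
#' * turn — contiguous spans where the absolute heading rate exceeds
#'   `turn_rate` for at least `min_duration` frames, while the centroid is
#'   moving (at or above the run-speed gate; heading is undefined when
#'   nearly stationary);
#' * cast — spans where the head-bend angle (deviation from a straight
#'   head-midpoint-tail axis) exceeds `cast_angle` while the centroid
#'   speed is below the run-speed gate, for at least `min_duration`
#'   frames; casts take precedence over turns;
#' * run — everything else.
#'
#' @param records A `sensorimotor_records` data.frame.
#' @param thresholds List: `turn_rate` (deg/s), `cast_angle` (deg),
#'   `min_duration` (frames), `run_speed` (mm/s; default 0.15 body
#'   lengths/s using the records' median body length).
#' @return `list(events, labels)`: `events` a data.frame (type,
#'   start_frame, end_frame, magnitude — net heading change for turns,
#'   peak bend for casts), `labels` the per-frame label vector.
#' @export
detect_events <- function(records,
                          thresholds = list()) {
  if (nrow(records) < 3) stopf("need >= 3 records")
  if (any(diff(records$t) <= 0)) stopf("non-monotonic timestamps")
  turn_rate <- thresholds$turn_rate %||% 20
  cast_angle <- thresholds$cast_angle %||% 30
  min_dur <- thresholds$min_duration %||% 2
  bl <- attr(records, "body_length") %||%
    stats::median(records$skeleton_length)
  run_speed <- thresholds$run_speed %||% (0.15 * bl)

  n <- nrow(records)
  th <- unwrap_deg(records$heading)
  i0 <- pmax(seq_len(n) - 1L, 1L); i1 <- pmin(seq_len(n) + 1L, n)
  rate <- (th[i1] - th[i0]) / (records$t[i1] - records$t[i0])

  # head-bend angle: angle between (midpoint - head) and (tail - midpoint)
  v1x <- records$midpoint_x - records$head_x
  v1y <- records$midpoint_y - records$head_y
  v2x <- records$tail_x - records$midpoint_x
  v2y <- records$tail_y - records$midpoint_y
  bend <- abs(atan2(v1x * v2y - v1y * v2x,
                    v1x * v2x + v1y * v2y)) * 180 / pi

  slow <- records$speed < run_speed
  cast_f <- bend > cast_angle & slow

  label <- rep("run", n)
  assign_spans <- function(flag, type) {
    sp <- runs_of(flag)
    sp <- sp[sp$value & (sp$end - sp$start + 1L) >= min_dur, , drop = FALSE]
    for (k in seq_len(nrow(sp)))
      label[sp$start[k]:sp$end[k]] <<- type
    sp
  }
  cast_sp0 <- runs_of(cast_f)
  cast_sp0 <- cast_sp0[cast_sp0$value &
                       (cast_sp0$end - cast_sp0$start + 1L) >= min_dur, ,
                       drop = FALSE]
  # centroid-derived heading is contaminated during and shortly after a
  # head cast (the swing displaces the centroid); exclude a guard window
  # around detected casts from turn candidacy
  guard_s <- thresholds$cast_guard %||% 1
  dt_med <- stats::median(diff(records$t))
  guard_n <- ceiling(guard_s / dt_med)
  near_cast <- rep(FALSE, n)
  for (k in seq_len(nrow(cast_sp0))) {
    lo <- max(1L, cast_sp0$start[k] - guard_n)
    hi <- min(n, cast_sp0$end[k] + guard_n)
    near_cast[lo:hi] <- TRUE
  }
  turn_f <- abs(rate) > turn_rate & !slow & !cast_f & !near_cast

  turn_sp <- assign_spans(turn_f, "turn")
  cast_sp <- assign_spans(cast_f, "cast")   # casts override turns

  ev <- list()
  for (k in seq_len(nrow(turn_sp))) {
    s <- turn_sp$start[k]; e <- turn_sp$end[k]
    if (!any(label[s:e] == "turn")) next
    ev[[length(ev) + 1L]] <- data.frame(
      type = "turn", start_frame = records$frame[s],
      end_frame = records$frame[e],
      magnitude = th[min(e + 1L, n)] - th[max(s - 1L, 1L)])
  }
  for (k in seq_len(nrow(cast_sp))) {
    s <- cast_sp$start[k]; e <- cast_sp$end[k]
    ev[[length(ev) + 1L]] <- data.frame(
      type = "cast", start_frame = records$frame[s],
      end_frame = records$frame[e], magnitude = max(bend[s:e]))
  }
  events <- if (length(ev)) do.call(rbind, ev)
    else data.frame(type = character(0), start_frame = integer(0),
                    end_frame = integer(0), magnitude = numeric(0))
  list(events = events, labels = label)
}

#' Merge sensorimotor records from several trials
#'
#' Row-concatenates per-trial record tables into a single data file with a
#' `trial` id column; trials must share the same schema and stimulus
#' units.
#'
#' @param trials Named (or unnamed) list of `sensorimotor_records`.
#' @return Combined data.frame with a `trial` column; per-trial units kept
#'   in the `units` attribute.
#' @export
merge_trials <- function(trials) {
  if (!length(trials)) stopf("empty trial list")
  units <- vapply(trials, function(tr) {
    u <- attr(tr, "units")
    if (is.null(u)) NA_character_ else u
  }, character(1))
  uu <- unique(units[!is.na(units)])
  if (length(uu) > 1) stopf("incompatible_units")
  ids <- names(trials) %||% as.character(seq_along(trials))
  if (is.null(names(trials))) ids <- as.character(seq_along(trials))
  out <- do.call(rbind, lapply(seq_along(trials), function(i) {
    df <- as.data.frame(trials[[i]])
    cbind(trial = ids[i], df)
  }))
  attr(out, "units") <- if (length(uu)) uu else NA_character_
  out
}
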