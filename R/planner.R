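# Experiment-design calculator: posture resolution, tracking time before
# the animal reaches the arena edge, and storage requirements.

#' Posture resolution in pixels per body length
#'
#' For a frame of `P` pixels along the field of view and an
#' arena-to-organism length ratio `ratio` (L / lambda), the organism spans
#' `P / ratio` pixels. A 1024-px frame at ratio 20 gives 51.2 px per body
#' length.
#'
#' @param P Frame resolution (px) along the field-of-view length.
#' @param ratio Field-of-view length over organism length (>= 1).
#' @return Pixels per body length.
#' @export
posture_resolution <- function(P, ratio) {
  if (any(ratio < 1)) stopf("ratio must be >= 1 (the animal must fit)")
  P / ratio
}

#' Tracking time before the animal reaches the arena edge
#'
#' Distance to the nearest edge in body lengths (ratio / 2 from the
#' center, ratio from the far edge) divided by the speed in body lengths
#' per second. Zero speed yields `Inf`.
#'
#' @param ratio Arena-to-organism length ratio.
#' @param v Speed in body lengths per second (>= 0).
#' @param start `"center"` or `"edge"` (worst case, from the far edge).
#' @return Time in seconds.
#' @export
time_to_edge <- function(ratio, v, start = c("center", "edge")) {
  start <- match.arg(start)
  if (v < 0) stopf("speed must be >= 0")
  dist_bl <- if (start == "center") ratio / 2 else ratio
  if (v == 0) return(Inf)
  dist_bl / v
}

#' Storage requirements of a tracking experiment
#'
#' Frame counts are floored (a partial frame is never stored). Bounding-box
#' mode stores only the crop around the animal; full-frame mode stores the
#' whole frame.
#'
#' @param frequency Tracking frequency (Hz).
#' @param duration Experiment duration (s).
#' @param crop_px Crop size in pixels (px^2).
#' @param bytes_per_pixel Bytes per pixel (default 1, 8-bit grayscale).
#' @param full_frame_px Optional full frame size (px^2).
#' @return `list(n_frames, bbox_bytes, full_frame_bytes)`.
#' @export
storage_estimate <- function(frequency, duration, crop_px,
                             bytes_per_pixel = 1, full_frame_px = NULL) {
  n_frames <- floor(frequency * duration)
  list(n_frames = n_frames,
       bbox_bytes = n_frames * crop_px * bytes_per_pixel,
       full_frame_bytes = if (is.null(full_frame_px)) NULL
         else n_frames * full_frame_px * bytes_per_pixel)
}

#' Plan a tracking experiment
#'
#' Relates organism size, field of view, frame resolution, speed,
#' tracking frequency and duration into the quantities that matter when
#' designing a tracking experiment, and warns when the sampling is too
#' slow for the head/tail distance rule (more than half a body length of
#' motion per sample).
#'
#' @param lambda Organism length (mm).
#' @param fov Field-of-view length (mm).
#' @param pixels Frame resolution along the field of view (px).
#' @param speed Organism speed (body lengths / s).
#' @param freq Tracking frequency (Hz).
#' @param duration Experiment duration (s).
#' @param bytes_per_pixel Bytes per pixel.
#' @param crop_margin_factor Crop size relative to the organism's pixel
#'   length (the tracker's bounding box plus margin).
#' @return A `tracking_plan` list; printed as a table.
#' @export
plan_experiment <- function(lambda, fov, pixels, speed, freq, duration,
                            bytes_per_pixel = 1, crop_margin_factor = 2) {
  if (fov < lambda) stopf("field of view must contain the organism")
  ratio <- fov / lambda
  res <- posture_resolution(pixels, ratio)
  crop_side <- crop_margin_factor * res
  st <- storage_estimate(freq, duration, crop_side^2, bytes_per_pixel,
                         full_frame_px = pixels^2)
  bl_per_sample <- speed / freq
  plan <- list(ratio = ratio,
               posture_resolution_px = res,
               time_to_edge_center_s = time_to_edge(ratio, speed, "center"),
               time_to_edge_far_s = time_to_edge(ratio, speed, "edge"),
               n_frames = st$n_frames,
               bbox_bytes = st$bbox_bytes,
               full_frame_bytes = st$full_frame_bytes,
               body_lengths_per_sample = bl_per_sample,
               distance_rule_ok = bl_per_sample < 0.5)
  if (!plan$distance_rule_ok)
    warning("sampling slower than 0.5 body length per frame: ",
            "head/tail distance rule may fail")
  class(plan) <- "tracking_plan"
  plan
}

#' @export
print.tracking_plan <- function(x, ...) {
  cat(sprintf("arena/organism ratio        %10.2f\n", x$ratio))
  cat(sprintf("posture resolution          %10.1f px/body length\n",
              x$posture_resolution_px))
  cat(sprintf("time to edge (center start) %10.1f s\n",
              x$time_to_edge_center_s))
  cat(sprintf("time to edge (edge start)   %10.1f s\n",
              x$time_to_edge_far_s))
  cat(sprintf("frames stored               %10d\n", x$n_frames))
  cat(sprintf("storage, bounding box       %10.2f MB\n",
              x$bbox_bytes / 2^20))
  cat(sprintf("storage, full frames        %10.2f MB\n",
              x$full_frame_bytes / 2^20))
  cat(sprintf("motion per sample           %10.3f body lengths%s\n",
              x$body_lengths_per_sample,
              if (x$distance_rule_ok) "" else "  (TOO SLOW)"))
  invisible(x)
}
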