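# Pixel/frame to arena millimeter/second conversion.

#' Build a calibration object
#'
#' @param mm_per_pixel Spatial scale (mm per pixel, isotropic).
#' @param frames_per_second Temporal resolution (Hz).
#' @param landmarks Optional landmark table (see [fit_scale()]).
#' @return A `calibration` object.
#' @export
calibration <- function(mm_per_pixel, frames_per_second = 1,
                        landmarks = NULL) {
  if (mm_per_pixel <= 0 || frames_per_second <= 0)
    stopf("mm_per_pixel and frames_per_second must be positive")
  structure(list(mm_per_pixel = mm_per_pixel,
                 frames_per_second = frames_per_second,
                 landmarks = landmarks),
            class = "calibration")
}

#' Fit the spatial scale from arena landmarks
#'
#' Each landmark pair is two pixel positions separated by a distance known
#' to the experimenter. The conversion factor is the mean over pairs of
#' known mm / pixel distance; a relative spread above 2% among pairs
#' triggers a warning (inconsistent landmarks).
#'
#' @param landmarks data.frame with columns `x1, y1, x2, y2` (px) and
#'   `mm` (known distance).
#' @return mm-per-pixel scale factor.
#' @export
fit_scale <- function(landmarks) {
  if (!nrow(landmarks)) stopf("need at least one landmark pair")
  dpx <- sqrt((landmarks$x2 - landmarks$x1)^2 +
              (landmarks$y2 - landmarks$y1)^2)
  if (any(dpx == 0)) stopf("zero pixel distance in landmark pair")
  scales <- landmarks$mm / dpx
  m <- mean(scales)
  if (length(scales) > 1 && (max(scales) - min(scales)) / m > 0.02)
    warning(sprintf("landmark scales spread by %.1f%% (> 2%%)",
                    100 * (max(scales) - min(scales)) / m))
  m
}

#' Convert a posture to the arena frame of reference
#'
#' Translates crop-local coordinates by the bounding-box offset and scales
#' to millimeters: every coordinate c becomes (c + offset) * mm_per_pixel;
#' areas scale by mm_per_pixel^2, lengths by mm_per_pixel.
#'
#' @param posture A `posture` object (crop-local pixel coordinates).
#' @param bbox_offset `c(x0, y0)` 0-based offset of the crop's top-left
#'   corner in the full frame.
#' @param cal A `calibration` object.
#' @return The posture with all coordinates in arena mm (and a
#'   `units = "mm"` marker).
#' @export
to_arena_frame <- function(posture, bbox_offset, cal) {
  stopifnot(inherits(cal, "calibration"))
  s <- cal$mm_per_pixel
  shift_pts <- function(m) {
    if (is.null(m)) return(NULL)
    cbind((m[, 1] + bbox_offset[1]) * s, (m[, 2] + bbox_offset[2]) * s)
  }
  shift_pt <- function(p) {
    if (is.null(p)) return(NULL)
    c(x = unname((p[1] + bbox_offset[1]) * s),
      y = unname((p[2] + bbox_offset[2]) * s))
  }
  posture$contour <- shift_pts(posture$contour)
  posture$skeleton <- shift_pts(posture$skeleton)
  posture$ends <- shift_pts(posture$ends)
  posture$head <- shift_pt(posture$head)
  posture$tail <- shift_pt(posture$tail)
  posture$centroid <- shift_pt(posture$centroid)
  posture$midpoint <- shift_pt(posture$midpoint)
  posture$area <- posture$area * s^2
  posture$perimeter <- posture$perimeter * s
  posture$skeleton_length <- posture$skeleton_length * s
  posture$units <- "mm"
  posture
}
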