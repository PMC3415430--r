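# Online-stage operations: thresholding, background reconstruction,
# largest-object retention, and the bounding-box tracking loop.

#' Binarize a grayscale frame
#'
#' @param frame Grayscale matrix (0-255).
#' @param threshold Intensity threshold in \[0, 255\].
#' @param polarity `"dark_on_light"` keeps pixels below the threshold,
#'   `"light_on_dark"` pixels above it.
#' @return Logical matrix (TRUE = animal-candidate pixels).
#' @export
binarize <- function(frame, threshold,
                     polarity = c("dark_on_light", "light_on_dark")) {
  polarity <- match.arg(polarity)
  if (threshold < 0 || threshold > 255)
    stopf("threshold must lie in [0, 255]")
  if (polarity == "dark_on_light") frame < threshold else frame > threshold
}

#' Suggest a binarization threshold
#'
#' Returns the threshold maximizing the between-class variance of the
#' intensity histogram (Otsu's criterion, via [EBImage::otsu()]). The caller
#' may override it; this is the automatic starting point.
#'
#' @inheritParams binarize
#' @return Threshold intensity (0-255).
#' @export
suggest_threshold <- function(frame,
                              polarity = c("dark_on_light",
                                           "light_on_dark")) {
  polarity <- match.arg(polarity)
  if (length(unique(as.vector(frame))) < 2L) stopf("degenerate_histogram")
  th <- EBImage::otsu(EBImage::Image(t(frame) / 255), range = c(0, 1),
                      levels = 256)
  th * 255
}

# Robust default threshold for detecting a small animal: halfway between
# the background level (median intensity) and the most animal-like
# intensity. Otsu's between-class-variance criterion degenerates when the
# animal occupies a tiny fraction of the frame (it splits the background
# noise instead), so the tracking loop uses this midpoint rule by default;
# suggest_threshold() remains available for balanced histograms and both
# can be overridden in the config.
detection_threshold <- function(frame, polarity) {
  med <- stats::median(frame)
  if (polarity == "dark_on_light") (med + min(frame)) / 2
  else (med + max(frame)) / 2
}

# 8-connected component labeling by breadth-first flood fill over the
# foreground pixels (EBImage::bwlabel is 4-connected, which would split
# thin diagonal bodies).
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  # pad by one so neighbor indexing never leaves the matrix
  pm <- matrix(FALSE, nr + 2L, nc + 2L)
  pm[2:(nr + 1L), 2:(nc + 1L)] <- mask
  npr <- nr + 2L
  offs <- c(-1L, 1L, -npr, npr, -npr - 1L, -npr + 1L, npr - 1L, npr + 1L)
  labels <- integer(length(pm))
  fg <- which(pm)
  lab <- 0L
  for (s in fg) {
    if (labels[s] != 0L) next
    lab <- lab + 1L
    queue <- s
    labels[s] <- lab
    while (length(queue)) {
      nb <- unique(as.vector(outer(queue, offs, `+`)))
      nb <- nb[pm[nb] & labels[nb] == 0L]
      labels[nb] <- lab
      queue <- nb
    }
  }
  out <- matrix(labels, npr)[2:(nr + 1L), 2:(nc + 1L)]
  out
}

#' Retain only the largest connected object
#'
#' Keeps the largest 8-connected component of a binary mask and clears all
#' other foreground pixels; small noise specks and substrate impurities are
#' erased this way. Ties are broken in favor of the component whose
#' top-left-most pixel comes first in row-major order.
#'
#' @param mask Logical matrix.
#' @return Logical matrix containing a single component.
#' @export
largest_object <- function(mask) {
  if (!any(mask)) stopf("no_object")
  labels <- label_components(mask)
  sizes <- tabulate(labels)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # row-major key: (row - 1) * ncol + (col - 1)
    nc <- ncol(mask)
    key <- vapply(best, function(l) {
      idx <- which(labels == l, arr.ind = TRUE)
      min((idx[, 1] - 1) * nc + (idx[, 2] - 1))
    }, numeric(1))
    best <- best[which.min(key)]
  }
  labels == best
}

bbox_of <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  c(r0 = min(idx[, 1]), r1 = max(idx[, 1]),
    c0 = min(idx[, 2]), c1 = max(idx[, 2]))
}

expand_bbox <- function(bb, margin, nr, nc) {
  c(r0 = max(1, floor(bb["r0"] - margin)),
    r1 = min(nr, ceiling(bb["r1"] + margin)),
    c0 = max(1, floor(bb["c0"] - margin)),
    c1 = min(nc, ceiling(bb["c1"] + margin)))
}

boxes_disjoint <- function(a, b) {
  a["r1"] < b["r0"] || b["r1"] < a["r0"] ||
    a["c1"] < b["c0"] || b["c1"] < a["c0"]
}

#' Reconstruct the arena background from a frame sequence
#'
#' Implements background completion with the animal present from the start:
#' the animal is detected in the first frame as the largest salient object,
#' a box is cropped around it, the outer image is kept, and the box interior
#' is patched from the first later frame whose detected animal box is
#' disjoint from it (the animal has moved away). Static clutter thereby
#' stays in the background and cancels on subtraction.
#'
#' @param frames List of grayscale matrices.
#' @param threshold Binarization threshold; `NULL` picks one automatically
#'   from the first frame via [suggest_threshold()].
#' @param polarity See [binarize()].
#' @param margin Box margin in pixels around the detected animal.
#' @return A `background` object: `list(pixels, completed, patch_box)`.
#'   If the animal never leaves its initial box a warning of class
#'   `background_incomplete` is signalled and `completed` is `FALSE`.
#' @export
reconstruct_background <- function(frames, threshold = NULL,
                                   polarity = c("dark_on_light",
                                                "light_on_dark"),
                                   margin = 5) {
  polarity <- match.arg(polarity)
  f0 <- frames[[1]]
  threshold <- threshold %||% detection_threshold(f0, polarity)
  nr <- nrow(f0); nc <- ncol(f0)
  obj0 <- largest_object(binarize(f0, threshold, polarity))
  box0 <- expand_bbox(bbox_of(obj0), margin, nr, nc)
  for (i in seq_along(frames)[-1]) {
    m <- binarize(frames[[i]], threshold, polarity)
    if (!any(m)) next
    box <- bbox_of(largest_object(m))
    if (boxes_disjoint(box, box0)) {
      bg <- f0
      bg[box0["r0"]:box0["r1"], box0["c0"]:box0["c1"]] <-
        frames[[i]][box0["r0"]:box0["r1"], box0["c0"]:box0["c1"]]
      return(structure(list(pixels = bg, completed = TRUE,
                            patch_box = box0),
                       class = "background"))
    }
  }
  warning(warningCondition("background_incomplete",
                           class = "background_incomplete"))
  structure(list(pixels = f0, completed = FALSE, patch_box = box0),
            class = "background")
}

#' Subtract the background from a frame
#'
#' Signed difference folded to the animal-positive side per polarity and
#' clipped at zero: the result is a grayscale image in which the animal is
#' bright on a dark (zero) background regardless of the original polarity,
#' and static clutter present in both images cancels.
#'
#' @param frame Grayscale matrix.
#' @param bg A `background` object or a grayscale matrix of the same shape.
#' @param polarity See [binarize()].
#' @return Grayscale difference matrix (animal-positive).
#' @export
subtract_background <- function(frame, bg,
                                polarity = c("dark_on_light",
                                             "light_on_dark")) {
  polarity <- match.arg(polarity)
  pix <- if (inherits(bg, "background")) bg$pixels else bg
  if (!all(dim(frame) == dim(pix))) stopf("shape mismatch")
  d <- if (polarity == "dark_on_light") pix - frame else frame - pix
  pmax(d, 0)
}

#' Track an animal through a frame sequence
#'
#' The online tracking loop: per frame, subtract the background, binarize,
#' keep the largest object, and save a cropped bounding box (with a margin
#' of half the object's major-axis length) together with its offset. The
#' next frame is searched in the previous box dilated by the margin,
#' falling back to a whole-frame search if the object is lost there.
#' Tracking stops after the frame budget is exhausted
#' (`stop_reason = "completed"`), or when the object touches the frame
#' border (`"left_field_of_view"`). A live-mode per-frame time budget
#' (`"too_slow"`) is not evaluated when replaying files.
#'
#' @param frames List of grayscale matrices (the frame source).
#' @param config List with elements `polarity`, `threshold` (NULL = auto
#'   on the first background-subtracted frame), `n_frames` (frame budget;
#'   default all), `sampling_interval` (s), `margin_factor` (default 0.5),
#'   `background` (a `background` object; reconstructed from the sequence
#'   when omitted).
#' @return A `trial_recording`: `list(background, crops, offsets,
#'   sampling_interval, n_frames, stop_reason, threshold, polarity)`.
#'   `crops` is a list of `list(img, r0, c0)` with 1-based top-left corner
#'   (row, col); `offsets` a data.frame with 0-based `x0`, `y0`.
#' @export
track_stream <- function(frames, config = list()) {
  polarity <- config$polarity %||% "dark_on_light"
  bg <- config$background %||%
    reconstruct_background(frames, config$background_threshold,
                           polarity, margin = config$bg_margin %||% 5)
  sub1 <- subtract_background(frames[[1]], bg, polarity)
  threshold <- config$threshold %||%
    detection_threshold(sub1, "light_on_dark")
  budget <- config$n_frames %||% length(frames)
  margin_factor <- config$margin_factor %||% 0.5
  dt <- config$sampling_interval %||% 1
  nr <- nrow(frames[[1]]); nc <- ncol(frames[[1]])

  crops <- list()
  offs <- list()
  stop_reason <- "completed"
  search <- NULL
  for (i in seq_len(min(budget, length(frames)))) {
    sub <- subtract_background(frames[[i]], bg, polarity)
    m <- sub > threshold
    mm <- m
    if (!is.null(search)) {
      mm[] <- FALSE
      mm[search["r0"]:search["r1"], search["c0"]:search["c1"]] <-
        m[search["r0"]:search["r1"], search["c0"]:search["c1"]]
      if (!any(mm)) mm <- m  # lost in the search region: whole frame
    }
    if (!any(mm)) {
      if (i == 1L) stopf("no_animal")
      stop_reason <- "left_field_of_view"
      break
    }
    obj <- largest_object(mm)
    bb <- bbox_of(obj)
    if (bb["r0"] == 1 || bb["c0"] == 1 || bb["r1"] == nr || bb["c1"] == nc) {
      stop_reason <- "left_field_of_view"
      break
    }
    major <- max(bb["r1"] - bb["r0"], bb["c1"] - bb["c0"]) + 1
    margin <- margin_factor * major
    box <- expand_bbox(bb, margin, nr, nc)
    crops[[length(crops) + 1L]] <-
      list(img = frames[[i]][box["r0"]:box["r1"], box["c0"]:box["c1"],
                             drop = FALSE],
           r0 = unname(box["r0"]), c0 = unname(box["c0"]))
    offs[[length(offs) + 1L]] <-
      data.frame(frame = i - 1L, x0 = unname(box["c0"]) - 1L,
                 y0 = unname(box["r0"]) - 1L,
                 w = unname(box["c1"] - box["c0"]) + 1L,
                 h = unname(box["r1"] - box["r0"]) + 1L,
                 timestamp = (i - 1L) * dt)
    search <- expand_bbox(box, margin, nr, nc)
  }
  structure(list(background = bg, crops = crops,
                 offsets = do.call(rbind, offs),
                 sampling_interval = dt, n_frames = length(crops),
                 stop_reason = stop_reason, threshold = threshold,
                 polarity = polarity),
            class = "trial_recording")
}

#' Recover the binary animal mask for one saved crop
#'
#' Re-runs background subtraction, thresholding and largest-object
#' retention on crop `k` of a trial recording (the offline starting point
#' for posture analysis).
#'
#' @param trial A `trial_recording` from [track_stream()].
#' @param k Crop index (1-based).
#' @return Logical mask the size of the crop.
#' @export
crop_mask <- function(trial, k) {
  cr <- trial$crops[[k]]
  bgc <- trial$background$pixels[cr$r0 + seq_len(nrow(cr$img)) - 1L,
                                 cr$c0 + seq_len(ncol(cr$img)) - 1L,
                                 drop = FALSE]
  sub <- if (trial$polarity == "dark_on_light") bgc - cr$img
         else cr$img - bgc
  largest_object(pmax(sub, 0) > trial$threshold)
}
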