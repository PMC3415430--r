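# Per-frame shape analysis: contour, curvature, skeleton, endpoints and
# morphometrics.

fill_holes <- function(mask) {
  f <- EBImage::fillHull(matrix(as.numeric(mask), nrow(mask)))
  matrix(as.logical(f), nrow(mask))
}

#' Extract the ordered outer contour of a mask
#'
#' Fills interior holes, then traces the outer boundary of the (single)
#' object as an ordered closed polyline. The orientation is normalized so
#' the signed (shoelace) area in pixel coordinates is positive.
#'
#' @param mask Logical matrix containing one 8-connected component.
#' @return n x 2 matrix of (x, y) pixel coordinates (1-based, implicitly
#'   cyclic). A degenerate single-pixel mask yields a 1-row contour.
#' @export
extract_contour <- function(mask) {
  if (!any(mask)) stopf("empty mask")
  filled <- fill_holes(mask)
  oc <- EBImage::ocontour(matrix(as.numeric(t(filled)), ncol(filled)))[[1]]
  contour <- cbind(x = oc[, 1] + 1, y = oc[, 2] + 1)
  if (nrow(contour) >= 3) {
    x <- contour[, 1]; y <- contour[, 2]
    a <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
    if (a < 0) contour <- contour[nrow(contour):1, , drop = FALSE]
  }
  contour
}

#' Smooth a closed contour
#'
#' Cyclic moving average of the coordinates; the point count is preserved
#' and `window = 1` is the identity.
#'
#' @param contour n x 2 matrix (cyclic).
#' @param window Odd window size in points.
#' @return Smoothed n x 2 matrix.
#' @export
smooth_contour <- function(contour, window = 5) {
  if (window %% 2 != 1 || window < 1) stopf("window must be odd and >= 1")
  n <- nrow(contour)
  if (window > n) stopf("window larger than contour")
  if (window == 1) return(contour)
  h <- (window - 1) / 2
  idx <- outer(seq_len(n), -h:h, `+`)
  idx <- ((idx - 1) %% n) + 1
  cbind(x = rowMeans(matrix(contour[idx, 1], n)),
        y = rowMeans(matrix(contour[idx, 2], n)))
}

# One Zhang-Suen subiteration, vectorized over the whole (padded) mask.
zs_subiter <- function(m, step) {
  nr <- nrow(m); nc <- ncol(m)
  sh <- function(dr, dc) {
    out <- matrix(0L, nr, nc)
    out[(1 + max(0, dr)):(nr + min(0, dr)),
        (1 + max(0, dc)):(nc + min(0, dc))] <-
      m[(1 - min(0, dr)):(nr - max(0, dr)),
        (1 - min(0, dc)):(nc - max(0, dc))]
    out
  }
  # p2..p9: N, NE, E, SE, S, SW, W, NW neighbor values at each pixel
  p2 <- sh(1, 0); p3 <- sh(1, -1); p4 <- sh(0, -1); p5 <- sh(-1, -1)
  p6 <- sh(-1, 0); p7 <- sh(-1, 1); p8 <- sh(0, 1); p9 <- sh(1, 1)
  b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
  a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
       (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
       (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
  if (step == 1L) {
    cond <- p2 * p4 * p6 == 0 & p4 * p6 * p8 == 0
  } else {
    cond <- p2 * p4 * p8 == 0 & p2 * p6 * p8 == 0
  }
  del <- m == 1L & b >= 2 & b <= 6 & a == 1 & cond
  m[del] <- 0L
  m
}

#' Skeletonize a binary mask by thinning
#'
#' Zhang-Suen thinning: boundary pixels are removed in two alternating
#' subiterations until no change, leaving a single-pixel-wide, connected,
#' topology-preserving medial curve. Interior holes are filled first so
#' that segmentation noise cannot change the topology.
#'
#' @param mask Logical matrix with a single component.
#' @return Logical matrix of skeleton pixels.
#' @export
skeletonize <- function(mask) {
  if (!any(mask)) stopf("empty mask")
  m <- matrix(as.integer(fill_holes(mask)), nrow(mask))
  repeat {
    m1 <- zs_subiter(m, 1L)
    m2 <- zs_subiter(m1, 2L)
    if (identical(m2, m)) break
    m <- m2
  }
  m == 1L
}

neighbor_counts <- function(skel) {
  nr <- nrow(skel); nc <- ncol(skel)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- skel
  n <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    n <- n + p[2:(nr + 1L) + dr, 2:(nc + 1L) + dc]
  }
  n
}

#' Skeleton endpoints and spur flag
#'
#' Endpoints are skeleton pixels with at most one 8-neighbor in the
#' skeleton (an isolated pixel counts as an endpoint). Thinning can produce
#' spurious branches giving more than two endpoints; such frames are
#' flagged so their fraction can be tracked and they can be discarded.
#'
#' @param skel Logical skeleton matrix.
#' @return `list(endpoints, spur)`: endpoints as k x 2 (x, y) matrix and
#'   `spur = (k != 2)`.
#' @export
skeleton_endpoints <- function(skel) {
  if (!any(skel)) stopf("empty skeleton")
  nn <- neighbor_counts(skel)
  idx <- which(skel & nn <= 1L, arr.ind = TRUE)
  ep <- cbind(x = idx[, 2], y = idx[, 1])
  list(endpoints = ep, spur = nrow(ep) != 2L)
}

#' Signed curvature along a closed contour
#'
#' Curvature at point i is estimated as the turning angle between the
#' chords to the points `arc_window` steps behind and ahead, divided by the
#' arc length between the two chord midpoints (half the spanned arc; this
#' normalization makes the estimator converge to 1/r on a circle).
#' Positive values are convex for the normalized orientation produced by
#' [extract_contour()].
#'
#' @param contour n x 2 cyclic matrix.
#' @param arc_window Chord half-span in contour points; default 5% of the
#'   contour length, at least 3.
#' @return Numeric vector of curvatures (1/px), one per contour point.
#' @export
contour_curvature <- function(contour, arc_window = NULL) {
  n <- nrow(contour)
  arc_window <- arc_window %||% max(3L, round(0.05 * n))
  if (n <= 2 * arc_window) stopf("contour too short for arc_window")
  im <- ((seq_len(n) - 1 - arc_window) %% n) + 1
  ip <- ((seq_len(n) - 1 + arc_window) %% n) + 1
  v1x <- contour[, 1] - contour[im, 1]; v1y <- contour[, 2] - contour[im, 2]
  v2x <- contour[ip, 1] - contour[, 1]; v2y <- contour[ip, 2] - contour[, 2]
  ang <- atan2(v1x * v2y - v1y * v2x, v1x * v2x + v1y * v2y)
  steps <- sqrt(diff(rbind(contour, contour[1, ])[, 1])^2 +
                diff(rbind(contour, contour[1, ])[, 2])^2)
  cum <- c(0, cumsum(steps))     # length n + 1, total = perimeter
  total <- cum[n + 1]
  arc <- (cum[ip] - cum[im]) %% total
  arc[arc == 0] <- total
  ang / (arc / 2)
}

#' Head/tail candidate points from contour curvature
#'
#' Picks the two highest positive local curvature maxima separated by at
#' least a quarter of the contour length. Shapes without two well-separated
#' maxima above the baseline curvature (e.g. a curled-up, blob-like body)
#' are flagged.
#'
#' @param contour n x 2 cyclic matrix.
#' @param curvature Output of [contour_curvature()] for `contour`.
#' @param min_sep Minimum separation as a fraction of contour length.
#' @return `list(points, blob_like)`: a 2 x 2 matrix of (x, y) candidates
#'   (best first) and a logical flag.
#' @export
head_tail_candidates <- function(contour, curvature, min_sep = 0.25) {
  n <- nrow(contour)
  prev <- c(n, seq_len(n - 1)); nxt <- c(seq_len(n - 1) + 1, 1)
  is_max <- curvature > 0 & curvature >= curvature[prev] &
    curvature >= curvature[nxt]
  # reject shapes whose maxima do not stand out from the baseline
  baseline <- stats::median(abs(curvature))
  cand <- which(is_max & curvature > 1.5 * baseline)
  cand <- cand[order(curvature[cand], decreasing = TRUE)]
  if (length(cand) >= 2) {
    first <- cand[1]
    sep <- pmin(abs(cand - first), n - abs(cand - first)) / n
    second <- cand[sep >= min_sep][1]
    if (!is.na(second)) {
      return(list(points = contour[c(first, second), , drop = FALSE],
                  blob_like = FALSE))
    }
  }
  # best effort: highest-curvature point and the point farthest from it
  i <- if (length(cand)) cand[1] else which.max(curvature)
  d <- (contour[, 1] - contour[i, 1])^2 + (contour[, 2] - contour[i, 2])^2
  list(points = contour[c(i, which.max(d)), , drop = FALSE],
       blob_like = TRUE)
}

#' Order skeleton pixels into a path from one end
#'
#' Walks the single-pixel-wide skeleton from the endpoint nearest `head`,
#' visiting every pixel once. Orthogonal neighbors are preferred over
#' diagonal ones so that staircase configurations are traversed without
#' skipping pixels.
#'
#' @param skel Logical skeleton matrix with exactly 2 endpoints.
#' @param head (x, y) start point; snapped to the nearest endpoint.
#' @return n x 2 matrix of (x, y) pixels, ordered from the head end.
#' @export
order_skeleton <- function(skel, head) {
  ep <- skeleton_endpoints(skel)
  if (nrow(ep$endpoints) != 2L) stopf("branched")
  d <- (ep$endpoints[, 1] - head[1])^2 + (ep$endpoints[, 2] - head[2])^2
  start <- ep$endpoints[which.min(d), ]
  visited <- matrix(FALSE, nrow(skel), ncol(skel))
  cur <- c(start[2], start[1])             # (row, col)
  visited[cur[1], cur[2]] <- TRUE
  path <- list(cur)
  nr <- nrow(skel); nc <- ncol(skel)
  ortho <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  diag <- rbind(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  total <- sum(skel)
  repeat {
    nxt <- NULL
    for (set in list(ortho, diag)) {
      cand <- sweep(set, 2, cur, `+`)
      ok <- cand[, 1] >= 1 & cand[, 1] <= nr & cand[, 2] >= 1 &
        cand[, 2] <= nc
      cand <- cand[ok, , drop = FALSE]
      hit <- cand[skel[cand] & !visited[cand], , drop = FALSE]
      if (nrow(hit) == 1L) { nxt <- hit[1, ]; break }
      if (nrow(hit) > 1L) stopf("branched")
    }
    if (is.null(nxt)) break
    cur <- nxt
    visited[cur[1], cur[2]] <- TRUE
    path[[length(path) + 1L]] <- cur
  }
  if (length(path) != total) stopf("branched")
  m <- do.call(rbind, path)
  cbind(x = m[, 2], y = m[, 1])
}

#' Morphometrics of a posture
#'
#' @param mask Logical body mask.
#' @param contour Closed contour from [extract_contour()].
#' @param skeleton Ordered skeleton path (n x 2).
#' @return `list(area, perimeter, skeleton_length, centroid, midpoint)`:
#'   area in px^2 (pixel count), perimeter and skeleton length as Euclidean
#'   arc lengths (steps of 1 and sqrt(2)), centroid as the mean of mask
#'   pixel coordinates, midpoint as the skeleton point at half arc length.
#' @export
posture_metrics <- function(mask, contour, skeleton) {
  idx <- which(mask, arr.ind = TRUE)
  centroid <- c(x = mean(idx[, 2]), y = mean(idx[, 1]))
  closed <- rbind(contour, contour[1, ])
  perimeter <- sum(sqrt(diff(closed[, 1])^2 + diff(closed[, 2])^2))
  al <- arc_lengths(skeleton)
  skeleton_length <- max(al)
  midpoint <- skeleton[which.min(abs(al - skeleton_length / 2)), ]
  list(area = sum(mask), perimeter = perimeter,
       skeleton_length = skeleton_length, centroid = centroid,
       midpoint = c(x = midpoint[1], y = midpoint[2]))
}

#' Full shape analysis of one binary frame
#'
#' Runs the complete per-frame posture pipeline: hole filling, contour
#' extraction and smoothing, curvature, head/tail candidates, thinning,
#' endpoint check, skeleton ordering and extension to the contour tips,
#' and morphometrics. Head/tail identity (which candidate is anterior) is
#' assigned later by the identity module.
#'
#' @param mask Logical single-object mask (e.g. from [crop_mask()]).
#' @param smooth_window Contour smoothing window (odd; 1 disables).
#' @param arc_window Curvature window; `NULL` = 5% of contour length.
#' @return A `posture` object: contour, skeleton (ordered end1 -> end2 and
#'   extended to the candidate tips), `ends` (2 x 2 candidate tips),
#'   metrics, and `flags` (subset of `"spur"`, `"blob_like"`).
#' @export
analyze_posture <- function(mask, smooth_window = 5, arc_window = NULL) {
  if (!any(mask)) stopf("empty mask")
  mask <- fill_holes(mask)
  flags <- character(0)
  contour <- extract_contour(mask)
  if (nrow(contour) > smooth_window && smooth_window > 1)
    contour <- smooth_contour(contour, smooth_window)
  skel <- skeletonize(mask)
  ep <- skeleton_endpoints(skel)
  if (ep$spur) flags <- c(flags, "spur")

  if (nrow(contour) > 2 * max(3L, round(0.05 * nrow(contour)))) {
    curv <- contour_curvature(contour, arc_window)
    ht <- head_tail_candidates(contour, curv)
  } else {
    ht <- list(points = contour[c(1, nrow(contour)), , drop = FALSE],
               blob_like = TRUE)
    curv <- NULL
  }

  skeleton <- NULL
  if (!ep$spur) {
    skeleton <- order_skeleton(skel, ht$points[1, ])
    # extend the medial curve out to the contour tips so that the skeleton
    # endpoints coincide with head/tail and its length spans the full body
    ends <- ht$points
    d_head <- pt_dist(ends[1, ], skeleton[1, ])
    d_tail <- pt_dist(ends[2, ], skeleton[nrow(skeleton), ])
    if (d_head > 0.5) skeleton <- rbind(ends[1, ], skeleton)
    if (d_tail > 0.5) skeleton <- rbind(skeleton, ends[2, ])
    # smooth the pixelated path so arc length is not inflated by the
    # staircase pattern of the thinned curve
    skeleton <- smooth_path(skeleton, 5)
  }
  met <- posture_metrics(mask, contour,
                         skeleton %||% ht$points)
  blob <- ht$blob_like || met$skeleton_length < 5 ||
    (pt_dist(ht$points[1, ], ht$points[2, ]) / met$skeleton_length < 0.3)
  if (blob) flags <- c(flags, "blob_like")
  structure(list(contour = contour, skeleton = skeleton,
                 ends = ht$points, curvature = curv,
                 area = met$area, perimeter = met$perimeter,
                 skeleton_length = met$skeleton_length,
                 centroid = met$centroid, midpoint = met$midpoint,
                 head = NULL, tail = NULL, flags = flags),
            class = "posture")
}

#' Quality-control summary over postures
#'
#' Fractions of frames flagged by the shape pipeline, tracked so that
#' problematic frames can be reviewed or discarded.
#'
#' @param postures List of `posture` objects.
#' @return `list(fraction_spur, fraction_blob_like, fraction_discarded)`.
#' @export
qc_summary <- function(postures) {
  if (!length(postures)) stopf("no postures")
  has <- function(flag)
    mean(vapply(postures, function(p) flag %in% p$flags, logical(1)))
  list(fraction_spur = has("spur"),
       fraction_blob_like = has("blob_like"),
       fraction_discarded = has("discarded"))
}
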