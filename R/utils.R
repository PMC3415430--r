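# Internal helpers shared across modules.

#' Null-coalescing operator
#' @param a,b Values; `b` is returned when `a` is `NULL`.
#' @return `a` unless it is `NULL`, then `b`.
#' @export
#' @name op-null-default
`%||%` <- function(a, b) if (is.null(a)) b else a

clip01 <- function(x, lo = 0, hi = 255) pmin(pmax(x, lo), hi)

# Euclidean distance between two points given as length-2 vectors.
pt_dist <- function(a, b) sqrt(sum((a - b)^2))

# Row-wise Euclidean norms of an n x 2 matrix.
row_norms <- function(m) sqrt(rowSums(m^2))

as_point_matrix <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 2, byrow = TRUE)
  storage.mode(p) <- "double"
  p
}

# Minimum distance from each point in `pts` (n x 2) to the polyline `poly`
# (m x 2). Vectorized over points for each segment.
dist_to_polyline <- function(pts, poly) {
  pts <- as_point_matrix(pts)
  poly <- as_point_matrix(poly)
  n <- nrow(pts)
  best <- rep(Inf, n)
  if (nrow(poly) == 1L) {
    return(sqrt((pts[, 1] - poly[1, 1])^2 + (pts[, 2] - poly[1, 2])^2))
  }
  for (i in seq_len(nrow(poly) - 1L)) {
    a <- poly[i, ]
    d <- poly[i + 1L, ] - a
    len2 <- sum(d^2)
    if (len2 == 0) {
      di <- sqrt((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2)
    } else {
      t <- ((pts[, 1] - a[1]) * d[1] + (pts[, 2] - a[2]) * d[2]) / len2
      t <- pmin(pmax(t, 0), 1)
      px <- a[1] + t * d[1]
      py <- a[2] + t * d[2]
      di <- sqrt((pts[, 1] - px)^2 + (pts[, 2] - py)^2)
    }
    best <- pmin(best, di)
  }
  best
}

# Cumulative arc length along an n x 2 polyline (first entry 0).
arc_lengths <- function(poly) {
  poly <- as_point_matrix(poly)
  if (nrow(poly) < 2L) return(0)
  steps <- sqrt(diff(poly[, 1])^2 + diff(poly[, 2])^2)
  c(0, cumsum(steps))
}

# Angle of a 2D vector in degrees, measured from +x axis.
vec_angle_deg <- function(v) atan2(v[2], v[1]) * 180 / pi

# Unsigned angle between two vectors, degrees in [0, 180].
angle_between_deg <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero-length vector")
  cosv <- sum(a * b) / (na * nb)
  acos(pmin(pmax(cosv, -1), 1)) * 180 / pi
}

# Rotate points (n x 2) about a center by angle (radians).
rotate_about <- function(pts, center, theta) {
  pts <- as_point_matrix(pts)
  ct <- cos(theta); st <- sin(theta)
  dx <- pts[, 1] - center[1]
  dy <- pts[, 2] - center[2]
  cbind(center[1] + ct * dx - st * dy,
        center[2] + st * dx + ct * dy)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Resample a polyline at given arc-length positions (linear interpolation).
polyline_at <- function(poly, s) {
  poly <- as_point_matrix(poly)
  al <- arc_lengths(poly)
  s <- pmin(pmax(s, 0), max(al))
  cbind(stats::approx(al, poly[, 1], xout = s)$y,
        stats::approx(al, poly[, 2], xout = s)$y)
}

# Non-cyclic moving-average smoothing of an ordered path; the first and
# last points are kept fixed and the window shrinks near the ends.
smooth_path <- function(path, window = 5) {
  n <- nrow(path)
  if (n < 3 || window < 3) return(path)
  h <- (window - 1) %/% 2
  out <- path
  for (i in 2:(n - 1)) {
    k <- min(h, i - 1, n - i)
    out[i, ] <- colMeans(path[(i - k):(i + k), , drop = FALSE])
  }
  out
}
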