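# Parametric scalar stimulus fields with analytic gradients, and
# geometric sampling of those fields at body loci.

#' Stimulus landscapes
#'
#' Three parametric field shapes cover the assay modalities:
#' * `landscape_linear()` — a linear gradient (e.g. a thermal gradient of
#'   slope `slope` degC/mm along `direction`):
#'   v(p) = ref_value + slope * ((p - ref_point) . direction).
#' * `landscape_radial()` — a radial exponential profile around a source
#'   (e.g. an odor droplet): v(p) = peak * exp(-|p - source| / decay_length).
#' * `landscape_sideways_light()` — light from a source line, with
#'   intensity decaying with distance from the line,
#'   v(p) = I0 * exp(-d(p) / decay_length), plus an optional lit/shadow
#'   half-plane boundary used for contour exposure fractions.
#' * `landscape_grid()` — bilinear interpolation over a measured map
#'   given as a regular x/y grid of values.
#'
#' @param slope Gradient slope in units/mm.
#' @param direction Unit vector of increasing stimulus (normalized
#'   internally).
#' @param ref_point,ref_value Point (mm) where the field equals
#'   `ref_value`.
#' @param units Free-text units label; compared when merging trials.
#' @return A `landscape` object.
#' @name landscapes
NULL

#' @rdname landscapes
#' @export
landscape_linear <- function(slope, direction = c(1, 0),
                             ref_point = c(0, 0), ref_value = 0,
                             units = "units") {
  direction <- direction / sqrt(sum(direction^2))
  structure(list(kind = "linear", slope = slope, direction = direction,
                 ref_point = ref_point, ref_value = ref_value,
                 units = units),
            class = c("landscape_linear", "landscape"))
}

#' @rdname landscapes
#' @param source Source point (mm).
#' @param peak Field value at the source.
#' @param decay_length Exponential decay length (mm).
#' @export
landscape_radial <- function(source, peak, decay_length,
                             units = "units") {
  structure(list(kind = "radial", source = source, peak = peak,
                 decay_length = decay_length, units = units),
            class = c("landscape_radial", "landscape"))
}

#' @rdname landscapes
#' @param line_point A point on the source line (mm).
#' @param normal Unit normal of the source line, pointing into the arena
#'   (direction of increasing distance from the source).
#' @param I0 Intensity at the source line.
#' @param lit_boundary Signed distance (mm, along `normal` from
#'   `line_point`) beyond which points are in shadow; `Inf` = all lit.
#' @export
landscape_sideways_light <- function(line_point, normal = c(1, 0), I0 = 1,
                                     decay_length = 10, lit_boundary = Inf,
                                     units = "a.u.") {
  normal <- normal / sqrt(sum(normal^2))
  structure(list(kind = "sideways_light", line_point = line_point,
                 normal = normal, I0 = I0, decay_length = decay_length,
                 lit_boundary = lit_boundary, units = units),
            class = c("landscape_sideways_light", "landscape"))
}

#' @rdname landscapes
#' @param x,y Grid axis positions (ascending, mm).
#' @param values Matrix of field values, `values[i, j]` at `(x[i], y[j])`.
#' @export
landscape_grid <- function(x, y, values, units = "units") {
  stopifnot(nrow(values) == length(x), ncol(values) == length(y))
  structure(list(kind = "grid", x = x, y = y, values = values,
                 units = units),
            class = c("landscape_grid", "landscape"))
}

#' Evaluate a landscape at points
#'
#' @param landscape A `landscape` object.
#' @param p A point `c(x, y)` or an n x 2 matrix of points (mm).
#' @return Field value(s) in the landscape's units.
#' @export
field_at <- function(landscape, p) UseMethod("field_at", landscape)

#' @export
field_at.landscape_linear <- function(landscape, p) {
  p <- as_point_matrix(p)
  proj <- (p[, 1] - landscape$ref_point[1]) * landscape$direction[1] +
          (p[, 2] - landscape$ref_point[2]) * landscape$direction[2]
  landscape$ref_value + landscape$slope * proj
}

#' @export
field_at.landscape_radial <- function(landscape, p) {
  p <- as_point_matrix(p)
  r <- sqrt((p[, 1] - landscape$source[1])^2 +
            (p[, 2] - landscape$source[2])^2)
  landscape$peak * exp(-r / landscape$decay_length)
}

#' @export
field_at.landscape_sideways_light <- function(landscape, p) {
  p <- as_point_matrix(p)
  s <- (p[, 1] - landscape$line_point[1]) * landscape$normal[1] +
       (p[, 2] - landscape$line_point[2]) * landscape$normal[2]
  landscape$I0 * exp(-abs(s) / landscape$decay_length)
}

#' @export
field_at.landscape_grid <- function(landscape, p) {
  p <- as_point_matrix(p)
  x <- landscape$x; y <- landscape$y; v <- landscape$values
  xi <- findInterval(p[, 1], x, all.inside = TRUE)
  yi <- findInterval(p[, 2], y, all.inside = TRUE)
  tx <- (p[, 1] - x[xi]) / (x[xi + 1] - x[xi])
  ty <- (p[, 2] - y[yi]) / (y[yi + 1] - y[yi])
  tx <- pmin(pmax(tx, 0), 1); ty <- pmin(pmax(ty, 0), 1)
  v[cbind(xi, yi)] * (1 - tx) * (1 - ty) +
    v[cbind(xi + 1, yi)] * tx * (1 - ty) +
    v[cbind(xi, yi + 1)] * (1 - tx) * ty +
    v[cbind(xi + 1, yi + 1)] * tx * ty
}

#' Analytic spatial gradient of a landscape
#'
#' @inheritParams field_at
#' @return For a single point, the gradient vector `c(gx, gy)` in
#'   units/mm; for a matrix of points, an n x 2 matrix.
#' @export
gradient_at <- function(landscape, p) UseMethod("gradient_at", landscape)

drop_single <- function(g, p) if (is.null(dim(p)) && nrow(g) == 1L)
  g[1, ] else g

#' @export
gradient_at.landscape_linear <- function(landscape, p) {
  pm <- as_point_matrix(p)
  g <- matrix(landscape$slope * landscape$direction, nrow(pm), 2,
              byrow = TRUE)
  drop_single(g, p)
}

#' @export
gradient_at.landscape_radial <- function(landscape, p) {
  pm <- as_point_matrix(p)
  dx <- pm[, 1] - landscape$source[1]
  dy <- pm[, 2] - landscape$source[2]
  r <- sqrt(dx^2 + dy^2)
  if (any(r == 0)) stopf("gradient undefined at the source point")
  mag <- landscape$peak * exp(-r / landscape$decay_length) /
    landscape$decay_length
  g <- cbind(-mag * dx / r, -mag * dy / r)
  drop_single(g, p)
}

#' @export
gradient_at.landscape_sideways_light <- function(landscape, p) {
  pm <- as_point_matrix(p)
  s <- (pm[, 1] - landscape$line_point[1]) * landscape$normal[1] +
       (pm[, 2] - landscape$line_point[2]) * landscape$normal[2]
  if (any(s == 0)) stopf("gradient undefined on the source line")
  mag <- -landscape$I0 * exp(-abs(s) / landscape$decay_length) /
    landscape$decay_length * sign(s)
  g <- cbind(mag * landscape$normal[1], mag * landscape$normal[2])
  drop_single(g, p)
}

#' Sample a landscape along an ordered skeleton
#'
#' Evaluates the field at each skeleton point (head first) and returns the
#' values together with their differences relative to the head — e.g. the
#' temperature difference experienced along the body axis.
#'
#' @param landscape A `landscape`.
#' @param skeleton n x 2 matrix of skeleton points in mm, head first.
#' @return `list(values, differences)`; `differences[1]` is 0.
#' @export
sample_along_skeleton <- function(landscape, skeleton) {
  if (is.null(skeleton) || !nrow(as_point_matrix(skeleton)))
    stopf("empty skeleton")
  v <- field_at(landscape, skeleton)
  list(values = v, differences = v - v[1])
}

#' Fraction of the body contour exposed to light
#'
#' For a sideways light landscape with a lit/shadow half-plane boundary,
#' returns the percentage of the contour's arc length lying in the lit
#' half-plane. Segments crossing the boundary are split at the crossing
#' point, so the result converges as the polygon is refined.
#'
#' @param landscape A `landscape_sideways_light` with finite
#'   `lit_boundary`.
#' @param contour Closed contour in mm (n x 2, cyclic; n >= 3).
#' @return Percentage in \[0, 100\].
#' @export
contour_light_fraction <- function(landscape, contour) {
  stopifnot(inherits(landscape, "landscape_sideways_light"))
  contour <- as_point_matrix(contour)
  if (nrow(contour) < 3) stopf("open contour")
  # signed coordinate along the light direction; lit side: s < boundary
  s <- (contour[, 1] - landscape$line_point[1]) * landscape$normal[1] +
       (contour[, 2] - landscape$line_point[2]) * landscape$normal[2]
  g <- s - landscape$lit_boundary            # < 0 = lit
  n <- nrow(contour)
  nxt <- c(seq_len(n - 1) + 1, 1)
  seg <- sqrt((contour[nxt, 1] - contour[, 1])^2 +
              (contour[nxt, 2] - contour[, 2])^2)
  g1 <- g; g2 <- g[nxt]
  lit_len <- sum(seg[g1 <= 0 & g2 <= 0])
  cross <- xor(g1 > 0, g2 > 0)
  if (any(cross)) {
    t <- g1[cross] / (g1[cross] - g2[cross])   # crossing parameter
    lit_part <- ifelse(g1[cross] <= 0, t, 1 - t)
    lit_len <- lit_len + sum(seg[cross] * lit_part)
  }
  100 * lit_len / sum(seg)
}

#' Light exposure split by body side
#'
#' Splits the contour into left and right arcs relative to the midline
#' (sign of the cross product with the local skeleton tangent) and
#' returns the lit arc-length percentage for each side — differences in
#' illumination between the two body sides are a candidate orientation
#' cue during phototaxis.
#'
#' @inheritParams contour_light_fraction
#' @param skeleton Ordered skeleton in mm (head first).
#' @return `list(left, right)` percentages.
#' @export
side_light_fractions <- function(landscape, contour, skeleton) {
  contour <- as_point_matrix(contour)
  skeleton <- as_point_matrix(skeleton)
  n <- nrow(skeleton)
  side <- vapply(seq_len(nrow(contour)), function(i) {
    p <- contour[i, ]
    d <- (skeleton[, 1] - p[1])^2 + (skeleton[, 2] - p[2])^2
    k <- which.min(d)
    k2 <- min(k + 1, n); k1 <- max(k - 1, 1)
    tang <- skeleton[k2, ] - skeleton[k1, ]
    sign(tang[1] * (p[2] - skeleton[k, 2]) -
         tang[2] * (p[1] - skeleton[k, 1]))
  }, numeric(1))
  frac <- function(pts) {
    if (nrow(pts) < 3) return(NA_real_)
    contour_light_fraction(landscape, pts)
  }
  list(left = frac(contour[side < 0, , drop = FALSE]),
       right = frac(contour[side >= 0, , drop = FALSE]))
}

#' Bearing of a body axis to the local gradient
#'
#' Angle in degrees between an axis vector (e.g. the heading, or the
#' tail-to-head body axis) and the stimulus gradient at a point;
#' 0 = aligned up-gradient, 180 = down-gradient.
#'
#' @param landscape A `landscape`.
#' @param p Point (mm).
#' @param axis Non-zero axis vector.
#' @return Angle in \[0, 180\] degrees.
#' @export
bearing_to_gradient <- function(landscape, p, axis) {
  g <- gradient_at(landscape, p)
  if (sqrt(sum(g^2)) < 1e-12) stopf("flat_field")
  angle_between_deg(axis, g)
}
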