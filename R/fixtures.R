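#' Parameters for the synthetic crawling-animal generator
#'
#' Bundles the geometry, kinematics and appearance of a synthetic worm-like
#' animal (a curved midline with a constant half-width, rendered as a capsule)
#' crawling over a noisy background with optional static clutter. The
#' generator produces frame sequences with exact ground truth so that every
#' downstream tracking stage can be validated without real video.
#'
#' Coordinates are in arena millimeters with the origin at the top-left
#' corner, x rightward and y downward; the pixel grid maps the center of
#' pixel (row, col) to ((col - 0.5), (row - 0.5)) * `mm_per_pixel`.
#'
#' @param body_length Body length in mm (default 4, a third-instar larva).
#' @param body_halfwidth Body half-width in mm; must satisfy
#'   `body_length > 2 * body_halfwidth`.
#' @param speed Crawling speed in body lengths per second.
#' @param cast_amplitude Head-cast amplitude in degrees (peak swing of the
#'   anterior third of the midline).
#' @param cast_times Numeric vector of cast onset times (s). Each cast
#'   spans a fixed 1 s window with a smooth (sinusoidal) swing out and back;
#'   forward progression pauses during the window.
#' @param turns List of `c(time, angle_deg)` pairs: instantaneous heading
#'   changes.
#' @param duration,dt Trial duration and sampling interval (s).
#' @param arena_size Arena width and height in mm, `c(w, h)`.
#' @param mm_per_pixel Spatial scale of the rendered frames.
#' @param polarity `"dark_on_light"` or `"light_on_dark"`.
#' @param background_level,contrast Background intensity and animal contrast
#'   (0-255); the animal is rendered at `background_level -/+ contrast`
#'   according to polarity.
#' @param noise_sd Standard deviation of i.i.d. Gaussian pixel noise,
#'   clipped to \[0, 255\].
#' @param clutter List of static clutter discs, each
#'   `list(center = c(x, y), radius = r, intensity = I)` (mm, mm, 0-255).
#' @param start Starting head position (mm); defaults to the arena center.
#' @param heading0 Initial heading in degrees (0 = +x).
#' @param seed Integer seed controlling all randomness.
#' @return An object of class `crawl_params`.
#' @export
crawl_params <- function(body_length = 4, body_halfwidth = 0.25,
                         speed = 0.15, cast_amplitude = 60,
                         cast_times = numeric(0), turns = list(),
                         duration = 10, dt = 1 / 7,
                         arena_size = c(40, 40), mm_per_pixel = 0.1,
                         polarity = c("dark_on_light", "light_on_dark"),
                         background_level = 200, contrast = 100,
                         noise_sd = 5, clutter = list(),
                         start = NULL, heading0 = 0, seed = 1L) {
  polarity <- match.arg(polarity)
  if (dt <= 0) stopf("dt must be > 0")
  if (duration < dt) stopf("duration must be >= dt")
  if (body_length <= 2 * body_halfwidth)
    stopf("body_length must exceed 2 * body_halfwidth")
  if (background_level < 0 || background_level > 255 || contrast < 0 ||
      contrast > 255)
    stopf("intensity levels must lie in [0, 255]")
  bad <- c(cast_times, vapply(turns, `[`, numeric(1), 1))
  if (length(bad) && any(bad < 0 | bad > duration))
    stopf("event times must lie within [0, duration]")
  p <- list(body_length = body_length, body_halfwidth = body_halfwidth,
            speed = speed, cast_amplitude = cast_amplitude,
            cast_times = sort(cast_times),
            turns = turns[order(vapply(turns, `[`, numeric(1), 1))],
            duration = duration, dt = dt, arena_size = arena_size,
            mm_per_pixel = mm_per_pixel, polarity = polarity,
            background_level = background_level, contrast = contrast,
            noise_sd = noise_sd, clutter = clutter,
            start = start %||% (arena_size / 2), heading0 = heading0,
            seed = as.integer(seed), cast_window = 1)
  class(p) <- "crawl_params"
  p
}

#' Constant-curvature body midline
#'
#' Builds a midline polyline of given arc length and constant curvature,
#' starting at `start` with initial tangent `theta0` (degrees). Useful for
#' generating families of curved test postures with known head/tail truth.
#'
#' @param length Arc length (mm).
#' @param curvature Signed curvature in 1/mm (0 = straight).
#' @param start Head position (mm).
#' @param theta0 Initial tangent direction at the head, degrees;
#'   the midline extends backwards from the head along `-theta0`.
#' @param n Number of polyline points.
#' @return An `n` x 2 matrix of (x, y) mm, ordered head to tail.
#' @export
arc_midline <- function(length, curvature = 0, start = c(0, 0),
                        theta0 = 0, n = 25) {
  s <- seq(0, length, length.out = n)
  th0 <- theta0 * pi / 180
  if (abs(curvature) < 1e-12) {
    x <- start[1] - s * cos(th0)
    y <- start[2] - s * sin(th0)
  } else {
    # tangent angle rotates linearly with arc length behind the head
    th <- th0 + curvature * s
    x <- start[1] - (sin(th) - sin(th0)) / curvature
    y <- start[2] + (cos(th) - cos(th0)) / curvature
  }
  cbind(x, y)
}

# Rasterize clutter discs and background level onto a blank canvas.
render_canvas <- function(params) {
  mpp <- params$mm_per_pixel
  nc <- round(params$arena_size[1] / mpp)
  nr <- round(params$arena_size[2] / mpp)
  canvas <- matrix(params$background_level, nrow = nr, ncol = nc)
  for (cl in params$clutter) {
    cx <- cl$center[1] / mpp + 0.5
    cy <- cl$center[2] / mpp + 0.5
    r <- cl$radius / mpp
    cols <- max(1, floor(cx - r)):min(nc, ceiling(cx + r))
    rows <- max(1, floor(cy - r)):min(nr, ceiling(cy + r))
    d2 <- outer((rows - cy)^2, (cols - cx)^2, `+`)
    sub <- canvas[rows, cols, drop = FALSE]
    sub[d2 <= r^2] <- cl$intensity
    canvas[rows, cols] <- sub
  }
  canvas
}

#' Render the animal-free scene
#'
#' Renders the arena background (uniform level plus static clutter) without
#' the animal and without noise. This is the exact image that background
#' reconstruction should recover in the noise-free case.
#'
#' @param params A [crawl_params()] object.
#' @return A grayscale matrix (rows = y, cols = x), intensities 0-255.
#' @export
render_scene <- function(params) render_canvas(params)

#' Render one frame of a worm-like body
#'
#' Rasterizes the capsule of half-width `params$body_halfwidth` around a
#' midline polyline onto the arena canvas, applies the configured polarity
#' and contrast, and adds Gaussian pixel noise. The ground-truth mask is the
#' noiseless hard capsule (no anti-aliasing), so segmentation oracles are
#' exact.
#'
#' @param midline Midline polyline in mm (n x 2, head first), at least 2
#'   points, inside the arena.
#' @param params A [crawl_params()] object (appearance fields are used).
#' @param seed Optional integer; if supplied the RNG is seeded before noise
#'   is drawn, otherwise the current RNG stream is used.
#' @param heading Optional ground-truth heading (degrees) stored verbatim.
#' @return `list(frame, truth)` where `truth` holds the midline, head,
#'   tail, centroid (mm), heading and the binary body mask.
#' @export
render_worm <- function(midline, params, seed = NULL, heading = NULL) {
  midline <- as_point_matrix(midline)
  if (nrow(midline) < 2L) stopf("midline needs >= 2 points")
  w <- params$arena_size[1]; h <- params$arena_size[2]
  if (any(midline[, 1] < 0 | midline[, 1] > w |
          midline[, 2] < 0 | midline[, 2] > h))
    stopf("out_of_arena")
  mpp <- params$mm_per_pixel
  canvas <- render_canvas(params)
  nr <- nrow(canvas); nc <- ncol(canvas)

  # restrict the capsule test to a window around the midline
  hw <- params$body_halfwidth
  pad <- hw / mpp + 2
  c0 <- max(1L, floor(min(midline[, 1]) / mpp + 0.5 - pad))
  c1 <- min(nc, ceiling(max(midline[, 1]) / mpp + 0.5 + pad))
  r0 <- max(1L, floor(min(midline[, 2]) / mpp + 0.5 - pad))
  r1 <- min(nr, ceiling(max(midline[, 2]) / mpp + 0.5 + pad))
  rows <- r0:r1; cols <- c0:c1
  px <- cbind(rep((cols - 0.5) * mpp, each = length(rows)),
              rep((rows - 0.5) * mpp, times = length(cols)))
  # the capsule spine is the midline inset by one halfwidth at both ends,
  # so that the rendered body tips coincide with the midline endpoints
  # (head and tail are the visible tips of the body)
  total <- max(arc_lengths(midline))
  if (total <= 2 * hw) stopf("midline shorter than body width")
  spine <- polyline_at(midline, seq(hw, total - hw, length.out =
                                      max(2L, nrow(midline))))
  d <- dist_to_polyline(px, spine)
  submask <- matrix(d <= hw, nrow = length(rows), ncol = length(cols))

  mask <- matrix(FALSE, nr, nc)
  mask[rows, cols] <- submask
  body <- if (params$polarity == "dark_on_light")
    params$background_level - params$contrast
  else params$background_level + params$contrast
  frame <- canvas
  frame[mask] <- clip01(body)
  if (params$noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    frame <- clip01(frame + stats::rnorm(length(frame), 0, params$noise_sd))
  }
  idx <- which(mask, arr.ind = TRUE)
  centroid <- c(mean((idx[, 2] - 0.5) * mpp), mean((idx[, 1] - 0.5) * mpp))
  if (is.null(heading)) {
    v <- midline[1, ] - midline[2, ]
    heading <- vec_angle_deg(v)
  }
  truth <- list(midline = midline, head = midline[1, ],
                tail = midline[nrow(midline), ], centroid = centroid,
                heading = heading, mask = mask)
  list(frame = frame, truth = truth)
}

# Midline of the simulated animal at time t: straight body behind the head
# along the heading, with the anterior third rotated during cast windows.
crawl_midline <- function(params, t, n = 25) {
  L <- params$body_length
  th <- params$heading0
  for (tu in params$turns) if (t >= tu[1]) th <- th + tu[2]
  thr <- th * pi / 180
  w <- params$cast_window
  # head travels along the (piecewise-constant) heading
  head <- params$start
  tprev <- 0; hh <- params$heading0
  for (tu in params$turns) {
    if (t >= tu[1]) {
      seg <- seg_distance(params, tprev, tu[1])
      head <- head + seg * c(cos(hh * pi / 180), sin(hh * pi / 180))
      tprev <- tu[1]; hh <- hh + tu[2]
    }
  }
  seg <- seg_distance(params, tprev, t)
  head <- head + seg * c(cos(hh * pi / 180), sin(hh * pi / 180))

  s <- seq(0, L, length.out = n)
  mid <- cbind(head[1] - s * cos(thr), head[2] - s * sin(thr))

  # cast deformation: rotate the anterior third about the 1/3 arc point
  active <- params$cast_times[t >= params$cast_times &
                              t < params$cast_times + w]
  if (length(active)) {
    tc <- active[length(active)]
    k <- which(params$cast_times == tc)
    sign <- if (k %% 2 == 0) -1 else 1
    phi <- sign * params$cast_amplitude * sin(pi * (t - tc) / w) * pi / 180
    ant <- s < L / 3
    pivot <- c(head[1] - (L / 3) * cos(thr), head[2] - (L / 3) * sin(thr))
    mid[ant, ] <- rotate_about(mid[ant, , drop = FALSE], pivot, phi)
  }
  list(midline = mid, heading = th)
}

# travel distance between times a < b, excluding cast pauses
seg_distance <- function(params, a, b) {
  w <- params$cast_window
  paused <- sum(pmax(0, pmin(b, params$cast_times + w) -
                        pmax(a, params$cast_times)))
  params$speed * params$body_length * (b - a - paused)
}

#' Simulate a crawling trial
#'
#' Generates a frame sequence of the synthetic animal crawling through the
#' arena at constant speed, with optional instantaneous turns and smooth
#' 1 s head-cast windows, plus per-frame ground truth.
#'
#' @param params A [crawl_params()] object.
#' @param render If `FALSE`, skip frame rasterization and return ground
#'   truth only (kinematics validation without the image pipeline);
#'   ground-truth masks and centroids are then omitted (`NULL` /
#'   midline mean).
#' @return `list(frames, truth, times, params)`: `frames` is a list of
#'   grayscale matrices (`floor(duration/dt) + 1` of them), `truth` the
#'   matching list of ground-truth records (see [render_worm()]).
#' @export
simulate_crawl <- function(params, render = TRUE) {
  stopifnot(inherits(params, "crawl_params"))
  times <- seq(0, by = params$dt,
               length.out = floor(params$duration / params$dt) + 1L)
  set.seed(params$seed)
  frames <- vector("list", length(times))
  truth <- vector("list", length(times))
  for (i in seq_along(times)) {
    st <- crawl_midline(params, times[i])
    if (render) {
      rw <- render_worm(st$midline, params, heading = st$heading)
      frames[[i]] <- rw$frame
      truth[[i]] <- rw$truth
    } else {
      ml <- st$midline
      truth[[i]] <- list(midline = ml, head = ml[1, ],
                         tail = ml[nrow(ml), ],
                         centroid = colMeans(ml), heading = st$heading,
                         mask = NULL)
    }
  }
  structure(list(frames = frames, truth = truth, times = times,
                 params = params),
            class = "crawl_simulation")
}

#' Write a simulated trial to disk
#'
#' Writes zero-padded numbered PNG frames and a JSON ground-truth sidecar
#' (midline, head, tail, centroid, heading per frame; masks omitted).
#'
#' @param sim A [simulate_crawl()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_frames <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(sim$frames)) {
    png::writePNG(sim$frames[[i]] / 255,
                  file.path(dir, sprintf("frame_%04d.png", i - 1L)))
  }
  gt <- lapply(seq_along(sim$truth), function(i) {
    tr <- sim$truth[[i]]
    list(frame = i - 1L, time = sim$times[i], head = tr$head,
         tail = tr$tail, centroid = tr$centroid, heading = tr$heading,
         midline = tr$midline)
  })
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Ground-truth trajectory of a simulated trial
#'
#' Converts the generator's exact per-frame ground truth into a labeled
#' trajectory in arena millimeters (head/tail/centroid/midpoint and the
#' midline as skeleton), bypassing the image-processing stages. Useful for
#' validating downstream analyses (records, event detection) against known
#' kinematics.
#'
#' @param sim A [simulate_crawl()] result.
#' @return A `labeled_trajectory` with postures in mm.
#' @export
ground_truth_trajectory <- function(sim) {
  postures <- lapply(sim$truth, function(tr) {
    ml <- tr$midline
    al <- arc_lengths(ml)
    mid <- polyline_at(ml, max(al) / 2)[1, ]
    structure(list(contour = NULL, skeleton = ml,
                   ends = rbind(tr$head, tr$tail),
                   head = c(x = tr$head[1], y = tr$head[2]),
                   tail = c(x = tr$tail[1], y = tr$tail[2]),
                   centroid = c(x = tr$centroid[1], y = tr$centroid[2]),
                   midpoint = c(x = mid[1], y = mid[2]),
                   area = NA_real_, perimeter = NA_real_,
                   skeleton_length = max(al), flags = character(0),
                   units = "mm"),
              class = "posture")
  })
  structure(list(postures = postures,
                 flagged_frames = data.frame(frame = integer(0),
                                             reason = character(0)),
                 corrections = NULL),
            class = "labeled_trajectory")
}

#' Read a directory of grayscale frames
#'
#' Reads zero-padded PNG (or TIFF) frames into a list of 0-255 matrices,
#' sorted by filename.
#'
#' @param dir Directory containing `*.png` or `*.tif(f)` files.
#' @return List of grayscale matrices.
#' @export
read_frames <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(png|tif|tiff)$",
                           full.names = TRUE, ignore.case = TRUE))
  if (!length(files)) stopf("no frames found in %s", dir)
  lapply(files, function(f) {
    if (grepl("\\.png$", f, ignore.case = TRUE)) {
      img <- png::readPNG(f)
    } else {
      if (!requireNamespace("tiff", quietly = TRUE))
        stopf("tiff package required to read %s", f)
      img <- tiff::readTIFF(f)
    }
    if (length(dim(img)) == 3L) img <- img[, , 1]
    img * 255
  })
}
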