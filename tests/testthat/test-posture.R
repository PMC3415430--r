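# Shape analysis: contour, smoothing, thinning, endpoints, curvature,
# head/tail candidates, ordering, morphometrics, QC.

circle_contour <- function(r, n = 360, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

test_that("contour of a filled rectangle has the expected perimeter", {
  m <- matrix(FALSE, 16, 10); m[4:13, 4:7] <- TRUE   # 10 x 4 rectangle
  ct <- extract_contour(m)
  closed <- rbind(ct, ct[1, ])
  per <- sum(sqrt(diff(closed[, 1])^2 + diff(closed[, 2])^2))
  # boundary-tracing oracle: the pixel-center boundary path of an h x w
  # block has length 2 * ((h - 1) + (w - 1)) = 24
  expect_equal(per, 24)
  expect_error(extract_contour(matrix(FALSE, 3, 3)), "empty")
})

test_that("interior holes are filled before tracing", {
  m <- matrix(FALSE, 12, 12); m[3:10, 3:10] <- TRUE; m[6:7, 6:7] <- FALSE
  ct <- extract_contour(m)
  # outer boundary only: all contour points on the outer rectangle edge
  expect_true(all(ct[, 1] %in% c(3, 10) | ct[, 2] %in% c(3, 10)))
})

test_that("contour smoothing preserves point count and closure", {
  ct <- circle_contour(50, 300)
  expect_identical(smooth_contour(ct, 1), ct)
  sm <- smooth_contour(ct, 5)
  expect_equal(nrow(sm), nrow(ct))
  radii <- sqrt(sm[, 1]^2 + sm[, 2]^2)
  expect_lt(max(abs(radii - 50)), 1)
  expect_error(smooth_contour(ct[1:3, ], 5), "window")
  expect_error(smooth_contour(ct, 4), "odd")
})

test_that("thinning matches the brute-force oracle on all fixture masks", {
  for (nm in names(fixture_masks())) {
    m <- fixture_masks()[[nm]]
    impl <- skeletonize(m)
    oracle <- zs_thin_oracle(m)
    expect_identical(impl, oracle, label = sprintf("mask '%s'", nm))
    ep <- skeleton_endpoints(impl)
    expect_equal(nrow(ep$endpoints), endpoint_count_oracle(oracle),
                 label = sprintf("endpoints of '%s'", nm))
  }
})

test_that("thinning a bar yields a 2-endpoint axial path", {
  bar <- matrix(FALSE, 7, 15); bar[3:5, 3:13] <- TRUE
  sk <- skeletonize(bar)
  # frozen oracle result: 8 collinear pixels on the middle row
  expect_equal(sum(sk), 8)
  expect_true(all(which(sk, arr.ind = TRUE)[, 1] == 4))
  ep <- skeleton_endpoints(sk)
  expect_equal(nrow(ep$endpoints), 2L)
  expect_false(ep$spur)
  # L-shaped band: connected path, exactly 2 endpoints
  Lb <- matrix(FALSE, 20, 20); Lb[5:16, 5:7] <- TRUE; Lb[14:16, 5:16] <- TRUE
  epL <- skeleton_endpoints(skeletonize(Lb))
  expect_equal(nrow(epL$endpoints), 2L)
  # filled disk collapses to a tiny remnant, flagged blob-like downstream
  disk <- fixture_masks()$disk
  expect_lte(sum(skeletonize(disk)), 2 * 7 + 2)
  expect_true("blob_like" %in% analyze_posture(disk)$flags)
})

test_that("endpoint rule counts isolated and branch pixels correctly", {
  y <- matrix(FALSE, 9, 9)
  y[5, 2:5] <- TRUE; y[4:2, 6] <- TRUE; y[6:8, 6] <- TRUE  # Y shape
  y[4, 6] <- TRUE
  ep <- skeleton_endpoints(y)
  expect_equal(nrow(ep$endpoints), 3L)
  expect_true(ep$spur)
  single <- matrix(FALSE, 3, 3); single[2, 2] <- TRUE
  eps <- skeleton_endpoints(single)
  expect_equal(nrow(eps$endpoints), 1L)
  expect_true(eps$spur)
  straight <- matrix(FALSE, 3, 9); straight[2, 2:8] <- TRUE
  expect_false(skeleton_endpoints(straight)$spur)
})

test_that("curvature of a circle matches 1/r across radii", {
  for (r in c(20, 50, 100)) {
    ct <- circle_contour(r, max(60, round(2 * pi * r)))
    k <- contour_curvature(ct)
    expect_lt(max(abs(k - 1 / r)) / (1 / r), 0.15)
  }
  # straight edge: negligible curvature away from corners
  sq <- rbind(cbind(seq(0, 100), 0), cbind(100, seq(1, 100)),
              cbind(seq(99, 0), 100), cbind(0, seq(99, 1)))
  k <- contour_curvature(sq, arc_window = 5)
  interior <- abs(k[20:80])
  expect_lt(max(interior), 0.002)
  expect_error(contour_curvature(circle_contour(5, 8), arc_window = 5),
               "short")
})

test_that("curvature maxima sit at the capsule tips", {
  p <- posture_params()
  ml <- arc_midline(4, 0.2, start = c(8, 6), theta0 = 15)
  mask <- render_worm(ml, p)$truth$mask
  ct <- smooth_contour(extract_contour(mask), 5)
  k <- contour_curvature(ct)
  ht <- head_tail_candidates(ct, k)
  expect_false(ht$blob_like)
  errs <- c(min(px_err(ht$points[1, ], ml[1, ], 0.05),
                px_err(ht$points[1, ], ml[nrow(ml), ], 0.05)),
            min(px_err(ht$points[2, ], ml[1, ], 0.05),
                px_err(ht$points[2, ], ml[nrow(ml), ], 0.05)))
  expect_lt(max(errs), 3)
})

test_that("a circle has no well-separated curvature maxima", {
  disk <- fixture_masks()$disk
  ct <- smooth_contour(extract_contour(disk), 5)
  ht <- head_tail_candidates(ct, contour_curvature(ct))
  expect_true(ht$blob_like)
})

test_that("a U-shaped body still resolves its two tips", {
  p <- posture_params()
  ml <- arc_midline(4, 0.785, start = c(8, 5), theta0 = 90)  # ~180 deg bend
  mask <- render_worm(ml, p)$truth$mask
  po <- analyze_posture(mask)
  errs <- c(min(px_err(po$ends[1, ], ml[1, ], 0.05),
                px_err(po$ends[1, ], ml[nrow(ml), ], 0.05)),
            min(px_err(po$ends[2, ], ml[1, ], 0.05),
                px_err(po$ends[2, ], ml[nrow(ml), ], 0.05)))
  expect_lt(max(errs), 3)
})

test_that("skeleton ordering starts at the requested end", {
  straight <- matrix(FALSE, 3, 11); straight[2, 2:10] <- TRUE
  left <- order_skeleton(straight, c(1, 2))
  expect_equal(left[1, ], c(x = 2, y = 2))
  expect_equal(left[nrow(left), ], c(x = 10, y = 2))
  right <- order_skeleton(straight, c(11, 2))
  expect_identical(right, left[nrow(left):1, ])
  y <- matrix(FALSE, 9, 9)
  y[5, 2:5] <- TRUE; y[4:2, 6] <- TRUE; y[6:8, 6] <- TRUE
  expect_error(order_skeleton(y, c(2, 5)), "branched")
})

test_that("posture metrics are exact on simple shapes", {
  m <- matrix(FALSE, 16, 10); m[4:13, 4:7] <- TRUE
  ct <- extract_contour(m)
  sk <- cbind(5.5, 4:13)
  met <- posture_metrics(m, ct, sk)
  expect_equal(met$area, 40)
  expect_equal(unname(met$centroid), c(5.5, 8.5))
  expect_equal(met$skeleton_length, 9)
  expect_equal(unname(met$midpoint[2]), 8.5, tolerance = 0.51)
})

test_that("full posture analysis of a capsule is accurate", {
  p <- posture_params()
  ml <- arc_midline(4, 0, start = c(9, 6), theta0 = 0)
  po <- analyze_posture(render_worm(ml, p)$truth$mask)
  expect_length(po$flags, 0)
  # body length 4 mm = 80 px at 0.05 mm/px
  expect_lt(abs(po$skeleton_length - 80) / 80, 0.1)
  expect_lt(px_err(po$centroid, c(7, 6), 0.05), 2)
  expect_lt(px_err(po$midpoint, c(7, 6), 0.05), 2)
  # skeleton endpoints coincide with the candidate tips
  expect_equal(unname(po$skeleton[1, ]), unname(po$ends[1, ]))
  expect_equal(unname(po$skeleton[nrow(po$skeleton), ]),
               unname(po$ends[2, ]))
})

test_that("random curved postures meet the accuracy invariants", {
  p <- posture_params()
  set.seed(202)
  n_trials <- 60
  two_ep <- logical(n_trials); errs <- c(); lens <- numeric(n_trials)
  in_mask_1px <- function(pts, mask) {
    all(vapply(seq_len(nrow(pts)), function(j) {
      r <- round(pts[j, 2]); c <- round(pts[j, 1])
      rr <- max(1, r - 1):min(nrow(mask), r + 1)
      cc <- max(1, c - 1):min(ncol(mask), c + 1)
      any(mask[rr, cc])
    }, logical(1)))
  }
  for (i in seq_len(n_trials)) {
    ml <- arc_midline(4, runif(1, -0.35, 0.35), start = c(6, 6),
                      theta0 = runif(1, 0, 360))
    mask <- render_worm(ml, p)$truth$mask
    po <- analyze_posture(mask)
    two_ep[i] <- !("spur" %in% po$flags)
    lens[i] <- po$skeleton_length
    errs <- c(errs,
              min(px_err(po$ends[1, ], ml[1, ], 0.05),
                  px_err(po$ends[1, ], ml[nrow(ml), ], 0.05)),
              min(px_err(po$ends[2, ], ml[1, ], 0.05),
                  px_err(po$ends[2, ], ml[nrow(ml), ], 0.05)))
    # skeleton stays within the body mask (1 px slack for smoothing)
    expect_true(in_mask_1px(po$skeleton, mask))
  }
  expect_gte(mean(two_ep), 0.95)
  expect_lt(max(errs), 3)
  expect_true(all(abs(lens - 80) / 80 < 0.1))
})

test_that("qc_summary reports flag fractions", {
  mk <- function(flags) structure(list(flags = flags), class = "posture")
  ps <- c(replicate(98, mk(character(0)), simplify = FALSE),
          list(mk("spur"), mk("spur")))
  qc <- qc_summary(ps)
  expect_equal(qc$fraction_spur, 0.02)
  expect_equal(qc$fraction_blob_like, 0)
  expect_equal(qc_summary(list(mk(c("spur", "discarded"))))$fraction_discarded,
               1)
  expect_error(qc_summary(list()), "no postures")
})
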