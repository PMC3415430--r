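# Online stage: thresholding, component retention, background
# reconstruction, tracking loop.

test_that("binarize follows threshold and polarity", {
  f <- matrix(10, 8, 8); f[3:5, 3:5] <- 200
  expect_identical(binarize(f, 100, "light_on_dark"), f == 200)
  expect_false(any(binarize(matrix(10, 5, 5), 100, "light_on_dark")))
  expect_true(all(binarize(matrix(10, 5, 5), 255, "dark_on_light")))
  expect_error(binarize(f, 300, "dark_on_light"), "threshold")
})

test_that("suggested threshold maximizes between-class variance", {
  f2 <- matrix(c(rep(10, 500), rep(200, 100)), 30, 20)
  th <- suggest_threshold(f2)
  expect_gt(th, 10); expect_lt(th, 200)
  set.seed(1)
  f <- pmin(pmax(matrix(round(c(rnorm(3000, 40, 10),
                                rnorm(3000, 180, 10))), 60, 100), 0), 255)
  th_pkg <- suggest_threshold(f)
  th_oracle <- otsu_exhaustive(f)
  expect_gte(th_pkg, 80); expect_lte(th_pkg, 140)
  expect_gte(th_oracle, 80); expect_lte(th_oracle, 140)
  # both thresholds induce the same partition of this histogram
  expect_identical(binarize(f, th_pkg, "light_on_dark"),
                   binarize(f, th_oracle, "light_on_dark"))
  expect_error(suggest_threshold(matrix(7, 5, 5)), "degenerate_histogram")
})

test_that("largest_object keeps one 8-connected component", {
  m <- matrix(FALSE, 20, 20)
  m[2:11, 2:11] <- TRUE            # 100 px
  m[15:16, 15:17] <- TRUE          # 6 px (well separated)
  keep <- largest_object(m)
  expected <- m; expected[15:16, 15:17] <- FALSE
  expect_identical(keep, expected)
  # single component is returned unchanged
  single <- matrix(FALSE, 9, 9); single[3:5, 3:7] <- TRUE
  expect_identical(largest_object(single), single)
  # diagonal chains are one component (8-connectivity)
  d <- matrix(FALSE, 8, 8)
  for (i in 1:6) d[i, i] <- TRUE
  d[8, 1] <- TRUE
  expect_equal(sum(largest_object(d)), 6)
  expect_error(largest_object(matrix(FALSE, 4, 4)), "no_object")
})

test_that("equal-size components tie-break by row-major first pixel", {
  m <- matrix(FALSE, 10, 10)
  m[6, 1:3] <- TRUE      # lower-left, 3 px; first pixel row 6 col 1
  m[2, 5:7] <- TRUE      # upper-right, 3 px; first pixel row 2 col 5
  keep <- largest_object(m)
  expect_true(all(keep[2, 5:7]))   # row 2 precedes row 6 in row-major order
  expect_false(any(keep[6, 1:3]))
})

test_that("background reconstruction recovers the animal-free scene", {
  clutter <- list(list(center = c(30, 12), radius = 0.6, intensity = 120))
  p <- crawl_params(noise_sd = 0, duration = 20, dt = 0.5, speed = 0.2,
                    arena_size = c(40, 25), start = c(8, 18),
                    clutter = clutter, seed = 4)
  sim <- simulate_crawl(p)
  bg <- reconstruct_background(sim$frames, polarity = "dark_on_light")
  expect_true(bg$completed)
  expect_identical(bg$pixels, render_scene(p))
  # no clutter, uniform level: background is uniform
  p2 <- crawl_params(noise_sd = 0, duration = 20, dt = 0.5, speed = 0.2,
                     arena_size = c(40, 25), start = c(8, 18),
                     background_level = 200)
  bg2 <- reconstruct_background(simulate_crawl(p2)$frames,
                                polarity = "dark_on_light")
  expect_true(all(bg2$pixels == 200))
})

test_that("a static animal leaves the background incomplete", {
  p <- crawl_params(noise_sd = 0, duration = 3, dt = 1, speed = 0,
                    arena_size = c(20, 20), start = c(12, 10))
  sim <- simulate_crawl(p)
  expect_warning(bg <- reconstruct_background(sim$frames,
                                              polarity = "dark_on_light"),
                 class = "background_incomplete")
  expect_false(bg$completed)
})

test_that("background subtraction cancels clutter and isolates the animal", {
  bg <- matrix(200, 30, 30); bg[20:24, 20:24] <- 120    # clutter
  fr <- bg; fr[5:9, 5:9] <- 100                          # dark animal
  d <- subtract_background(fr, bg, "dark_on_light")
  expect_true(all(d[5:9, 5:9] == 100))
  expect_true(all(d[-(5:9), ] == 0))
  expect_true(all(subtract_background(bg, bg, "dark_on_light") == 0))
  # light-on-dark folds to the positive side too
  fr2 <- bg; fr2[5:9, 5:9] <- 255
  d2 <- subtract_background(fr2, bg, "light_on_dark")
  expect_true(all(d2[5:9, 5:9] == 55))
  expect_error(subtract_background(matrix(0, 2, 2), bg), "shape")
})

test_that("track_stream crops contain the animal and reconstruct losslessly", {
  p <- crawl_params(noise_sd = 0, duration = 24.5, dt = 0.5, speed = 0.2,
                    arena_size = c(50, 30), start = c(12, 15), seed = 9)
  sim <- simulate_crawl(p)
  trial <- track_stream(sim$frames, list(polarity = "dark_on_light",
                                         sampling_interval = 0.5))
  expect_s3_class(trial, "trial_recording")
  expect_equal(trial$n_frames, 50L)
  expect_equal(trial$stop_reason, "completed")
  for (k in c(1, 25, 50)) {
    truth_idx <- which(sim$truth[[k]]$mask, arr.ind = TRUE)
    off <- trial$offsets[k, ]
    expect_true(all(truth_idx[, 1] > off$y0 &
                      truth_idx[, 1] <= off$y0 + off$h &
                      truth_idx[, 2] > off$x0 &
                      truth_idx[, 2] <= off$x0 + off$w))
    # offsets + crops reproduce the original frame pixels
    cr <- trial$crops[[k]]
    expect_identical(cr$img,
                     sim$frames[[k]][cr$r0 + seq_len(nrow(cr$img)) - 1,
                                     cr$c0 + seq_len(ncol(cr$img)) - 1])
  }
})

test_that("tracking stops at the frame budget or the arena edge", {
  p <- crawl_params(noise_sd = 0, duration = 24.5, dt = 0.5, speed = 0.2,
                    arena_size = c(50, 30), start = c(12, 15), seed = 9)
  sim <- simulate_crawl(p)
  t10 <- track_stream(sim$frames, list(polarity = "dark_on_light",
                                       n_frames = 10))
  expect_equal(t10$n_frames, 10L)
  expect_equal(t10$stop_reason, "completed")
  # a crawl that leaves the field of view stops early: restrict the
  # camera to the left 30 mm of the arena so the animal walks out
  p2 <- crawl_params(noise_sd = 0, duration = 40, dt = 0.5, speed = 0.2,
                     arena_size = c(50, 30), start = c(12, 15),
                     heading0 = 0, seed = 9)
  sim2 <- simulate_crawl(p2)
  fov <- lapply(sim2$frames, function(f) f[, 1:300])
  t2 <- track_stream(fov, list(polarity = "dark_on_light"))
  expect_lt(t2$n_frames, length(fov))
  expect_equal(t2$stop_reason, "left_field_of_view")
})

test_that("segmentation recovers the exact ground-truth mask without noise", {
  p <- crawl_params(noise_sd = 0, duration = 14.5, dt = 0.5, speed = 0.2,
                    arena_size = c(40, 25), start = c(8, 12), seed = 3)
  sim <- simulate_crawl(p)
  trial <- track_stream(sim$frames, list(polarity = "dark_on_light"))
  for (k in seq_len(trial$n_frames)) {
    m <- crop_mask(trial, k)
    full <- matrix(FALSE, 250, 400)
    cr <- trial$crops[[k]]
    full[cr$r0 + seq_len(nrow(m)) - 1, cr$c0 + seq_len(ncol(m)) - 1] <- m
    expect_identical(full, sim$truth[[k]]$mask)
  }
})

test_that("with noise the recovered masks overlap ground truth closely", {
  p <- crawl_params(noise_sd = 5, contrast = 100, duration = 14.5,
                    dt = 0.5, speed = 0.2, arena_size = c(40, 25),
                    start = c(8, 12), seed = 21)
  sim <- simulate_crawl(p)
  trial <- track_stream(sim$frames, list(polarity = "dark_on_light"))
  jac <- vapply(seq_len(trial$n_frames), function(k) {
    m <- crop_mask(trial, k)
    full <- matrix(FALSE, 250, 400)
    cr <- trial$crops[[k]]
    full[cr$r0 + seq_len(nrow(m)) - 1, cr$c0 + seq_len(ncol(m)) - 1] <- m
    tr <- sim$truth[[k]]$mask
    sum(full & tr) / sum(full | tr)
  }, numeric(1))
  expect_gte(mean(jac >= 0.95), 0.99)
})

test_that("clutter is never retained as the animal after completion", {
  clutter <- list(list(center = c(30, 8), radius = 0.6, intensity = 110))
  p <- crawl_params(noise_sd = 0, duration = 19.5, dt = 0.5, speed = 0.2,
                    arena_size = c(40, 25), start = c(8, 18),
                    clutter = clutter, seed = 6)
  sim <- simulate_crawl(p)
  trial <- track_stream(sim$frames, list(polarity = "dark_on_light"))
  for (k in seq_len(trial$n_frames)) {
    m <- crop_mask(trial, k)
    cr <- trial$crops[[k]]
    full <- matrix(FALSE, 250, 400)
    full[cr$r0 + seq_len(nrow(m)) - 1, cr$c0 + seq_len(ncol(m)) - 1] <- m
    expect_gt(sum(full & sim$truth[[k]]$mask), 0)   # overlaps the animal
  }
})
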