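# Sensorimotor records, event detection, trial merging.

gt_records <- function(params, landscape = NULL) {
  sim <- simulate_crawl(params, render = FALSE)
  cal <- calibration(params$mm_per_pixel, 1 / params$dt)
  build_records(ground_truth_trajectory(sim), cal, landscape)
}

test_that("relative change computes percentages", {
  expect_identical(relative_change(0.05, 1), 5)    # 50 nM on 1 uM
  expect_identical(relative_change(0, 3), 0)
  expect_error(relative_change(1, 0), "zero_baseline")
})

test_that("head-value derivative obeys the chain rule on a straight run", {
  lin <- landscape_linear(0.1, c(1, 0), c(0, 0), 18, units = "degC")
  p <- crawl_params(noise_sd = 0, duration = 20, dt = 0.5, speed = 0.15,
                    arena_size = c(60, 60), start = c(10, 30), heading0 = 0)
  rec <- gt_records(p, lin)
  v <- 0.15 * 4                      # mm/s
  interior <- 2:(nrow(rec) - 1)
  expect_lt(max(abs(rec$head_value_derivative[interior] - 0.1 * v)) /
              (0.1 * v), 0.02)
  expect_true(all(abs(rec$bearing[interior]) < 1))
})

test_that("a stationary animal has zero derivative", {
  lin <- landscape_linear(0.1, c(1, 0), units = "degC")
  p <- crawl_params(noise_sd = 0, duration = 10, dt = 0.5, speed = 0,
                    arena_size = c(40, 40))
  rec <- gt_records(p, lin)
  expect_true(all(rec$head_value_derivative == 0))
  expect_true(all(rec$speed == 0))
})

test_that("head values track the ground-truth head in a radial field", {
  rad <- landscape_radial(c(45, 25), 1, 15, units = "uM")
  p <- crawl_params(noise_sd = 5, duration = 24.5, dt = 0.5, speed = 0.2,
                    arena_size = c(50, 50), start = c(15, 25),
                    heading0 = 10, seed = 3)
  sim <- simulate_crawl(p)
  trial <- track_stream(sim$frames, list(polarity = "dark_on_light",
                                         sampling_interval = 0.5))
  postures <- lapply(seq_len(trial$n_frames), function(k)
    analyze_posture(crop_mask(trial, k)))
  pxcal <- calibration(1, 2)
  glob <- lapply(seq_along(postures), function(k)
    to_arena_frame(postures[[k]],
                   c(trial$crops[[k]]$c0 - 1, trial$crops[[k]]$r0 - 1),
                   pxcal))
  traj <- label_trajectory(glob, sim$truth[[1]]$head / 0.1 + 0.5,
                           sim$truth[[1]]$tail / 0.1 + 0.5)
  traj$postures <- lapply(traj$postures, to_arena_frame,
                          bbox_offset = c(0, 0),
                          cal = calibration(0.1, 2))
  rec <- build_records(traj, calibration(0.1, 2), rad)
  truth_vals <- vapply(sim$truth, function(tr) field_at(rad, tr$head),
                       numeric(1))
  # within the field variation over ~2 px (0.2 mm) around the head
  tol <- max(abs(truth_vals)) * (1 - exp(-0.25 / 15)) + 1e-4
  expect_lt(max(abs(rec$head_value - truth_vals)), 2 * tol)
})

test_that("a constant-heading crawl is one run with no events", {
  p <- crawl_params(noise_sd = 0, duration = 30, dt = 0.2, speed = 0.25,
                    arena_size = c(100, 100), start = c(20, 50))
  rec <- gt_records(p, landscape_linear(0.1, units = "degC"))
  ev <- detect_events(rec)
  expect_equal(nrow(ev$events), 0L)
  expect_true(all(ev$labels == "run"))
})

test_that("injected turns are recovered at the injection time", {
  p <- crawl_params(noise_sd = 0, duration = 30, dt = 0.2, speed = 0.25,
                    arena_size = c(200, 200), start = c(100, 100),
                    turns = list(c(12, 90)))
  rec <- gt_records(p)
  ev <- detect_events(rec, list(turn_rate = 20))
  turns <- ev$events[ev$events$type == "turn", ]
  expect_equal(nrow(turns), 1L)
  t_start <- rec$t[match(turns$start_frame, rec$frame)]
  t_end <- rec$t[match(turns$end_frame, rec$frame)]
  expect_lte(t_start, 12.5); expect_gte(t_end, 11.5)
  expect_equal(abs(turns$magnitude), 90, tolerance = 5)
})

test_that("injected casts are counted exactly", {
  p <- crawl_params(noise_sd = 0, duration = 40, dt = 0.2, speed = 0.25,
                    arena_size = c(200, 200), start = c(100, 100),
                    cast_times = c(8, 20, 31), cast_amplitude = 60)
  rec <- gt_records(p)
  ev <- detect_events(rec, list(cast_angle = 30))
  casts <- ev$events[ev$events$type == "cast", ]
  expect_equal(nrow(casts), 3L)
  expect_true(all(casts$magnitude > 30))
  # the event partition covers every frame with exactly one label
  expect_length(ev$labels, nrow(rec))
  expect_true(all(ev$labels %in% c("run", "turn", "cast")))
})

test_that("merging trials concatenates rows and checks units", {
  lin <- landscape_linear(0.1, units = "degC")
  p1 <- crawl_params(noise_sd = 0, duration = 9.9, dt = 0.1, speed = 0.1,
                     arena_size = c(40, 40))
  p2 <- crawl_params(noise_sd = 0, duration = 14.9, dt = 0.1, speed = 0.1,
                     arena_size = c(40, 40))
  r1 <- gt_records(p1, lin)   # 100 records
  r2 <- gt_records(p2, lin)   # 150 records
  expect_equal(nrow(r1), 100L); expect_equal(nrow(r2), 150L)
  merged <- merge_trials(list(a = r1, b = r2))
  expect_equal(nrow(merged), 250L)
  expect_setequal(unique(merged$trial), c("a", "b"))
  single <- merge_trials(list(only = r1))
  expect_equal(nrow(single), nrow(r1))
  expect_true("trial" %in% names(single))
  r3 <- gt_records(p1, landscape_radial(c(1, 1), 1, 5, units = "uM"))
  expect_error(merge_trials(list(r1, r3)), "incompatible_units")
  expect_error(merge_trials(list()), "empty")
})
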