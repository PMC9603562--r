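test_that("ramp-plateau kinetics reproduce the printed climbing speeds", {
  # fast riser: 0 -> 9 mm between 8 h and 15 h
  k1 <- flow_onset_end(make_ramp_trajectory(9e-3, 8, 15))
  expect_equal(round(k1$mean_speed * 1e3, 1), 1.3)
  expect_equal(k1$h_max, 9e-3, tolerance = 1e-9)
  expect_lt(abs(k1$t_start - 8), 0.25)
  expect_lt(abs(k1$t_end - 15), 0.5)
  # slow riser: 0 -> 9 mm between 2 h and 18 h
  k2 <- flow_onset_end(make_ramp_trajectory(9e-3, 2, 18))
  expect_equal(round(k2$mean_speed * 1e3, 1), 0.6)
})

test_that("mean speed of a pure linear ramp equals the slope exactly", {
  t <- seq(0, 10, by = 0.1)
  slope <- 1.1e-3 # m/h
  traj <- tip_trajectory(t, t * slope)
  k <- flow_onset_end(traj)
  expect_equal(k$mean_speed, slope, tolerance = 1e-12)
})

test_that("all-zero and sub-threshold trajectories are flagged no-flow", {
  t <- seq(0, 24, by = 0.5)
  k <- flow_onset_end(tip_trajectory(t, rep(0, length(t))))
  expect_false(k$flow)
  expect_identical(k$mean_speed, 0)
  k2 <- flow_onset_end(tip_trajectory(t, rep(0.1e-3, length(t))),
                       movement_threshold = 0.2e-3)
  expect_false(k2$flow)
})

test_that("negative detections are clipped and counted", {
  tr <- tip_trajectory(c(0, 1, 2), c(-1e-3, 0, 2e-3))
  expect_identical(tr$n_clipped, 1L)
  expect_true(all(tr$heights_m >= 0))
  expect_error(tip_trajectory(c(1, 1, 2), c(0, 0, 0)),
               class = "cf_invalid_input")
})

test_that("tracker recovers the truth trajectory from a synthetic stack", {
  tl <- gen_corner_timelapse(h_max = 9e-3, t_start = 8, t_end = 15,
                             frame_interval_min = 10, seed = 21)
  traj <- track_tip_heights(tl$frames, tl$corner_roi, tl$baseline_row,
                            tl$calibration, frame_interval_min = 10)
  expect_equal(length(traj$heights_m), length(tl$truth$truth$heights_m))
  err_px <- abs(traj$heights_m - tl$truth$truth$heights_m) / tl$calibration
  expect_lt(max(err_px), 2)
})

test_that("no-signal stack yields an all-zero trajectory and single frames work", {
  tl <- gen_corner_timelapse(h_max = 0, t_start = 8, t_end = 15,
                             frame_interval_min = 30, seed = 6)
  traj <- track_tip_heights(tl$frames, tl$corner_roi, tl$baseline_row,
                            tl$calibration, frame_interval_min = 30)
  expect_true(all(traj$heights_m == 0))
  single <- track_tip_heights(tl$frames[1], tl$corner_roi, tl$baseline_row,
                              tl$calibration)
  expect_length(single$heights_m, 1L)
  expect_error(track_tip_heights(list(), tl$corner_roi, tl$baseline_row,
                                 tl$calibration), class = "cf_invalid_input")
  expect_error(track_tip_heights(tl$frames[1], c(0, 500), tl$baseline_row,
                                 tl$calibration), class = "cf_invalid_input")
})

test_that("recovery holds across 20 seeded stacks (onset and plateau sweep)", {
  set.seed(99)
  hmaxes <- runif(20, 3e-3, 12e-3)
  onsets <- runif(20, 1, 10)
  for (i in seq_len(20)) {
    tl <- gen_corner_timelapse(h_max = hmaxes[i], t_start = onsets[i],
                               t_end = onsets[i] + 6, frame_interval_min = 10,
                               seed = 100 + i)
    traj <- track_tip_heights(tl$frames, tl$corner_roi, tl$baseline_row,
                              tl$calibration, frame_interval_min = 10)
    kin <- flow_onset_end(traj)
    kin_truth <- flow_onset_end(tip_trajectory(tl$truth$truth$times_h,
                                               tl$truth$truth$heights_m))
    expect_lte(abs(kin$t_start - kin_truth$t_start), 10 / 60 + 1e-9)
    expect_lte(abs(kin$h_max - kin_truth$h_max) / tl$calibration, 2)
  }
})

test_that("tracked monotone stacks are monotone after 3-frame median filtering", {
  tl <- gen_corner_timelapse(h_max = 6e-3, t_start = 2, t_end = 12,
                             frame_interval_min = 20, noise_sigma = 0.05,
                             seed = 31)
  traj <- track_tip_heights(tl$frames, tl$corner_roi, tl$baseline_row,
                            tl$calibration, frame_interval_min = 20)
  sm <- stats::runmed(traj$heights_m, 3)
  expect_true(all(diff(sm) >= -1e-12))
})

test_that("trajectories round-trip through CSV", {
  tr <- make_ramp_trajectory(9e-3, 8, 15, interval_min = 30)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tip_trajectory(tr, path)
  back <- read_tip_trajectory(path)
  expect_equal(back$times_h, tr$times_h, tolerance = 1e-9)
  expect_equal(back$heights_m, tr$heights_m, tolerance = 1e-12)
})
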