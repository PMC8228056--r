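test_that("threshold calibration uses the midpoint of the separating gap", {
  segs <- data.frame(level = c("inactive", "inactive", "active", "active", "high_active"),
                     summary = c(0.01, 0.02, 0.06, 0.08, 0.20))
  th <- calibrate_thresholds(segs)
  expect_equal(th$theta_inactive_active, 0.04)
  expect_equal(th$theta_active_high, 0.14)

  sym <- calibrate_thresholds(data.frame(level = c("inactive", "active", "high_active"),
                                         summary = c(0.0, 0.1, 0.2)))
  expect_equal(sym$theta_inactive_active, 0.05)
  expect_equal(sym$theta_active_high, 0.15)
})

test_that("calibration fails on non-separable or incomplete reference material", {
  overlap <- data.frame(level = c("inactive", "active", "high_active"),
                        summary = c(0.06, 0.05, 0.2))
  expect_error(calibrate_thresholds(overlap), "not separable")
  expect_error(calibrate_thresholds(data.frame(level = c("inactive", "active"),
                                               summary = c(0.0, 0.1))),
               "missing: high_active")
  expect_error(activity_thresholds(0.2, 0.1), "theta_inactive_active < theta_active_high")
})

test_that("segment summaries take the maximum observed windowed value", {
  s <- motion_series(0:4, c(0.01, NA, 0.03, 0.02, NA))
  expect_equal(segment_summary(s), 0.03)
  expect_error(segment_summary(motion_series(0:1, c(NA, NA))), "no observed samples")
})

test_that("classification applies the decision tree with upward boundaries", {
  th <- activity_thresholds(0.05, 0.15)
  s <- motion_series(0:4, c(0, 0.04, 0.05, 0.16, NA))
  tl <- classify_activity(s, th)
  expect_equal(as.character(tl$level),
               c("inactive", "inactive", "active", "high_active", "out"))
})

test_that("classification is monotone in the series values", {
  th <- activity_thresholds(0.05, 0.15)
  set.seed(3)
  v <- runif(200, 0, 0.3)
  lower <- classify_activity(motion_series(seq_along(v) - 1, v), th)
  higher <- classify_activity(motion_series(seq_along(v) - 1, pmin(v + 0.02, 0.3)), th)
  rank_of <- c(inactive = 1, active = 2, high_active = 3)
  expect_true(all(rank_of[as.character(higher$level)] >=
                    rank_of[as.character(lower$level)]))
})

test_that("durations count seconds per level and conserve total time", {
  expect_equal(activity_durations(rep("inactive", 1800))[["inactive"]], 1800)
  # half-hour bookkeeping with the scripted 985/205/102/509 block layout
  labels <- rep(c("high_active", "active", "inactive", "out"),
                c(985, 205, 102, 509))
  d <- activity_durations(labels)
  expect_equal(d[["high_active"]], 985)
  expect_equal(d[["active"]], 205)
  expect_equal(d[["inactive"]], 102)
  expect_equal(d[["out"]], 509)
  expect_equal(sum(d), 1801)
  # order invariance: durations are a multiset statistic
  expect_equal(activity_durations(sample(labels)), d)
  expect_error(activity_durations(c("inactive", "asleep")), "unknown")
})

test_that("binned overview conserves time and re-bins additively", {
  set.seed(44)
  n <- 6 * 3600
  tl <- data.frame(time_s = 0:(n - 1),
                   level = sample(c("inactive", "active", "high_active", "out"),
                                  n, replace = TRUE))
  ov30 <- activity_overview(tl, bin_s = 1800)
  expect_equal(sum(ov30$seconds), n)
  expect_equal(tapply(ov30$seconds, ov30$bin_start_s, sum),
               tapply(rep(1800, 12), seq(0, by = 1800, length.out = 12), sum),
               ignore_attr = TRUE)
  expect_equal(activity_durations(tl),
               tapply(ov30$seconds, ov30$level, sum), ignore_attr = TRUE)
  # hourly bins are the sum of their two half-hour bins
  ov60 <- activity_overview(tl, bin_s = 3600)
  for (lv in levels(ov30$level)) {
    half <- ov30$seconds[ov30$level == lv]
    hour <- ov60$seconds[ov60$level == lv]
    expect_equal(hour, half[c(TRUE, FALSE)] + half[c(FALSE, TRUE)])
  }
  # uniform labels give identical full bins
  uni <- data.frame(time_s = 0:3599, level = "active")
  ovu <- activity_overview(uni, bin_s = 600)
  expect_equal(unique(ovu$seconds[ovu$level == "active"]), 600)
  expect_error(activity_overview(uni, bin_s = 0.5), "at least 1 second")
})

test_that("partial final bins are flagged", {
  tl <- data.frame(time_s = 0:2499, level = "inactive")
  ov <- activity_overview(tl, bin_s = 1800)
  expect_equal(attr(ov, "partial_bins"), 1800)
})

test_that("calibrated thresholds separate the training segments perfectly", {
  set.seed(55)
  full_cam <- list(A = list(xmin = 0, xmax = 1, ymin = 0, ymax = 1))
  traj <- simulate_trajectory(sim_config(duration_s = 1800, seed = 56,
                                         cameras = full_cam,
                                         state_script = scripted_half_hour))
  stream <- render_detections(traj, "A", seed = 57)
  truth <- true_activity_labels(traj)
  windowed <- sliding_mean(per_second_series(frame_pair_norms(stream)))
  segs <- reference_segments(truth, windowed)
  th <- calibrate_thresholds(segs)
  expect_true(all(segs$summary[segs$level == "inactive"] < th$theta_inactive_active))
  expect_true(all(segs$summary[segs$level == "active"] > th$theta_inactive_active))
  expect_true(all(segs$summary[segs$level == "active"] < th$theta_active_high))
  expect_true(all(segs$summary[segs$level == "high_active"] > th$theta_active_high))
})

test_that("thresholds round-trip through the two-key config file", {
  th <- activity_thresholds(0.0123, 0.0456)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_thresholds(th, path)
  expect_equal(read_thresholds(path), th)
})
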