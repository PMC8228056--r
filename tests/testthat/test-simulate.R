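test_that("simulator configuration enforces the state-speed ordering", {
  expect_s3_class(sim_config(), "sim_config")
  bad <- list(inactive = list(mean_dwell_s = 100, speed = c(0, 0.1)),
              active = list(mean_dwell_s = 100, speed = c(0.05, 0.2)),
              high_active = list(mean_dwell_s = 100, speed = c(0.3, 0.6)))
  expect_error(sim_config(states = bad), "non-overlapping")
  expect_error(sim_config(duration_s = 1.3, fps = 3), "integer frame count")
})

test_that("simulator configs round-trip through YAML", {
  cfg <- sim_config(duration_s = 120, seed = 5,
                    state_script = data.frame(level = c("active", "inactive"),
                                              duration_s = c(60, 60)))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back$states, cfg$states)
  expect_equal(back$state_script, cfg$state_script)
  expect_equal(back$cameras, cfg$cameras)
})

test_that("trajectories are deterministic under a fixed seed", {
  cfg <- sim_config(duration_s = 120, seed = 33)
  t1 <- simulate_trajectory(cfg)
  t2 <- simulate_trajectory(cfg)
  expect_equal(t1, t2)
  t3 <- simulate_trajectory(sim_config(duration_s = 120, seed = 34))
  expect_false(isTRUE(all.equal(t1$x, t3$x)))
})

test_that("an all-inactive animal barely moves and stays put", {
  script <- data.frame(level = "inactive", duration_s = 300)
  traj <- simulate_trajectory(sim_config(duration_s = 300, seed = 2,
                                         state_script = script))
  expect_true(all(traj$state == "inactive"))
  d <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  expect_lte(max(d), 0.002 / 5 + 1e-12)
  expect_true(all(traj$x >= 0 & traj$x <= 1 & traj$y >= 0 & traj$y <= 1))
})

test_that("realized per-frame displacements fall inside each state's speed band", {
  cfg <- sim_config(duration_s = 600)
  for (seed in 1:10) {
    cfg$seed <- seed
    traj <- simulate_trajectory(cfg)
    d <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
    st <- traj$state[-1]
    same_block <- traj$state[-1] == traj$state[-nrow(traj)]
    for (lv in names(cfg$states)) {
      sel <- st == lv & same_block
      if (!any(sel)) next
      band <- cfg$states[[lv]]$speed / cfg$fps
      m <- mean(d[sel])
      # reflection at walls can only shorten net displacement
      expect_lte(m, band[2] + 1e-9)
      if (lv == "inactive") expect_lte(m, band[2]) else expect_gt(m, 0)
    }
  }
})

test_that("rendering respects camera visibility and jitters centers", {
  cfg <- sim_config(duration_s = 900, seed = 44,
                    cameras = list(full = list(xmin = 0, xmax = 1, ymin = 0, ymax = 1),
                                   half = list(xmin = 0, xmax = 0.5, ymin = 0, ymax = 1)))
  traj <- simulate_trajectory(cfg)
  full <- render_detections(traj, "full", seed = 45)
  expect_false(anyNA(full$cx))  # full-coverage camera sees every frame
  half <- render_detections(traj, "half", seed = 46)
  expect_equal(is.na(half$cx), traj$x > 0.5)
  seen <- !is.na(half$cx)
  expect_gt(sum(seen), 0)
  expect_lte(max(abs(half$cx[seen] - traj$x[seen]), 0), 6 * cfg$jitter_sd)
  expect_error(render_detections(traj, "nope"), "unknown camera")
})

test_that("two complementary cameras cover more than either alone", {
  cfg <- sim_config(duration_s = 1200, seed = 47)
  traj <- simulate_trajectory(cfg)
  a <- render_detections(traj, "A", seed = 48)
  b <- render_detections(traj, "B", seed = 49)
  cov_a <- sum(!is.na(a$cx))
  cov_b <- sum(!is.na(b$cx))
  cov_ab <- sum(!is.na(a$cx) | !is.na(b$cx))
  expect_gt(cov_ab, cov_a)
  expect_gt(cov_ab, cov_b)
})

test_that("motion detector reports per-interval motion inside its coverage only", {
  # stationary animal: no motion at all
  still <- simulate_trajectory(sim_config(duration_s = 300, seed = 51,
                                          state_script = data.frame(level = "inactive",
                                                                    duration_s = 300)))
  md <- emulate_motion_detector(still)
  expect_equal(nrow(md), 30)
  expect_false(any(md$motion))
  # an active animal confined to the detector's blind spot stays undetected
  cfg <- sim_config(duration_s = 300, seed = 52,
                    motion_region = list(xmin = 0.9, xmax = 1, ymin = 0.9, ymax = 1),
                    state_script = data.frame(level = "high_active", duration_s = 300))
  traj <- simulate_trajectory(cfg)
  restricted <- traj
  restricted$x <- traj$x * 0.5          # squeeze the path into x < 0.5
  attr(restricted, "config") <- cfg
  md2 <- emulate_motion_detector(restricted)
  expect_false(any(md2$motion))
})

test_that("manual sampling extrapolates the modal label to whole intervals", {
  const <- data.frame(time_s = 0:3599, level = "active")
  mm <- emulate_manual_sampling(const)
  expect_equal(nrow(mm), 4)
  expect_true(all(mm$level == "active"))
  expect_error(emulate_manual_sampling(const, period_s = 50, half_window_s = 30),
               "twice half_window_s")
})

test_that("manual sampling over-represents activity seen at the sample points", {
  # 47 active minutes placed so that every sample window is fully active:
  # manual scoring reports the whole hour as active
  lv <- rep("inactive", 3600)
  for (start in c(195, 1095, 1995, 2895)) lv[(start + 1):(start + 705)] <- "active"
  tl <- data.frame(time_s = 0:3599, level = lv)
  true_active_min <- sum(lv == "active") / 60
  expect_equal(true_active_min, 47)
  mm <- emulate_manual_sampling(tl)
  expect_true(all(mm$level == "active"))  # 60 reported active minutes
})
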