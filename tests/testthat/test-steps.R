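test_that("steps are recovered on clean walking and refused on junk", {
  wf <- walking_frame(120, duration_s = 60, jitter_ms = 0, noise_g = 0)
  st <- frame_steps(wf$frame, wf$stage1, ww_config())
  expect_lte(abs(length(st$step_times) - 120), 2)
  # constant signal
  expect_equal(detect_steps(rep(0, 400), 100, ww_config()), numeric(0))
  expect_equal(detect_steps(rep(0.5, 400), 100, ww_config()), numeric(0))
  # white noise: the autocorrelation cross-check rejects aperiodic peaks
  set.seed(5)
  rejected <- vapply(1:20, function(i)
    length(detect_steps(rnorm(400, 0, 0.3), 100, ww_config())) == 0,
    logical(1))
  expect_gt(mean(rejected), 0.9)
})

test_that("corrective steps are rate times window count", {
  labels <- rep(c("unspecified_arms_walking", "stationary"), c(10, 5))
  expect_equal(corrective_step_count(labels, 6.4), 64)
  expect_equal(corrective_step_count(rep("stationary", 5), 6.4), 0)
  expect_error(corrective_step_count(labels, -1), "non-negative")
  expect_error(corrective_step_count(labels, NA_real_), "non-negative")
})

test_that("episode metrics follow the eight-step interval rule", {
  cfg <- ww_config()
  # constant 500 ms intervals: cadence 120 spm, zero variability
  st <- seq(0, by = 0.5, length.out = 40)
  em <- episode_metrics(st, cfg)
  expect_equal(nrow(em$episodes), 5)
  expect_equal(unique(em$episodes$cadence_spm), 120)
  expect_equal(unique(em$episodes$step_time_sd_ms), 0)
  expect_equal(em$cadence_median_spm, 120)
  expect_equal(em$step_time_variability_ms, 0)
  # a partial trailing episode is discarded
  em2 <- episode_metrics(st[1:19], cfg)
  expect_equal(nrow(em2$episodes), 2)
  # too few steps: metrics flagged missing
  em3 <- episode_metrics(st[1:5], cfg)
  expect_true(is.na(em3$cadence_median_spm))
  expect_equal(nrow(em3$episodes), 0)
})

test_that("daily variability is the interpolated 95th order statistic", {
  # brute-force oracle for the linear-interpolation quantile at p = 0.95:
  # h = 1 + p (n - 1); value = x(floor(h)) + (h - floor(h)) diff
  sds <- c(10, 20, 30, 40, 50, 60, 70, 80, 90, 100)
  h <- 1 + 0.95 * (length(sds) - 1)
  oracle <- sds[floor(h)] + (h - floor(h)) * (sds[floor(h) + 1] - sds[floor(h)])
  # realize episodes whose per-episode SDs are exactly `sds`
  steps <- c()
  t0 <- 0
  for (s in sds / 1000) {
    iv <- rep(0.5, 7) + s * c(-1, 1, -1, 1, -1, 1, 0) /
      sd(c(-1, 1, -1, 1, -1, 1, 0))
    steps <- c(steps, t0 + cumsum(c(0, iv)))
    t0 <- t0 + 8  # > 2 s break between episodes
  }
  em <- episode_metrics(steps, ww_config())
  expect_equal(sort(em$episodes$step_time_sd_ms), sds, tolerance = 1e-9)
  expect_equal(em$step_time_variability_ms, oracle, tolerance = 1e-9)
})

test_that("simulated step-time jitter is recovered from episode SDs", {
  wf <- walking_frame(120, duration_s = 250, jitter_ms = 20, noise_g = 0.02,
                      seed = 6)
  st <- frame_steps(wf$frame, wf$stage1, ww_config())
  em <- episode_metrics(st$step_times, ww_config())
  expect_gt(nrow(em$episodes), 30)
  med_sd <- median(em$episodes$step_time_sd_ms)
  expect_lt(abs(med_sd - 20) / 20, 0.3)
})

test_that("regularity is high for periodic signals, bounded, and missing on noise", {
  fs <- 100
  t <- (0:399) / fs
  x <- sin(2 * pi * 2 * t)
  r <- regularity(x, fs)
  expect_gte(r$step_regularity, 0.99)
  expect_true(all(unlist(r) >= -1 & unlist(r) <= 1, na.rm = TRUE))
  # amplitude invariance
  r10 <- regularity(10 * x, fs)
  expect_equal(r10$step_regularity, r$step_regularity, tolerance = 1e-10)
  # white noise is flagged missing or tiny
  set.seed(9)
  for (i in 1:10) {
    rn <- regularity(rnorm(400), fs)
    expect_true(is.na(rn$step_regularity) ||
                  abs(rn$step_regularity) <= 0.1)
  }
})

test_that("daily regularity aggregates only over walking windows", {
  wf <- walking_frame(110, duration_s = 40, jitter_ms = 5, noise_g = 0.01)
  reg <- frame_regularity(wf$frame, wf$stage1)
  expect_gt(reg$step_regularity_pct, 80)
  expect_lte(reg$step_regularity_pct, 100)
  none <- frame_regularity(wf$frame, rep("stationary",
                                         length(wf$stage1)))
  expect_true(is.na(none$step_regularity_pct))
})
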