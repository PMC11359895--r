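test_that("scheduled cadence and duration fix the ground-truth step count", {
  subj <- subject_meta("A", "female", 165, 60)
  sched <- activity_schedule(0, 60, "walk_arm_swing", cadence_spm = 120,
                             step_time_jitter_ms = 0)
  sim <- synthesize_recording(sched, subj, seed = 1)
  expect_equal(length(sim$truth$step_times), 120)
  expect_true(all(diff(sim$truth$step_times) > 0))
  # step counts are invariant to the noise realization
  sim2 <- synthesize_recording(sched, subj, seed = 2)
  expect_equal(length(sim2$truth$step_times), 120)
  expect_false(identical(sim$recording$xyz, sim2$recording$xyz))
  # with jitter the count is still seed-invariant
  schedj <- activity_schedule(0, 60, "walk_arm_swing", cadence_spm = 120,
                              step_time_jitter_ms = 30)
  n1 <- length(synthesize_recording(schedj, subj, seed = 1)$truth$step_times)
  n2 <- length(synthesize_recording(schedj, subj, seed = 9)$truth$step_times)
  expect_equal(n1, n2)
})

test_that("identical schedule and seed give bit-identical output", {
  subj <- subject_meta("A", "male", 180, 70)
  sched <- activity_schedule(c(0, 70), c(60, 30),
                             c("walk_arm_swing", "stationary"),
                             speed_ms = c(1.2, NA),
                             step_time_jitter_ms = 10)
  a <- synthesize_recording(sched, subj, seed = 5)
  b <- synthesize_recording(sched, subj, seed = 5)
  expect_identical(a$recording$xyz, b$recording$xyz)
  expect_identical(a$truth, b$truth)
})

test_that("sleep entries hold a stable orientation between posture turns", {
  subj <- subject_meta("A", "female", 160, 55)
  cfg <- ww_config(sampling_rate_hz = 20)
  sched <- activity_schedule(0, 8 * 3600, "sleep")
  sim <- synthesize_recording(sched, subj, seed = 3, cfg)
  expect_equal(unique(sim$truth$stage1), "stationary")
  expect_equal(sim$truth$sleep$onset, 0)
  expect_equal(sim$truth$sleep$offset, 8 * 3600)
  # within any 10-minute stretch the 5-s median orientation is either fixed
  # or contains a single posture turn
  xyz <- sim$recording$xyz[1:(600 * 20), ]
  med <- apply(xyz, 2, function(v) median(v[1:100]))
  ang0 <- atan2(med[3], sqrt(med[1]^2 + med[2]^2))
  med2 <- apply(xyz, 2, function(v) median(v[101:200]))
  ang1 <- atan2(med2[3], sqrt(med2[1]^2 + med2[2]^2))
  expect_lt(abs(ang1 - ang0) * 180 / pi, 5)
})

test_that("overlapping schedules and bad arguments are rejected", {
  expect_error(activity_schedule(c(0, 30), c(60, 30),
                                 c("stationary", "stationary")), "overlap")
  expect_error(activity_schedule(0, 60, "moonwalk"), "unknown activity")
  expect_error(synthesize_cohort(0, 1, 1), "n_subjects")
  expect_error(synthesize_cohort(2, 0, 1), "days")
})

test_that("scheduled cadence is recoverable by Fourier analysis", {
  subj <- subject_meta("A", "female", 165, 60)
  for (cad in c(90, 120)) {
    sched <- activity_schedule(0, 60, "walk_arm_swing", cadence_spm = cad,
                               step_time_jitter_ms = 0)
    sim <- synthesize_recording(sched, subj, seed = 1, noise_g = 0.01)
    x <- bandpass(euclidean_norm(sim$recording), ww_config())
    n <- length(x)
    p <- Mod(fft(x - mean(x)))^2
    freq <- (0:(n - 1)) * 100 / n
    sel <- freq > 0.5 & freq < 4
    f_dom <- freq[sel][which.max(p[sel])]
    expect_lt(abs(f_dom * 60 - cad), 2)
  }
})

test_that("cohorts have the requested shape and documented demographics", {
  cfg <- ww_config(sampling_rate_hz = 20)
  coh <- synthesize_cohort(5, days = 2, seed = 10, cfg, kind = "session")
  expect_length(coh, 5)
  expect_true(all(vapply(coh, function(s) length(s$days), integer(1)) == 2))
  ids <- vapply(coh, function(s) s$subject$id, character(1))
  expect_equal(anyDuplicated(ids), 0L)
  hts <- vapply(coh, function(s) s$subject$height_cm, numeric(1))
  expect_true(all(hts > 100 & hts < 230))
})

test_that("the biomarker matrix generator hits its theoretical ICC", {
  # closed form: icc = sd_b^2 / (sd_b^2 + (sd_day^2 + var_e) / k) by
  # construction; degenerate within-subject variance gives ICC 1
  m <- simulate_biomarker_matrix(20, 5, icc = 1 - 1e-12, sd_between = 2,
                                 seed = 4)
  expect_gt(icc_2k(m)$icc, 0.999)
  # average of replicate cohorts concentrates on the target
  ests <- vapply(1:8, function(r)
    icc_2k(simulate_biomarker_matrix(50, 7, 0.9, sd_between = 1.5,
                                     sd_day = 0.2, seed = 100 + r))$icc,
    numeric(1))
  expect_lt(abs(mean(ests) - 0.9), 0.05)
})

test_that("the speed map is monotone and height-aware", {
  v <- seq(0.6, 1.6, by = 0.1)
  cad <- cadence_from_speed(v, 170)
  expect_true(all(diff(cad) > 0))
  expect_true(all(cad >= 60 & cad <= 160))
  expect_gt(cadence_from_speed(1.2, 155), cadence_from_speed(1.2, 190))
})
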