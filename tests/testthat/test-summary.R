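# Cheap constructed recordings for the wear-time heuristic: 1 Hz signal,
# "worn" hours fidget above the 13 mg threshold, "unworn" hours lie still.
wear_recording <- function(worn_hours_per_day) {
  set.seed(101)
  n_days <- length(worn_hours_per_day)
  xyz <- NULL
  for (d in seq_len(n_days)) {
    worn_s <- round(worn_hours_per_day[[d]] * 3600)
    day <- rbind(
      matrix(rnorm(3 * worn_s, 0, 0.05), ncol = 3),
      matrix(rnorm(3 * (86400 - worn_s), 0, 0.002), ncol = 3))
    day[, 3] <- day[, 3] + 1
    xyz <- rbind(xyz, day)
  }
  n <- nrow(xyz)
  ww_recording(0:(n - 1), xyz, sampling_rate = 1)
}

test_that("wear-time criteria match the published inclusion rules", {
  cfg <- ww_config()
  full <- wear_time(wear_recording(rep(24, 5)), cfg)
  expect_true(full$full_criterion)
  expect_true(full$relaxed_criterion)
  expect_equal(full$days$wear_hours, rep(24, 5))

  relaxed <- wear_time(wear_recording(c(12.5, 12.5, 12.5, 0, 0)), cfg)
  expect_false(relaxed$full_criterion)
  expect_true(relaxed$relaxed_criterion)
  expect_true(all(abs(relaxed$days$wear_hours[1:3] - 12.5) <= 0.75))

  two <- wear_time(wear_recording(c(24, 24)), cfg)
  expect_false(two$full_criterion)
  expect_false(two$relaxed_criterion)
})

mk_day_row <- function(stage1, stage2 = NULL, cfg = ww_config()) {
  n <- length(stage1)
  labels <- data.frame(start_time = seq(0, by = 4, length.out = n),
                       stage1 = stage1,
                       stage2 = stage2 %||% rep(NA_character_, n),
                       stringsAsFactors = FALSE)
  bouts <- assemble_bouts(labels, cfg)
  summarize_day(labels, bouts,
                steps = list(step_times = numeric(0),
                             per_window = rep(list(numeric(0)), n)),
                corrective_rate = NA_real_,
                episode = episode_metrics(numeric(0), cfg),
                reg = list(step_regularity_pct = NA_real_,
                           stride_regularity_pct = NA_real_),
                speeds = numeric(0),
                sleep = list(sleep_duration_h = 7.5, bedtime_h = 23,
                             missing = FALSE),
                cfg)
}

test_that("hand-position identities hold exactly and sum to 100%", {
  stage1 <- c(rep("walk_arm_swing", 10),
              rep("other_complex_walking", 10),
              rep("stationary", 5))
  stage2 <- c(rep(NA, 10),
              rep(c("hands_in_pockets", "hands_held_stationary",
                    "hand_next_to_ear", "hand_on_shoulder",
                    "briefcase_grocery_bag"), 2),
              rep(NA, 5))
  row <- mk_day_row(stage1, stage2)
  expect_equal(row$pct_static, row$pct_texting + row$pct_phone_call)
  expect_equal(row$pct_adaptive,
               row$pct_hands_in_pockets + row$pct_shoulder_bag +
                 row$pct_briefcase)
  total <- row$pct_arm_swing + row$pct_texting + row$pct_phone_call +
    row$pct_hands_in_pockets + row$pct_shoulder_bag + row$pct_briefcase
  expect_equal(total, 100)
  expect_equal(row$pct_arm_swing, 50)
})

test_that("a day without walking leaves gait fields missing, sleep intact", {
  row <- mk_day_row(rep("stationary", 20))
  expect_true(is.na(row$longest_walk_s))
  expect_true(is.na(row$pct_walk_ge_8s))
  expect_true(is.na(row$max_speed_cms))
  expect_true(is.na(row$cadence_median_spm))
  expect_true(is.na(row$pct_arm_swing))
  expect_equal(row$sleep_duration_h, 7.5)
  expect_equal(row$steps_per_day, 0)
})

test_that("normative strata follow the interpolated order statistics", {
  cfg <- ww_config()
  subjects <- data.frame(sex = rep("female", 100),
                         age_years = rep(50, 100),
                         steps_per_day = 1:100)
  tab <- normative_table(subjects, cfg, markers = "steps_per_day")
  row <- tab[tab$sex == "female" & tab$age_group == "45-54", ]
  expect_equal(row$n, 100)
  expect_equal(row$p50, 50.5)
  expect_equal(row$p25, 25.75)
  expect_equal(row$p75, 75.25)
  # brute-force oracle for p5 of 1..100: h = 1 + 0.05 * 99 = 5.95
  expect_equal(row$p5, 5.95)
  # identical values collapse all percentiles
  same <- normative_table(data.frame(sex = "male", age_years = 66,
                                     steps_per_day = rep(7000, 8)),
                          cfg, markers = "steps_per_day")
  srow <- same[same$sex == "male" & same$age_group == "65-74", ]
  expect_true(all(srow[paste0("p", cfg$norm_percentiles)] == 7000))
  # out-of-range ages are excluded from every stratum
  out <- normative_table(data.frame(sex = "male", age_years = 44,
                                    steps_per_day = 1), cfg,
                         markers = "steps_per_day")
  expect_equal(sum(out$n), 0)
})

test_that("percentile grids are monotone and strata pool consistently", {
  set.seed(33)
  n <- 400
  subjects <- data.frame(
    sex = sample(c("female", "male"), n, TRUE),
    age_years = runif(n, 45, 79.9),
    max_speed_cms = rnorm(n, 149, 8))
  cfg <- ww_config()
  tab <- normative_table(subjects, cfg, markers = "max_speed_cms")
  pcols <- paste0("p", cfg$norm_percentiles)
  for (i in seq_len(nrow(tab)))
    if (tab$n[i] > 0)
      expect_true(!is.unsorted(as.numeric(tab[i, pcols])))
  expect_equal(sum(tab$n), n)
  # pooling all strata values reproduces whole-cohort percentiles
  pooled <- quantile(subjects$max_speed_cms, cfg$norm_percentiles / 100,
                     names = FALSE)
  direct <- quantile(subjects$max_speed_cms[subjects$age_years >= 45 &
                                              subjects$age_years < 80],
                     cfg$norm_percentiles / 100, names = FALSE)
  expect_equal(pooled, direct)
})

test_that("z-score profiles standardize against the reference with reversal", {
  set.seed(44)
  ref <- data.frame(steps_per_day = rnorm(200, 7700, 2700),
                    step_time_variability_ms = rnorm(200, 61, 14),
                    max_speed_cms = rnorm(200, 149, 8))
  subj <- data.frame(steps_per_day = mean(ref$steps_per_day),
                     step_time_variability_ms =
                       mean(ref$step_time_variability_ms) +
                       sd(ref$step_time_variability_ms),
                     max_speed_cms = mean(ref$max_speed_cms))
  prof <- zscore_profile(subj, ref)
  expect_equal(prof$z[prof$biomarker == "steps_per_day"], 0)
  expect_equal(prof$z[prof$biomarker == "max_speed_cms"], 0)
  # one SD worse variability scores -1 after direction reversal
  expect_equal(prof$z[prof$biomarker == "step_time_variability_ms"], -1)
  # zero reference SD flags the score missing
  ref0 <- data.frame(steps_per_day = rep(7000, 10))
  expect_true(is.na(zscore_profile(data.frame(steps_per_day = 7000),
                                   ref0)$z))
  # scoring the reference cohort itself is standard normal per marker
  zs <- vapply(seq_len(nrow(ref)), function(i)
    zscore_profile(ref[i, ], ref)$z[1], numeric(1))
  expect_lt(abs(mean(zs)), 0.05)
  expect_lt(abs(sd(zs) - 1), 0.05)
})

test_that("per-subject pooling uses mean or median by skew class", {
  daily <- data.frame(matrix(NA_real_, 3, length(watchwalk:::biomarker_fields()),
                             dimnames = list(NULL,
                                             watchwalk:::biomarker_fields())))
  daily$steps_per_day <- c(1000, 2000, 6000)    # normal: mean
  daily$longest_walk_s <- c(100, 200, 900)      # skewed: median
  daily$bedtime_h <- c(23.5, 0.5, NA)           # circular mean
  pooled <- pool_subject_days(daily)
  expect_equal(pooled$steps_per_day, 3000)
  expect_equal(pooled$longest_walk_s, 200)
  expect_equal(pooled$bedtime_h, 0)
})
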