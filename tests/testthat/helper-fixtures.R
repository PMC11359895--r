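# Shared fixtures, built once per test run and memoised.  Everything is
# generated in code from the synthetic-accelerometry module; no data files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# Labelled window features of a session cohort at the native 100 Hz rate,
# with ground-truth speeds for the speed model.  Used by the classifier and
# speed-model recovery tests.
session_cohort_data <- function(n_subjects = 20, seed = 42) {
  memo(paste0("sess", n_subjects, "_", seed), function() {
    cfg <- ww_config()
    coh <- synthesize_cohort(n_subjects, days = 1, seed = seed, cfg,
                             kind = "session")
    X <- NULL; y1 <- c(); y2 <- c(); pid <- c(); spw <- c()
    sX <- NULL; sv <- c(); sp <- c()
    daily_max <- c(); daily_usual <- c()
    for (s in coh) {
      sim <- s$days[[1]]
      fr <- segment_windows(sim$recording, cfg)
      f <- extract_features(fr, cfg)
      l1 <- window_truth(fr, sim$truth$stage1)
      X <- rbind(X, f)
      y1 <- c(y1, l1)
      y2 <- c(y2, window_truth(fr, sim$truth$stage2))
      pid <- c(pid, rep(s$subject$id, nrow(f)))
      spw <- c(spw, window_step_counts(fr, sim$truth$step_times))
      st <- frame_steps(fr, l1, cfg)
      pr <- speed_predictors(fr, l1, st$per_window)
      tv <- window_truth(fr, sim$truth$speed_ms)[pr$window]
      ok <- is.finite(tv)
      sX <- rbind(sX, pr$x[ok, , drop = FALSE])
      sv <- c(sv, tv[ok])
      sp <- c(sp, rep(s$subject$id, sum(ok)))
    }
    list(cfg = cfg, features = X, stage1 = y1, stage2 = y2,
         participant = pid, steps_per_window = spw,
         speed_x = sX, speed_truth = sv, speed_participant = sp)
  })
}

trained_classifier <- function() {
  memo("clf", function() {
    d <- session_cohort_data()
    train_activity_classifier(d$features, d$stage1, d$stage2, d$participant,
                              d$cfg, seed = 7,
                              steps_per_window = d$steps_per_window)
  })
}

trained_speed_model <- function() {
  memo("spd", function() {
    d <- session_cohort_data()
    fit_speed(d$speed_x, d$speed_truth, d$speed_participant, d$cfg, seed = 3)
  })
}

# Coarser 20 Hz configuration for day-scale work: full noon-to-noon days at
# 100 Hz would be needlessly heavy for tests while the method is unchanged.
cfg20 <- function() ww_config(sampling_rate_hz = 20)

day_models <- function() {
  memo("day_models", function() {
    cfg <- cfg20()
    coh <- synthesize_cohort(6, days = 1, seed = 31, cfg, kind = "session")
    X <- NULL; y1 <- c(); y2 <- c(); pid <- c(); spw <- c()
    sX <- NULL; sv <- c(); sp <- c()
    for (s in coh) {
      sim <- s$days[[1]]
      fr <- segment_windows(sim$recording, cfg)
      f <- extract_features(fr, cfg)
      l1 <- window_truth(fr, sim$truth$stage1)
      X <- rbind(X, f); y1 <- c(y1, l1)
      y2 <- c(y2, window_truth(fr, sim$truth$stage2))
      pid <- c(pid, rep(s$subject$id, nrow(f)))
      spw <- c(spw, window_step_counts(fr, sim$truth$step_times))
      st <- frame_steps(fr, l1, cfg)
      pr <- speed_predictors(fr, l1, st$per_window)
      tv <- window_truth(fr, sim$truth$speed_ms)[pr$window]
      ok <- is.finite(tv)
      sX <- rbind(sX, pr$x[ok, , drop = FALSE]); sv <- c(sv, tv[ok])
      sp <- c(sp, rep(s$subject$id, sum(ok)))
    }
    list(cfg = cfg,
         classifier = train_activity_classifier(X, y1, y2, pid, cfg,
                                                seed = 2,
                                                steps_per_window = spw),
         speed = fit_speed(sX, sv, sp, cfg, seed = 2))
  })
}

simulated_day <- function() {
  memo("day1", function() {
    cfg <- cfg20()
    subj <- subject_meta("D01", "female", 164, 58)
    sched <- with_test_seed(77, day_schedule(subj, 1.1))
    synthesize_recording(sched, subj, seed = 78, cfg)
  })
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# A single-entry walking frame plus per-window truth, for step-level tests
# under controlled conditions (no posture wander).
walking_frame <- function(cadence_spm, duration_s = 60, jitter_ms = 0,
                          noise_g = 0, seed = 1, cfg = ww_config()) {
  subj <- subject_meta("W01", "female", 165, 60)
  sched <- activity_schedule(0, duration_s, "walk_arm_swing",
                             cadence_spm = cadence_spm,
                             step_time_jitter_ms = jitter_ms)
  sim <- synthesize_recording(sched, subj, seed = seed, cfg,
                              noise_g = noise_g, posture_wander_g = 0)
  frame <- segment_windows(sim$recording, cfg)
  list(sim = sim, frame = frame,
       stage1 = rep("walk_arm_swing", length(frame$start_time)))
}
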