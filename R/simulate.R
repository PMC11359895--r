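#' Build an activity schedule
#'
#' A schedule is a chronologically sorted, non-overlapping list of scripted
#' activity entries from which [synthesize_recording()] generates a signal.
#' Walking and running entries carry a cadence and/or walking speed; when only
#' the speed is given the cadence follows the generator's documented monotone
#' speed map (see [cadence_from_speed()]).
#'
#' @param start_s entry start times, seconds since recording start.
#' @param duration_s entry durations, seconds.
#' @param activity stage-1 activity, or a stage-2 hand-position label (which
#'   implies stage-1 `other_complex_walking`), or `"sleep"` (a stationary
#'   entry with fixed wrist orientation marked as the true sleep interval).
#' @param cadence_spm step rate, steps per minute (walking/running only).
#' @param speed_ms true walking speed, m/s (walking/running only).
#' @param step_time_jitter_ms standard deviation of the step-time jitter, ms.
#' @return A `data.frame` of class `ww_schedule`.
#' @export
activity_schedule <- function(start_s, duration_s, activity,
                              cadence_spm = NA_real_, speed_ms = NA_real_,
                              step_time_jitter_ms = NA_real_) {
  n <- length(start_s)
  sched <- data.frame(start_s = as.numeric(start_s),
                      duration_s = as.numeric(duration_s),
                      activity = as.character(activity),
                      cadence_spm = rep_len(as.numeric(cadence_spm), n),
                      speed_ms = rep_len(as.numeric(speed_ms), n),
                      step_time_jitter_ms =
                        rep_len(as.numeric(step_time_jitter_ms), n),
                      stringsAsFactors = FALSE)
  sched <- sched[order(sched$start_s), , drop = FALSE]
  rownames(sched) <- NULL
  known <- c(stage1_levels(), stage2_levels(), "sleep")
  bad <- setdiff(sched$activity, known)
  if (length(bad))
    stop("unknown activity: ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(sched$duration_s <= 0))
    stop("entry durations must be positive", call. = FALSE)
  ends <- sched$start_s + sched$duration_s
  if (n > 1 && any(sched$start_s[-1] < ends[-n] - 1e-9))
    stop("schedule entries overlap", call. = FALSE)
  class(sched) <- c("ww_schedule", "data.frame")
  sched
}

# Stage-1 / stage-2 resolution of a schedule activity string.
schedule_stage1 <- function(activity) {
  ifelse(activity %in% stage2_levels(), "other_complex_walking",
         ifelse(activity == "sleep", "stationary", activity))
}
schedule_stage2 <- function(activity) {
  ifelse(activity %in% stage2_levels(), activity, NA_character_)
}
is_steps_activity <- function(activity) {
  schedule_stage1(activity) %in% c(walking_levels(), "running",
                                   "unspecified_arms_walking")
}

#' Monotone speed-to-cadence map of the generator
#'
#' The generator couples true walking speed to the signal through cadence and
#' arm-swing/impact amplitude.  Cadence follows from a speed-dependent step
#' length scaled by body height:
#' `step_length_m = (0.25 + 0.30 * speed) * height_cm / 170`,
#' `cadence_spm = 60 * speed / step_length_m`, clamped to 60--160 spm.
#' Over typical speeds (0.6--1.6 m/s) this spans roughly 80--130 spm.
#'
#' @param speed_ms walking speed, m/s.
#' @param height_cm body height, cm.
#' @return Cadence in steps per minute.
#' @export
cadence_from_speed <- function(speed_ms, height_cm = 170) {
  step_len <- (0.25 + 0.30 * speed_ms) * height_cm / 170
  pmin(pmax(60 * speed_ms / step_len, 60), 160)
}

# Amplitude scaling with speed: faster walking swings the arm and loads the
# wrist harder.  Documented part of the speed -> signal map.
speed_amplitude_scale <- function(speed_ms) 0.4 + 0.5 * speed_ms

# Per-class signal signature: arm-swing sinusoid amplitude (at stride
# frequency, mostly on x), step-impact bump amplitude (mostly along gravity),
# wrist gravity orientation, and aperiodic arm-movement level.
class_signature <- function(activity) {
  g_down <- c(0, 0, 1)
  switch(activity,
    walk_arm_swing        = list(swing = 0.30, impact = 0.22, grav = g_down,
                                 arm_noise = 0.00),
    hands_in_pockets      = list(swing = 0.06, impact = 0.20,
                                 grav = c(0.30, 0.05, 0.95), arm_noise = 0.00),
    hands_held_stationary = list(swing = 0.015, impact = 0.13,
                                 grav = c(0.55, 0.15, 0.82), arm_noise = 0.01),
    hand_next_to_ear      = list(swing = 0.02, impact = 0.10,
                                 grav = c(0.85, 0.25, 0.46), arm_noise = 0.01),
    hand_on_shoulder      = list(swing = 0.04, impact = 0.15,
                                 grav = c(0.30, 0.60, 0.74), arm_noise = 0.01),
    briefcase_grocery_bag = list(swing = 0.10, impact = 0.28,
                                 grav = c(0.10, 0.30, 0.95), arm_noise = 0.02),
    running               = list(swing = 0.50, impact = 0.80, grav = g_down,
                                 arm_noise = 0.02),
    unspecified_arms_walking = list(swing = 0.02, impact = 0.07, grav = g_down,
                                 arm_noise = 0.10),
    stop("no signature for activity ", activity)
  )
}

# Ground-truth step times of one entry.  The step count is a deterministic
# function of duration and cadence (noise seed never changes it): jittered
# intervals are recentred so they sum to the nominal total.
entry_step_times <- function(start_s, duration_s, cadence_spm, jitter_ms) {
  base <- 60 / cadence_spm
  n_steps <- floor(duration_s / base)
  if (n_steps < 1) return(numeric(0))
  if (is.na(jitter_ms) || jitter_ms <= 0) {
    iv <- rep(base, n_steps - 1)
  } else {
    iv <- base + stats::rnorm(n_steps - 1, 0, jitter_ms / 1000)
    iv <- pmax(iv, 0.2 * base)
    if (n_steps > 1) iv <- iv * (base * (n_steps - 1)) / sum(iv)
  }
  start_s + base / 2 + c(0, cumsum(iv))
}

# Gaussian step-impact bump train added along the gravity axis.
add_impacts <- function(dyn, t, step_times, amp, fs, grav) {
  sigma <- 0.06
  half <- as.integer(ceiling(3 * sigma * fs))
  n <- length(t)
  for (st in step_times) {
    i0 <- as.integer(round((st - t[[1]]) * fs)) + 1L
    lo <- max(1L, i0 - half); hi <- min(n, i0 + half)
    if (lo > hi) next
    k <- amp * exp(-((t[lo:hi] - st)^2) / (2 * sigma^2))
    dyn[lo:hi, ] <- dyn[lo:hi, ] + outer(k, grav)
  }
  dyn
}

# Piecewise-constant gravity orientation: random unit vectors held for
# random segment lengths, emulating posture shifts during rest and posture
# turns during sleep.
posture_segments <- function(n, fs, seg_min_s, seg_max_s, tilt = 0.5) {
  out <- matrix(0, n, 3)
  i <- 1L
  prev_elev <- Inf
  while (i <= n) {
    len <- as.integer(stats::runif(1, seg_min_s, seg_max_s) * fs)
    j <- min(n, i + len - 1L)
    # re-draw until the elevation angle moves by >= 10 degrees: a posture
    # shift always breaks a sustained-inactivity run
    repeat {
      ang <- stats::runif(2, -tilt, tilt)
      grav <- c(sin(ang[[1]]), sin(ang[[2]]),
                sqrt(max(0, 1 - sin(ang[[1]])^2 - sin(ang[[2]])^2)))
      elev <- atan2(grav[[3]], sqrt(grav[[1]]^2 + grav[[2]]^2)) * 180 / pi
      if (!is.finite(prev_elev) || abs(elev - prev_elev) >= 10) break
    }
    prev_elev <- elev
    out[i:j, ] <- matrix(grav, j - i + 1L, 3, byrow = TRUE)
    i <- j + 1L
  }
  out
}

# Smooth aperiodic arm movement: AR(1)-filtered white noise, per axis.
smooth_noise <- function(n, sd_target, rho = 0.98) {
  e <- stats::rnorm(n)
  x <- as.numeric(stats::filter(e, rho, method = "recursive"))
  x / stats::sd(x) * sd_target
}

#' Synthesize a wrist accelerometer recording with ground truth
#'
#' Generates a tri-axial signal at the configured sampling rate from a
#' scripted [activity_schedule()].  Walking-type entries produce a
#' quasi-periodic arm-swing sinusoid at stride frequency plus a step-impact
#' bump train at the scheduled cadence with the scheduled step-time jitter;
#' stationary entries produce gravity plus low-amplitude noise; sleep entries
#' hold a fixed wrist orientation.  Identical inputs and seed give
#' bit-identical output, and ground-truth step counts do not depend on the
#' noise realization.
#'
#' @param schedule an [activity_schedule()].
#' @param subject a [subject_meta()].
#' @param seed integer RNG seed.
#' @param cfg a [ww_config()]; `sampling_rate_hz` sets the output rate.
#' @param noise_g standard deviation of the white sensor noise, g.
#' @param posture_wander_g amplitude of the slow wrist-posture wander added
#'   to every dynamic (non-rest) entry so that the 5-second median arm angle
#'   keeps moving during waking activity, as on a real wrist.  Set to 0 for
#'   idealized signals in controlled experiments.
#' @param start_clock_s clock time of sample 1 (seconds after midnight).
#' @return A list with `recording` (a [ww_recording()]) and `truth`, a list
#'   holding per-sample `stage1`/`stage2` labels, per-sample true `speed_ms`,
#'   ground-truth `step_times`, `sleep` intervals (onset/offset in recording
#'   seconds) and the resolved schedule (`entries`).
#' @export
synthesize_recording <- function(schedule, subject, seed, cfg = ww_config(),
                                 noise_g = 0.02, posture_wander_g = 0.10,
                                 start_clock_s = 12 * 3600) {
  stopifnot(inherits(schedule, "ww_schedule"), nrow(schedule) >= 1)
  fs <- cfg$sampling_rate_hz
  total_s <- max(schedule$start_s + schedule$duration_s)
  n <- as.integer(round(total_s * fs))
  time <- (seq_len(n) - 1L) / fs

  with_seed(seed, {
    xyz <- matrix(stats::rnorm(3L * n, 0, noise_g), ncol = 3)
    xyz[, 3] <- xyz[, 3] + 1           # default gravity along +z
    stage1 <- rep("stationary", n)
    stage2 <- rep(NA_character_, n)
    speed <- rep(NA_real_, n)
    step_times <- numeric(0)
    sleep <- data.frame(onset = numeric(0), offset = numeric(0))
    entries <- schedule
    entries$n_steps <- 0L

    for (j in seq_len(nrow(schedule))) {
      en <- schedule[j, ]
      i0 <- as.integer(floor(en$start_s * fs)) + 1L
      i1 <- min(n, as.integer(ceiling((en$start_s + en$duration_s) * fs)))
      idx <- i0:i1
      tt <- time[idx]
      stage1[idx] <- schedule_stage1(en$activity)
      stage2[idx] <- schedule_stage2(en$activity)

      if (en$activity == "sleep") {
        # stable lying orientation with occasional posture turns
        # (every 20-45 min), as real sleepers provide; very low noise
        xyz[idx, ] <- matrix(stats::rnorm(3L * length(idx), 0, 0.004),
                             ncol = 3) +
          posture_segments(length(idx), fs, seg_min_s = 20 * 60,
                           seg_max_s = 45 * 60, tilt = 0.5)
        sleep <- rbind(sleep, data.frame(onset = en$start_s,
                                         offset = en$start_s + en$duration_s))
        next
      }
      if (en$activity == "stationary") {
        # seated/standing rest: posture shifts every 1-4 min and fidget
        # noise well above the non-wear movement threshold
        xyz[idx, ] <- matrix(stats::rnorm(3L * length(idx), 0, noise_g),
                             ncol = 3) +
          posture_segments(length(idx), fs, seg_min_s = 60,
                           seg_max_s = 240, tilt = 0.8)
        next
      }
      if (en$activity == "unspecified_arms_sit_stand") {
        for (ax in 1:3)
          xyz[idx, ax] <- xyz[idx, ax] + smooth_noise(length(idx), 0.12)
        next
      }

      sig <- class_signature(en$activity)
      v <- en$speed_ms
      cad <- en$cadence_spm
      if (is.na(cad) && !is.na(v))
        cad <- cadence_from_speed(v, subject$height_cm)
      if (is.na(cad)) cad <- if (en$activity == "running") 160 else 105
      amp_scale <- if (!is.na(v)) speed_amplitude_scale(v) else 1
      st <- entry_step_times(en$start_s, en$duration_s, cad,
                             en$step_time_jitter_ms)
      entries$n_steps[j] <- length(st)
      entries$cadence_spm[j] <- cad
      step_times <- c(step_times, st)
      if (!is.na(v)) speed[idx] <- v

      dyn <- matrix(0, length(idx), 3)
      f_stride <- cad / 120            # one arm swing per two steps
      swing <- sig$swing * amp_scale
      dyn[, 1] <- swing * sin(2 * pi * f_stride * (tt - en$start_s))
      dyn[, 2] <- 0.25 * swing * sin(2 * pi * f_stride * (tt - en$start_s) +
                                       pi / 3)
      dyn <- add_impacts(dyn, tt, st, sig$impact * amp_scale, fs, sig$grav)
      if (sig$arm_noise > 0)
        for (ax in 1:3)
          dyn[, ax] <- dyn[, ax] + smooth_noise(length(idx), sig$arm_noise)
      # slow wrist-posture wander: the gravity direction drifts smoothly
      # (a rotation, so the magnitude stays 1 g), keeping the 5-s median
      # arm angle moving during waking activity as on a real wrist
      g0 <- sig$grav / sqrt(sum(sig$grav^2))
      gmat <- matrix(g0, length(idx), 3, byrow = TRUE)
      if (posture_wander_g > 0) {
        for (ax in 1:3)
          gmat[, ax] <- gmat[, ax] + smooth_noise(length(idx),
                                                  posture_wander_g)
        gmat <- gmat / sqrt(rowSums(gmat^2))
      }
      xyz[idx, ] <- dyn +
        matrix(stats::rnorm(3L * length(idx), 0, noise_g), ncol = 3) + gmat
    }

    rec <- ww_recording(time, xyz, fs, subject, start_clock_s)
    list(recording = rec,
         truth = list(stage1 = stage1, stage2 = stage2, speed_ms = speed,
                      step_times = sort(step_times), sleep = sleep,
                      entries = entries))
  })
}

# --- schedule builders ------------------------------------------------------

#' Scripted training session schedule
#'
#' One laboratory-style session covering every activity class: arm-swing
#' walking at three paces, each stage-2 hand position, running, stationary
#' rest, unspecified arm activity while seated and while walking.  Used to
#' train and cross-validate the classifier and the speed model on synthetic
#' cohorts.
#'
#' @param subject a [subject_meta()].
#' @param base_speed_ms the subject's usual walking speed, m/s.
#' @param block_s duration of each walking block, seconds.
#' @param jitter_ms step-time jitter SD, ms.
#' @return An [activity_schedule()].
#' @export
session_schedule <- function(subject, base_speed_ms = 1.15, block_s = 64,
                             jitter_ms = 15) {
  speeds <- base_speed_ms * c(0.7, 1.0, 1.3)
  acts <- c(rep("walk_arm_swing", 3), stage2_levels(),
            "running", "stationary", "unspecified_arms_sit_stand",
            "unspecified_arms_walking")
  speed <- c(speeds, rep(base_speed_ms, 5), 2.8, NA, NA, base_speed_ms)
  durs <- c(rep(block_s, 8), 40, 120, 90, block_s)
  starts <- cumsum(c(0, durs[-length(durs)] + 8))  # 8 s standing between
  activity_schedule(starts, durs, acts, speed_ms = speed,
                    step_time_jitter_ms = jitter_ms)
}

#' Free-living day schedule (noon to noon)
#'
#' Builds one 24-hour noon-to-noon day: alternating stationary rest,
#' unspecified arm activity and walking bouts of varying length and hand
#' position through the afternoon and morning, with one overnight sleep block
#' around the scheduled bedtime.  Randomness (bout lengths, paces, hand
#' positions) comes from the current RNG state, so wrap calls in a seed.
#'
#' @param subject a [subject_meta()].
#' @param day_speed_ms the subject's walking speed on this day, m/s.
#' @param bedtime_h clock hour of sleep onset (fractional, 24 h clock).
#' @param sleep_h sleep duration, hours.
#' @param jitter_ms step-time jitter SD, ms.
#' @return An [activity_schedule()] covering exactly 86400 s from noon.
#' @export
day_schedule <- function(subject, day_speed_ms = 1.15, bedtime_h = 23.25,
                         sleep_h = 8, jitter_ms = 20) {
  entries <- list()
  add <- function(start, dur, act, speed = NA) {
    entries[[length(entries) + 1L]] <<-
      data.frame(start = start, dur = dur, act = act, speed = speed)
    start + dur
  }
  sleep_start <- (bedtime_h - 12) * 3600
  sleep_end <- sleep_start + sleep_h * 3600
  fill_active <- function(t, t_end) {
    while (t < t_end - 30) {
      r <- stats::runif(1)
      if (r < 0.45) {                       # rest
        t <- add(t, min(stats::runif(1, 300, 1500), t_end - t), "stationary")
      } else if (r < 0.6) {                 # arm activity seated/standing
        t <- add(t, min(stats::runif(1, 120, 400), t_end - t),
                 "unspecified_arms_sit_stand")
      } else if (r < 0.9) {                 # a walk, mostly arm swing
        act <- if (stats::runif(1) < 0.85) "walk_arm_swing"
               else sample(stage2_levels(), 1)
        v <- day_speed_ms * stats::runif(1, 0.85, 1.15)
        t <- add(t, min(stats::runif(1, 20, 420), t_end - t), act, v)
      } else {                              # walking with busy arms
        t <- add(t, min(stats::runif(1, 30, 120), t_end - t),
                 "unspecified_arms_walking", day_speed_ms)
      }
      t <- t + stats::runif(1, 4, 40)       # brief transition
    }
    t
  }
  fill_active(0, sleep_start)
  add(sleep_start, sleep_h * 3600, "sleep")
  fill_active(sleep_end, 86400)
  df <- do.call(rbind, entries)
  df <- df[df$start + df$dur <= 86400 + 1e-9, , drop = FALSE]
  activity_schedule(df$start, df$dur, df$act, speed_ms = df$speed,
                    step_time_jitter_ms = jitter_ms)
}

#' Sample subject metadata from the generator's population model
#'
#' Sex is balanced; height is normal by sex (women 162 +/- 6 cm, men
#' 175 +/- 7 cm); age is uniform over the normative range 45--79; each
#' subject's usual walking speed combines a sex offset, an age-related
#' decline and individual variation.
#'
#' @param n number of subjects.
#' @return A `data.frame` with columns id, sex, height_cm, age_years,
#'   usual_speed_ms (one row per subject).
#' @export
sample_subjects <- function(n) {
  sex <- ifelse(stats::runif(n) < 0.5, "female", "male")
  height <- ifelse(sex == "male", stats::rnorm(n, 175, 7),
                   stats::rnorm(n, 162, 6))
  height <- pmin(pmax(height, 140), 205)
  age <- stats::runif(n, 45, 79)
  speed <- 1.15 + 0.08 * (sex == "male") - 0.004 * (age - 62) +
    stats::rnorm(n, 0, 0.10)
  speed <- pmin(pmax(speed, 0.6), 1.7)
  data.frame(id = sprintf("S%03d", seq_len(n)), sex = sex,
             height_cm = height, age_years = age, usual_speed_ms = speed,
             stringsAsFactors = FALSE)
}

#' Synthesize a cohort of recordings with ground truth
#'
#' Draws subjects from the generator's population model and synthesizes, per
#' subject, either `days` laboratory-style training sessions
#' (`kind = "session"`, for classifier and speed-model training) or `days`
#' free-living noon-to-noon days (`kind = "daily"`).  Day-to-day walking
#' speed varies within subject by `within_sd_frac` (multiplicative), giving
#' test-retest analyses a known within-subject structure.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param days recordings per subject (>= 1).
#' @param seed integer seed.
#' @param cfg a [ww_config()].
#' @param kind `"session"` or `"daily"`.
#' @param within_sd_frac within-subject day-to-day SD of walking speed,
#'   as a fraction of the subject's usual speed.
#' @param jitter_ms step-time jitter SD, ms.
#' @param noise_g sensor noise SD, g.
#' @return A list of length `n_subjects`; each element has `subject`
#'   (a [subject_meta()]), `meta` (the subject's row from
#'   [sample_subjects()]) and `days`, a list of [synthesize_recording()]
#'   results.
#' @export
synthesize_cohort <- function(n_subjects, days = 1, seed = 1,
                              cfg = ww_config(),
                              kind = c("session", "daily"),
                              within_sd_frac = 0.04, jitter_ms = 15,
                              noise_g = 0.02) {
  kind <- match.arg(kind)
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  if (days < 1) stop("days must be >= 1", call. = FALSE)
  meta <- with_seed(seed, sample_subjects(n_subjects))
  lapply(seq_len(n_subjects), function(i) {
    subj <- subject_meta(meta$id[i], meta$sex[i], meta$height_cm[i],
                         meta$age_years[i])
    day_list <- lapply(seq_len(days), function(d) {
      dseed <- (seed * 1009L + i * 131L + d) %% .Machine$integer.max
      day_speed <- with_seed(dseed + 7L,
        meta$usual_speed_ms[i] *
          max(0.5, 1 + stats::rnorm(1, 0, within_sd_frac)))
      sched <- with_seed(dseed + 13L,
        if (kind == "session")
          session_schedule(subj, base_speed_ms = day_speed,
                           jitter_ms = jitter_ms)
        else day_schedule(subj, day_speed_ms = day_speed,
                          bedtime_h = 23.25 + stats::rnorm(1, 0, 0.25),
                          sleep_h = max(5, 8 + stats::rnorm(1, 0, 0.4)),
                          jitter_ms = jitter_ms))
      synthesize_recording(sched, subj, seed = dseed, cfg = cfg,
                           noise_g = noise_g)
    })
    list(subject = subj, meta = meta[i, ], days = day_list)
  })
}

#' Generate a subjects-by-days biomarker matrix with known reliability
#'
#' Draws from the two-way random-effects model
#' `y_ij = mu + r_i + c_j + e_ij` with subject SD `sd_between`, day (column)
#' SD `sd_day` and residual SD chosen so that the population intraclass
#' correlation ICC(2,k) -- two-way random effects, absolute agreement,
#' average of k measures -- equals `icc`:
#' `sigma_e^2 = k * sigma_r^2 * (1 - icc) / icc - sigma_c^2`.
#'
#' @param n_subjects rows.
#' @param k_days columns.
#' @param icc target population ICC(2,k), in (0, 1].
#' @param mean grand mean.
#' @param sd_between subject SD.
#' @param sd_day systematic day-effect SD.
#' @param seed integer seed.
#' @return Numeric `n_subjects x k_days` matrix.
#' @export
simulate_biomarker_matrix <- function(n_subjects, k_days, icc, mean = 0,
                                      sd_between = 1, sd_day = 0, seed = 1) {
  stopifnot(icc > 0, icc <= 1, n_subjects >= 2, k_days >= 2)
  var_e <- k_days * sd_between^2 * (1 - icc) / icc - sd_day^2
  if (var_e < 0)
    stop("sd_day too large for the requested icc", call. = FALSE)
  with_seed(seed, {
    r <- stats::rnorm(n_subjects, 0, sd_between)
    cl <- stats::rnorm(k_days, 0, sd_day)
    e <- matrix(stats::rnorm(n_subjects * k_days, 0, sqrt(var_e)),
                n_subjects, k_days)
    mean + outer(r, rep(1, k_days)) + outer(rep(1, n_subjects), cl) + e
  })
}

# --- ground-truth helpers ---------------------------------------------------

#' Per-window ground truth from per-sample values
#'
#' Maps simulator per-sample ground truth onto the windows of a frame:
#' majority vote for categorical values, a summary function for numeric ones.
#'
#' @param frame a `ww_frame`.
#' @param values per-sample vector aligned with the recording the frame was
#'   cut from.
#' @param fun summary for numeric values (default mean over non-missing).
#' @return Per-window vector.
#' @export
window_truth <- function(frame, values, fun = NULL) {
  w <- as.integer(round(frame$window_s * frame$fs))
  get <- function(i) values[frame$first_sample[i] + 0:(w - 1L)]
  if (is.numeric(values)) {
    fun <- fun %||% function(v) if (all(is.na(v))) NA_real_ else
      mean(v, na.rm = TRUE)
    vapply(seq_len(n_windows(frame)), function(i) fun(get(i)), numeric(1))
  } else {
    vapply(seq_len(n_windows(frame)), function(i) {
      v <- get(i); v <- v[!is.na(v)]
      if (!length(v)) return(NA_character_)
      tb <- table(v)
      names(tb)[which.max(tb)]
    }, character(1))
  }
}

#' Ground-truth step count per window
#'
#' @param frame a `ww_frame`.
#' @param step_times ground-truth step event times (recording seconds).
#' @return Integer vector, steps whose event time falls inside each window.
#' @export
window_step_counts <- function(frame, step_times) {
  vapply(seq_len(n_windows(frame)), function(i) {
    s <- frame$start_time[[i]]
    sum(step_times >= s & step_times < s + frame$window_s)
  }, numeric(1))
}
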