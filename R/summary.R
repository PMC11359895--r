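biomarker_fields <- function() {
  c("sleep_duration_h", "bedtime_h", "steps_per_day", "longest_walk_s",
    "pct_walk_ge_8s", "pct_walk_ge_60s", "max_speed_cms", "usual_speed_cms",
    "cadence_median_spm", "cadence_iqr_spm", "step_time_variability_ms",
    "step_regularity_pct", "stride_regularity_pct",
    "pct_arm_swing", "pct_texting", "pct_phone_call", "pct_hands_in_pockets",
    "pct_shoulder_bag", "pct_briefcase", "pct_static", "pct_adaptive")
}

# Markers with strongly skewed population distributions are pooled and
# summarized by median/IQR; the classification is fixed (not re-estimated).
skewed_markers <- function() {
  c("longest_walk_s", "pct_walk_ge_60s", "pct_arm_swing", "pct_texting",
    "pct_phone_call", "pct_hands_in_pockets", "pct_shoulder_bag",
    "pct_briefcase", "pct_static", "pct_adaptive")
}

# Markers where lower values mean better performance; their z-scores are
# sign-flipped so that positive always indicates better.
reversed_markers <- function() c("step_time_variability_ms")

#' Daily wear time and inclusion criteria
#'
#' Non-wear is detected per 15-minute epoch: an epoch is non-worn when the
#' per-axis standard deviation over the surrounding 60-minute block is below
#' 13 mg on all three axes.  Wear hours per noon-to-noon day are 24 minus
#' non-wear; missing data count as non-wear.  The strict inclusion criterion
#' requires `weartime_full_days` days with at least 23 wear hours
#' ("complete" days); the relaxed criterion requires
#' `weartime_relaxed_days` days with at least `weartime_relaxed_hours` wear
#' hours.
#'
#' @param recording a multi-day [ww_recording()].
#' @param cfg a [ww_config()].
#' @param sd_threshold_g non-wear movement threshold (0.013 g).
#' @param epoch_s epoch length, seconds (900).
#' @param block_s SD block length, seconds (3600).
#' @param complete_hours wear hours defining a complete day (23).
#' @return List with `days` (`data.frame`: day index, wear_hours,
#'   complete, relaxed) and logical flags `full_criterion`,
#'   `relaxed_criterion`.
#' @export
wear_time <- function(recording, cfg = ww_config(), sd_threshold_g = 0.013,
                      epoch_s = 900, block_s = 3600, complete_hours = 23) {
  t <- recording$time - recording$time[[1]]
  n_days <- max(1L, ceiling((max(t) + 1e-9) / 86400))
  days <- data.frame(day = seq_len(n_days), wear_hours = 0)
  for (d in seq_len(n_days)) {
    d0 <- (d - 1) * 86400
    worn_h <- 0
    for (e in seq_len(86400 / epoch_s)) {
      e0 <- d0 + (e - 1) * epoch_s
      b0 <- e0 + epoch_s / 2 - block_s / 2
      sel <- t >= max(d0, b0) & t < min(d0 + 86400, b0 + block_s)
      if (sum(sel) < 2) next                      # no data: non-wear
      sds <- apply(recording$xyz[sel, , drop = FALSE], 2, stats::sd)
      # epoch must itself contain data to count as worn time
      has <- any(t >= e0 & t < e0 + epoch_s)
      if (has && any(sds >= sd_threshold_g))
        worn_h <- worn_h + epoch_s / 3600
    }
    days$wear_hours[d] <- worn_h
  }
  days$complete <- days$wear_hours >= complete_hours
  days$relaxed <- days$wear_hours >= cfg$weartime_relaxed_hours
  list(days = days,
       full_criterion = sum(days$complete) >= cfg$weartime_full_days,
       relaxed_criterion = sum(days$relaxed) >= cfg$weartime_relaxed_days)
}

#' Assemble the daily biomarker row
#'
#' Combines the outputs of the individual stages into the 21 fields of one
#' subject-day: sleep duration and bedtime, steps per day (detected plus
#' corrective), longest continuous walk, walk-exposure proportions, maximal
#' and usual walking speed (cm/s), cadence median and IQR, step-time
#' variability, step and stride regularity, and the hand-position
#' percentages over walking windows with the two derived groupings
#' `pct_static = pct_texting + pct_phone_call` and
#' `pct_adaptive = pct_hands_in_pockets + pct_shoulder_bag + pct_briefcase`.
#' Fields that cannot be computed (e.g. a day without walking) are `NA`;
#' missingness is data, not an error.
#'
#' @param labels per-window `data.frame` with `start_time`, `stage1`,
#'   `stage2`.
#' @param bouts bout table from [assemble_bouts()].
#' @param steps list from [frame_steps()].
#' @param corrective_rate steps per `unspecified_arms_walking` window
#'   (`NA` skips the correction).
#' @param episode list from [episode_metrics()].
#' @param reg list from [frame_regularity()].
#' @param speeds per-window predicted speeds of the day, m/s.
#' @param sleep list from [estimate_sleep()].
#' @param cfg a [ww_config()].
#' @return One-row `data.frame` with the fields above.
#' @export
summarize_day <- function(labels, bouts, steps, corrective_rate, episode,
                          reg, speeds, sleep, cfg = ww_config()) {
  expo <- walk_exposure_proportions(bouts, cfg)
  sp <- daily_speeds(speeds, cfg)
  n_steps <- length(steps$step_times)
  corr <- if (is.na(corrective_rate)) 0
          else corrective_step_count(labels$stage1, corrective_rate)

  walk_idx <- labels$stage1 %in% walking_levels()
  n_walk <- sum(walk_idx)
  pct_of <- function(cond) if (n_walk == 0) NA_real_ else 100 * sum(cond) / n_walk
  pct_arm <- pct_of(labels$stage1 == "walk_arm_swing")
  pos <- function(lv) pct_of(!is.na(labels$stage2) & labels$stage2 == lv)
  pct_pockets <- pos("hands_in_pockets")
  pct_text <- pos("hands_held_stationary")
  pct_phone <- pos("hand_next_to_ear")
  pct_shoulder <- pos("hand_on_shoulder")
  pct_brief <- pos("briefcase_grocery_bag")

  data.frame(
    sleep_duration_h = sleep$sleep_duration_h,
    bedtime_h = sleep$bedtime_h,
    steps_per_day = n_steps + corr,
    longest_walk_s = if (nrow(bouts)) longest_walk(bouts) else NA_real_,
    pct_walk_ge_8s = expo$pct_ge_short,
    pct_walk_ge_60s = expo$pct_ge_long,
    max_speed_cms = sp$max_speed_ms * 100,
    usual_speed_cms = sp$usual_speed_ms * 100,
    cadence_median_spm = episode$cadence_median_spm,
    cadence_iqr_spm = episode$cadence_iqr_spm,
    step_time_variability_ms = episode$step_time_variability_ms,
    step_regularity_pct = reg$step_regularity_pct,
    stride_regularity_pct = reg$stride_regularity_pct,
    pct_arm_swing = pct_arm,
    pct_texting = pct_text,
    pct_phone_call = pct_phone,
    pct_hands_in_pockets = pct_pockets,
    pct_shoulder_bag = pct_shoulder,
    pct_briefcase = pct_brief,
    pct_static = pct_text + pct_phone,
    pct_adaptive = pct_pockets + pct_shoulder + pct_brief
  )
}

#' Pool a subject's included days into one biomarker row
#'
#' Normally distributed markers are averaged across days; skewed markers
#' (bout durations, hand-position percentages) take the median.  Bedtime is
#' pooled with the circular mean on the 24-hour clock.
#'
#' @param daily `data.frame` of one subject's [summarize_day()] rows.
#' @return One-row `data.frame`.
#' @export
pool_subject_days <- function(daily) {
  out <- daily[1, biomarker_fields(), drop = FALSE]
  for (f in biomarker_fields()) {
    v <- daily[[f]]
    out[[f]] <- if (f == "bedtime_h") circular_mean_hour(v)
    else if (f %in% skewed_markers()) stats::median(v, na.rm = TRUE)
    else mean(v, na.rm = TRUE)
  }
  rownames(out) <- NULL
  out
}

age_group_labels <- function(edges) {
  paste0(utils::head(edges, -1), "-", utils::tail(edges, -1) - 1)
}

#' Sex- and age-stratified normative percentile tables
#'
#' For every biomarker, reports the configured percentiles (default 5, 10,
#' 25, 50, 75, 90, 95) within each sex-by-age-group stratum, from
#' per-subject pooled biomarker values.  Age groups follow
#' `cfg$age_group_edges` (default 45--54, 55--64, 65--74, 75--79, closed on
#' the left); subjects outside the range are excluded.  Empty strata are
#' reported with `n = 0` and missing percentiles.
#'
#' @param subjects `data.frame` with `sex`, `age_years` and one column per
#'   biomarker (one row per subject, e.g. from [pool_subject_days()]).
#' @param cfg a [ww_config()].
#' @param markers biomarker columns to tabulate (default: all present
#'   biomarker fields).
#' @return `data.frame` of class `ww_normative`: biomarker, sex, age_group,
#'   n, and one `p<q>` column per percentile; percentile columns are
#'   non-decreasing left to right within each row.
#' @export
normative_table <- function(subjects, cfg = ww_config(), markers = NULL) {
  markers <- markers %||% intersect(biomarker_fields(), names(subjects))
  edges <- cfg$age_group_edges
  groups <- age_group_labels(edges)
  probs <- cfg$norm_percentiles / 100
  pcols <- paste0("p", cfg$norm_percentiles)
  ag <- cut(subjects$age_years, breaks = edges, right = FALSE,
            labels = groups)
  rows <- list()
  for (m in markers) for (sx in c("female", "male")) for (g in groups) {
    v <- subjects[[m]][!is.na(ag) & ag == g & subjects$sex == sx]
    v <- v[is.finite(v)]
    q <- if (length(v)) ww_quantile(v, probs) else rep(NA_real_,
                                                       length(probs))
    row <- data.frame(biomarker = m, sex = sx, age_group = g,
                      n = length(v), stringsAsFactors = FALSE)
    row[pcols] <- as.list(q)
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ww_normative", "data.frame")
  out
}

#' Standardized biomarker profile
#'
#' z-scores a subject's pooled biomarkers against a reference cohort:
#' `z = (x - mean_ref) / sd_ref`, with the sign flipped for markers where
#' lower is better (step-time variability), so that positive always means
#' better performance.  Markers with zero reference SD are flagged missing.
#'
#' @param subject one-row `data.frame` of pooled biomarkers.
#' @param reference `data.frame` of the reference cohort's pooled biomarkers
#'   (one row per subject).
#' @param markers biomarkers to score (default: all shared fields).
#' @return `data.frame`: biomarker, value, ref_mean, ref_sd, z, reversed.
#' @export
zscore_profile <- function(subject, reference, markers = NULL) {
  markers <- markers %||%
    intersect(intersect(biomarker_fields(), names(subject)),
              names(reference))
  rows <- lapply(markers, function(m) {
    mu <- mean(reference[[m]], na.rm = TRUE)
    sdv <- stats::sd(reference[[m]], na.rm = TRUE)
    rev <- m %in% reversed_markers()
    z <- if (!is.finite(sdv) || sdv == 0) NA_real_
         else (subject[[m]][[1]] - mu) / sdv * (if (rev) -1 else 1)
    data.frame(biomarker = m, value = subject[[m]][[1]], ref_mean = mu,
               ref_sd = sdv, z = z, reversed = rev,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
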