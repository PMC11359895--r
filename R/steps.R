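# Minimum autocorrelation first-peak coefficient for a window to count as
# having a valid gait period.  Real gait sits far above (step regularity is
# typically 0.5-0.7); iid noise at the 4-s window length sits far below
# (sampling SD of the coefficient is about 0.05 at 400 samples).
ac_gait_threshold <- function() 0.3

#' Detect steps in a walking window
#'
#' Steps are candidate peaks of the bandpass-filtered magnitude with minimum
#' spacing 0.25 s (at most 4 steps/s) and prominence at least one quarter of
#' the window RMS, cross-checked against the window's autocorrelation: the
#' window must show an autocorrelation peak (lag 0.25--1.0 s, coefficient
#' >= 0.3) and the median inter-peak interval must agree with that period
#' within +/-20% at the step or the stride lag, otherwise no steps are
#' returned.  Degenerate (constant or aperiodic) windows yield no steps.
#'
#' @param x bandpass-filtered magnitude of one window.
#' @param fs sampling rate, Hz.
#' @param cfg a [ww_config()].
#' @param t0 window start time; detected times are `t0`-relative-absolute.
#' @return Numeric vector of step event times (possibly empty).
#' @export
detect_steps <- function(x, fs, cfg = ww_config(), t0 = 0) {
  n <- length(x)
  rms <- sqrt(mean(x^2))
  if (!is.finite(rms) || rms < 1e-6) return(numeric(0))

  acp <- ac_peaks(x, fs)
  if (acp[[1]] < ac_gait_threshold() || acp[[2]] <= 0) return(numeric(0))
  period <- acp[[2]]

  min_space <- as.integer(round(0.25 * fs))
  cand <- local_maxima(x)
  cand <- cand[x[cand] > 0]
  if (!length(cand)) return(numeric(0))
  # prominence: height above the higher of the two flanking minima between
  # neighbouring candidate peaks
  prom <- vapply(seq_along(cand), function(k) {
    lo <- if (k == 1) 1L else cand[[k - 1L]]
    hi <- if (k == length(cand)) n else cand[[k + 1L]]
    x[cand[[k]]] - max(min(x[lo:cand[[k]]]), min(x[cand[[k]]:hi]))
  }, numeric(1))
  cand <- cand[prom >= 0.25 * rms]
  if (!length(cand)) return(numeric(0))
  # enforce minimum spacing, keeping the taller peak
  keep <- integer(0)
  for (i in cand) {
    if (length(keep) && i - keep[[length(keep)]] < min_space) {
      if (x[i] > x[keep[[length(keep)]]]) keep[[length(keep)]] <- i
    } else keep <- c(keep, i)
  }
  if (length(keep) < 2) return(numeric(0))

  med_iv <- stats::median(diff(keep)) / fs
  # the autocorrelation period may sit at the step or the stride lag
  agrees <- any(abs(med_iv - c(period, period / 2)) <=
                  0.2 * c(period, period / 2))
  if (!agrees) return(numeric(0))
  t0 + (keep - 1L) / fs
}

#' Steps for every walking window of a labelled frame
#'
#' Runs [detect_steps()] on each window whose stage-1 label is a walking
#' class and returns absolute step times.
#'
#' @param frame a `ww_frame`.
#' @param stage1 per-window stage-1 labels.
#' @param cfg a [ww_config()].
#' @return List with `step_times` (sorted numeric vector) and
#'   `per_window` (list of step-time vectors, one per window; empty for
#'   non-walking windows).
#' @export
frame_steps <- function(frame, stage1, cfg = ww_config()) {
  stopifnot(n_windows(frame) == length(stage1))
  per <- vector("list", n_windows(frame))
  for (i in seq_len(n_windows(frame))) {
    per[[i]] <- if (stage1[[i]] %in% walking_levels())
      detect_steps(frame$filt_norm[i, ], frame$fs, cfg,
                   t0 = frame$start_time[[i]])
    else numeric(0)
  }
  list(step_times = sort(unlist(per)), per_window = per)
}

#' Corrective step count for unspecified arm activity while walking
#'
#' Walking with busy or loaded arms transmits little periodicity to the
#' wrist, so step detection misses those windows.  The correction adds
#' `rate x count(unspecified_arms_walking windows)` steps, where `rate` is
#' the mean ground-truth steps per such window estimated at training time
#' and stored in the classifier metadata.
#'
#' @param stage1 per-window stage-1 labels (predicted).
#' @param rate steps per `unspecified_arms_walking` window (>= 0).
#' @return Number of additional steps.
#' @export
corrective_step_count <- function(stage1, rate) {
  if (is.na(rate) || rate < 0)
    stop("corrective step rate must be a non-negative number",
         call. = FALSE)
  rate * sum(stage1 == "unspecified_arms_walking")
}

#' Episode cadence and step-time variability
#'
#' Consecutive steps (splitting where an interval exceeds `max_break_s`) are
#' regrouped into non-overlapping episodes of `episode_steps` steps; the
#' trailing partial episode is discarded.  An 8-step episode spans 7
#' intervals: its cadence is `60 * 7 / (t_8 - t_1)` steps per minute and its
#' step-time SD is the standard deviation of those intervals.  Daily values
#' are the median and IQR of episode cadences and the 95th percentile
#' (`variability_percentile`) of episode SDs.
#'
#' @param step_times sorted step event times, seconds.
#' @param cfg a [ww_config()].
#' @param max_break_s largest interval still treated as consecutive steps.
#' @return List with `episodes` (`data.frame`: start, duration_s,
#'   cadence_spm, step_time_sd_ms), `cadence_median_spm`, `cadence_iqr_spm`,
#'   `step_time_variability_ms`; the scalars are `NA` when no complete
#'   episode exists.
#' @export
episode_metrics <- function(step_times, cfg = ww_config(),
                            max_break_s = 2) {
  k <- cfg$episode_steps
  eps <- data.frame(start = numeric(0), duration_s = numeric(0),
                    cadence_spm = numeric(0), step_time_sd_ms = numeric(0))
  if (length(step_times) >= k) {
    grp <- cumsum(c(0, diff(step_times) > max_break_s))
    for (g in unique(grp)) {
      st <- step_times[grp == g]
      n_ep <- floor(length(st) / k)
      for (e in seq_len(n_ep)) {
        s <- st[((e - 1) * k + 1):(e * k)]
        dur <- s[[k]] - s[[1]]
        if (dur <= 0) next
        eps <- rbind(eps, data.frame(
          start = s[[1]], duration_s = dur,
          cadence_spm = 60 * (k - 1) / dur,
          step_time_sd_ms = stats::sd(diff(s)) * 1000))
      }
    }
  }
  if (!nrow(eps))
    return(list(episodes = eps, cadence_median_spm = NA_real_,
                cadence_iqr_spm = NA_real_,
                step_time_variability_ms = NA_real_))
  list(episodes = eps,
       cadence_median_spm = stats::median(eps$cadence_spm),
       cadence_iqr_spm = stats::IQR(eps$cadence_spm),
       step_time_variability_ms =
         ww_quantile(eps$step_time_sd_ms, cfg$variability_percentile / 100))
}

#' Step and stride regularity of a walking window
#'
#' The unbiased, lag-0-normalized autocorrelation of the filtered magnitude
#' is evaluated at its first dominant peak (step period, searched in
#' 0.25--1.0 s) and at the second peak near twice that lag (+/-25%, stride
#' period).  Both coefficients lie between -1 and 1; 1 means perfectly repeatable
#' gait.  Windows without an autocorrelation peak of at least 0.3 are
#' flagged missing.  Regularity is invariant to amplitude scaling.
#'
#' @param x bandpass-filtered magnitude of one walking window.
#' @param fs sampling rate, Hz.
#' @return List with `step_regularity` and `stride_regularity` (either may
#'   be `NA` when no peak is found).
#' @export
regularity <- function(x, fs) {
  acp <- ac_peaks(x, fs)
  if (acp[[1]] < ac_gait_threshold() || acp[[2]] <= 0)
    return(list(step_regularity = NA_real_, stride_regularity = NA_real_))
  clamp <- function(v) max(-1, min(1, v))
  list(step_regularity = clamp(acp[[1]]),
       stride_regularity = if (acp[[3]] == 0) NA_real_ else clamp(acp[[3]]))
}

#' Daily regularity aggregated over walking windows
#'
#' @param frame a `ww_frame`.
#' @param stage1 per-window stage-1 labels.
#' @param aggregate aggregation policy over windows (`"mean"`, the default,
#'   or `"median"`).
#' @return List with `step_regularity_pct` and `stride_regularity_pct`
#'   (percent; `NA` when no walking window has a detectable period).
#' @export
frame_regularity <- function(frame, stage1, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "mean") function(v) mean(v, na.rm = TRUE)
         else function(v) stats::median(v, na.rm = TRUE)
  idx <- which(stage1 %in% walking_levels())
  if (!length(idx))
    return(list(step_regularity_pct = NA_real_,
                stride_regularity_pct = NA_real_))
  vals <- vapply(idx, function(i) {
    r <- regularity(frame$filt_norm[i, ], frame$fs)
    c(r$step_regularity, r$stride_regularity)
  }, numeric(2))
  stepv <- vals[1, ]; stridev <- vals[2, ]
  list(
    step_regularity_pct = if (all(is.na(stepv))) NA_real_
                          else 100 * agg(stepv),
    stride_regularity_pct = if (all(is.na(stridev))) NA_real_
                            else 100 * agg(stridev))
}
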