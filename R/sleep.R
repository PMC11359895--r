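#' Estimate the sleep period of one (noon-to-noon) day
#'
#' A simplified arm-angle heuristic: the wrist elevation angle
#' `atan(z / sqrt(x^2 + y^2))` is computed on 5-second rolling medians of the
#' raw axes; epochs whose successive angle change stays below 5 degrees for
#' at least 5 minutes form sustained-inactivity runs; runs separated by less
#' than 60 minutes are chained into candidate sleep blocks, and the longest
#' block is the sleep period.  Sleep duration is the block span and bedtime
#' its onset clock time.  This intentionally omits diary anchoring and
#' multi-block nights; one block is reported per noon-to-noon day.
#'
#' @param recording a [ww_recording()] day slice (>= 12 h of data).
#' @param cfg a [ww_config()].
#' @param epoch_s angle epoch length, seconds (5).
#' @param angle_deg maximum successive-epoch angle change, degrees (5).
#' @param min_run_s minimum sustained-inactivity run, seconds (300).
#' @param merge_gap_s maximum gap chained into one block, seconds (3600).
#' @return List with `sleep_duration_h`, `bedtime_h` (clock hour of day,
#'   fractional), `blocks` (`data.frame` of inactivity runs, onset/offset in
#'   recording seconds) and `missing` (logical).  Duration and bedtime are
#'   `NA` when no sustained inactivity is found or data are insufficient.
#' @export
estimate_sleep <- function(recording, cfg = ww_config(), epoch_s = 5,
                           angle_deg = 5, min_run_s = 300,
                           merge_gap_s = 3600) {
  miss <- list(sleep_duration_h = NA_real_, bedtime_h = NA_real_,
               blocks = data.frame(onset = numeric(0), offset = numeric(0)),
               missing = TRUE)
  span <- diff(range(recording$time))
  if (span < 12 * 3600) return(miss)
  fs <- recording$sampling_rate
  per <- as.integer(round(epoch_s * fs))
  n_ep <- floor(length(recording$time) / per)
  if (n_ep < 3) return(miss)
  ep_idx <- rep(seq_len(n_ep), each = per)
  med <- function(v) {
    v <- v[seq_len(n_ep * per)]
    as.numeric(tapply(v, ep_idx, stats::median))
  }
  mx <- med(recording$xyz[, 1]); my <- med(recording$xyz[, 2])
  mz <- med(recording$xyz[, 3])
  angle <- atan2(mz, sqrt(mx^2 + my^2)) * 180 / pi
  calm <- c(FALSE, abs(diff(angle)) < angle_deg)

  r <- rle(calm)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths * epoch_s >= min_run_s
  if (!any(keep)) return(miss)
  ep_time <- function(e) recording$time[[1]] + (e - 1L) * epoch_s
  runs <- data.frame(onset = ep_time(starts[keep]),
                     offset = ep_time(ends[keep] + 1L))

  # chain runs separated by < merge_gap_s into candidate blocks
  block <- cumsum(c(0, runs$onset[-1] - runs$offset[-nrow(runs)] >=
                      merge_gap_s))
  spans <- do.call(rbind, lapply(unique(block), function(b) {
    rr <- runs[block == b, , drop = FALSE]
    data.frame(onset = min(rr$onset), offset = max(rr$offset))
  }))
  main <- spans[which.max(spans$offset - spans$onset), ]
  list(sleep_duration_h = (main$offset - main$onset) / 3600,
       bedtime_h = ((recording$start_clock_s + main$onset -
                       recording$time[[1]]) %% 86400) / 3600,
       blocks = runs, missing = FALSE)
}

#' Circular mean of bedtimes
#'
#' Bedtimes straddle midnight, so averaging across days uses the circular
#' mean on the 24-hour clock.
#'
#' @param hours clock hours in [0, 24).
#' @return Circular mean hour in [0, 24), `NA` if no finite input.
#' @export
circular_mean_hour <- function(hours) {
  hours <- hours[is.finite(hours)]
  if (!length(hours)) return(NA_real_)
  th <- hours / 24 * 2 * pi
  m <- atan2(mean(sin(th)), mean(cos(th)))
  h <- (m / (2 * pi) * 24) %% 24
  if (h >= 24 - 1e-9) 0 else h
}
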