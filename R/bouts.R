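#' Assemble walking bouts with gap bridging
#'
#' A window counts as walking when its stage-1 label is `walk_arm_swing` or
#' `other_complex_walking`.  Maximal runs of consecutive walking windows form
#' candidate bouts; a pause between two runs is bridged when all three
#' criteria hold: (1) the gap does not exceed 60 s (`bridge_max_gap_s`),
#' (2) the gap does not exceed either neighbouring run's duration, and
#' (3) the gap does not exceed one fifth (`bridge_fraction`) of at least one
#' neighbouring run's duration.  Bridging is applied iteratively left to
#' right, re-evaluating after every merge, until no gap qualifies; merged
#' runs thereby legitimately enable further merges.
#'
#' @param labels `data.frame` with per-window `start_time` (seconds) and
#'   `stage1` label, time-ordered, or the output of [predict_activity()]
#'   plus a `start_time` column.
#' @param cfg a [ww_config()].
#' @param window_s window duration (defaults to `cfg$window_s`).
#' @return `data.frame` of bouts: `start_time`, `end_time`, `duration_s`,
#'   `n_windows` (walking windows), `n_bridged_gaps`, `bridged_s` (total
#'   bridged pause time).  Zero rows when nothing was walked.
#' @export
assemble_bouts <- function(labels, cfg = ww_config(),
                           window_s = cfg$window_s) {
  stopifnot(is.data.frame(labels), all(c("start_time", "stage1") %in%
                                         names(labels)))
  if (is.unsorted(labels$start_time, strictly = FALSE))
    stop("labels must be time-ordered", call. = FALSE)
  empty <- data.frame(start_time = numeric(0), end_time = numeric(0),
                      duration_s = numeric(0), n_windows = integer(0),
                      n_bridged_gaps = integer(0), bridged_s = numeric(0))
  if (!nrow(labels)) return(empty)

  walk <- labels$stage1 %in% walking_levels()
  if (!any(walk)) return(empty)
  r <- rle(walk)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  wi <- which(r$values)
  runs <- data.frame(
    start = labels$start_time[starts_i[wi]],
    end = labels$start_time[ends_i[wi]] + window_s,
    n_windows = r$lengths[wi],
    n_bridged = 0L, bridged_s = 0
  )

  repeat {
    merged <- FALSE
    i <- 1L
    while (i < nrow(runs)) {
      gap <- runs$start[i + 1L] - runs$end[i]
      d1 <- runs$end[i] - runs$start[i]
      d2 <- runs$end[i + 1L] - runs$start[i + 1L]
      ok <- gap <= cfg$bridge_max_gap_s &&
        gap <= min(d1, d2) &&
        gap <= cfg$bridge_fraction * max(d1, d2)
      if (ok) {
        runs$end[i] <- runs$end[i + 1L]
        runs$n_windows[i] <- runs$n_windows[i] + runs$n_windows[i + 1L]
        runs$n_bridged[i] <- runs$n_bridged[i] + runs$n_bridged[i + 1L] + 1L
        runs$bridged_s[i] <- runs$bridged_s[i] + runs$bridged_s[i + 1L] + gap
        runs <- runs[-(i + 1L), , drop = FALSE]
        merged <- TRUE
      } else {
        i <- i + 1L
      }
    }
    if (!merged) break
  }
  data.frame(start_time = runs$start, end_time = runs$end,
             duration_s = runs$end - runs$start,
             n_windows = runs$n_windows,
             n_bridged_gaps = runs$n_bridged, bridged_s = runs$bridged_s)
}

#' Longest continuous walk duration
#'
#' @param bouts bout table from [assemble_bouts()].
#' @return Longest bout duration in seconds; 0 when there are no bouts.
#' @export
longest_walk <- function(bouts) {
  if (!nrow(bouts)) return(0)
  max(bouts$duration_s)
}

#' Cumulative-exposure proportions of walking time
#'
#' The share of total walking time contributed by bouts of at least 8 s and
#' at least 60 s (thresholds from the configuration).
#'
#' @param bouts bout table from [assemble_bouts()].
#' @param cfg a [ww_config()].
#' @return List with `pct_ge_short` and `pct_ge_long` (percent); both `NA`
#'   when there is no walking time (the marker is missing, not zero).
#' @export
walk_exposure_proportions <- function(bouts, cfg = ww_config()) {
  tot <- sum(bouts$duration_s)
  if (!nrow(bouts) || tot <= 0)
    return(list(pct_ge_short = NA_real_, pct_ge_long = NA_real_))
  list(
    pct_ge_short = 100 *
      sum(bouts$duration_s[bouts$duration_s >= cfg$walk_threshold_short_s]) /
      tot,
    pct_ge_long = 100 *
      sum(bouts$duration_s[bouts$duration_s >= cfg$walk_threshold_long_s]) /
      tot
  )
}
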