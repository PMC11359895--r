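#' Activity taxonomy
#'
#' Stage-1 labels partition every 4-second window into six activities; windows
#' labelled `other_complex_walking` are refined by the stage-2 hand-position
#' labels.  Windows whose stage-1 label is `walk_arm_swing` or
#' `other_complex_walking` count as walking for bout assembly and step
#' detection.
#'
#' @return Character vector of class labels, in canonical order.
#' @export
stage1_levels <- function() {
  c("walk_arm_swing", "other_complex_walking", "running", "stationary",
    "unspecified_arms_sit_stand", "unspecified_arms_walking")
}

#' @rdname stage1_levels
#' @export
stage2_levels <- function() {
  c("hands_in_pockets", "hands_held_stationary", "hand_next_to_ear",
    "hand_on_shoulder", "briefcase_grocery_bag")
}

#' @rdname stage1_levels
#' @export
walking_levels <- function() c("walk_arm_swing", "other_complex_walking")

# Shared quantile rule: linear interpolation between order statistics
# (stats::quantile type 7).  Used everywhere a percentile appears so that
# episode variability, daily speeds and normative tables are mutually
# consistent.
ww_quantile <- function(x, probs) {
  stats::quantile(x, probs = probs, na.rm = TRUE, names = FALSE, type = 7)
}

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards.  Keeps pipeline determinism independent of the
# session RNG.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Unbiased, lag-0-normalized autocorrelation of a demeaned signal:
#   r(k) = [ sum_t x_t x_{t+k} / (n - k) ] / [ sum_t x_t^2 / n ]
# Returns r for lags 0..max_lag.  For a perfectly periodic signal r at the
# period is 1 regardless of how many periods fit the window, which is why the
# unbiased form is used for step/stride regularity.
acf_unbiased <- function(x, max_lag = length(x) - 1L) {
  n <- length(x)
  x <- x - mean(x)
  denom <- sum(x^2) / n
  if (denom <= .Machine$double.eps)
    return(rep(NA_real_, max_lag + 1L))
  max_lag <- min(max_lag, n - 1L)
  # full autocovariance via FFT, then unbiased scaling
  m <- stats::nextn(2L * n, 2L)
  f <- stats::fft(c(x, rep(0, m - n)))
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(max_lag + 1L)] / m
  (ac / (n - 0:max_lag)) / denom
}

# Indices of strict local maxima of r (interior points).
local_maxima <- function(r) {
  n <- length(r)
  if (n < 3) return(integer(0))
  which(r[2:(n - 1)] > r[1:(n - 2)] & r[2:(n - 1)] >= r[3:n]) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
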