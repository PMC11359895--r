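#' Names of the 54 window features
#'
#' The feature set is fixed and versioned: the classifier's RBF kernel
#' coefficient (1/54) and every persisted model depend on this exact ordering.
#' Features are computed per non-overlapping window from the bandpass-filtered
#' magnitude (time-domain statistics, spectral shape, band powers,
#' autocorrelation peaks), the raw per-axis signals, the filtered per-axis
#' signals (correlations, RMS, zero crossings), the jerk of the filtered
#' magnitude, the raw magnitude and the static-removed magnitude.
#'
#' @return Character vector of length 54.
#' @export
feature_names <- function() {
  c(
    # bandpass-filtered magnitude: time domain
    "fn_mean", "fn_sd", "fn_median", "fn_iqr", "fn_min", "fn_max", "fn_rms",
    "fn_skewness", "fn_kurtosis", "fn_sma", "fn_zero_crossings",
    # bandpass-filtered magnitude: frequency domain
    "fn_dom_freq_hz", "fn_dom_freq_power_frac", "fn_spectral_entropy",
    "fn_bandpower_0.25_0.75", "fn_bandpower_0.75_1.25",
    "fn_bandpower_1.25_1.75", "fn_bandpower_1.75_2.5",
    # bandpass-filtered magnitude: autocorrelation and extra order statistics
    "fn_ac_peak1_value", "fn_ac_peak1_lag_s", "fn_ac_peak2_value",
    "fn_p5", "fn_p25", "fn_p75", "fn_p95", "fn_mad",
    # raw axes
    "x_mean", "y_mean", "z_mean", "x_sd", "y_sd", "z_sd",
    "x_range", "y_range", "z_range",
    # bandpass-filtered axes
    "corr_xy", "corr_xz", "corr_yz",
    "fx_rms", "fy_rms", "fz_rms",
    "fx_zero_crossings", "fy_zero_crossings", "fz_zero_crossings",
    # jerk of the filtered magnitude
    "jerk_mean_abs", "jerk_sd",
    # raw magnitude
    "rn_mean", "rn_sd", "rn_min", "rn_max",
    # static-removed magnitude (ENMO-style)
    "srm_mean", "srm_median", "srm_iqr", "srm_max"
  )
}

#' Static-removed acceleration magnitude
#'
#' The gravity-subtracted magnitude `max(norm - 1 g, 0)` (ENMO-style),
#' approximating the dynamic component of the acceleration.  Its median and
#' interquartile range are two of the eight walking-speed predictors.
#'
#' @param raw_norm raw (unfiltered) magnitude stream in g.
#' @return Non-negative stream, same length.
#' @export
static_removed_magnitude <- function(raw_norm) {
  if (any(!is.finite(raw_norm)))
    stop("non-finite magnitude sample", call. = FALSE)
  pmax(raw_norm - 1, 0)
}

zero_crossings <- function(x) {
  s <- sign(x - mean(x))
  s <- s[s != 0]
  if (length(s) < 2) return(0)
  sum(diff(s) != 0)
}

safe_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

# One-sided periodogram power split by frequency band, total-normalized
# spectral entropy and dominant frequency.  DC is excluded throughout.
spectral_summary <- function(x, fs, bands) {
  n <- length(x)
  p <- Mod(stats::fft(x - mean(x)))^2 / n
  half <- 2:floor(n / 2 + 1)          # positive frequencies, no DC
  freq <- (half - 1) * fs / n
  p <- p[half]
  tot <- sum(p)
  if (tot <= .Machine$double.eps) {
    return(list(dom_freq = 0, dom_frac = 0, entropy = 0,
                bandpower = rep(0, nrow(bands))))
  }
  i <- which.max(p)
  pr <- p / tot
  ent <- -sum(pr[pr > 0] * log(pr[pr > 0])) / log(length(pr))
  bp <- apply(bands, 1, function(b) sum(p[freq >= b[[1]] & freq < b[[2]]]))
  list(dom_freq = freq[[i]], dom_frac = p[[i]] / tot, entropy = ent,
       bandpower = bp)
}

# Autocorrelation first peak (lag searched in 0.25-1.0 s, the plausible step
# period band) and the value at twice that lag's neighbourhood.
ac_peaks <- function(x, fs) {
  max_lag <- min(length(x) - 1L, as.integer(2.2 * fs))
  r <- acf_unbiased(x, max_lag)
  if (any(is.na(r))) return(c(0, 0, 0))
  lo <- max(2L, as.integer(round(0.25 * fs)))
  hi <- min(max_lag, as.integer(round(1.0 * fs)))
  if (hi <= lo) return(c(0, 0, 0))
  cand <- local_maxima(r[1:(hi + 1L)])   # indices into r (lag = idx - 1)
  cand <- cand[cand - 1L >= lo]
  if (!length(cand)) return(c(0, 0, 0))
  pk <- cand[which.max(r[cand])]
  lag1 <- pk - 1L
  # second peak near twice the first lag (+-25%)
  lo2 <- as.integer(round(2 * lag1 * 0.75)); hi2 <- min(max_lag,
                                                as.integer(round(2 * lag1 * 1.25)))
  v2 <- 0
  if (hi2 > lo2 + 1L) {
    cand2 <- local_maxima(r[(lo2 + 1L):(hi2 + 1L)])
    if (length(cand2)) v2 <- max(r[(lo2 + 1L):(hi2 + 1L)][cand2])
  }
  c(r[pk], lag1 / fs, v2)
}

window_features <- function(rx, ry, rz, fx, fy, fz, rn, fn, fs, cfg) {
  q <- function(p) ww_quantile(fn, p / 100)
  spec <- spectral_summary(fn, fs, bands = rbind(
    c(cfg$filter_low_hz, 0.75), c(0.75, 1.25), c(1.25, 1.75),
    c(1.75, cfg$filter_high_hz)))
  acp <- ac_peaks(fn, fs)
  jerk <- diff(fn) * fs
  srm <- static_removed_magnitude(rn)
  sd0 <- stats::sd(fn)
  vals <- c(
    mean(fn), sd0, stats::median(fn), stats::IQR(fn), min(fn), max(fn),
    sqrt(mean(fn^2)),
    if (sd0 > 0) e1071::skewness(fn) else 0,
    if (sd0 > 0) e1071::kurtosis(fn) else 0,
    mean(abs(fn)), zero_crossings(fn),
    spec$dom_freq, spec$dom_frac, spec$entropy, spec$bandpower,
    acp[[1]], acp[[2]], acp[[3]],
    q(5), q(25), q(75), q(95), stats::mad(fn),
    mean(rx), mean(ry), mean(rz), stats::sd(rx), stats::sd(ry), stats::sd(rz),
    diff(range(rx)), diff(range(ry)), diff(range(rz)),
    safe_cor(fx, fy), safe_cor(fx, fz), safe_cor(fy, fz),
    sqrt(mean(fx^2)), sqrt(mean(fy^2)), sqrt(mean(fz^2)),
    zero_crossings(fx), zero_crossings(fy), zero_crossings(fz),
    mean(abs(jerk)), stats::sd(jerk),
    mean(rn), stats::sd(rn), min(rn), max(rn),
    mean(srm), stats::median(srm), stats::IQR(srm), max(srm)
  )
  vals[!is.finite(vals)] <- 0
  vals
}

#' Extract the 54-dimensional feature matrix of a window frame
#'
#' @param frame a `ww_frame` from [segment_windows()].
#' @param cfg a [ww_config()].
#' @return Numeric matrix, one row per window, 54 named columns in the fixed
#'   order of [feature_names()].  All entries are finite; dispersion-type
#'   features are exactly 0 on constant input.
#' @export
extract_features <- function(frame, cfg = ww_config()) {
  stopifnot(inherits(frame, "ww_frame"))
  nms <- feature_names()
  n <- n_windows(frame)
  out <- matrix(0, nrow = n, ncol = length(nms),
                dimnames = list(NULL, nms))
  w <- as.integer(round(cfg$window_s * frame$fs))
  if (n > 0 && ncol(frame$raw_norm) != w)
    stop("window sample count (", ncol(frame$raw_norm),
         ") does not match config (", w, ")", call. = FALSE)
  for (i in seq_len(n)) {
    out[i, ] <- window_features(
      frame$raw_x[i, ], frame$raw_y[i, ], frame$raw_z[i, ],
      frame$filt_x[i, ], frame$filt_y[i, ], frame$filt_z[i, ],
      frame$raw_norm[i, ], frame$filt_norm[i, ], frame$fs, cfg)
  }
  stopifnot(length(nms) == cfg$n_features)
  out
}
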