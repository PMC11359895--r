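#' Subject metadata
#'
#' @param id opaque subject identifier.
#' @param sex `"female"` or `"male"`.
#' @param height_cm body height in centimetres, in (100, 230).
#' @param age_years age in years, >= 0.
#' @return An object of class `ww_subject`.
#' @export
subject_meta <- function(id, sex, height_cm, age_years) {
  sex <- match.arg(sex, c("female", "male"))
  if (!is.numeric(height_cm) || height_cm <= 100 || height_cm >= 230)
    stop("height_cm must lie in (100, 230)", call. = FALSE)
  if (!is.numeric(age_years) || age_years < 0)
    stop("age_years must be >= 0", call. = FALSE)
  structure(list(id = as.character(id), sex = sex,
                 height_cm = as.numeric(height_cm),
                 age_years = as.numeric(age_years)),
            class = "ww_subject")
}

#' Construct a raw tri-axial recording
#'
#' @param time numeric vector, seconds since recording start, strictly
#'   increasing and nominally uniform.
#' @param xyz numeric matrix with columns x, y, z in gravitational units (g).
#' @param sampling_rate sampling frequency in Hz.
#' @param subject optional [subject_meta()] object.
#' @param start_clock_s clock time of the first sample, seconds after
#'   midnight.  Used for noon-to-noon day slicing and bedtime reporting;
#'   defaults to noon.
#' @return An object of class `ww_recording`.
#' @export
ww_recording <- function(time, xyz, sampling_rate, subject = NULL,
                         start_clock_s = 12 * 3600) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3) stop("xyz must have 3 columns", call. = FALSE)
  if (length(time) != nrow(xyz))
    stop("time and xyz lengths differ", call. = FALSE)
  if (length(time) > 1 && any(diff(time) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  colnames(xyz) <- c("x", "y", "z")
  structure(list(time = as.numeric(time), xyz = xyz,
                 sampling_rate = sampling_rate, subject = subject,
                 start_clock_s = start_clock_s),
            class = "ww_recording")
}

#' @export
print.ww_recording <- function(x, ...) {
  cat(sprintf("<ww_recording> %d samples @ %g Hz (%.1f s)%s\n",
              length(x$time), x$sampling_rate,
              diff(range(x$time)),
              if (!is.null(x$subject)) paste0(", subject ", x$subject$id)
              else ""))
  invisible(x)
}

#' Per-sample Euclidean norm of the tri-axial acceleration
#'
#' @param x a `ww_recording` or a 3-column numeric matrix in g.
#' @return Numeric vector of acceleration magnitudes in g, same length as the
#'   input.
#' @export
euclidean_norm <- function(x) {
  xyz <- if (inherits(x, "ww_recording")) x$xyz else as.matrix(x)
  if (ncol(xyz) != 3) stop("expected 3 axes", call. = FALSE)
  bad <- which(!is.finite(rowSums(xyz)))
  if (length(bad))
    stop("non-finite acceleration at sample index ", bad[[1]], call. = FALSE)
  sqrt(rowSums(xyz^2))
}

# Design the bandpass as a cascade of two Butterworth half-filters
# (`filter_order`-th order high-pass at the low cutoff, same-order low-pass at
# the high cutoff).  The factored form keeps all pole moduli well inside the
# unit circle at 100 Hz, where the equivalent single transfer-function
# bandpass polynomial is numerically fragile.
design_bandpass <- function(cfg) {
  ny <- cfg$sampling_rate_hz / 2
  list(hp = signal::butter(cfg$filter_order, cfg$filter_low_hz / ny,
                           type = "high"),
       lp = signal::butter(cfg$filter_order, cfg$filter_high_hz / ny,
                           type = "low"))
}

#' Zero-phase Butterworth bandpass
#'
#' Applies the pipeline bandpass (default 0.25--2.5 Hz) to a signal, removing
#' the gravitational DC component and high-frequency content while preserving
#' the 0.5--2.5 Hz band in which step and arm-swing dynamics live.  Filtering
#' is zero-phase (forward--backward), so step-event timing downstream is not
#' shifted.
#'
#' @param x numeric signal (typically the magnitude stream from
#'   [euclidean_norm()], or one raw axis).
#' @param cfg a [ww_config()].
#' @return Filtered signal, same length as `x`.
#' @export
bandpass <- function(x, cfg = ww_config()) {
  if (length(x) <= 3 * (2 * cfg$filter_order + 1))
    stop("signal too short to filter (", length(x), " samples)",
         call. = FALSE)
  d <- design_bandpass(cfg)
  signal::filtfilt(d$lp, signal::filtfilt(d$hp, x))
}

# Analytic squared magnitude response of the zero-phase cascade; the closed
# form against which the implementation is validated.
bandpass_response <- function(f, cfg = ww_config()) {
  n <- cfg$filter_order
  hp <- (f / cfg$filter_low_hz)^n / sqrt(1 + (f / cfg$filter_low_hz)^(2 * n))
  lp <- 1 / sqrt(1 + (f / cfg$filter_high_hz)^(2 * n))
  (hp * lp)^2
}

# Split sample indices into contiguous segments at timestamp gaps larger than
# `tol` sampling intervals; windows never span a recording break.
recording_segments <- function(time, fs, tol = 1.5) {
  if (length(time) < 2) return(list(seq_along(time)))
  brk <- which(diff(time) > tol / fs)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, length(time))
  Map(seq.int, starts, ends)
}

#' Segment a recording into non-overlapping 4-second windows
#'
#' Computes the Euclidean norm, bandpass filters the norm and each axis, and
#' cuts the streams into non-overlapping windows of `cfg$window_s` seconds.
#' Trailing samples that do not fill a window are discarded; timestamp gaps
#' longer than 1.5 sampling intervals act as recording breaks that windows
#' never span.
#'
#' @param recording a [ww_recording()].
#' @param cfg a [ww_config()].
#' @param labels optional per-sample stage-1 labels (e.g. simulator ground
#'   truth); each window is then tagged with its majority label.
#' @return An object of class `ww_frame` with elements `start_time` (numeric,
#'   per window), matrices `raw_norm`, `filt_norm`, raw and filtered per-axis
#'   matrices (windows in rows), `fs`, `window_s`, `subject`,
#'   `start_clock_s`, and optionally `label`.
#' @export
segment_windows <- function(recording, cfg = ww_config(), labels = NULL) {
  fs <- cfg$sampling_rate_hz
  w <- as.integer(round(cfg$window_s * fs))
  segs <- recording_segments(recording$time, fs)
  norm <- euclidean_norm(recording)

  idx_list <- list()
  for (seg in segs) {
    nwin <- floor(length(seg) / w)
    if (nwin < 1) next
    for (k in seq_len(nwin))
      idx_list[[length(idx_list) + 1L]] <- seg[((k - 1L) * w + 1L):(k * w)]
  }
  n <- length(idx_list)
  empty <- function() matrix(numeric(0), nrow = 0, ncol = w)
  frame <- list(start_time = numeric(n), first_sample = integer(n),
                raw_norm = empty(), filt_norm = empty(),
                raw_x = empty(), raw_y = empty(), raw_z = empty(),
                filt_x = empty(), filt_y = empty(), filt_z = empty(),
                fs = fs, window_s = cfg$window_s,
                subject = recording$subject,
                start_clock_s = recording$start_clock_s,
                label = NULL)
  class(frame) <- "ww_frame"
  if (n == 0) {
    warning("recording shorter than one window; empty frame", call. = FALSE)
    return(frame)
  }

  take <- function(v) t(vapply(idx_list, function(i) v[i], numeric(w)))
  # filter per contiguous segment so breaks do not leak through filtfilt
  filt_of <- function(v) {
    out <- rep(NA_real_, length(v))
    for (seg in segs) {
      if (diff(range(v[seg])) < .Machine$double.eps)
        out[seg] <- 0          # a DC-only segment has zero in-band content
      else if (length(seg) > 3 * (2 * cfg$filter_order + 1))
        out[seg] <- bandpass(v[seg], cfg)
      else out[seg] <- v[seg] - mean(v[seg])
    }
    out
  }
  fn <- filt_of(norm)
  fx <- filt_of(recording$xyz[, 1]); fy <- filt_of(recording$xyz[, 2])
  fz <- filt_of(recording$xyz[, 3])

  frame$start_time <- vapply(idx_list, function(i) recording$time[i[[1]]],
                             numeric(1))
  frame$first_sample <- vapply(idx_list, function(i) i[[1]], integer(1))
  frame$raw_norm <- take(norm)
  frame$filt_norm <- take(fn)
  frame$raw_x <- take(recording$xyz[, 1])
  frame$raw_y <- take(recording$xyz[, 2])
  frame$raw_z <- take(recording$xyz[, 3])
  frame$filt_x <- take(fx); frame$filt_y <- take(fy); frame$filt_z <- take(fz)

  if (!is.null(labels)) {
    if (length(labels) != length(recording$time))
      stop("labels must be per-sample", call. = FALSE)
    frame$label <- vapply(idx_list, function(i) {
      tb <- table(labels[i])
      names(tb)[which.max(tb)]
    }, character(1))
  }
  frame
}

#' @export
print.ww_frame <- function(x, ...) {
  cat(sprintf("<ww_frame> %d windows of %g s @ %g Hz%s\n",
              length(x$start_time), x$window_s, x$fs,
              if (!is.null(x$label)) " (labelled)" else ""))
  invisible(x)
}

n_windows <- function(frame) length(frame$start_time)
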