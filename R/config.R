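#' Pipeline configuration
#'
#' Builds the single parameter surface shared by every stage of the pipeline.
#' Defaults reproduce the published processing chain: 100 Hz sampling, a
#' 5th-order 0.25--2.5 Hz Butterworth bandpass on the acceleration magnitude,
#' non-overlapping 4-second windows, a 54-dimensional feature vector with RBF
#' kernel coefficient gamma = 1/54, stage-1 class weights 50, 25, 10, 5, 5, 5,
#' gap bridging up to 60 s, 8-step episodes, and 95th-percentile rules for
#' step-time variability and maximal walking speed.
#'
#' @param ... named overrides of individual fields; unknown names are an error.
#'
#' @return An object of class `ww_config`: a validated named list.
#'
#' @details Fields and defaults:
#' \describe{
#'   \item{sampling_rate_hz}{nominal sampling frequency, Hz (100)}
#'   \item{filter_order}{Butterworth order per edge (5)}
#'   \item{filter_low_hz, filter_high_hz}{bandpass cutoffs, Hz (0.25, 2.5)}
#'   \item{window_s}{window length, seconds (4)}
#'   \item{n_features}{feature-vector dimensionality (fixed at 54)}
#'   \item{svm_gamma}{RBF kernel coefficient (1/54)}
#'   \item{stage1_class_weights}{six per-class weights (50, 25, 10, 5, 5, 5)}
#'   \item{bridge_max_gap_s}{largest bridgeable pause, seconds (60)}
#'   \item{bridge_fraction}{gap must not exceed this fraction of a
#'     neighbouring run (1/5)}
#'   \item{episode_steps}{steps per cadence episode (8)}
#'   \item{variability_percentile}{daily step-time variability percentile (95)}
#'   \item{speed_max_percentile}{maximal-speed percentile (95)}
#'   \item{walk_threshold_short_s, walk_threshold_long_s}{bout-exposure
#'     thresholds, seconds (8, 60)}
#'   \item{weartime_full_days}{complete days required by the strict
#'     inclusion criterion (5)}
#'   \item{weartime_relaxed_days, weartime_relaxed_hours}{days and wear hours
#'     for the relaxed criterion (3 days of 12 h)}
#'   \item{norm_percentiles}{percentiles of the normative tables
#'     (5, 10, 25, 50, 75, 90, 95)}
#'   \item{age_group_edges}{age-group boundaries, years (45, 55, 65, 75, 80)}
#' }
#'
#' @examples
#' cfg <- ww_config()
#' cfg$svm_gamma * cfg$n_features  # 1
#' ww_config(window_s = 2)$window_s
#' @export
ww_config <- function(...) {
  cfg <- list(
    sampling_rate_hz       = 100,
    filter_order           = 5L,
    filter_low_hz          = 0.25,
    filter_high_hz         = 2.5,
    window_s               = 4,
    n_features             = 54L,
    svm_gamma              = 1 / 54,
    stage1_class_weights   = c(50, 25, 10, 5, 5, 5),
    bridge_max_gap_s       = 60,
    bridge_fraction        = 1 / 5,
    episode_steps          = 8L,
    variability_percentile = 95,
    speed_max_percentile   = 95,
    walk_threshold_short_s = 8,
    walk_threshold_long_s  = 60,
    weartime_full_days     = 5L,
    weartime_relaxed_days  = 3L,
    weartime_relaxed_hours = 12,
    norm_percentiles       = c(5, 10, 25, 50, 75, 90, 95),
    age_group_edges        = c(45, 55, 65, 75, 80)
  )
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("configuration overrides must be named", call. = FALSE)
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
      stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    int_fields <- c("filter_order", "n_features", "episode_steps",
                    "weartime_full_days", "weartime_relaxed_days")
    for (nm in names(over)) {
      v <- over[[nm]]
      if (!is.numeric(v)) stop("field '", nm, "' must be numeric", call. = FALSE)
      if (nm %in% int_fields) v <- as.integer(v)
      cfg[[nm]] <- v
    }
  }
  class(cfg) <- "ww_config"
  validate_config(cfg)
  cfg
}

#' @export
print.ww_config <- function(x, ...) {
  cat("<ww_config>\n")
  for (nm in names(x))
    cat(sprintf("  %-24s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  invisible(x)
}

validate_config <- function(cfg) {
  fail <- function(field, why)
    stop("invalid configuration field '", field, "': ", why, call. = FALSE)
  scalars <- setdiff(names(cfg),
                     c("stage1_class_weights", "norm_percentiles",
                       "age_group_edges"))
  for (nm in scalars)
    if (length(cfg[[nm]]) != 1 || !is.finite(cfg[[nm]]))
      fail(nm, "must be a single finite number")
  if (cfg$sampling_rate_hz <= 0) fail("sampling_rate_hz", "must be positive")
  if (!(cfg$filter_low_hz < cfg$filter_high_hz))
    fail("filter_low_hz", "low cutoff must be below high cutoff")
  if (!(cfg$filter_high_hz < cfg$sampling_rate_hz / 2))
    fail("filter_high_hz", "high cutoff must be below the Nyquist frequency")
  if (cfg$filter_order < 1) fail("filter_order", "must be >= 1")
  if (cfg$window_s <= 0) fail("window_s", "must be positive")
  if (cfg$n_features != 54L)
    fail("n_features", "the feature set is fixed at 54 dimensions")
  if (abs(cfg$svm_gamma - 1 / cfg$n_features) > 1e-12)
    fail("svm_gamma", "must equal 1/n_features")
  w <- cfg$stage1_class_weights
  if (length(w) != 6 || any(!is.finite(w)) || any(w <= 0))
    fail("stage1_class_weights", "must be 6 positive numbers")
  if (cfg$bridge_max_gap_s < 0) fail("bridge_max_gap_s", "must be >= 0")
  if (cfg$bridge_fraction <= 0 || cfg$bridge_fraction > 1)
    fail("bridge_fraction", "must lie in (0, 1]")
  if (cfg$episode_steps < 2) fail("episode_steps", "must be >= 2")
  for (nm in c("variability_percentile", "speed_max_percentile"))
    if (cfg[[nm]] <= 0 || cfg[[nm]] >= 100) fail(nm, "must lie in (0, 100)")
  p <- cfg$norm_percentiles
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 100) ||
      any(diff(p) <= 0))
    fail("norm_percentiles", "must be strictly increasing within (0, 100)")
  e <- cfg$age_group_edges
  if (length(e) < 2 || any(diff(e) <= 0))
    fail("age_group_edges", "must be strictly increasing with >= 2 edges")
  invisible(cfg)
}

#' Read a pipeline configuration from a key = value file
#'
#' The file is plain text, one `key = value` per line; blank lines and lines
#' starting with `#` are ignored.  Vector fields take comma-separated values.
#' Keys absent from the file keep their defaults; keys outside the
#' configuration schema are rejected.
#'
#' @param path path to the file, or `NULL` for all defaults.
#' @return A validated [ww_config()] object.
#' @seealso [write_config()]
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(ww_config())
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  over <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" || startsWith(ln, "#")) next
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(m) != 3)
      stop("cannot parse config line ", i, ": '", lines[[i]], "'",
           call. = FALSE)
    val <- suppressWarnings(as.numeric(strsplit(m[[3]], ",")[[1]]))
    if (any(is.na(val)))
      stop("non-numeric value on config line ", i, ": '", lines[[i]], "'",
           call. = FALSE)
    over[[m[[2]]]] <- val
  }
  do.call(ww_config, over)
}

#' Write a pipeline configuration as a key = value file
#'
#' @param cfg a [ww_config()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "ww_config"))
  lines <- vapply(names(cfg), function(nm)
    paste0(nm, " = ", paste(format(cfg[[nm]], digits = 17), collapse = ",")),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
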