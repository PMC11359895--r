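#' Read a raw recording from delimited text
#'
#' The canonical on-disk form is delimited text with header columns
#' `time,x,y,z` (seconds since start, acceleration in g).  Subject metadata
#' may sit in a JSON sidecar `<path stem>_meta.json` with fields `id`,
#' `sex`, `height_cm`, `age_years` and optionally `start_clock_s`.  The
#' sampling rate is inferred from the median timestamp spacing; when it
#' differs from the configured rate by more than 1% the signal is linearly
#' resampled onto the configured rate and a warning is recorded on the
#' returned object (attribute `warnings`).
#'
#' @param path file path.
#' @param cfg a [ww_config()].
#' @param subject optional [subject_meta()] overriding the sidecar.
#' @return A [ww_recording()].
#' @export
read_recording <- function(path, cfg = ww_config(), subject = NULL) {
  dt <- data.table::fread(path, showProgress = FALSE)
  need <- c("time", "x", "y", "z")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols))
    stop("recording file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  tm <- dt$time
  warns <- character(0)
  start_clock <- 12 * 3600
  meta_path <- paste0(sub("\\.[A-Za-z0-9]+$", "", path), "_meta.json")
  if (is.null(subject) && file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(meta$start_clock_s)) start_clock <- meta$start_clock_s
    if (all(c("id", "sex", "height_cm", "age_years") %in% names(meta)))
      subject <- subject_meta(meta$id, meta$sex, meta$height_cm,
                              meta$age_years)
  }
  xyz <- as.matrix(dt[, c("x", "y", "z")])
  if (length(tm) > 1) {
    rate <- 1 / stats::median(diff(tm))
    if (abs(rate - cfg$sampling_rate_hz) / cfg$sampling_rate_hz > 0.01) {
      warns <- c(warns, sprintf(
        "inferred rate %.3f Hz differs from configured %g Hz; resampled",
        rate, cfg$sampling_rate_hz))
      grid <- seq(tm[[1]], tm[[length(tm)]], by = 1 / cfg$sampling_rate_hz)
      xyz <- vapply(1:3, function(a)
        stats::approx(tm, xyz[, a], xout = grid)$y,
        numeric(length(grid)))
      tm <- grid
    }
  }
  rec <- ww_recording(tm, xyz, cfg$sampling_rate_hz, subject, start_clock)
  attr(rec, "warnings") <- warns
  rec
}

#' Write a recording (and optional ground truth) as delimited text
#'
#' @param recording a [ww_recording()].
#' @param path output CSV path (`time,x,y,z`); a `_meta.json` sidecar is
#'   written when the recording carries a subject, and a `_truth.json`
#'   sidecar when ground truth is supplied.
#' @param truth optional truth list from [synthesize_recording()].
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, truth = NULL) {
  dt <- data.table::data.table(time = recording$time,
                               x = recording$xyz[, 1],
                               y = recording$xyz[, 2],
                               z = recording$xyz[, 3])
  data.table::fwrite(dt, path)
  stem <- sub("\\.[A-Za-z0-9]+$", "", path)
  if (!is.null(recording$subject)) {
    meta <- c(recording$subject[c("id", "sex", "height_cm", "age_years")],
              list(start_clock_s = recording$start_clock_s))
    jsonlite::write_json(meta, paste0(stem, "_meta.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(truth)) {
    tr <- list(step_times = truth$step_times, sleep = truth$sleep,
               entries = truth$entries)
    jsonlite::write_json(tr, paste0(stem, "_truth.json"), digits = NA,
                         dataframe = "columns")
  }
  invisible(path)
}

subset_recording <- function(recording, from_s, to_s) {
  sel <- recording$time >= from_s & recording$time < to_s
  rec <- ww_recording(recording$time[sel],
                      recording$xyz[sel, , drop = FALSE],
                      recording$sampling_rate, recording$subject,
                      recording$start_clock_s)
  rec
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(names(cfg), vapply(cfg, function(v)
    paste(format(v, digits = 17), collapse = ","), character(1)),
    sep = "="), f)
  unname(tools::md5sum(f))
}

#' Run the full biomarker pipeline on one recording
#'
#' Executes preprocess, feature extraction, two-stage classification, bout
#' assembly, step detection, speed regression, sleep estimation and daily
#' summarization for every noon-to-noon day of the recording, and returns
#' the daily biomarker table together with a run manifest (package version,
#' configuration hash, seed, per-stage record counts, warnings).  The run
#' is deterministic given identical inputs, models, configuration and seed.
#'
#' @param recording a [ww_recording()] (or a path readable by
#'   [read_recording()]).
#' @param classifier a trained [train_activity_classifier()] model.
#' @param speed_model a trained [fit_speed()] model.
#' @param cfg a [ww_config()].
#' @param seed integer seed (recorded in the manifest; the pipeline itself
#'   is deterministic).
#' @return List of class `ww_run` with `daily` (one biomarker row per day,
#'   plus `day` and `subject_id` columns), `wear` (from [wear_time()]) and
#'   `manifest`.
#' @export
run_pipeline <- function(recording, classifier, speed_model,
                         cfg = ww_config(), seed = 1) {
  if (is.character(recording)) recording <- read_recording(recording, cfg)
  warns <- attr(recording, "warnings") %||% character(0)
  t0 <- recording$time[[1]]
  span <- max(recording$time) - t0
  n_days <- max(1L, ceiling((span - 1e-9) / 86400))
  wear <- if (span >= 3600) wear_time(recording, cfg) else NULL
  rate <- classifier$meta$corrective_step_rate

  rows <- list()
  counts <- list()
  for (d in seq_len(n_days)) {
    slice <- subset_recording(recording, t0 + (d - 1) * 86400,
                              t0 + d * 86400)
    frame <- withCallingHandlers(
      segment_windows(slice, cfg),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    if (n_windows(frame) == 0) next
    feats <- extract_features(frame, cfg)
    pred <- predict_activity(classifier, feats)
    labels <- data.frame(start_time = frame$start_time,
                         stage1 = pred$stage1, stage2 = pred$stage2,
                         stringsAsFactors = FALSE)
    bouts <- assemble_bouts(labels, cfg)
    steps <- frame_steps(frame, pred$stage1, cfg)
    ep <- episode_metrics(steps$step_times, cfg)
    reg <- frame_regularity(frame, pred$stage1)
    spx <- speed_predictors(frame, pred$stage1, steps$per_window)
    speeds <- predict_speed(speed_model, spx$x)
    sleep <- estimate_sleep(slice, cfg)
    row <- summarize_day(labels, bouts, steps,
                         corrective_rate = if (is.null(rate)) NA_real_
                                           else rate,
                         ep, reg, speeds, sleep, cfg)
    row <- cbind(data.frame(
      subject_id = if (!is.null(recording$subject))
        recording$subject$id else NA_character_,
      day = d, stringsAsFactors = FALSE), row)
    rows[[length(rows) + 1L]] <- row
    counts[[length(counts) + 1L]] <-
      list(day = d, n_windows = n_windows(frame), n_bouts = nrow(bouts),
           n_steps = length(steps$step_times),
           n_speed_windows = nrow(spx$x))
  }
  daily <- if (length(rows)) do.call(rbind, rows) else NULL
  manifest <- list(
    package = "watchwalk",
    version = as.character(utils::packageVersion("watchwalk")),
    config_hash = config_hash(cfg),
    seed = seed,
    subject = if (!is.null(recording$subject)) recording$subject$id else NA,
    n_samples = length(recording$time),
    n_days = n_days,
    stages = counts,
    warnings = warns)
  structure(list(daily = daily, wear = wear, manifest = manifest),
            class = "ww_run")
}

#' @export
print.ww_run <- function(x, ...) {
  cat(sprintf("<ww_run> %d day(s), %d warnings\n",
              x$manifest$n_days, length(x$manifest$warnings)))
  invisible(x)
}
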