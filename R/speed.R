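#' Walking-speed predictors for arm-swing windows
#'
#' Builds the eight-predictor matrix of the speed model for every window
#' labelled `walk_arm_swing` in which steps were detected: (1) sex (0 =
#' female, 1 = male), (2) body height in cm, (3) median and (4) interquartile
#' range of the static-removed magnitude, (5) mean raw (crude) magnitude,
#' (6) mean step time in the window, and correlations between the
#' bandpass-filtered (7) x--y and (8) x--z axes.
#'
#' @param frame a `ww_frame` (must carry a subject).
#' @param stage1 per-window stage-1 labels.
#' @param per_window_steps list of per-window step times
#'   ([frame_steps()]`$per_window`).
#' @return List with `x` (predictor matrix, one row per scored window, fixed
#'   column order) and `window` (indices of the scored windows in the frame).
#' @export
speed_predictors <- function(frame, stage1, per_window_steps) {
  subj <- frame$subject
  if (is.null(subj)) stop("frame carries no subject metadata", call. = FALSE)
  idx <- which(stage1 == "walk_arm_swing" &
                 vapply(per_window_steps, length, integer(1)) >= 2)
  x <- matrix(NA_real_, length(idx), 8,
              dimnames = list(NULL, c(
                "sex_code", "height_cm", "median_srm", "iqr_srm",
                "mean_crude", "mean_step_time_s", "corr_xy", "corr_xz")))
  for (k in seq_along(idx)) {
    i <- idx[[k]]
    srm <- static_removed_magnitude(frame$raw_norm[i, ])
    x[k, ] <- c(
      as.numeric(subj$sex == "male"), subj$height_cm,
      stats::median(srm), stats::IQR(srm), mean(frame$raw_norm[i, ]),
      mean(diff(per_window_steps[[i]])),
      safe_cor(frame$filt_x[i, ], frame$filt_y[i, ]),
      safe_cor(frame$filt_x[i, ], frame$filt_z[i, ]))
  }
  list(x = x, window = idx)
}

#' Fit the walking-speed regression model
#'
#' RBF-kernel support vector regression of per-window ground-truth walking
#' speed on the eight predictors, with participant-level cross-validation
#' (default 10 folds; scaling and model re-fitted per fold) reported as
#' out-of-fold predictions.  The kernel coefficient is 1/8 (one over the
#' number of predictors, mirroring the classification convention); cost and
#' epsilon keep their library defaults and are recorded in the metadata.
#'
#' @param x predictor matrix (8 columns, see [speed_predictors()]).
#' @param speed true speed per row, m/s.
#' @param participant participant id per row.
#' @param cfg a [ww_config()].
#' @param seed integer seed controlling fold assignment.
#' @param n_folds number of folds.
#' @return An object of class `ww_speed_model` with the fitted SVR,
#'   `scaler`, `oof` (out-of-fold predictions and fold ids), `r2_oof` and
#'   `meta`.
#' @export
fit_speed <- function(x, speed, participant, cfg = ww_config(), seed = 1,
                      n_folds = 10) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(speed), length(speed) == length(participant))
  if (!nrow(x))
    stop("no arm-swing windows with detected steps to fit on",
         call. = FALSE)
  if (length(unique(participant)) < 2)
    stop("participant-level folds need at least 2 participants",
         call. = FALSE)
  gamma <- 1 / ncol(x)
  # canonical row order: the fit (and hence every prediction) is invariant
  # to permutations of the training windows
  ord <- do.call(order, c(list(participant),
                          lapply(seq_len(ncol(x)), function(j) x[, j]),
                          list(speed)))
  inv <- order(ord)
  x <- x[ord, , drop = FALSE]
  speed <- speed[ord]
  participant <- participant[ord]
  fold <- participant_folds(participant, n_folds, seed)
  oof <- rep(NA_real_, length(speed))
  for (f in sort(unique(fold))) {
    tr <- fold != f
    sc <- fit_scaler(x[tr, , drop = FALSE])
    m <- e1071::svm(x = apply_scaler(x[tr, , drop = FALSE], sc),
                    y = speed[tr], type = "eps-regression",
                    kernel = "radial", gamma = gamma, scale = FALSE)
    oof[!tr] <- stats::predict(m, apply_scaler(x[!tr, , drop = FALSE], sc))
  }
  r2 <- 1 - sum((speed - oof)^2) / sum((speed - mean(speed))^2)
  scaler <- fit_scaler(x)
  m <- e1071::svm(x = apply_scaler(x, scaler), y = speed,
                  type = "eps-regression", kernel = "radial", gamma = gamma,
                  scale = FALSE)
  structure(list(model = m, scaler = scaler,
                 oof = data.frame(fold = fold[inv], predicted = oof[inv],
                                  truth = speed[inv]),
                 r2_oof = r2,
                 meta = list(gamma = gamma, cost = m$cost,
                             epsilon = m$epsilon, n_folds =
                               length(unique(fold)), seed = seed,
                             predictors = colnames(x))),
            class = "ww_speed_model")
}

#' @export
print.ww_speed_model <- function(x, ...) {
  cat(sprintf("<ww_speed_model> RBF SVR on 8 predictors, out-of-fold R2 = %.3f\n",
              x$r2_oof))
  invisible(x)
}

#' Predict per-window walking speed
#'
#' @param model a `ww_speed_model`.
#' @param x predictor matrix from [speed_predictors()].
#' @return Numeric vector of speeds, m/s.
#' @export
predict_speed <- function(model, x) {
  stopifnot(inherits(model, "ww_speed_model"))
  x <- as.matrix(x)
  if (!nrow(x)) return(numeric(0))
  if (ncol(x) != length(model$scaler$center))
    stop("predictor mismatch", call. = FALSE)
  as.numeric(stats::predict(model$model, apply_scaler(x, model$scaler)))
}

#' Maximal and usual walking speed of a day
#'
#' Maximal speed is the 95th percentile (`speed_max_percentile`) and usual
#' speed the median of the day's per-window speed predictions, under the
#' shared linear-interpolation quantile rule.
#'
#' @param speeds per-window predicted speeds of one day, m/s.
#' @param cfg a [ww_config()].
#' @return List with `max_speed_ms` and `usual_speed_ms`; both `NA` when
#'   there are no predictions.
#' @export
daily_speeds <- function(speeds, cfg = ww_config()) {
  speeds <- speeds[is.finite(speeds)]
  if (!length(speeds))
    return(list(max_speed_ms = NA_real_, usual_speed_ms = NA_real_))
  list(max_speed_ms = ww_quantile(speeds, cfg$speed_max_percentile / 100),
       usual_speed_ms = stats::median(speeds))
}
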