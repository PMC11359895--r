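#' Two-stage activity classifier
#'
#' Stage 1 labels every 4-second window as one of six activities with a
#' weighted RBF-kernel SVM (class weights 50, 25, 10, 5, 5, 5 to focus on
#' walking; kernel coefficient gamma = 1/54).  Stage 2 refines
#' `other_complex_walking` windows into five hand positions with a second,
#' uniformly weighted RBF SVM.  Cross-validation is always partitioned at the
#' participant level: all of one participant's windows share a fold.
#'
#' @name activity_classifier
NULL

# Deterministic participant-level fold assignment: participants sorted,
# shuffled by the seeded RNG, dealt round-robin.  Fewer participants than
# folds degrades to leave-one-participant-out.
participant_folds <- function(participant, n_folds, seed) {
  ids <- sort(unique(as.character(participant)))
  if (length(ids) < 2)
    stop("participant-level folds need at least 2 participants",
         call. = FALSE)
  n_folds <- min(n_folds, length(ids))
  perm <- with_seed(seed, sample(ids))
  fold_of <- stats::setNames(rep_len(seq_len(n_folds), length(perm)), perm)
  unname(fold_of[as.character(participant)])
}

# Per-feature z-scaling fitted on the training rows only; constant features
# get unit scale so the kernel ignores them consistently.
fit_scaler <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  list(center = mu, scale = sdv)
}
apply_scaler <- function(x, sc) {
  sweep(sweep(x, 2, sc$center, "-"), 2, sc$scale, "/")
}

svm_fit_stage <- function(x, y, gamma, weights = NULL, cost = 1) {
  e1071::svm(x = x, y = y, type = "C-classification", kernel = "radial",
             gamma = gamma, cost = cost, class.weights = weights,
             scale = FALSE, fitted = FALSE)
}

#' Train the two-stage activity classifier
#'
#' Fits both SVM stages on all labelled windows and reports out-of-fold
#' predictions from participant-level cross-validation (feature scaling and
#' both stages are re-fitted within each fold).  When ground-truth step
#' counts are supplied, the corrective step rate -- the mean number of true
#' steps per `unspecified_arms_walking` window -- is estimated and stored in
#' the model metadata for later step-count correction.
#'
#' @param features numeric matrix of window features ([extract_features()]).
#' @param stage1 true stage-1 label per window.
#' @param stage2 true stage-2 label per window (`NA` outside
#'   `other_complex_walking`).
#' @param participant participant id per window.
#' @param cfg a [ww_config()].
#' @param seed integer seed controlling fold assignment.
#' @param n_folds number of cross-validation folds (default 10).
#' @param steps_per_window optional ground-truth step count per window, used
#'   to estimate the corrective step rate.
#' @param cost SVM cost parameter (C); recorded in metadata.
#' @return An object of class `ww_classifier` with elements `stage1`,
#'   `stage2` (fitted SVMs), `scaler`, `oof` (data.frame of out-of-fold
#'   stage-1/stage-2 predictions with fold ids) and `meta`.
#' @export
train_activity_classifier <- function(features, stage1, stage2, participant,
                                      cfg = ww_config(), seed = 1,
                                      n_folds = 10,
                                      steps_per_window = NULL, cost = 1) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(stage1),
            length(stage1) == length(participant))
  if (ncol(features) != cfg$n_features)
    stop("expected ", cfg$n_features, " features", call. = FALSE)
  missing1 <- setdiff(stage1_levels(), unique(stage1))
  if (length(missing1))
    stop("stage-1 class absent from training data: ",
         paste(missing1, collapse = ", "), call. = FALSE)
  y1 <- factor(stage1, levels = stage1_levels())
  is_ocw <- stage1 == "other_complex_walking"
  missing2 <- setdiff(stage2_levels(), unique(stage2[is_ocw]))
  if (length(missing2))
    stop("stage-2 class absent from training data: ",
         paste(missing2, collapse = ", "), call. = FALSE)
  y2 <- factor(stage2[is_ocw], levels = stage2_levels())
  w1 <- stats::setNames(cfg$stage1_class_weights, stage1_levels())

  fold <- participant_folds(participant, n_folds, seed)
  oof1 <- rep(NA_character_, length(stage1))
  oof2 <- rep(NA_character_, length(stage1))
  for (f in sort(unique(fold))) {
    tr <- fold != f; te <- !tr
    sc <- fit_scaler(features[tr, , drop = FALSE])
    xtr <- apply_scaler(features[tr, , drop = FALSE], sc)
    xte <- apply_scaler(features[te, , drop = FALSE], sc)
    m1 <- svm_fit_stage(xtr, droplevels(y1[tr]), cfg$svm_gamma, w1[levels(droplevels(y1[tr]))],
                        cost)
    oof1[te] <- as.character(stats::predict(m1, xte))
    tr2 <- tr & is_ocw; te2 <- te & is_ocw
    if (sum(tr2) > 1 && any(te2)) {
      ytr2 <- droplevels(factor(stage2[tr2], levels = stage2_levels()))
      if (nlevels(ytr2) >= 2) {
        m2 <- svm_fit_stage(apply_scaler(features[tr2, , drop = FALSE], sc),
                            ytr2, cfg$svm_gamma, cost = cost)
        oof2[te2] <- as.character(
          stats::predict(m2, apply_scaler(features[te2, , drop = FALSE], sc)))
      }
    }
  }

  scaler <- fit_scaler(features)
  xs <- apply_scaler(features, scaler)
  m1 <- svm_fit_stage(xs, y1, cfg$svm_gamma, w1, cost)
  m2 <- svm_fit_stage(xs[is_ocw, , drop = FALSE], y2, cfg$svm_gamma,
                      cost = cost)

  corrective_rate <- NA_real_
  if (!is.null(steps_per_window)) {
    uw <- stage1 == "unspecified_arms_walking"
    if (any(uw)) corrective_rate <- mean(steps_per_window[uw])
  }

  structure(list(
    stage1 = m1, stage2 = m2, scaler = scaler,
    oof = data.frame(fold = fold, stage1 = oof1, stage2 = oof2,
                     stringsAsFactors = FALSE),
    meta = list(feature_version = "ww-54-v1", gamma = cfg$svm_gamma,
                cost = cost, stage1_class_weights = cfg$stage1_class_weights,
                n_folds = length(unique(fold)), seed = seed,
                corrective_step_rate = corrective_rate,
                n_windows = nrow(features),
                n_participants = length(unique(participant)))),
    class = "ww_classifier")
}

#' @export
print.ww_classifier <- function(x, ...) {
  cat(sprintf(paste0("<ww_classifier> two-stage RBF SVM, gamma = 1/%d, ",
                     "%d windows from %d participants (%d folds)\n"),
              round(1 / x$meta$gamma), x$meta$n_windows,
              x$meta$n_participants, x$meta$n_folds))
  invisible(x)
}

#' Predict activity labels for a window frame
#'
#' @param model a `ww_classifier`.
#' @param features feature matrix of the windows to label (54 columns), or a
#'   `ww_frame` (features are then extracted with [extract_features()]).
#' @param cfg a [ww_config()] (used only when `features` is a frame).
#' @return `data.frame` with columns `stage1` and `stage2`; `stage2` is `NA`
#'   except where `stage1 == "other_complex_walking"`.
#' @export
predict_activity <- function(model, features, cfg = ww_config()) {
  stopifnot(inherits(model, "ww_classifier"))
  if (inherits(features, "ww_frame"))
    features <- extract_features(features, cfg)
  features <- as.matrix(features)
  if (ncol(features) != length(model$scaler$center))
    stop("feature-version mismatch: model expects ",
         length(model$scaler$center), " features, got ", ncol(features),
         call. = FALSE)
  if (nrow(features) == 0)
    return(data.frame(stage1 = character(0), stage2 = character(0),
                      stringsAsFactors = FALSE))
  xs <- apply_scaler(features, model$scaler)
  s1 <- as.character(stats::predict(model$stage1, xs))
  s2 <- rep(NA_character_, length(s1))
  ocw <- s1 == "other_complex_walking"
  if (any(ocw))
    s2[ocw] <- as.character(stats::predict(model$stage2,
                                           xs[ocw, , drop = FALSE]))
  data.frame(stage1 = s1, stage2 = s2, stringsAsFactors = FALSE)
}

#' Confusion matrix with per-class sensitivity, precision and specificity
#'
#' Rows are truth, columns are predictions.  Sensitivity is the
#' row-normalized diagonal (recall), precision the column-normalized
#' diagonal, specificity the true-negative rate of each one-vs-rest split.
#'
#' @param truth,predicted equal-length label vectors.
#' @param levels label taxonomy; defaults to the union of observed labels.
#' @return A list with `table` (counts), and per-class `sensitivity`,
#'   `precision`, `specificity`.
#' @export
confusion_matrix <- function(truth, predicted, levels = NULL) {
  if (length(truth) == 0 || length(truth) != length(predicted))
    stop("truth and predicted must be non-empty and of equal length",
         call. = FALSE)
  levels <- levels %||% sort(unique(c(truth, predicted)))
  bad <- setdiff(unique(c(truth, predicted)), levels)
  if (length(bad))
    stop("label outside taxonomy: ", paste(bad, collapse = ", "),
         call. = FALSE)
  tb <- table(factor(truth, levels), factor(predicted, levels),
              dnn = c("truth", "predicted"))
  diagv <- diag(tb)
  sens <- diagv / rowSums(tb)
  prec <- diagv / colSums(tb)
  tn <- vapply(seq_along(levels), function(i)
    sum(tb[-i, -i]), numeric(1))
  fp <- colSums(tb) - diagv
  spec <- tn / (tn + fp)
  list(table = tb,
       sensitivity = stats::setNames(as.numeric(sens), levels),
       precision = stats::setNames(as.numeric(prec), levels),
       specificity = stats::setNames(as.numeric(spec), levels))
}
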