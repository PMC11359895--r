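#' Intraclass correlation ICC(2,k): two-way random effects, absolute
#' agreement, average of k measures
#'
#' Estimated from the mean squares of the two-way ANOVA decomposition of a
#' complete subjects-by-days matrix:
#' `ICC = (MSR - MSE) / (MSR + (MSC - MSE) / n)`,
#' with MSR the between-subject, MSC the between-day and MSE the residual
#' mean square.  The 95% confidence interval follows the F-distribution
#' bounds of the standard two-way random-effects derivation
#' (single-measure bounds with Satterthwaite degrees of freedom, stepped up
#' to average measures by the Spearman-Brown relation).  Rows containing
#' missing values are dropped (complete-case), and the number retained is
#' reported.
#'
#' @param mat numeric matrix, subjects in rows, days (measurements) in
#'   columns.
#' @param conf confidence level (0.95).
#' @return List of class `ww_icc`: `icc`, `ci95` (low, high), `n_subjects`,
#'   `k_days`, `ms` (MSR, MSC, MSE).
#' @export
icc_2k <- function(mat, conf = 0.95) {
  mat <- as.matrix(mat)
  keep <- stats::complete.cases(mat)
  mat <- mat[keep, , drop = FALSE]
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2 || k < 2)
    stop("ICC needs at least 2 complete subjects and 2 days", call. = FALSE)
  grand <- mean(mat)
  rm_ <- rowMeans(mat); cm_ <- colMeans(mat)
  ssr <- k * sum((rm_ - grand)^2)
  ssc <- n * sum((cm_ - grand)^2)
  sst <- sum((mat - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (msc - mse) / n
  icc <- if (denom <= 0) 0 else (msr - mse) / denom
  # single-measure point estimate feeding the CI
  icc1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  if (mse <= .Machine$double.eps * max(1, msr)) {
    ci <- c(icc, icc)   # degenerate: zero residual variance
  } else {
    alpha <- 1 - conf
    fc <- msc / mse
    a <- k * icc1 / (n * (1 - icc1))
    b <- 1 + k * icc1 * (n - 1) / (n * (1 - icc1))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_u <- stats::qf(1 - alpha / 2, n - 1, v)
    f_l <- stats::qf(1 - alpha / 2, v, n - 1)
    l1 <- n * (msr - f_u * mse) /
      (f_u * (k * msc + (k * n - k - n) * mse) + n * msr)
    u1 <- n * (f_l * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_l * msr)
    sb <- function(r) k * r / (1 + (k - 1) * r)   # Spearman-Brown step-up
    ci <- c(sb(l1), sb(u1))
  }
  ci <- pmin(pmax(ci, -1), 1)
  ci <- c(min(ci[[1]], icc), max(ci[[2]], icc))
  structure(list(icc = icc, ci95 = ci, n_subjects = n, k_days = k,
                 n_dropped = sum(!keep),
                 ms = c(MSR = msr, MSC = msc, MSE = mse)),
            class = "ww_icc")
}

#' @export
print.ww_icc <- function(x, ...) {
  cat(sprintf("ICC(2,%d) = %.3f [%.3f, %.3f], n = %d subjects\n",
              x$k_days, x$icc, x$ci95[[1]], x$ci95[[2]], x$n_subjects))
  invisible(x)
}

#' Mean absolute percentage error
#'
#' @param predicted,truth equal-length numeric vectors; `truth` must be
#'   nonzero everywhere.
#' @return List with `mape_pct` (mean of `|pred - truth| / |truth| * 100`)
#'   and `sd_pct`.
#' @export
mape <- function(predicted, truth) {
  if (length(predicted) != length(truth) || !length(truth))
    stop("predicted and truth must be non-empty and of equal length",
         call. = FALSE)
  z <- which(truth == 0)
  if (length(z))
    stop("zero truth entry at index ", z[[1]], call. = FALSE)
  ape <- abs(predicted - truth) / abs(truth) * 100
  list(mape_pct = mean(ape), sd_pct = stats::sd(ape))
}

#' Group-stratified biomarker summaries
#'
#' Descriptive per-group summaries (n, mean, SD, median, IQR) of one
#' biomarker across a grouping such as sex, age group or a self-report
#' category.  Inferential p-values are delegated to the standard routines --
#' t-test / one-way ANOVA for parametric markers, Wilcoxon-Mann-Whitney /
#' Kruskal-Wallis otherwise -- and recorded verbatim.
#'
#' @param values biomarker value per subject.
#' @param group grouping factor (>= 2 non-empty groups).
#' @param parametric whether to use the parametric test family.
#' @return List with `summary` (`data.frame`, one row per group), `test`
#'   (name of the delegated test) and `p_value`.
#' @export
stratified_contrast <- function(values, group, parametric = TRUE) {
  group <- factor(group)
  if (nlevels(group) < 2)
    stop("need at least two groups", call. = FALSE)
  smry <- do.call(rbind, lapply(levels(group), function(g) {
    v <- values[group == g & is.finite(values)]
    data.frame(group = g, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               median = if (length(v)) stats::median(v) else NA_real_,
               iqr = if (length(v)) stats::IQR(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  two <- nlevels(droplevels(group[is.finite(values)])) == 2
  res <- if (parametric && two)
    list(test = "t-test", p = stats::t.test(values ~ group)$p.value)
  else if (parametric)
    list(test = "one-way ANOVA",
         p = summary(stats::aov(values ~ group))[[1]][["Pr(>F)"]][[1]])
  else if (two)
    list(test = "Mann-Whitney U",
         p = stats::wilcox.test(values ~ group)$p.value)
  else
    list(test = "Kruskal-Wallis",
         p = stats::kruskal.test(values, group)$p.value)
  list(summary = smry, test = res$test, p_value = res$p)
}
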