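# Independent ANOVA oracle: explicit sums of squares, no shared code with
# the implementation's mean-square computation path beyond base arithmetic.
icc_oracle <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  long <- data.frame(y = as.vector(mat),
                     s = factor(rep(seq_len(n), k)),
                     d = factor(rep(seq_len(k), each = n)))
  a <- summary(stats::aov(y ~ s + d, data = long))[[1]]
  msr <- a["s", "Mean Sq"]; msc <- a["d", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (msc - mse) / n)
}

test_that("ICC(2,k) agrees with the brute-force ANOVA oracle", {
  m <- matrix(c(9, 8, 6, 5, 4, 3, 7, 6), nrow = 4, byrow = TRUE)
  r <- icc_2k(m)
  expect_lt(abs(r$icc - icc_oracle(m)), 1e-10)
  set.seed(8)
  for (i in 1:5) {
    m2 <- matrix(rnorm(36, 10, 2), 6, 6)
    expect_lt(abs(icc_2k(m2)$icc - icc_oracle(m2)), 1e-10)
  }
})

test_that("identical columns give ICC exactly 1; pure noise gives about 0", {
  m <- matrix(c(1, 1, 5, 5, 9, 9), 3, 2, byrow = TRUE)
  expect_identical(icc_2k(m)$icc, 1)
  set.seed(13)
  noise <- matrix(rnorm(200 * 4), 200, 4)
  expect_lt(abs(icc_2k(noise)$icc), 0.15)
})

test_that("the interval brackets the estimate and matches a published-form check", {
  # frozen cross-check value computed independently with the
  # two-way random-effects absolute-agreement CI formulas
  x <- simulate_biomarker_matrix(12, 4, 0.8, mean = 5, sd_between = 1.5,
                                 sd_day = 0.4, seed = 21)
  r <- icc_2k(x)
  expect_equal(r$icc, 0.8359602419, tolerance = 1e-9)
  expect_equal(r$ci95[[1]], 0.6100344582, tolerance = 1e-6)
  expect_equal(r$ci95[[2]], 0.9467670547, tolerance = 1e-6)
  expect_lte(r$ci95[[1]], r$icc)
  expect_gte(r$ci95[[2]], r$icc)
  expect_lte(r$icc, 1)
})

test_that("ICC is invariant to shifting and positive scaling", {
  x <- simulate_biomarker_matrix(30, 5, 0.7, seed = 2)
  base <- icc_2k(x)$icc
  expect_equal(icc_2k(x + 100)$icc, base, tolerance = 1e-12)
  expect_equal(icc_2k(x * 3.5)$icc, base, tolerance = 1e-12)
})

test_that("incomplete rows are dropped and tiny designs rejected", {
  x <- simulate_biomarker_matrix(10, 3, 0.8, seed = 5)
  x[3, 2] <- NA
  r <- icc_2k(x)
  expect_equal(r$n_subjects, 9)
  expect_equal(r$n_dropped, 1)
  expect_error(icc_2k(matrix(1:2, 1, 2)), "at least 2")
  bad <- matrix(NA_real_, 5, 2); bad[1, ] <- 1:2
  expect_error(icc_2k(bad), "at least 2")
})

test_that("MAPE matches hand computation and rejects zero truth", {
  expect_equal(mape(c(1, 2, 3), c(1, 2, 3))$mape_pct, 0)
  r <- mape(1.1 * c(2, 4, 8), c(2, 4, 8))
  expect_equal(r$mape_pct, 10, tolerance = 1e-9)
  expect_equal(r$sd_pct, 0, tolerance = 1e-9)
  r2 <- mape(c(1.0, 2.2, 2.7), c(1.0, 2.0, 3.0))
  expect_equal(r2$mape_pct, mean(c(0, 10, 10)), tolerance = 1e-9)
  expect_error(mape(c(1, 2), c(1, 0)), "index 2")
  expect_error(mape(1, c(1, 2)), "equal length")
})

test_that("stratified contrasts summarize groups and recover known offsets", {
  g <- rep(c("a", "b"), each = 20)
  v <- rep(5, 40)
  r <- stratified_contrast(v + rnorm(40, 0, 1e-9), g)
  expect_equal(r$summary$mean[1], r$summary$mean[2], tolerance = 1e-6)
  set.seed(10)
  speed <- c(rnorm(200, 145, 7), rnorm(200, 153, 7))
  sex <- rep(c("female", "male"), each = 200)
  rc <- stratified_contrast(speed, sex)
  diff_mean <- rc$summary$mean[2] - rc$summary$mean[1]
  expect_lt(abs(diff_mean - 8), 3 * 7 * sqrt(2 / 200))  # 3 SE of the diff
  expect_equal(rc$test, "t-test")
  expect_lt(rc$p_value, 0.001)
  rk <- stratified_contrast(speed, sex, parametric = FALSE)
  expect_equal(rk$test, "Mann-Whitney U")
  r3 <- stratified_contrast(rnorm(90), rep(c("x", "y", "z"), 30))
  expect_equal(r3$test, "one-way ANOVA")
  expect_error(stratified_contrast(rnorm(10), rep("only", 10)),
               "at least two groups")
})
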