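# Independent oracle: direct evaluation of the three bridging criteria on a
# (previous run, gap, following run) triple, in seconds.
bridge_oracle <- function(prev, gap, nxt, max_gap = 60, fraction = 1 / 5) {
  gap <= max_gap && gap <= min(prev, nxt) && gap <= fraction * max(prev, nxt)
}

# Build a label sequence realizing runs/gaps given in seconds (4-s windows).
label_seq <- function(durations, walking) {
  stopifnot(all(durations %% 4 == 0))
  stage1 <- unlist(mapply(function(d, w)
    rep(if (w) "walk_arm_swing" else "stationary", d / 4),
    durations, walking, SIMPLIFY = FALSE))
  data.frame(start_time = seq(0, by = 4, length.out = length(stage1)),
             stage1 = stage1, stringsAsFactors = FALSE)
}

test_that("single-gap bridging matches the three-criteria oracle exactly", {
  cases <- rbind(
    c(120, 20, 160), c(120, 72, 120), c(8, 12, 100), c(200, 40, 200),
    c(200, 44, 200), c(4, 4, 4), c(40, 8, 400), c(400, 8, 40),
    c(60, 60, 300), c(300, 60, 60), c(16, 16, 16), c(120, 24, 120))
  for (i in seq_len(nrow(cases))) {
    prev <- cases[i, 1]; gap <- cases[i, 2]; nxt <- cases[i, 3]
    labels <- label_seq(c(prev, gap, nxt), c(TRUE, FALSE, TRUE))
    bouts <- assemble_bouts(labels, ww_config())
    bridged <- bridge_oracle(prev, gap, nxt)
    expect_equal(nrow(bouts), if (bridged) 1L else 2L,
                 label = sprintf("case %d (%g|%g|%g)", i, prev, gap, nxt))
    if (bridged) {
      expect_equal(bouts$duration_s, prev + gap + nxt)
      expect_equal(bouts$n_bridged_gaps, 1L)
      expect_equal(bouts$bridged_s, gap)
    }
  }
})

test_that("bridging iterates left to right until no gap qualifies", {
  # the second gap (12 s vs neighbours 52 s | 56 s) fails the one-fifth rule
  # on the raw runs but qualifies once the first merge lengthens the left
  # neighbour to 64 s
  expect_false(bridge_oracle(52, 12, 56))
  expect_true(bridge_oracle(64, 12, 56))
  labels <- label_seq(c(8, 4, 52, 12, 56), c(TRUE, FALSE, TRUE, FALSE, TRUE))
  bouts <- assemble_bouts(labels, ww_config())
  expect_equal(nrow(bouts), 1L)
  expect_equal(bouts$duration_s, 8 + 4 + 52 + 12 + 56)
  expect_equal(bouts$n_bridged_gaps, 2L)
  expect_equal(bouts$bridged_s, 16)
})

test_that("disabling bridging returns the raw runs", {
  labels <- label_seq(c(120, 20, 160), c(TRUE, FALSE, TRUE))
  raw <- assemble_bouts(labels, ww_config(bridge_max_gap_s = 0))
  expect_equal(nrow(raw), 2L)
  expect_equal(raw$duration_s, c(120, 160))
  # bridging never decreases the longest walk
  expect_gte(longest_walk(assemble_bouts(labels, ww_config())),
             longest_walk(raw))
})

test_that("longest walk handles the trivial cases", {
  b <- data.frame(duration_s = c(40, 333, 12))
  expect_equal(longest_walk(b), 333)
  expect_equal(longest_walk(b[0, , drop = FALSE]), 0)
  expect_equal(longest_walk(data.frame(duration_s = 600)), 600)
})

test_that("exposure proportions follow cumulative walking time", {
  b <- data.frame(duration_s = c(4, 8, 120))
  e <- walk_exposure_proportions(b, ww_config())
  expect_equal(e$pct_ge_short, 100 * 128 / 132)
  expect_equal(e$pct_ge_long, 100 * 120 / 132)
  one <- walk_exposure_proportions(data.frame(duration_s = 120), ww_config())
  expect_equal(one$pct_ge_short, 100)
  expect_equal(one$pct_ge_long, 100)
  short <- walk_exposure_proportions(data.frame(duration_s = c(4, 4)),
                                     ww_config())
  expect_equal(short$pct_ge_short, 0)
  none <- walk_exposure_proportions(data.frame(duration_s = numeric(0)),
                                    ww_config())
  expect_true(is.na(none$pct_ge_short))
})

test_that("unsorted labels are rejected and totals stay bounded", {
  labels <- label_seq(c(40, 8, 40), c(TRUE, FALSE, TRUE))
  expect_error(assemble_bouts(labels[rev(seq_len(nrow(labels))), ],
                              ww_config()), "time-ordered")
  bouts <- assemble_bouts(labels, ww_config())
  total_window_time <- nrow(labels) * 4
  expect_gte(sum(bouts$duration_s), sum(labels$stage1 == "walk_arm_swing") * 4)
  expect_lte(sum(bouts$duration_s), total_window_time)
})
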