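# Period construction, the matching ledger, scores and timing.

test_that("window runs merge into periods with the midpoint convention", {
  w <- make_windows(1000, 1000, window_ms = 400, step_ms = 50)
  lab <- factor(rep("idle", nrow(w)), levels = c("idle", "active"))
  lab[2:3] <- "active"
  p <- windows_to_periods(lab, w)
  expect_equal(nrow(p), 1)
  expect_equal(p$start_s, w$mid_s[2] - 0.025)
  expect_equal(p$end_s, w$mid_s[3] + 0.025)

  expect_equal(nrow(windows_to_periods(
    factor(rep("idle", nrow(w)), levels = c("idle", "active")), w)), 0)

  alt <- factor(rep(c("idle", "active"), length.out = nrow(w)),
                levels = c("idle", "active"))
  expect_equal(nrow(windows_to_periods(alt, w)), sum(alt == "active"))
})

test_that("matching reproduces hand-computed ledgers", {
  P <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(start_s = m[, 1], end_s = m[, 2])
  }
  # 1. exact identity
  led <- match_periods(P(1, 1.7, 3, 3.7), P(1, 1.7, 3, 3.7))
  expect_equal(led[c("TP", "FP", "FN")], list(TP = 2L, FP = 0L, FN = 0L))
  expect_equal(led$diffs$onset_diff_s, c(0, 0))
  # 2. one matched within tolerance, one missed
  led <- match_periods(P(1, 1.7, 3, 3.7), P(0.95, 1.75))
  expect_equal(led[c("TP", "FP", "FN")], list(TP = 1L, FP = 0L, FN = 1L))
  expect_equal(led$diffs$onset_diff_s, -0.05)
  expect_equal(led$diffs$end_diff_s, 0.05)
  # 3. spurious detection only
  led <- match_periods(P(1, 1.7), P(1, 1.7, 5, 5.4))
  expect_equal(led[c("TP", "FP", "FN")], list(TP = 1L, FP = 1L, FN = 0L))
  # 4. penetration: one detection spanning two actual periods
  led <- match_periods(P(1.2, 1.9, 3.2, 3.9), P(1.0, 4.0))
  expect_equal(led[c("TP", "FP", "FN")], list(TP = 1L, FP = 1L, FN = 0L))
  expect_equal(led$diffs$onset_diff_s, -0.2)
  expect_equal(led$diffs$end_diff_s, 0.1)
  # 5. onset off by more than 400 ms: extra FP
  led <- match_periods(P(1, 1.7), P(0.5, 1.7))
  expect_equal(led[c("TP", "FP", "FN")], list(TP = 1L, FP = 1L, FN = 0L))
  expect_equal(led$diffs$onset_diff_s, -0.5)
  # 6. end off by more than 400 ms: extra FN
  led <- match_periods(P(1, 1.7), P(1, 2.2))
  expect_equal(led[c("TP", "FP", "FN")], list(TP = 1L, FP = 0L, FN = 1L))
  # 7. both boundaries off: extra FP and FN
  led <- match_periods(P(1, 1.7), P(0.4, 2.3))
  expect_equal(led[c("TP", "FP", "FN")], list(TP = 1L, FP = 1L, FN = 1L))
  # 8. one actual split across two detections: 1 TP + 1 FP, and the first
  # detection's end misses by 0.6 s, so the 400-ms rule adds an FN
  led <- match_periods(P(1, 2), P(1, 1.4, 1.6, 2.0))
  expect_equal(led[c("TP", "FP", "FN")], list(TP = 1L, FP = 1L, FN = 1L))
  expect_equal(led$diffs$end_diff_s, -0.6)
  # 9. all missed
  led <- match_periods(P(1, 1.7, 3, 3.7), P(0, 0)[0, ])
  expect_equal(led[c("TP", "FP", "FN")], list(TP = 0L, FP = 0L, FN = 2L))
  # 10. nothing actual, one detection
  led <- match_periods(P(0, 0)[0, ], P(1, 1.5), session_span = c(0, 10))
  expect_equal(led[c("TP", "FP", "FN", "TN")],
               list(TP = 0L, FP = 1L, FN = 0L, TN = 0L))
})

test_that("boundary-excess rule: case 8 end difference adds an FN", {
  P <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(start_s = m[, 1], end_s = m[, 2])
  }
  led <- match_periods(P(1, 2), P(1, 1.4, 1.6, 2.0))
  expect_equal(led$FN, 1L)  # end_diff -0.6 exceeds 400 ms
})

test_that("true negatives count idle periods containing no detection", {
  P <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(start_s = m[, 1], end_s = m[, 2])
  }
  actual <- P(1, 2, 4, 5, 7, 8)
  # detection crossing a boundary does not void the idle gap
  led <- match_periods(actual, P(0.9, 2.1, 4, 5), session_span = c(0, 10))
  expect_equal(led$TN, 4L)  # gaps: [0,1],[2,4],[5,7],[8,10]
  # a spurious detection inside a gap voids it
  led <- match_periods(actual, P(2.5, 3.0), session_span = c(0, 10))
  expect_equal(led$TN, 3L)
  expect_equal(led$FP, 1L)
})

test_that("matching agrees with the brute-force matcher on random sets", {
  set.seed(99)
  for (i in 1:500) {
    a <- random_periods(sample(0:6, 1))
    d <- random_periods(sample(0:6, 1))
    got <- match_periods(a, d)
    want <- bf_match(a, d)
    expect_equal(got$TP, want$TP, info = paste("case", i))
    expect_equal(got$FP, want$FP, info = paste("case", i))
    expect_equal(got$FN, want$FN, info = paste("case", i))
  }
})

test_that("ledger conservation: every interval annotated exactly once", {
  set.seed(123)
  for (i in 1:100) {
    a <- random_periods(sample(0:5, 1))
    d <- random_periods(sample(0:5, 1))
    led <- match_periods(a, d)
    expect_false(anyNA(led$annotations$actual))
    expect_false(anyNA(led$annotations$detected))
    expect_equal(nrow(led$diffs), led$TP)
  }
})

test_that("scores follow the period-level definitions", {
  expect_equal(score(list(TP = 9, FN = 1, FP = 0, TN = 0))$sensitivity, 90)
  expect_equal(score(list(TP = 11, FP = 1, FN = 0, TN = 0))$precision,
               100 * 11 / 12)
  s <- suppressWarnings(score(list(TP = 0, FP = 0, FN = 0, TN = 5)))
  expect_true(is.na(s$sensitivity))
  expect_true(is.na(s$precision))
  expect_equal(s$accuracy, 100)
  w <- testthat::capture_warnings(score(list(TP = 0, FP = 0, FN = 0,
                                             TN = 5)))
  expect_true(any(grepl("undefined", w)))
  # scale-free
  s1 <- score(list(TP = 3, FP = 1, FN = 2, TN = 4))
  s2 <- score(list(TP = 6, FP = 2, FN = 4, TN = 8))
  expect_equal(s1$sensitivity, s2$sensitivity)
  expect_equal(s1$precision, s2$precision)
  expect_equal(s1$accuracy, s2$accuracy)
})

test_that("timing summaries pool overlapping-pair differences", {
  l1 <- list(diffs = data.frame(onset_diff_s = -0.05, end_diff_s = 0.02))
  l2 <- list(diffs = data.frame(onset_diff_s = 0.05, end_diff_s = -0.02))
  class(l1) <- class(l2) <- "match_ledger"
  ts <- timing_summary(list(l1, l2))
  expect_equal(ts$onset_mean_s, 0)
  expect_equal(ts$end_mean_s, 0)
  expect_equal(ts$n_tp, 2)
  single <- timing_summary(l1)
  expect_true(is.na(single$onset_se_s))
  expect_equal(single$onset_mean_s, -0.05)
})
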