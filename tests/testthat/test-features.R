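# Window layout, labelling, and the four time-domain operators.

test_that("sliding-window layout follows the step/length arithmetic", {
  w <- make_windows(1000, 1000, window_ms = 400, step_ms = 50)
  expect_equal(nrow(w), 13)  # floor((1000-400)/50)+1
  expect_equal(w$start_sample[1], 0)
  expect_equal(w$end_sample[13], 1000)
  expect_equal(diff(w$start_s), rep(0.05, 12))

  w1 <- make_windows(150, 1000, window_ms = 150, step_ms = 50)
  expect_equal(nrow(w1), 1)

  expect_error(make_windows(1000, 1000, window_ms = 100, step_ms = 200),
               "step_ms")
  expect_silent(make_windows(1000, 1000, window_ms = 100, step_ms = 200,
                             allow_gaps = TRUE))
  expect_error(make_windows(100, 1000, window_ms = 400), "shorter")
})

test_that("window labels follow the midpoint rule (majority as option)", {
  truth <- make_truth(2000, list(c(500, 1200)))
  w <- make_windows(2000, 1000, window_ms = 400, step_ms = 100)
  lab <- label_windows(w, truth)
  # window [600, 1000): fully inside the active span
  expect_equal(as.character(lab[w$start_sample == 600]), "active")
  # window [1100, 1500): midpoint 1300 is idle although 100 ms overlap
  expect_equal(as.character(lab[w$start_sample == 1100]), "idle")

  maj <- label_windows(w, truth, rule = "majority")
  mid <- label_windows(w, truth, rule = "midpoint")
  straddle <- w$start_sample < 1200 & w$end_sample > 500 &
    !(w$start_sample >= 500 & w$end_sample <= 1200)
  expect_true(all(maj[!straddle] == mid[!straddle]))
})

test_that("three-class labels preserve the stimulus type", {
  truth <- make_truth(1500, list(c(100, 400), c(700, 1000)), codes = c(1L, 2L))
  w <- make_windows(1500, 1000, window_ms = 200, step_ms = 100)
  lab3 <- label_windows(w, truth, collapse = FALSE)
  expect_setequal(levels(lab3), c("idle", "own", "other"))
  expect_equal(as.character(lab3[w$start_sample == 200]), "own")
  expect_equal(as.character(lab3[w$start_sample == 800]), "other")
  lab2 <- label_windows(w, truth, collapse = TRUE)
  expect_equal(as.character(lab2[w$start_sample == 800]), "active")
})

test_that("operators match their frozen hand-computed examples", {
  expect_equal(line_length(c(1, 3, 2)), 3)
  expect_equal(rms(c(3, 4)), sqrt(12.5))
  expect_equal(slope(c(0, 1, 2), fs = 1000), 1000)
  expect_equal(avg_amplitude(rep(2.5, 10)), 2.5)
  expect_equal(slope(rep(2.5, 10), fs = 500), 0)
  expect_equal(line_length(rep(2.5, 10)), 0)
  expect_equal(rms(rep(-2.5, 10)), 2.5)
  expect_error(avg_amplitude(1), "2 samples")
  expect_error(slope(numeric(0), 1000), "2 samples")
})

test_that("operators agree with brute-force oracles on random windows", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(2:200, 1)
    x <- stats::rnorm(n, sd = stats::runif(1, 0.1, 10))
    fs <- sample(c(500, 1000, 2000), 1)
    expect_equal(avg_amplitude(x), bf_amplitude(x), tolerance = 1e-9)
    expect_equal(rms(x), bf_rms(x), tolerance = 1e-9)
    expect_equal(slope(x, fs), bf_slope(x, fs), tolerance = 1e-9)
    expect_equal(line_length(x), bf_line_length(x), tolerance = 1e-9)
  }
})

test_that("vectorised window operators equal per-window evaluation", {
  set.seed(7)
  x <- stats::rnorm(3000)
  w <- make_windows(3000, 1000, window_ms = 250, step_ms = 50)
  ops <- seegstate:::window_ops(x, w, 1000)
  for (i in sample(nrow(w), 10)) {
    seg <- x[(w$start_sample[i] + 1):w$end_sample[i]]
    expect_equal(unname(ops[i, "A"]), avg_amplitude(seg), tolerance = 1e-10)
    expect_equal(unname(ops[i, "RMS"]), rms(seg), tolerance = 1e-10)
    expect_equal(unname(ops[i, "k"]), slope(seg, 1000), tolerance = 1e-8)
    expect_equal(unname(ops[i, "L"]), line_length(seg), tolerance = 1e-10)
  }
})

test_that("operator inequalities hold on arbitrary windows", {
  set.seed(11)
  for (i in 1:50) {
    x <- stats::rnorm(sample(2:50, 1))
    expect_gte(rms(x), abs(avg_amplitude(x)))
  }
  expect_identical(line_length(rep(1.3, 9)), 0)
  x <- c(1, 1, 1.0001)
  expect_gt(line_length(x), 0)
})

test_that("feature matrix has deterministic (trace, channel, operator) layout", {
  fs <- 1000
  set.seed(3)
  mk_trace <- function(kind, n_ch) {
    d <- matrix(abs(stats::rnorm(n_ch * 1000)), n_ch)
    trace_set(d, fs, data.frame(id = sprintf("c%d", 1:n_ch), shaft = "A",
                                contact = 1:n_ch), kind)
  }
  traces <- list(high_gamma = mk_trace("high_gamma", 3),
                 erp = mk_trace("erp", 3))
  sel <- list(high_gamma = c("c1", "c3"), erp = "c2")
  w <- make_windows(1000, fs, window_ms = 200, step_ms = 100)
  fe <- extract_features(traces, sel, w, "all16")
  expect_equal(ncol(fe$x), 2 * 4 + 1 * 4)
  expect_equal(colnames(fe$x)[1:4],
               paste("high_gamma.c1", c("A", "RMS", "k", "L"), sep = "."))
  # four-type subset: 3 high-gamma ops x 2 channels + erp L x 1 channel
  fe4 <- extract_features(traces, sel, w, "four_type")
  expect_equal(ncol(fe4$x), 2 * 3 + 1)
  expect_true(all(fe4$col_info$op %in% c("A", "RMS", "L")))
  # single-feature restriction
  fe1 <- extract_features(traces, sel, w, "single:erp:L")
  expect_equal(ncol(fe1$x), 1)
  expect_error(extract_features(traces, list(high_gamma = character(0),
                                             erp = character(0)), w),
               "empty")
})

test_that("feature-dimension selection keeps the discriminative columns", {
  set.seed(5)
  n <- 200
  lab <- rep(c(1, -1), each = n / 2)
  x <- matrix(stats::rnorm(n * 12), n)
  x[, 4] <- x[, 4] + (lab == -1) * 3   # planted discriminative column
  sel <- select_feature_dims(x, lab, keep = 3, n_perm = 200, seed = 9)
  expect_true(sel$kept[4])
  expect_equal(sum(sel$kept), 3)
  expect_lt(sel$p[4], min(sel$p[-4]) + 1e-12)

  small <- select_feature_dims(x[, 1:5], lab, keep = 10, n_perm = 100,
                               seed = 1)
  expect_equal(sum(small$kept), 5)  # fewer columns than keep: all kept

  xd <- cbind(x[, 1:3], 0)  # degenerate column
  seld <- select_feature_dims(xd, lab, keep = 2, n_perm = 100, seed = 2)
  expect_equal(seld$p[4], 1)
})

test_that("PCA reduction retains components by explained variance", {
  set.seed(8)
  v <- stats::rnorm(6)
  rank1 <- outer(stats::rnorm(50), v) + matrix(stats::rnorm(300), 50) * 1e-8
  p1 <- pca_reduce(rank1, scale. = FALSE)
  expect_equal(p1$ncomp, 1)

  iso <- matrix(stats::rnorm(5000 * 10), 5000)
  p10 <- pca_reduce(iso, threshold = 0.95)
  expect_equal(p10$ncomp, 10)

  # projection uses training centring/scaling only
  tr <- matrix(stats::rnorm(100 * 4), 100)
  fit <- pca_reduce(tr)
  z <- pca_project(fit, tr)
  expect_equal(ncol(z), fit$ncomp)
  expect_equal(unname(colMeans(z)), rep(0, ncol(z)), tolerance = 1e-10)
  expect_error(pca_reduce(tr[1, , drop = FALSE]), "2 rows")
})

test_that("trace z-scoring and smoothing behave as affine/unit-area maps", {
  set.seed(13)
  fs <- 1000
  d <- matrix(abs(stats::rnorm(2 * 3000)) + 1, 2)
  trc <- trace_set(d, fs, data.frame(id = c("a", "b"), shaft = "A",
                                     contact = 1:2), "high_gamma")
  ev <- event_table(c(500, 1500, 2400), rep("own", 3), 300, fs)
  z <- zscore_traces(trc, ev)
  # pooled baseline samples of the z-scored trace have mean 0, sd 1
  idx <- unlist(lapply(ev$onset_sample, function(o) (o - 199):o))
  expect_equal(mean(z$data[1, idx]), 0, tolerance = 1e-10)
  expect_equal(stats::sd(z$data[1, idx]), 1, tolerance = 1e-10)
  sm <- smooth_traces(z, width_ms = 80)
  cst <- z
  cst$data[] <- 2.5
  expect_equal(smooth_traces(cst)$data, cst$data, tolerance = 1e-12)
  expect_lt(stats::var(sm$data[1, ]), stats::var(z$data[1, ]))
})
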