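# Transition estimation, GMM emissions, HMM decoding, baselines, CV.

test_that("transition matrix counts label pairs and normalizes rows", {
  tf <- fit_transition_matrix(c("I", "I", "A", "A", "I"),
                              states = c("I", "A"))
  expect_equal(unname(tf$trans), matrix(0.5, 2, 2))
  expect_equal(tf$pi, c(3 / 5, 2 / 5))

  expect_error(fit_transition_matrix(rep("I", 10), states = c("I", "A")),
               "never observed")
  expect_warning(tf2 <- fit_transition_matrix(c("I", "A"),
                                              states = c("I", "A")),
                 "uniform")
  expect_equal(unname(tf2$trans["A", ]), c(0.5, 0.5))
})

test_that("transitions are not counted across segment seams", {
  segs <- list(c("I", "I", "A"), c("A", "A", "I"))
  tf <- fit_transition_matrix(segs, states = c("I", "A"))
  # pairs: (I,I), (I,A) | (A,A), (A,I) -- no (A,A) across the seam
  expect_equal(unname(tf$trans["I", ]), c(0.5, 0.5))
  expect_equal(unname(tf$trans["A", ]), c(0.5, 0.5))
})

test_that("transition estimates converge to generative probabilities", {
  set.seed(41)
  P <- matrix(c(0.95, 0.05, 0.2, 0.8), 2, byrow = TRUE,
              dimnames = list(c("idle", "active"), c("idle", "active")))
  n <- 10000
  s <- integer(n); s[1] <- 1
  for (t in 2:n) s[t] <- sample(1:2, 1, prob = P[s[t - 1], ])
  labs <- c("idle", "active")[s]
  tf <- fit_transition_matrix(labs, states = c("idle", "active"))
  expect_lt(max(abs(tf$trans - P)), 0.02)
})

test_that("GMM emissions pick the generative component count", {
  set.seed(42)
  one <- matrix(stats::rnorm(600 * 2), 600)
  two <- rbind(matrix(stats::rnorm(300 * 2, -4), 300),
               matrix(stats::rnorm(300 * 2, 4), 300))
  labels <- factor(rep(c("idle", "active"), each = 600),
                   levels = c("idle", "active"))
  em <- fit_gmm_emissions(rbind(one, two), labels, k_max = 5, seed = 1)
  expect_equal(em$idle$G, 1)
  expect_equal(em$active$G, 2)
  # density evaluation integrates weights properly (log scale, finite)
  ll <- seegstate:::gmm_logdens(em$active, two[1:10, ])
  expect_true(all(is.finite(ll)))
})

test_that("degenerate emission inputs fall back without failure", {
  dup <- matrix(1, 50, 2)
  labels <- factor(rep(c("idle", "active"), 25), levels = c("idle", "active"))
  em <- suppressWarnings(fit_gmm_emissions(dup, labels, k_max = 5, seed = 2))
  expect_true(all(is.finite(seegstate:::gmm_logdens(em$idle,
                                                    matrix(1, 3, 2)))))
  few <- matrix(stats::rnorm(8 * 3), 8)
  lab2 <- factor(c(rep("idle", 5), rep("active", 3)),
                 levels = c("idle", "active"))
  w <- testthat::capture_warnings(fit_gmm_emissions(few, lab2, k_max = 5,
                                                    seed = 3))
  expect_true(any(grepl("single-Gaussian", w)))
})

test_that("decoding equals exhaustive path enumeration on small instances", {
  set.seed(43)
  for (i in 1:40) {
    k <- sample(2:3, 1)
    n <- sample(2:8, 1)
    Tm <- matrix(stats::runif(k * k, 0.05, 1), k)
    Tm <- Tm / rowSums(Tm)
    pi0 <- stats::runif(k, 0.05, 1); pi0 <- pi0 / sum(pi0)
    ll <- matrix(stats::rnorm(n * k), n)
    states <- paste0("s", seq_len(k))
    model <- list(states = states, trans = Tm, pi = pi0)
    got <- hmm_decode(model, loglik = ll)
    want <- bf_best_path(ll, Tm, pi0)
    expect_equal(as.integer(got), want, info = paste("instance", i))
  }
})

test_that("identity transitions freeze the initial state", {
  model <- list(states = c("idle", "active"), trans = diag(2),
                pi = c(1, 0))
  ll <- matrix(stats::rnorm(20), 10, 2)
  ll[, 2] <- ll[, 2] + 100   # active emissions much more likely
  out <- hmm_decode(model, loglik = ll)
  expect_true(all(out == "idle"))
})

test_that("exact ties resolve toward idle", {
  model <- list(states = c("idle", "active"),
                trans = matrix(0.5, 2, 2), pi = c(0.5, 0.5))
  ll <- matrix(0, 6, 2)
  expect_true(all(hmm_decode(model, loglik = ll) == "idle"))
  expect_true(all(hmm_decode(model, loglik = ll,
                             method = "filtering") == "idle"))
})

test_that("decoding rejects non-finite features", {
  model <- list(states = c("idle", "active"),
                trans = matrix(0.5, 2, 2), pi = c(0.5, 0.5),
                emissions = NULL)
  x <- matrix(c(1, NA), 1)
  expect_error(hmm_decode(model, x), "non-finite")
})

test_that("baseline classifiers separate linearly separable features", {
  set.seed(44)
  x <- rbind(matrix(stats::rnorm(100 * 2, -3), 100),
             matrix(stats::rnorm(100 * 2, 3), 100))
  y <- factor(rep(c("idle", "active"), each = 100),
              levels = c("idle", "active"))
  for (kind in c("lda", "svm", "rf")) {
    m <- fit_baseline(kind, x, y, seed = 1)
    expect_equal(mean(predict_baseline(m, x) == y), 1,
                 info = kind)
  }
  expect_error(fit_baseline("lda", x, factor(rep("idle", 200))),
               "single class")
  # RF reproducibility under a fixed seed
  m1 <- fit_baseline("rf", x, y, seed = 9)
  m2 <- fit_baseline("rf", x, y, seed = 9)
  xt <- matrix(stats::rnorm(40), 20)
  expect_identical(predict_baseline(m1, xt), predict_baseline(m2, xt))
})

cv_fixture <- function(n = 600, seed = 45, sep = 4) {
  set.seed(seed)
  lab <- factor(rep(rep(c("idle", "active"), each = 20), length.out = n),
                levels = c("idle", "active"))
  x <- matrix(stats::rnorm(n * 6), n)
  x[lab == "active", 1:3] <- x[lab == "active", 1:3] + sep
  w <- make_windows((n - 1) * 50 + 400, 1000, 400, 50)[1:n, ]
  structure(list(x = x, windows = w, labels = lab,
                 col_info = data.frame(trace = "high_gamma",
                                       channel = paste0("c", 1:6),
                                       op = "A")),
            class = "window_features")
}

test_that("cross-validation covers the stream once with consecutive folds", {
  fe <- cv_fixture()
  cv <- run_cv(fe, classifier = "lda", n_perm = 50, seed = 2)
  expect_equal(length(cv$predictions), 600)
  expect_equal(as.vector(table(cv$fold)), rep(200L, 3))
  expect_equal(which(cv$fold == 2)[1], 201L)
  expect_gt(mean(cv$predictions == fe$labels), 0.95)
  cvh <- run_cv(fe, classifier = "hmm", n_perm = 50, seed = 2)
  expect_gt(mean(cvh$predictions == fe$labels), 0.95)
})

test_that("shuffled labels drive window accuracy to chance", {
  fe <- cv_fixture()
  set.seed(46)
  shuffled <- sample(fe$labels)
  cv <- suppressWarnings(run_cv(fe, labels = shuffled, classifier = "lda",
                                n_perm = 50, seed = 3))
  # evaluated against the true labels the predictions are uninformative
  expect_lt(mean(cv$predictions == fe$labels), 0.62)
})

test_that("folds missing a state raise a diagnostic error", {
  fe <- cv_fixture()
  lab <- fe$labels
  lab[1:200] <- "idle"   # first fold single-class
  expect_error(run_cv(fe, labels = lab, classifier = "lda", n_perm = 20,
                      seed = 1), "lacks a state")
})
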