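# GMM-HMM state decoding plus LDA/SVM/RF baselines under consecutive
# three-fold cross-validation.
#
#' @importFrom mclust Mclust mclustBIC
NULL
#
# The HMM's transition matrix is estimated from consecutive training labels,
# its per-state emission densities are Gaussian mixtures (component count by
# BIC), and decoding is the most-probable joint state path (max-product /
# Viterbi) in log space; a forward-filtering argmax decoder is available as
# an alternative.

#' Estimate an HMM transition matrix from labelled training sequences
#'
#' @param labels a factor/character vector of states in stream order, or a
#'   list of such vectors (one per contiguous segment; transitions are not
#'   counted across segment seams).
#' @param states state alphabet in order (first state = idle); defaults to
#'   the factor levels or the sorted unique labels.
#' @return list with row-stochastic matrix \code{trans}, initial distribution
#'   \code{pi} (empirical state frequencies) and \code{states}.
#' @export
fit_transition_matrix <- function(labels, states = NULL) {
  segs <- if (is.list(labels) && !is.data.frame(labels)) labels
          else list(labels)
  if (is.null(states))
    states <- if (is.factor(segs[[1]])) levels(segs[[1]])
              else sort(unique(unlist(lapply(segs, as.character))))
  all_lab <- unlist(lapply(segs, as.character))
  if (length(all_lab) < 2L) stop("need at least 2 labels", call. = FALSE)
  if (!all(states %in% all_lab))
    stop("state(s) never observed in training labels: ",
         paste(setdiff(states, all_lab), collapse = ", "), call. = FALSE)
  k <- length(states)
  counts <- matrix(0, k, k, dimnames = list(states, states))
  for (seg in segs) {
    s <- match(as.character(seg), states)
    if (length(s) >= 2L)
      for (i in seq_len(length(s) - 1L))
        counts[s[i], s[i + 1L]] <- counts[s[i], s[i + 1L]] + 1
  }
  rs <- rowSums(counts)
  trans <- counts
  for (i in seq_len(k)) {
    if (rs[i] == 0) {
      warning("state '", states[i],
              "' has no outgoing transitions; row set to uniform",
              call. = FALSE)
      trans[i, ] <- 1 / k
    } else trans[i, ] <- counts[i, ] / rs[i]
  }
  pi0 <- as.numeric(table(factor(all_lab, levels = states))) / length(all_lab)
  list(trans = trans, pi = pi0, states = states)
}

#' Fit Gaussian-mixture emission densities per state
#'
#' For each state, a full-covariance Gaussian mixture is fitted to the
#' training rows of that state; the component count is chosen by BIC over
#' \code{1:k_max}.  Covariances are floored (ridge of \code{reg} times the
#' mean feature variance) for numerical safety.  States with fewer than
#' \code{k_max * d} rows fall back to a single Gaussian with a warning.
#'
#' @param x training feature matrix (rows x dims, typically PCA scores).
#' @param labels state label per row.
#' @param k_max maximum number of mixture components.
#' @param seed integer seed (initialisation subsample).
#' @param reg covariance floor, relative to the mean feature variance.
#' @param init_subset initialisation subsample size for the mixture fit (component count and starting parameters are fitted on this seeded subsample, then refined by one EM pass over all rows).
#' @return named list (one per state) of mixtures: \code{weights},
#'   \code{means} (d x k), \code{covs} (d x d x k), \code{G}.
#' @export
fit_gmm_emissions <- function(x, labels, k_max = 5, seed = NULL, reg = 1e-6,
                              init_subset = 300) {
  x <- as.matrix(x)
  d <- ncol(x)
  states <- if (is.factor(labels)) levels(labels) else sort(unique(labels))
  out <- list()
  for (si in seq_along(states)) {
    rows <- x[labels == states[si], , drop = FALSE]
    floor_val <- max(reg * mean(apply(x, 2, stats::var)), 1e-10)
    if (nrow(rows) < k_max * d + 2) {
      warning("state '", states[si],
              "' has too few rows; single-Gaussian fallback", call. = FALSE)
      out[[states[si]]] <- single_gaussian(rows, floor_val)
      next
    }
    # model selection (G by BIC) on a seeded subsample, then one EM
    # refinement pass over all rows of the state
    fit <- local_seed(child_seed(seed, si), {
      sub <- sample(nrow(rows), min(init_subset, nrow(rows)))
      f <- try(suppressWarnings(
        mclust::Mclust(rows[sub, , drop = FALSE], G = 1:k_max,
                       modelNames = "VVV", verbose = FALSE)), silent = TRUE)
      if (!is.null(f) && !inherits(f, "try-error") &&
          nrow(rows) > length(sub)) {
        ref <- try(suppressWarnings(
          mclust::em(modelName = "VVV", data = rows,
                     parameters = f$parameters)), silent = TRUE)
        if (!inherits(ref, "try-error") && !is.null(ref$parameters) &&
            all(is.finite(ref$parameters$mean)))
          f$parameters <- ref$parameters
      }
      f
    })
    if (is.null(fit) || inherits(fit, "try-error")) {
      out[[states[si]]] <- single_gaussian(rows, floor_val)
      next
    }
    G <- fit$G
    mu <- matrix(fit$parameters$mean, nrow = d)
    sig <- array(fit$parameters$variance$sigma, c(d, d, G))
    for (g in seq_len(G)) sig[, , g] <- sig[, , g] + diag(floor_val, d)
    out[[states[si]]] <- list(weights = fit$parameters$pro, means = mu,
                              covs = sig, G = G)
  }
  out
}

single_gaussian <- function(rows, floor_val) {
  d <- ncol(rows)
  cv <- if (nrow(rows) > 1) stats::cov(rows) else diag(1, d)
  list(weights = 1, means = matrix(colMeans(rows), nrow = d),
       covs = array(cv + diag(floor_val, d), c(d, d, 1)), G = 1L)
}

# Log-density of a Gaussian mixture at each row of x.
gmm_logdens <- function(mix, x) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- ncol(x)
  comp <- matrix(NA_real_, n, mix$G)
  for (g in seq_len(mix$G)) {
    ch <- chol(mix$covs[, , g])
    cent <- sweep(x, 2, mix$means[, g])
    z <- backsolve(ch, t(cent), transpose = TRUE)
    comp[, g] <- log(mix$weights[g]) - sum(log(diag(ch))) -
      0.5 * d * log(2 * pi) - 0.5 * colSums(z^2)
  }
  apply(comp, 1, log_sum_exp)
}

#' Assemble a GMM-HMM model
#'
#' @param trans_fit result of [fit_transition_matrix()].
#' @param emissions result of [fit_gmm_emissions()] (same state order).
#' @return list of class \code{hmm_model}.
#' @export
hmm_model <- function(trans_fit, emissions) {
  stopifnot(identical(trans_fit$states, names(emissions)))
  structure(list(states = trans_fit$states, trans = trans_fit$trans,
                 pi = trans_fit$pi, emissions = emissions),
            class = "hmm_model")
}

#' Decode a feature stream with a GMM-HMM
#'
#' \code{"viterbi"} (default) returns the most probable joint state path by
#' max-product recursion in log space; \code{"filtering"} returns the
#' per-window argmax of the forward (filtering) distribution.  Ties break
#' toward the first state (idle), then lower state index.
#'
#' @param model an [hmm_model()].
#' @param x feature stream (windows x dims, in the model's feature space), or
#'   a precomputed log-likelihood matrix via \code{loglik}.
#' @param method decoding recursion.
#' @param loglik optional windows x states log-likelihood matrix (overrides
#'   \code{x}).
#' @return factor of decoded states, one per window.
#' @export
hmm_decode <- function(model, x = NULL, method = c("viterbi", "filtering"),
                       loglik = NULL) {
  method <- match.arg(method)
  if (is.null(loglik)) {
    if (any(!is.finite(as.matrix(x))))
      stop("non-finite feature values", call. = FALSE)
    loglik <- vapply(model$emissions, gmm_logdens, numeric(nrow(as.matrix(x))),
                     x = as.matrix(x))
    loglik <- matrix(loglik, ncol = length(model$states))
  }
  n <- nrow(loglik)
  k <- length(model$states)
  lt <- log(model$trans)
  lp <- log(model$pi)
  path <- integer(n)
  if (method == "viterbi") {
    delta <- matrix(-Inf, n, k)
    psi <- matrix(1L, n, k)
    delta[1, ] <- lp + loglik[1, ]
    for (t in 2:n) {
      for (j in seq_len(k)) {
        cand <- delta[t - 1, ] + lt[, j]
        psi[t, j] <- which.max(cand)      # first max = lowest state index
        delta[t, j] <- cand[psi[t, j]] + loglik[t, j]
      }
    }
    path[n] <- which.max(delta[n, ])
    for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  } else {
    alpha <- lp + loglik[1, ]
    path[1] <- which.max(alpha)
    for (t in 2:n) {
      alpha <- vapply(seq_len(k), function(j)
        log_sum_exp(alpha + lt[, j]), numeric(1)) + loglik[t, ]
      alpha <- alpha - max(alpha)
      path[t] <- which.max(alpha)
    }
  }
  factor(model$states[path], levels = model$states)
}

#' Fit a per-window baseline classifier
#'
#' LDA, radial-kernel SVM, or random forest, predicting each window
#' independently.  Class imbalance is handled by class-frequency weighting
#' (uniform priors for LDA, inverse-frequency class weights for SVM and RF).
#'
#' @param kind \code{"lda"}, \code{"svm"} or \code{"rf"}.
#' @param x training feature matrix.
#' @param labels factor of training labels.
#' @param seed integer seed (RF and SVM reproducibility).
#' @return classifier object of class \code{baseline_model}.
#' @export
fit_baseline <- function(kind = c("lda", "svm", "rf"), x, labels,
                         seed = NULL) {
  kind <- match.arg(kind)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L)
    stop("training set contains a single class", call. = FALSE)
  x <- as.matrix(x)
  colnames(x) <- paste0("V", seq_len(ncol(x)))
  k <- nlevels(labels)
  freq <- table(labels)
  w <- as.numeric(sum(freq) / (k * freq))
  names(w) <- names(freq)
  fit <- local_seed(seed, switch(kind,
    lda = MASS::lda(x, grouping = labels, prior = rep(1 / k, k)),
    svm = e1071::svm(x, labels, kernel = "radial", class.weights = w),
    rf = randomForest::randomForest(x, labels, ntree = 250,
                                    classwt = w / sum(w))))
  structure(list(kind = kind, fit = fit, levels = levels(labels)),
            class = "baseline_model")
}

#' @rdname fit_baseline
#' @param model a fitted \code{baseline_model}.
#' @export
predict_baseline <- function(model, x) {
  x <- as.matrix(x)
  colnames(x) <- paste0("V", seq_len(ncol(x)))
  p <- switch(model$kind,
              lda = stats::predict(model$fit, x)$class,
              svm = stats::predict(model$fit, x),
              rf = stats::predict(model$fit, x))
  factor(as.character(p), levels = model$levels)
}

#' Consecutive three-fold cross-validated state decoding
#'
#' The window stream is split into three consecutive, equal-length segments
#' (boundaries at \code{floor(n/3)} and \code{floor(2n/3)}).  For each
#' rotation, permutation feature selection, column scaling + PCA, and the
#' classifier are fitted on the two training segments only, and the held-out
#' segment is predicted; concatenated predictions cover the stream exactly
#' once.
#'
#' @param features a \code{window_features} object with labels, or a plain
#'   matrix plus \code{labels}.
#' @param labels factor of window labels (defaults to
#'   \code{features$labels}).
#' @param classifier \code{"hmm"}, \code{"lda"}, \code{"svm"} or
#'   \code{"rf"}.
#' @param keep feature dimensions kept by permutation selection (per
#'   contrast).
#' @param n_perm permutations for feature selection.
#' @param pca_threshold cumulative explained-variance threshold.
#' @param k_max maximum GMM components per state.
#' @param decode HMM decoding method (\code{"viterbi"} or
#'   \code{"filtering"}).
#' @param seed integer seed.
#' @param pairwise use pairwise (per state pair) feature selection; default
#'   automatically for three or more states.
#' @return list of class \code{cv_result}: \code{predictions} (factor over
#'   the full stream), \code{labels}, \code{fold} assignment, per-fold
#'   details.
#' @export
run_cv <- function(features, labels = NULL, classifier = "hmm", keep = 10,
                   n_perm = 200, pca_threshold = 0.95, k_max = 5,
                   decode = "viterbi", seed = NULL, pairwise = NULL) {
  x <- if (inherits(features, "window_features")) features$x else features
  labels <- labels %||% features$labels
  labels <- as.factor(labels)
  n <- nrow(x)
  if (n < 6L) stop("stream too short for three folds", call. = FALSE)
  b <- c(floor(n / 3), floor(2 * n / 3))
  fold <- rep(3L, n)
  fold[seq_len(b[1])] <- 1L
  fold[(b[1] + 1):b[2]] <- 2L
  if (is.null(pairwise)) pairwise <- nlevels(labels) > 2L
  preds <- factor(rep(levels(labels)[1], n), levels = levels(labels))
  details <- list()
  for (r in 1:3) {
    test_idx <- which(fold == r)
    train_segs <- lapply(setdiff(1:3, r), function(f) which(fold == f))
    train_idx <- unlist(train_segs)
    tl <- labels[train_idx]
    if (any(tabulate(tl, nlevels(labels)) == 0) ||
        any(tabulate(labels[test_idx], nlevels(labels)) == 0))
      stop("fold ", r, " lacks a state (label counts: train ",
           paste(tabulate(tl, nlevels(labels)), collapse = "/"), ", test ",
           paste(tabulate(labels[test_idx], nlevels(labels)), collapse = "/"),
           ")", call. = FALSE)
    sel_seed <- child_seed(seed, r)
    sel <- if (pairwise)
      select_feature_dims_pairwise(x[train_idx, , drop = FALSE], tl,
                                   keep_per_pair = keep, n_perm = n_perm,
                                   seed = sel_seed)
    else select_feature_dims(x[train_idx, , drop = FALSE], tl, keep = keep,
                             n_perm = n_perm, seed = sel_seed)
    kc <- which(sel$kept)
    pca <- pca_reduce(x[train_idx, kc, drop = FALSE],
                      threshold = pca_threshold)
    tr_z <- pca_project(pca, x[train_idx, kc, drop = FALSE])
    te_z <- pca_project(pca, x[test_idx, kc, drop = FALSE])
    if (classifier == "hmm") {
      tf <- fit_transition_matrix(lapply(train_segs, function(i) labels[i]),
                                  states = levels(labels))
      em <- fit_gmm_emissions(tr_z, labels[train_idx], k_max = k_max,
                              seed = child_seed(seed, 10 + r))
      model <- hmm_model(tf, em)
      preds[test_idx] <- hmm_decode(model, te_z, method = decode)
    } else {
      model <- fit_baseline(classifier, tr_z, labels[train_idx],
                            seed = child_seed(seed, 10 + r))
      preds[test_idx] <- predict_baseline(model, te_z)
    }
    details[[r]] <- list(selection = sel, ncomp = pca$ncomp)
  }
  structure(list(predictions = preds, labels = labels, fold = fold,
                 classifier = classifier, details = details),
            class = "cv_result")
}
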