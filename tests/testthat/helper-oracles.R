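# Independent brute-force oracles used to cross-check the implementation.

bf_amplitude <- function(x) sum(x) / length(x)

bf_rms <- function(x) sqrt(sum(x * x) / length(x))

bf_slope <- function(x, fs) {
  t <- (seq_along(x) - 1) / fs
  unname(stats::coef(stats::lm(x ~ t))[2])
}

bf_line_length <- function(x) {
  s <- 0
  for (i in seq_len(length(x) - 1)) s <- s + abs(x[i + 1] - x[i])
  s
}

# Exhaustive enumeration of the most probable joint state path.
# Tie-break mirrors lexicographic preference for lower state indices.
bf_best_path <- function(loglik, trans, pi0) {
  n <- nrow(loglik)
  k <- ncol(loglik)
  paths <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))[, n:1, drop = FALSE]
  # order rows lexicographically so the first argmax is the tie-preferred path
  ord <- do.call(order, as.data.frame(paths))
  paths <- paths[ord, , drop = FALSE]
  lp <- apply(paths, 1, function(s) {
    v <- log(pi0[s[1]]) + loglik[1, s[1]]
    if (n > 1)
      for (t in 2:n) v <- v + log(trans[s[t - 1], s[t]]) + loglik[t, s[t]]
    v
  })
  unname(paths[which.max(lp), ])
}

# Naive period matcher re-deriving the counting contract interval by
# interval, used to cross-check match_periods on random instances.
bf_match <- function(actual, detected, tol = 0.4) {
  na <- nrow(actual); nd <- nrow(detected)
  ov <- function(i, j) actual$start_s[i] < detected$end_s[j] &&
    detected$start_s[j] < actual$end_s[i]
  amat <- matrix(FALSE, max(na, 1), max(nd, 1))
  if (na > 0 && nd > 0)
    for (i in 1:na) for (j in 1:nd) amat[i, j] <- ov(i, j)
  TP <- 0; FP <- 0; FN <- 0
  a_used <- rep(FALSE, na); d_used <- rep(FALSE, nd)
  diffs <- NULL
  pen <- function(od, ed) {
    TP <<- TP + 1
    if (abs(od) > tol) FP <<- FP + 1
    if (abs(ed) > tol) FN <<- FN + 1
    diffs <<- rbind(diffs, c(od, ed))
  }
  if (nd > 0) for (j in 1:nd) {
    hits <- if (na > 0) which(amat[, j] & !a_used) else integer(0)
    if (length(hits) >= 2) {
      pen(detected$start_s[j] - actual$start_s[hits[1]],
          detected$end_s[j] - actual$end_s[hits[length(hits)]])
      FP <- FP + length(hits) - 1
      a_used[hits] <- TRUE; d_used[j] <- TRUE
    }
  }
  if (na > 0) for (i in 1:na) {
    if (a_used[i]) next
    hits <- if (nd > 0) which(amat[i, ] & !d_used) else integer(0)
    if (length(hits) == 0) next
    pen(detected$start_s[hits[1]] - actual$start_s[i],
        detected$end_s[hits[1]] - actual$end_s[i])
    a_used[i] <- TRUE; d_used[hits[1]] <- TRUE
    if (length(hits) > 1) { FP <- FP + length(hits) - 1; d_used[hits] <- TRUE }
  }
  FN <- FN + sum(!a_used)
  FP <- FP + sum(!d_used)
  list(TP = TP, FP = FP, FN = FN, diffs = diffs)
}

# Random non-overlapping sorted interval set in [0, span].
random_periods <- function(n, span = 20) {
  if (n == 0) return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  pts <- sort(stats::runif(2 * n, 0, span))
  data.frame(start_s = pts[seq(1, 2 * n, 2)], end_s = pts[seq(2, 2 * n, 2)])
}
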