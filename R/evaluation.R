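# Period-level detection metrics.
#
# Window predictions are merged into maximal same-state periods, matched
# against the actual active periods by overlap, and counted as TP/FP/FN/TN
# with two refinements: a TP whose onset (end) differs from the actual onset
# (end) by more than 400 ms additionally counts one FP (FN), and a detected
# period penetrating two actual periods counts 1 TP + 1 FP, with its onset
# difference taken against the first actual period and its end difference
# against the second.

#' Convert per-window predictions into state periods
#'
#' Maximal runs of identically-labelled windows become periods.  Each window
#' is attributed to the step-long interval centred on its midpoint, so a run
#' spans from the first window's midpoint minus half a step to the last
#' window's midpoint plus half a step.
#'
#' @param predictions factor of window labels.
#' @param windows a [make_windows()] result.
#' @param state the state whose periods to extract (default
#'   \code{"active"}).
#' @return data.frame of class \code{period_set} with columns \code{start_s},
#'   \code{end_s} (sorted, non-overlapping).
#' @export
windows_to_periods <- function(predictions, windows, state = "active") {
  stopifnot(length(predictions) == nrow(windows))
  step_s <- if (nrow(windows) > 1) stats::median(diff(windows$mid_s))
            else windows$end_s[1] - windows$start_s[1]
  act <- as.character(predictions) == state
  r <- rle(act)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  out <- data.frame(start_s = windows$mid_s[starts[keep]] - step_s / 2,
                    end_s = windows$mid_s[ends[keep]] + step_s / 2)
  class(out) <- c("period_set", "data.frame")
  out
}

#' Actual state periods from a ground-truth timeline
#'
#' @param truth a \code{ground_truth} object.
#' @param state \code{"active"} (any stimulus type) or one of the stimulus
#'   type names.
#' @return \code{period_set} data.frame.
#' @export
truth_to_periods <- function(truth, state = "active") {
  on <- if (state == "active") truth$states > 0
        else truth$states == match(state, truth$types)
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  out <- data.frame(start_s = (starts[keep] - 1) / truth$fs,
                    end_s = ends[keep] / truth$fs)
  class(out) <- c("period_set", "data.frame")
  out
}

#' Match detected against actual active periods
#'
#' Implements overlap-based period matching with the 400-ms boundary penalty
#' and the penetration rule (see the package vignette for the full counting
#' contract).  True negatives are counted over actual idle periods (the gaps
#' between actual active periods within \code{session_span}) that contain no
#' detected active interval.
#'
#' @param actual,detected \code{period_set} data.frames (columns
#'   \code{start_s}, \code{end_s}).
#' @param tol_s boundary tolerance in seconds (default 0.4).
#' @param session_span optional \code{c(start_s, end_s)} of the evaluated
#'   stream; enables leading/trailing idle periods in the TN count.
#' @return list of class \code{match_ledger}: counts \code{TP}, \code{FP},
#'   \code{FN}, \code{TN}, a data.frame \code{diffs} with one row per TP
#'   (\code{onset_diff_s}, \code{end_diff_s} = detected minus actual), and
#'   per-interval \code{annotations}.
#' @export
match_periods <- function(actual, detected, tol_s = 0.4,
                          session_span = NULL) {
  na <- nrow(actual)
  nd <- nrow(detected)
  overlaps <- function(a0, a1, b0, b1) a0 < b1 & b0 < a1
  # overlap incidence matrix: actual x detected
  ov <- matrix(FALSE, na, nd)
  if (na > 0 && nd > 0)
    for (i in seq_len(na))
      ov[i, ] <- overlaps(actual$start_s[i], actual$end_s[i],
                          detected$start_s, detected$end_s)
  TP <- 0L; FP <- 0L; FN <- 0L
  diffs <- list()
  ann_a <- rep(NA_character_, na)
  ann_d <- rep(NA_character_, nd)
  used_a <- rep(FALSE, na)
  used_d <- rep(FALSE, nd)

  add_tp <- function(onset_diff, end_diff) {
    TP <<- TP + 1L
    diffs[[length(diffs) + 1L]] <<- data.frame(onset_diff_s = onset_diff,
                                               end_diff_s = end_diff)
    if (abs(onset_diff) > tol_s) FP <<- FP + 1L
    if (abs(end_diff) > tol_s) FN <<- FN + 1L
  }

  # 1. penetration: one detected period overlapping >= 2 actual periods
  for (j in seq_len(nd)) {
    hits <- which(ov[, j] & !used_a)
    if (length(hits) >= 2L) {
      first <- hits[1]; last <- hits[length(hits)]
      add_tp(detected$start_s[j] - actual$start_s[first],
             detected$end_s[j] - actual$end_s[last])
      FP <- FP + (length(hits) - 1L)
      used_a[hits] <- TRUE
      used_d[j] <- TRUE
      ann_d[j] <- sprintf("TP+%dFP (penetration of %d actual)",
                          length(hits) - 1L, length(hits))
      ann_a[hits] <- "matched (penetration)"
    }
  }
  # 2. one actual overlapped by several detected: 1 TP (first) + extra FPs
  for (i in seq_len(na)) {
    if (used_a[i]) next
    hits <- which(ov[i, ] & !used_d)
    if (length(hits) == 0L) next
    first <- hits[1]
    add_tp(detected$start_s[first] - actual$start_s[i],
           detected$end_s[first] - actual$end_s[i])
    used_a[i] <- TRUE
    used_d[first] <- TRUE
    ann_a[i] <- "matched"
    ann_d[first] <- "TP"
    if (length(hits) > 1L) {
      extra <- hits[-1]
      FP <- FP + length(extra)
      used_d[extra] <- TRUE
      ann_d[extra] <- "FP (extra overlap)"
    }
  }
  # 3. leftovers
  FN <- FN + sum(!used_a)
  ann_a[!used_a] <- "FN (missed)"
  FP <- FP + sum(!used_d)
  ann_d[!used_d] <- "FP (spurious)"

  # 4. TN: actual idle periods containing no detected active interval
  # (a boundary-crossing TP detection does not void the neighbouring idle
  # period; only a detection falling inside it does)
  idle <- idle_periods(actual, session_span)
  TN <- 0L
  if (nrow(idle) > 0) {
    for (i in seq_len(nrow(idle))) {
      hit <- nd > 0 && any(detected$start_s >= idle$start_s[i] &
                             detected$end_s <= idle$end_s[i])
      if (!hit) TN <- TN + 1L
    }
  }
  diffs <- if (length(diffs)) do.call(rbind, diffs)
           else data.frame(onset_diff_s = numeric(0), end_diff_s = numeric(0))
  structure(list(TP = TP, FP = FP, FN = FN, TN = TN, diffs = diffs,
                 annotations = list(actual = ann_a, detected = ann_d)),
            class = "match_ledger")
}

# Gaps between actual active periods (plus lead/trail if a span is given).
idle_periods <- function(actual, session_span = NULL) {
  if (nrow(actual) == 0) {
    if (is.null(session_span))
      return(data.frame(start_s = numeric(0), end_s = numeric(0)))
    return(data.frame(start_s = session_span[1], end_s = session_span[2]))
  }
  starts <- actual$end_s[-nrow(actual)]
  ends <- actual$start_s[-1]
  if (!is.null(session_span)) {
    if (actual$start_s[1] > session_span[1]) {
      starts <- c(session_span[1], starts)
      ends <- c(actual$start_s[1], ends)
    }
    if (actual$end_s[nrow(actual)] < session_span[2]) {
      starts <- c(starts, actual$end_s[nrow(actual)])
      ends <- c(ends, session_span[2])
    }
  }
  keep <- ends > starts
  data.frame(start_s = starts[keep], end_s = ends[keep])
}

#' @export
print.match_ledger <- function(x, ...) {
  cat(sprintf("<match_ledger> TP=%d FP=%d FN=%d TN=%d\n", x$TP, x$FP, x$FN,
              x$TN))
  invisible(x)
}

#' Period-level detection scores
#'
#' Sensitivity = 100 TP / (TP + FN); precision = 100 TP / (TP + FP);
#' accuracy = 100 (TP + TN) / (TP + FP + TN + FN).  An indicator whose
#' denominator is zero is reported as \code{NA} with a warning.
#'
#' @param ledger a [match_periods()] result (or any list with TP/FP/FN/TN).
#' @return list with \code{sensitivity}, \code{precision}, \code{accuracy}
#'   (percent) and the \code{confusion} matrix.
#' @export
score <- function(ledger) {
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)", call. = FALSE)
      return(NA_real_)
    }
    100 * num / den
  }
  confusion <- matrix(c(ledger$TP, ledger$FN, ledger$FP, ledger$TN), 2, 2,
                      dimnames = list(actual = c("active", "idle"),
                                      detected = c("active", "idle")))
  list(sensitivity = safe(ledger$TP, ledger$TP + ledger$FN, "sensitivity"),
       precision = safe(ledger$TP, ledger$TP + ledger$FP, "precision"),
       accuracy = safe(ledger$TP + ledger$TN,
                       ledger$TP + ledger$FP + ledger$TN + ledger$FN,
                       "accuracy"),
       confusion = confusion)
}

#' Summarise onset/end timing differences across ledgers
#'
#' @param ledgers a \code{match_ledger} or list of them (e.g. across folds or
#'   sessions).
#' @return list with per-type mean, standard error and the pooled difference
#'   vectors (seconds; detected minus actual, overlapping pairs only).
#' @export
timing_summary <- function(ledgers) {
  if (inherits(ledgers, "match_ledger")) ledgers <- list(ledgers)
  onset <- unlist(lapply(ledgers, function(l) l$diffs$onset_diff_s))
  end <- unlist(lapply(ledgers, function(l) l$diffs$end_diff_s))
  se <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                    else NA_real_
  list(onset_mean_s = mean(onset), onset_se_s = se(onset),
       end_mean_s = mean(end), end_se_s = se(end),
       onset_diffs_s = onset, end_diffs_s = end, n_tp = length(onset))
}

#' Evaluate window predictions at the period level
#'
#' Convenience wrapper: periods from predictions and actual labels, matching,
#' scores and timing in one call.
#'
#' @param predictions factor of predicted window labels.
#' @param labels factor of actual window labels.
#' @param windows a [make_windows()] result.
#' @param state active-state label.
#' @param tol_s boundary tolerance (s).
#' @return list of class \code{detection_report}: \code{ledger},
#'   \code{sensitivity}, \code{precision}, \code{accuracy},
#'   \code{confusion}, \code{timing}.
#' @export
evaluate_detection <- function(predictions, labels, windows,
                               state = "active", tol_s = 0.4) {
  actual <- windows_to_periods(labels, windows, state = state)
  detected <- windows_to_periods(predictions, windows, state = state)
  span <- c(min(windows$start_s), max(windows$end_s))
  ledger <- match_periods(actual, detected, tol_s = tol_s,
                          session_span = span)
  sc <- score(ledger)
  structure(c(list(ledger = ledger, timing = timing_summary(ledger)), sc),
            class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf(
    "<detection_report> sensitivity %.1f%% | precision %.1f%% | accuracy %.1f%%\n",
    x$sensitivity, x$precision, x$accuracy))
  cat(sprintf("  TP=%d FP=%d FN=%d TN=%d | onset diff %.0f ms, end diff %.0f ms (n=%d)\n",
              x$ledger$TP, x$ledger$FP, x$ledger$FN, x$ledger$TN,
              1000 * x$timing$onset_mean_s, 1000 * x$timing$end_mean_s,
              x$timing$n_tp))
  invisible(x)
}

#' Plot actual versus detected active-state periods
#'
#' Draws the actual active periods as one row of bars and the detected
#' periods as a second row, over the session time axis.
#'
#' @param actual,detected \code{period_set} data.frames (or factors of
#'   window labels together with \code{windows}).
#' @param windows optional [make_windows()] result when labels are given.
#' @param xlim optional time range (s) to display.
#' @param ... passed to \code{plot}.
#' @return invisibly, \code{NULL}.
#' @export
plot_detection <- function(actual, detected, windows = NULL, xlim = NULL,
                           ...) {
  if (is.factor(actual)) actual <- windows_to_periods(actual, windows)
  if (is.factor(detected)) detected <- windows_to_periods(detected, windows)
  rng <- xlim %||% range(c(actual$start_s, actual$end_s,
                           detected$start_s, detected$end_s))
  graphics::plot(NA, xlim = rng, ylim = c(0, 3), xlab = "time (s)",
                 ylab = "", yaxt = "n", bty = "n", ...)
  graphics::axis(2, at = c(1, 2), labels = c("detected", "actual"),
                 las = 1, tick = FALSE)
  if (nrow(actual))
    graphics::rect(actual$start_s, 1.75, actual$end_s, 2.25,
                   col = "lightblue", border = NA)
  if (nrow(detected))
    graphics::rect(detected$start_s, 0.75, detected$end_s, 1.25,
                   col = "indianred", border = NA)
  invisible(NULL)
}

#' Permutation chance levels of the evaluation indicators
#'
#' Window labels are shuffled before feature selection and classification,
#' the full cross-validated pipeline is re-run, and the indicators are
#' evaluated against the actual labels; the chance level of each indicator is
#' the 95th percentile (linear interpolation) of its permutation
#' distribution.  Permutations with an undefined indicator (no detected
#' period) contribute 0 for precision.
#'
#' @param features a \code{window_features} object with labels.
#' @param classifier classifier kind, as in [run_cv()].
#' @param n_perm number of label permutations (desk-scale default 100).
#' @param percentile percentile defining the chance level.
#' @param seed integer seed.
#' @param ... passed to [run_cv()] (e.g. \code{n_perm} for feature selection
#'   via \code{select_n_perm}).
#' @param select_n_perm feature-selection permutations inside each run.
#' @return list with chance levels per indicator and the full permutation
#'   distributions.
#' @export
chance_level <- function(features, classifier = "hmm", n_perm = 100,
                         percentile = 95, seed = NULL, select_n_perm = 50,
                         ...) {
  labels <- features$labels
  dist <- matrix(NA_real_, n_perm, 3,
                 dimnames = list(NULL, c("sensitivity", "precision",
                                         "accuracy")))
  for (b in seq_len(n_perm)) {
    shuffled <- local_seed(child_seed(seed, b), sample(labels))
    res <- try(suppressWarnings(
      run_cv(features, labels = shuffled, classifier = classifier,
             n_perm = select_n_perm, seed = child_seed(seed, 1000 + b), ...)),
      silent = TRUE)
    if (inherits(res, "try-error")) next
    rep <- suppressWarnings(
      evaluate_detection(res$predictions, labels, features$windows))
    dist[b, ] <- c(rep$sensitivity,
                   if (is.na(rep$precision)) 0 else rep$precision,
                   rep$accuracy)
  }
  q <- apply(dist, 2, stats::quantile, probs = percentile / 100, na.rm = TRUE)
  list(sensitivity = q[["sensitivity"]], precision = q[["precision"]],
       accuracy = q[["accuracy"]], distributions = dist,
       percentile = percentile, n_perm = n_perm)
}
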