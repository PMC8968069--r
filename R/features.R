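# Sliding-window time-domain feature extraction.
#
# Four operators per selected channel and trace kind: average amplitude (A),
# root mean square (RMS), ordinary-least-squares slope against time (k, per
# second), and line-length (L, running sum of absolute sample-to-sample
# differences).  Features are computed on continuous z-scored traces, so all
# values are unitless.

#' Sliding-window layout over a session
#'
#' Windows start at 0 and advance by \code{step_ms}; the last window lies
#' fully inside the session.
#'
#' @param n_samples session length in samples.
#' @param fs sampling rate (Hz).
#' @param window_ms window length (ms), 150-500 in the reference analysis.
#' @param step_ms inter-window step (ms, default 50).
#' @param allow_gaps permit \code{step_ms > window_ms} (default FALSE).
#' @return data.frame of class \code{window_spec}: \code{start_sample} /
#'   \code{end_sample} (0-based, half-open), \code{start_s}, \code{end_s},
#'   \code{mid_s}; attributes \code{window_ms}, \code{step_ms}, \code{fs}.
#' @export
make_windows <- function(n_samples, fs, window_ms = 400, step_ms = 50,
                         allow_gaps = FALSE) {
  if (step_ms > window_ms && !allow_gaps)
    stop("step_ms must not exceed window_ms (set allow_gaps = TRUE to override)",
         call. = FALSE)
  wlen <- ms_to_samples(window_ms, fs)
  step <- ms_to_samples(step_ms, fs)
  if (wlen > n_samples) stop("session shorter than one window", call. = FALSE)
  n_win <- floor((n_samples - wlen) / step) + 1
  start <- (seq_len(n_win) - 1L) * step
  out <- data.frame(start_sample = start, end_sample = start + wlen,
                    start_s = start / fs, end_s = (start + wlen) / fs,
                    mid_s = (start + wlen / 2) / fs)
  attr(out, "window_ms") <- window_ms
  attr(out, "step_ms") <- step_ms
  attr(out, "fs") <- fs
  class(out) <- c("window_spec", "data.frame")
  out
}

#' Label windows from a ground-truth state timeline
#'
#' @param windows a [make_windows()] result.
#' @param truth a \code{ground_truth} object (per-sample state codes).
#' @param rule \code{"midpoint"}: the state occupying the window's midpoint
#'   sample (default); \code{"majority"}: most frequent state in the window.
#' @param collapse collapse stimulus-type states to a single
#'   \code{"active"} label (default TRUE; set FALSE for the three-class
#'   labels).
#' @return factor of window labels (\code{idle}/\code{active}, or
#'   \code{idle} plus the stimulus-type names).
#' @export
label_windows <- function(windows, truth, rule = c("midpoint", "majority"),
                          collapse = TRUE) {
  rule <- match.arg(rule)
  states <- truth$states
  if (max(windows$end_sample) > length(states))
    stop("truth timeline does not cover all windows", call. = FALSE)
  code <- if (rule == "midpoint") {
    mid <- floor((windows$start_sample + windows$end_sample) / 2)
    states[mid + 1L]
  } else {
    vapply(seq_len(nrow(windows)), function(i) {
      seg <- states[(windows$start_sample[i] + 1L):windows$end_sample[i]]
      as.integer(names(which.max(table(seg))))
    }, integer(1))
  }
  if (collapse)
    factor(ifelse(code > 0, "active", "idle"), levels = c("idle", "active"))
  else
    factor(c("idle", truth$types)[code + 1L],
           levels = c("idle", truth$types))
}

#' Time-domain window operators
#'
#' \code{avg_amplitude}: mean; \code{rms}: root mean square; \code{slope}:
#' ordinary-least-squares slope against time in seconds; \code{line_length}:
#' sum of absolute differences between consecutive samples.
#'
#' @param x numeric vector of window samples (length >= 2).
#' @param fs sampling rate (Hz), used by \code{slope} only.
#' @return scalar feature value.
#' @export
avg_amplitude <- function(x) {
  check_window(x)
  mean(x)
}

#' @rdname avg_amplitude
#' @export
rms <- function(x) {
  check_window(x)
  sqrt(mean(x^2))
}

#' @rdname avg_amplitude
#' @export
slope <- function(x, fs) {
  check_window(x)
  t <- (seq_along(x) - 1) / fs
  sum((t - mean(t)) * (x - mean(x))) / sum((t - mean(t))^2)
}

#' @rdname avg_amplitude
#' @export
line_length <- function(x) {
  check_window(x)
  sum(abs(diff(x)))
}

check_window <- function(x) {
  if (length(x) < 2L) stop("window must contain at least 2 samples",
                           call. = FALSE)
  invisible(x)
}

# All four operators for every window of one trace, via cumulative sums
# (every window has the same length).
window_ops <- function(x, windows, fs) {
  wlen <- windows$end_sample[1] - windows$start_sample[1]
  s0 <- windows$start_sample            # 0-based
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  csl <- c(0, cumsum(abs(diff(x))))     # csl[i+1] = sum of first i diffs
  cst <- c(0, cumsum(x * seq_along(x))) # for the slope numerator
  n <- wlen
  sum_x <- cs[s0 + n + 1] - cs[s0 + 1]
  sum_x2 <- cs2[s0 + n + 1] - cs2[s0 + 1]
  A <- sum_x / n
  RMS <- sqrt(sum_x2 / n)
  L <- csl[s0 + n] - csl[s0 + 1]        # diffs within [s0+1, s0+n]
  # OLS slope with t = (0, 1/fs, ..., (n-1)/fs) per window:
  # sum_i i * x[s0+i+1] = (cst window) - s0 * sum_x, i from 1..n on 1-based
  sum_ix <- (cst[s0 + n + 1] - cst[s0 + 1]) - s0 * sum_x
  i_mean <- (n + 1) / 2
  s_tt <- (n * (n^2 - 1)) / 12          # sum (i - i_mean)^2
  k <- ((sum_ix - i_mean * sum_x) / s_tt) * fs
  cbind(A = A, RMS = RMS, k = k, L = L)
}

#' Z-score continuous traces against pooled trial baselines
#'
#' Each channel of each trace is normalized by the mean and SD of its
#' pre-stimulus baseline samples pooled over trials, making the continuous
#' stream comparable to the per-trial z-scored epochs.
#'
#' @param traces named list of [trace_set()]s (or a single one).
#' @param events an [event_table()].
#' @param baseline_ms baseline window relative to onset (ms, half-open).
#' @return traces of the same shape, z-scored (attribute
#'   \code{normalized = TRUE}).
#' @export
zscore_traces <- function(traces, events, baseline_ms = c(-200, 0)) {
  single <- inherits(traces, "trace_set")
  if (single) traces <- list(traces)
  out <- lapply(traces, function(tr) {
    fs <- tr$fs
    b0 <- ms_to_samples(baseline_ms[1], fs)
    b1 <- ms_to_samples(baseline_ms[2], fs)
    idx <- unlist(lapply(events$onset_sample, function(on) {
      i <- (on + b0 + 1L):(on + b1)
      i[i >= 1L & i <= ncol(tr$data)]
    }))
    z <- tr$data
    for (ch in seq_len(nrow(z))) {
      b <- tr$data[ch, idx]
      z[ch, ] <- (tr$data[ch, ] - mean(b)) / stats::sd(b)
    }
    res <- tr
    res$data <- z
    attr(res, "normalized") <- TRUE
    res
  })
  if (single) out[[1]] else out
}

#' Restrict traces to a channel subset
#'
#' @param traces named list of [trace_set()]s.
#' @param ids named list (per trace kind) of channel ids to keep, or a
#'   character vector applied to every kind.
#' @return traces with only the requested channels.
#' @export
subset_traces <- function(traces, ids) {
  out <- lapply(names(traces), function(k) {
    tr <- traces[[k]]
    want <- if (is.list(ids)) ids[[k]] else ids
    keep <- match(intersect(want, tr$channels$id), tr$channels$id)
    tr$data <- tr$data[keep, , drop = FALSE]
    tr$channels <- tr$channels[keep, , drop = FALSE]
    tr
  })
  names(out) <- names(traces)
  out
}

#' Gaussian smoothing of continuous traces
#'
#' Applies the same unit-area 80-ms Gaussian kernel used on the per-trial
#' epochs to the continuous trace stream (reflect padding), so that windowed
#' features see the smoothed trace rather than raw sample-to-sample noise.
#'
#' @param traces named list of [trace_set()]s (or a single one).
#' @param width_ms total kernel support (ms).
#' @return traces of the same shape, smoothed.
#' @export
smooth_traces <- function(traces, width_ms = 80) {
  single <- inherits(traces, "trace_set")
  if (single) traces <- list(traces)
  out <- lapply(traces, function(tr) {
    k <- gaussian_kernel(ms_to_samples(width_ms, tr$fs))
    for (ch in seq_len(nrow(tr$data)))
      tr$data[ch, ] <- smooth_vec(tr$data[ch, ], k)
    tr
  })
  if (single) out[[1]] else out
}

FEATURE_OPS <- c("A", "RMS", "k", "L")

#' The informative four-feature subset
#'
#' High-gamma amplitude, high-gamma RMS, high-gamma line-length and ERP
#' line-length: the feature types found most informative for state
#' detection.
#'
#' @return data.frame with columns \code{trace}, \code{op}.
#' @export
four_type_set <- function() {
  data.frame(trace = c("high_gamma", "high_gamma", "high_gamma", "erp"),
             op = c("A", "RMS", "L", "L"), stringsAsFactors = FALSE)
}

# Resolve a feature_set argument into a (trace, op) data.frame.
resolve_feature_set <- function(feature_set, kinds) {
  if (is.data.frame(feature_set)) return(feature_set)
  if (identical(feature_set, "all16") || identical(feature_set, "all"))
    return(expand.grid(trace = kinds, op = FEATURE_OPS,
                       stringsAsFactors = FALSE))
  if (identical(feature_set, "four_type")) return(four_type_set())
  if (is.character(feature_set) && grepl("^single:", feature_set[1])) {
    parts <- strsplit(feature_set, ":")[[1]]
    return(data.frame(trace = parts[2], op = parts[3],
                      stringsAsFactors = FALSE))
  }
  stop("unknown feature_set: ", feature_set, call. = FALSE)
}

#' Extract the window feature matrix
#'
#' One column per (trace kind, selected channel, operator), in deterministic
#' (trace, channel, operator) order; one row per sliding window.
#'
#' @param traces named list of z-scored [trace_set()]s (see
#'   [zscore_traces()]).
#' @param selections named list of \code{channel_selection}s (same names), or
#'   a named list of channel-id vectors.
#' @param windows a [make_windows()] result.
#' @param feature_set \code{"all16"}, \code{"four_type"},
#'   \code{"single:<trace>:<op>"}, or a data.frame with columns \code{trace},
#'   \code{op}.
#' @param labels optional factor of window labels to attach.
#' @return object of class \code{window_features}: numeric matrix \code{x}
#'   (windows x features), \code{windows}, \code{labels}, and per-column
#'   metadata \code{col_info}.
#' @export
extract_features <- function(traces, selections, windows,
                             feature_set = "all16", labels = NULL) {
  spec <- resolve_feature_set(feature_set, names(traces))
  cols <- list()
  info <- list()
  for (kind in unique(spec$trace)) {
    if (!kind %in% names(traces))
      stop("no trace of kind '", kind, "' supplied", call. = FALSE)
    sel <- selections[[kind]]
    ids <- if (is.character(sel)) sel else sel$channel[sel$selected]
    if (length(ids) == 0L) next
    ops <- spec$op[spec$trace == kind]
    tr <- traces[[kind]]
    for (id in ids) {
      x <- tr$data[match(id, tr$channels$id), ]
      allops <- window_ops(x, windows, tr$fs)
      for (op in FEATURE_OPS[FEATURE_OPS %in% ops]) {
        cols[[length(cols) + 1L]] <- allops[, op]
        info[[length(info) + 1L]] <- data.frame(trace = kind, channel = id,
                                                op = op,
                                                stringsAsFactors = FALSE)
      }
    }
  }
  if (length(cols) == 0L)
    stop("empty channel selection across all trace kinds", call. = FALSE)
  x <- do.call(cbind, cols)
  col_info <- do.call(rbind, info)
  colnames(x) <- paste(col_info$trace, col_info$channel, col_info$op,
                       sep = ".")
  structure(list(x = x, windows = windows, labels = labels,
                 col_info = col_info),
            class = "window_features")
}

#' @export
print.window_features <- function(x, ...) {
  cat(sprintf("<window_features> %d windows x %d features", nrow(x$x),
              ncol(x$x)))
  if (!is.null(x$labels))
    cat(" | labels:", paste(sprintf("%s=%d", levels(x$labels),
                                    tabulate(x$labels)), collapse = " "))
  cat("\n")
  invisible(x)
}

#' Permutation selection of feature dimensions
#'
#' The same randomization machinery as channel selection, applied per feature
#' column over training windows; the \code{keep} smallest-p columns are kept.
#' Must only ever see training-fold rows.
#'
#' @param x training feature matrix (windows x features).
#' @param labels factor or -1/+1 labels per training window.
#' @param keep number of columns to keep.
#' @param n_perm label shufflings per column.
#' @param seed integer seed.
#' @return data.frame of class \code{feature_selection}: \code{column},
#'   \code{r_obs}, \code{p}, \code{kept}.
#' @export
select_feature_dims <- function(x, labels, keep = 10, n_perm = 200,
                                seed = NULL) {
  lab <- as_pm1(labels)
  res <- perm_spearman_columns(x, lab, n_perm = n_perm, seed = seed)
  kept <- rep(FALSE, ncol(x))
  ord <- order(res$p, -abs(res$r_obs), res$column)
  kept[ord[seq_len(min(keep, ncol(x)))]] <- TRUE
  res$kept <- kept
  if (!is.null(colnames(x))) res$name <- colnames(x)
  class(res) <- c("feature_selection", "data.frame")
  res
}

# Map a two-level factor (idle first) or numeric labels to -1 active / +1 idle.
as_pm1 <- function(labels) {
  if (is.numeric(labels)) return(labels)
  f <- as.factor(labels)
  ifelse(f == levels(f)[1], 1, -1)
}

#' Fit a PCA reduction on training rows
#'
#' Columns are centred (and by default scaled to unit variance) with training
#' statistics; the smallest number of principal components whose cumulative
#' explained variance exceeds \code{threshold} is retained.  Test rows must
#' be projected with [pca_project()] using the same fit.
#'
#' @param train training feature matrix.
#' @param threshold cumulative explained-variance threshold.
#' @param scale. scale columns to unit training variance.
#' @return list of class \code{pca_reduction}: \code{rotation},
#'   \code{center}, \code{scale}, \code{ncomp}, \code{explained}.
#' @export
pca_reduce <- function(train, threshold = 0.95, scale. = TRUE) {
  if (nrow(train) < 2L) stop("need at least 2 rows", call. = FALSE)
  sds <- apply(train, 2, stats::sd)
  keep <- sds > 0
  pc <- stats::prcomp(train[, keep, drop = FALSE], center = TRUE,
                      scale. = scale.)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  ncomp <- which(cumsum(ev) > threshold)[1]
  structure(list(rotation = pc$rotation[, seq_len(ncomp), drop = FALSE],
                 center = pc$center,
                 scale = if (scale.) pc$scale else NULL,
                 cols = which(keep), ncomp = ncomp,
                 explained = ev[seq_len(ncomp)]),
            class = "pca_reduction")
}

#' Project a feature matrix with a fitted PCA reduction
#'
#' @param fit a [pca_reduce()] result.
#' @param x feature matrix with the same columns as the training matrix.
#' @return matrix of principal-component scores (rows x ncomp).
#' @export
pca_project <- function(fit, x) {
  x <- x[, fit$cols, drop = FALSE]
  x <- sweep(x, 2, fit$center)
  if (!is.null(fit$scale)) x <- sweep(x, 2, fit$scale, "/")
  x %*% fit$rotation
}

#' Write a window feature matrix as tab-separated text
#'
#' @param features a \code{window_features} object.
#' @param path output file.
#' @param fold optional per-window fold assignment column.
#' @return \code{path}, invisibly.
#' @export
write_feature_matrix <- function(features, path, fold = NULL) {
  df <- data.frame(start_s = features$windows$start_s,
                   end_s = features$windows$end_s)
  if (!is.null(features$labels)) df$label <- features$labels
  if (!is.null(fold)) df$fold <- fold
  df <- cbind(df, as.data.frame(features$x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
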