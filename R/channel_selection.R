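# Responsive-channel selection by randomization testing.
#
# Per channel: the mean trace amplitude over the active window (300-1000 ms
# post-onset) and over the baseline window (-200-0 ms) of every trial form
# the value vector z = (x, y); its Spearman correlation with -1/+1
# active/idle labels is compared against 1000 label shufflings.  Channels
# significant after Bonferroni correction are kept, at most ten per trace
# kind (smallest p first).

#' Per-trial active and idle mean amplitudes
#'
#' @param epochs a normalized (and typically smoothed) \code{epoch_set}.
#' @param active_ms active window relative to onset (ms, half-open).
#' @param idle_ms idle/baseline window relative to onset (ms, half-open).
#' @return list with matrices \code{x} (active means) and \code{y} (idle
#'   means), each trials x channels.
#' @export
trial_state_means <- function(epochs, active_ms = c(300, 1000),
                              idle_ms = c(-200, 0)) {
  fs <- epochs$fs
  w0 <- ms_to_samples(epochs$window_ms[1], fs)
  idx_win <- function(win) {
    (ms_to_samples(win[1], fs) - w0 + 1):(ms_to_samples(win[2], fs) - w0)
  }
  ai <- idx_win(active_ms)
  ii <- idx_win(idle_ms)
  x <- apply(epochs$data[, ai, , drop = FALSE], c(1, 3), mean)
  y <- apply(epochs$data[, ii, , drop = FALSE], c(1, 3), mean)
  list(x = x, y = y)
}

#' Select responsive channels for one trace kind
#'
#' @param epochs a normalized, smoothed \code{epoch_set} for one trace kind.
#' @param alpha uncorrected significance level; the per-channel threshold is
#'   \code{alpha / n_channels} (Bonferroni).
#' @param max_keep maximum number of channels kept (smallest p first; ties
#'   broken by larger absolute r, then channel order).
#' @param n_perm permutations per channel.
#' @param seed integer seed (whole selection is reproducible).
#' @param active_ms,idle_ms analysis windows, see [trial_state_means()].
#' @param method,alternative passed to the permutation test.
#' @return data.frame of class \code{channel_selection}: one row per channel
#'   with \code{channel}, \code{r_obs}, \code{p}, \code{significant},
#'   \code{selected}.
#' @export
select_channels <- function(epochs, alpha = 0.05, max_keep = 10,
                            n_perm = 1000, seed = NULL,
                            active_ms = c(300, 1000), idle_ms = c(-200, 0),
                            method = "normal", alternative = "two.sided") {
  if (dim(epochs$data)[1] < 2L) stop("need at least 2 trials", call. = FALSE)
  ms <- trial_state_means(epochs, active_ms, idle_ms)
  n_tr <- nrow(ms$x)
  n_ch <- ncol(ms$x)
  values <- rbind(ms$x, ms$y)                   # (2*trials) x channels
  labels <- c(rep(-1, n_tr), rep(1, n_tr))      # -1 active / +1 idle
  res <- perm_spearman_columns(values, labels, n_perm = n_perm, seed = seed,
                               method = method, alternative = alternative)
  thr <- alpha / n_ch
  significant <- res$p < thr
  selected <- rep(FALSE, n_ch)
  if (any(significant)) {
    cand <- which(significant)
    ord <- order(res$p[cand], -abs(res$r_obs[cand]), cand)
    selected[cand[ord][seq_len(min(max_keep, length(cand)))]] <- TRUE
  } else {
    warning("no channel reached Bonferroni-corrected significance",
            call. = FALSE)
  }
  out <- data.frame(channel = epochs$channels$id, r_obs = res$r_obs,
                    p = res$p, significant = significant, selected = selected,
                    stringsAsFactors = FALSE)
  attr(out, "kind") <- epochs$kind
  attr(out, "alpha") <- alpha
  attr(out, "threshold") <- thr
  attr(out, "n_perm") <- n_perm
  class(out) <- c("channel_selection", "data.frame")
  out
}

#' Channel selection for several trace kinds at once
#'
#' Runs [epoch_and_normalize()], [gaussian_smooth()] and [select_channels()]
#' per trace kind.  The per-trial state means are taken on the smoothed
#' \emph{unnormalized} epochs: per-trial baseline z-scoring would pin every
#' idle-window mean at zero (the baseline is the idle window), destroying the
#' exchangeability the label-shuffling test relies on, whereas Spearman
#' correlation is invariant to the per-channel affine (pooled z-scoring)
#' alternative.
#'
#' @param traces named list of [trace_set()]s.
#' @param events an [event_table()].
#' @param seed integer seed.
#' @param ... passed to [select_channels()].
#' @return named list of \code{channel_selection} objects.
#' @export
select_channels_all <- function(traces, events, seed = NULL, ...) {
  out <- list()
  for (i in seq_along(traces)) {
    ep <- gaussian_smooth(epoch_and_normalize(traces[[i]], events,
                                              normalize = FALSE))
    out[[names(traces)[i]]] <-
      select_channels(ep, seed = child_seed(seed, i), ...)
  }
  out
}

#' Write a channel-selection report as tab-separated text
#'
#' @param selections named list of \code{channel_selection} objects (or one).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_selection_report <- function(selections, path) {
  if (inherits(selections, "channel_selection"))
    selections <- list(selection = selections)
  rows <- do.call(rbind, lapply(names(selections), function(k) {
    s <- selections[[k]]
    data.frame(channel = s$channel, trace = attr(s, "kind") %||% k,
               r_obs = s$r_obs, p = s$p, selected = s$selected)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
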