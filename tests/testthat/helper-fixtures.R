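# Small programmatic fixtures shared across tests.

# Recording with explicit per-channel signals (list of numeric vectors).
make_rec <- function(signals, fs = 1000, shaft = NULL) {
  x <- do.call(rbind, signals)
  n <- nrow(x)
  shaft <- shaft %||% rep("A", n)
  channels <- data.frame(id = sprintf("ch%02d", seq_len(n)), shaft = shaft,
                         contact = stats::ave(seq_len(n), shaft,
                                              FUN = seq_along))
  seegstate::seeg_recording(x, fs, channels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hand-built epoch_set (trials x samples x channels) for selection tests.
make_epochs <- function(arr, fs = 1000, window_ms = c(-200, 1000),
                        kind = "high_gamma") {
  n_ch <- dim(arr)[3]
  structure(list(data = arr, fs = fs, window_ms = window_ms,
                 baseline_ms = c(-200, 0), normalized = TRUE,
                 channels = data.frame(id = sprintf("ch%02d", seq_len(n_ch)),
                                       shaft = "A", contact = seq_len(n_ch)),
                 kind = kind, events = NULL),
            class = "epoch_set")
}

# Hand-built ground truth timeline from active spans (in samples, 0-based).
make_truth <- function(n, spans, fs = 1000, types = c("own", "other"),
                       codes = NULL) {
  states <- integer(n)
  codes <- codes %||% rep(1L, length(spans))
  for (i in seq_along(spans)) {
    idx <- (spans[[i]][1] + 1L):spans[[i]][2]
    states[idx] <- codes[i]
  }
  structure(list(states = states, types = types, fs = fs,
                 responsive = list(), active_window_ms = c(300, 1000)),
            class = "ground_truth")
}

# Fast small session for end-to-end tests (deterministic by seed).
small_session <- function(n_trials = 20, seed = 1, n_channels = 10,
                          iti_ms = c(1000, 1000), ...) {
  cfg <- seegstate::paradigm_config(n_trials = n_trials, iti_ms = iti_ms,
                                    cue_ms = 0, prep_ms = 0)
  # channel ids follow generate_background naming: A01..A10 on one shaft
  profiles <- seegstate::default_profiles(
    c("A02", "A05", "A08"), responsive = 1:3,
    hg_gain = c(8, 6, 5), erp_gain = c(30, 24, 20))
  seegstate::simulate_session(cfg, n_channels = n_channels,
                              profiles = profiles, seed = seed, ...)
}
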