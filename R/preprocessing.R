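# Pre-processing: from raw recordings to the four per-channel signal traces.
#
# Power traces: comb notch -> Laplacian re-reference -> Butterworth band-pass
#   -> Hilbert transform -> squared magnitude.
# ERP trace:    comb notch -> 0.5 Hz high-pass -> Laplacian re-reference.
# All filters are applied zero-phase (forward-backward) by default; causal
# single-pass filtering is available via `zero_phase = FALSE`.

BAND_DEFS <- list(high_gamma = c(60, 140), beta = c(13, 30), alpha = c(8, 12))

# Direct-form IIR filtering via stats::filter's compiled convolution (MA
# part) and recursion (AR part); coefficient vectors as in signal::Arma.
iir_filter <- function(b, a, x) {
  nb <- length(b)
  if (nb > 1) {
    u <- as.numeric(stats::filter(c(rep(0, nb - 1), x), b,
                                  sides = 1))[nb - 1 + seq_along(x)]
  } else u <- b * x
  if (length(a) > 1)
    u <- as.numeric(stats::filter(u, -a[-1], method = "recursive"))
  u
}

# Zero-phase filtering in time domain (forward-backward), small-signal path.
iir_filtfilt <- function(b, a, x, pad = NULL) {
  n <- length(x)
  pad <- min(pad %||% 1000L, n - 1L)
  xp <- c(rev(x[seq_len(pad) + 1L]), x, rev(x[n - seq_len(pad)]))
  y <- rev(iir_filter(b, a, rev(iir_filter(b, a, xp))))
  y[pad + seq_len(n)]
}

# H(e^{-iw}) of a rational filter, Horner evaluation over the bin grid.
iir_response <- function(b, a, ew) {
  horner <- function(cf) {
    p <- rep(cf[length(cf)] + 0i, length(ew))
    for (k in rev(seq_len(length(cf) - 1L))) p <- p * ew + cf[k]
    p
  }
  horner(b) / horner(a)
}

# Apply a cascade of IIR filters to every row.  Zero phase: the cascade's
# |H|^2 applied spectrally with reflect padding (forward-backward filtering
# of an infinite signal IS multiplication by |H|^2); causal: sequential
# direct-form recursion.
apply_filter_rows <- function(x, filters, zero_phase = TRUE, pad = 1000L) {
  if (!is.null(filters$b)) filters <- list(filters)
  out <- x
  n <- ncol(x)
  if (!zero_phase) {
    for (i in seq_len(nrow(x)))
      for (f in filters) out[i, ] <- iir_filter(f$b, f$a, out[i, ])
    return(out)
  }
  pad <- min(pad, n - 1L)
  m <- stats::nextn(n + 2L * pad, c(2, 3, 5))
  zfill <- m - n - 2L * pad
  w <- 2 * pi * (seq_len(m) - 1) / m
  ew <- exp(-1i * w)
  mag2 <- rep(1, m)
  for (f in filters) mag2 <- mag2 * Mod(iir_response(f$b, f$a, ew))^2
  for (i in seq_len(nrow(x))) {
    xi <- x[i, ]
    xp <- c(rev(xi[seq_len(pad) + 1L]), xi, rev(xi[n - seq_len(pad)]),
            numeric(zfill))
    y <- Re(stats::fft(stats::fft(xp) * mag2, inverse = TRUE)) / m
    out[i, ] <- y[pad + seq_len(n)]
  }
  out
}

# RBJ second-order IIR notch at f0 with quality factor q.
biquad_notch <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  signal::Arma(b / a[1], a / a[1])
}

#' Comb notch filter for line noise and harmonics
#'
#' Cascaded narrow second-order IIR notches (Q = 35) at \code{base_hz} and
#' every harmonic below Nyquist, applied zero-phase.
#'
#' @param rec a [seeg_recording()] (or any object with a channels x samples
#'   \code{data} matrix and \code{fs}).
#' @param base_hz line frequency (Hz); must be below Nyquist.
#' @param q notch quality factor.
#' @param zero_phase apply forward-backward (default) or causal.
#' @return filtered recording of the same class.
#' @export
comb_notch <- function(rec, base_hz = 50, q = 35, zero_phase = TRUE) {
  fs <- rec$fs
  if (is.null(fs)) stop("recording has no sampling rate", call. = FALSE)
  if (base_hz >= fs / 2)
    stop("base_hz must be below the Nyquist frequency", call. = FALSE)
  harmonics <- seq(base_hz, fs / 2 * 0.99, by = base_hz)
  cascade <- lapply(harmonics, biquad_notch, fs = fs, q = q)
  out <- rec
  out$data <- apply_filter_rows(rec$data, cascade, zero_phase,
                                pad = min(2000L, ncol(rec$data) - 1L))
  out
}

#' Laplacian re-referencing along electrode shafts
#'
#' Each contact is re-referenced against the mean of its two shaft-adjacent
#' neighbours; shaft-end contacts fall back to a bipolar reference against
#' their single neighbour.  Shafts with a single contact are dropped with a
#' warning.
#'
#' @param rec a [seeg_recording()].
#' @return re-referenced recording (possibly with fewer channels).
#' @export
laplacian_rereference <- function(rec) {
  ch <- rec$channels
  if (is.null(ch$shaft) || is.null(ch$contact))
    stop("shaft/contact metadata required for Laplacian re-referencing",
         call. = FALSE)
  keep <- rep(TRUE, nrow(ch))
  out <- rec$data
  for (sh in unique(ch$shaft)) {
    rows <- which(ch$shaft == sh)
    rows <- rows[order(ch$contact[rows])]
    m <- length(rows)
    if (m == 1L) {
      warning("dropping single-contact shaft '", sh, "'", call. = FALSE)
      keep[rows] <- FALSE
      next
    }
    x <- rec$data[rows, , drop = FALSE]
    out[rows[1], ] <- x[1, ] - x[2, ]
    if (m > 2L)
      for (i in 2:(m - 1))
        out[rows[i], ] <- x[i, ] - (x[i - 1, ] + x[i + 1, ]) / 2
    out[rows[m], ] <- x[m, ] - x[m - 1, ]
  }
  seeg_recording(out[keep, , drop = FALSE], rec$fs, ch[keep, , drop = FALSE])
}

#' Butterworth band-pass filter
#'
#' @param rec a [seeg_recording()].
#' @param band \code{c(low, high)} in Hz, inside (0, Nyquist).
#' @param order total filter order (even; 6 = the default 6th-order design).
#' @param zero_phase apply forward-backward (default) or causal.
#' @return filtered recording.
#' @export
bandpass <- function(rec, band, order = 6, zero_phase = TRUE) {
  fs <- rec$fs
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1] ||
      band[2] >= fs / 2)
    stop("band must satisfy 0 < low < high < fs/2", call. = FALSE)
  if (order %% 2 != 0) stop("order must be even", call. = FALSE)
  bf <- signal::butter(order / 2, band * 2 / fs, type = "pass")
  out <- rec
  out$data <- apply_filter_rows(rec$data, bf, zero_phase,
                                pad = ceiling(3 * fs / band[1]))
  out
}

#' Butterworth high-pass filter
#'
#' @param rec a [seeg_recording()].
#' @param cutoff cutoff frequency in Hz.
#' @param order filter order.
#' @param zero_phase apply forward-backward (default) or causal.
#' @return filtered recording.
#' @export
highpass <- function(rec, cutoff = 0.5, order = 2, zero_phase = TRUE) {
  fs <- rec$fs
  if (cutoff <= 0 || cutoff >= fs / 2)
    stop("cutoff must be inside (0, fs/2)", call. = FALSE)
  bf <- signal::butter(order, cutoff * 2 / fs, type = "high")
  out <- rec
  out$data <- apply_filter_rows(rec$data, bf, zero_phase,
                                pad = ceiling(3 * fs / cutoff))
  out
}

# FFT construction of the analytic signal (one-sided spectrum doubling).
# Inputs are reflect-padded to a 2-3-5-smooth length so the FFT stays
# O(n log n) for any session length; the Hilbert kernel decays as 1/t, so
# interior samples are unaffected to numerical precision.
analytic_signal <- function(x) {
  n <- length(x)
  m <- stats::nextn(n, c(2, 3, 5))
  if (m == n) return(analytic_core(x))
  pad <- m - n
  l <- pad %/% 2
  r <- pad - l
  xp <- c(rev(x[seq_len(l) + 1L]), x, rev(x[n - seq_len(r)]))
  analytic_core(xp)[l + seq_len(n)]
}

analytic_core <- function(x) {
  n <- length(x)
  xf <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(xf * h, inverse = TRUE) / n
}

#' Hilbert-envelope power trace
#'
#' Squared magnitude of the analytic signal of each (already band-passed)
#' channel.
#'
#' @param rec band-passed [seeg_recording()].
#' @param kind trace kind label for the result.
#' @return a [trace_set()] of nonnegative power values.
#' @export
hilbert_power <- function(rec, kind = "high_gamma") {
  p <- rec$data
  for (i in seq_len(nrow(p)))
    p[i, ] <- Mod(analytic_signal(rec$data[i, ]))^2
  trace_set(p, rec$fs, rec$channels, kind)
}

# Fused zero-phase band-pass + analytic-signal power: one padded FFT
# round-trip per channel (multiply by the Butterworth |H|^2 and the
# one-sided doubling mask together).  Identical to
# hilbert_power(bandpass(...)) up to edge padding.
bandpower_rows <- function(x, fs, band, order) {
  n <- ncol(x)
  pad <- min(ceiling(3 * fs / band[1]), n - 1L)
  m <- stats::nextn(n + 2L * pad, c(2, 3, 5))
  zfill <- m - n - 2L * pad
  ew <- exp(-2i * pi * (seq_len(m) - 1) / m)
  bf <- signal::butter(order / 2, band * 2 / fs, type = "pass")
  mag2 <- Mod(iir_response(bf$b, bf$a, ew))^2
  h <- numeric(m)                       # analytic one-sided mask (m even)
  h[1] <- 1
  if (m %% 2 == 0) {
    h[m / 2 + 1] <- 1
    h[2:(m / 2)] <- 2
  } else h[2:((m + 1) / 2)] <- 2
  out <- x
  for (i in seq_len(nrow(x))) {
    xi <- x[i, ]
    xp <- c(rev(xi[seq_len(pad) + 1L]), xi, rev(xi[n - seq_len(pad)]),
            numeric(zfill))
    y <- stats::fft(stats::fft(xp) * (mag2 * h), inverse = TRUE) / m
    out[i, ] <- Mod(y[pad + seq_len(n)])^2
  }
  out
}

#' Band-power trace from a raw recording
#'
#' Full power pipeline: comb notch, Laplacian re-reference, Butterworth
#' band-pass, Hilbert transform, squared magnitude.  With zero-phase
#' filtering (the default) the band-pass and analytic signal are computed in
#' a single spectral pass.
#'
#' @param rec raw [seeg_recording()].
#' @param kind \code{"high_gamma"}, \code{"beta"} or \code{"alpha"} (sets the
#'   band: 60-140, 13-30, 8-12 Hz).
#' @param order band-pass filter order.
#' @param zero_phase zero-phase filtering flag, passed to every stage.
#' @return a [trace_set()].
#' @export
band_power_trace <- function(rec, kind = "high_gamma", order = 6,
                             zero_phase = TRUE) {
  kind <- match.arg(kind, names(BAND_DEFS))
  lap <- laplacian_rereference(comb_notch(rec, zero_phase = zero_phase))
  if (zero_phase) {
    p <- bandpower_rows(lap$data, lap$fs, BAND_DEFS[[kind]], 6)
    trace_set(p, lap$fs, lap$channels, kind)
  } else {
    hilbert_power(bandpass(lap, BAND_DEFS[[kind]], order = order,
                           zero_phase = FALSE), kind = kind)
  }
}

#' ERP voltage trace from a raw recording
#'
#' Comb notch, then 0.5 Hz high-pass, then Laplacian re-referencing.
#'
#' @param rec raw [seeg_recording()].
#' @param zero_phase zero-phase filtering flag.
#' @return a [trace_set()] with \code{kind = "erp"}.
#' @export
erp_trace <- function(rec, zero_phase = TRUE) {
  out <- rec |>
    comb_notch(zero_phase = zero_phase) |>
    highpass(0.5, zero_phase = zero_phase) |>
    laplacian_rereference()
  trace_set(out$data, out$fs, out$channels, "erp")
}

#' Compute several trace kinds at once
#'
#' Equivalent to calling [band_power_trace()] / [erp_trace()] per kind, but
#' the shared comb-notch stage is computed once.
#'
#' @param rec raw [seeg_recording()].
#' @param kinds subset of \code{c("high_gamma", "beta", "alpha", "erp")}.
#' @param zero_phase zero-phase filtering flag.
#' @return named list of [trace_set()]s.
#' @export
compute_traces <- function(rec, kinds = c("high_gamma", "erp"),
                           zero_phase = TRUE) {
  kinds <- match.arg(kinds, c("high_gamma", "beta", "alpha", "erp"),
                     several.ok = TRUE)
  notched <- comb_notch(rec, zero_phase = zero_phase)
  out <- list()
  power_kinds <- intersect(kinds, names(BAND_DEFS))
  if (length(power_kinds)) {
    lap <- laplacian_rereference(notched)
    for (k in power_kinds) {
      out[[k]] <- if (zero_phase) {
        trace_set(bandpower_rows(lap$data, lap$fs, BAND_DEFS[[k]], 6),
                  lap$fs, lap$channels, k)
      } else {
        hilbert_power(bandpass(lap, BAND_DEFS[[k]], zero_phase = FALSE),
                      kind = k)
      }
    }
  }
  if ("erp" %in% kinds) {
    hp <- laplacian_rereference(highpass(notched, 0.5,
                                         zero_phase = zero_phase))
    out$erp <- trace_set(hp$data, hp$fs, hp$channels, "erp")
  }
  out[kinds]
}

#' Epoch a trace around stimulus onsets and z-score against baseline
#'
#' Each trial is cut to \code{window_ms} around its onset and normalized per
#' channel by the mean and SD of its own baseline segment
#' (\code{baseline_ms}, the 200 ms preceding onset by default).  Trials whose
#' window exceeds the recording bounds are dropped with a warning; a
#' zero-variance baseline is an error.
#'
#' @param trace a [trace_set()].
#' @param events an [event_table()].
#' @param window_ms epoch window relative to onset (ms, half-open).
#' @param baseline_ms baseline window relative to onset (ms, half-open).
#' @param normalize z-score against baseline (default TRUE).
#' @return object of class \code{epoch_set}: array \code{data} of dimension
#'   trials x samples x channels plus window metadata.
#' @export
epoch_and_normalize <- function(trace, events, window_ms = c(-200, 1000),
                                baseline_ms = c(-200, 0), normalize = TRUE) {
  fs <- trace$fs
  n <- ncol(trace$data)
  w0 <- ms_to_samples(window_ms[1], fs)
  w1 <- ms_to_samples(window_ms[2], fs)
  nt <- w1 - w0
  start <- events$onset_sample + w0   # 0-based
  ok <- start >= 0 & (start + nt) <= n
  if (any(!ok))
    warning(sum(!ok), " trial(s) exceed recording bounds and were dropped",
            call. = FALSE)
  start <- start[ok]
  n_tr <- length(start)
  n_ch <- nrow(trace$data)
  b_idx <- (ms_to_samples(baseline_ms[1], fs) - w0 + 1):
           (ms_to_samples(baseline_ms[2], fs) - w0)
  arr <- array(NA_real_, c(n_tr, nt, n_ch),
               dimnames = list(NULL, NULL, trace$channels$id))
  for (ch in seq_len(n_ch)) {
    x <- trace$data[ch, ]
    for (tr in seq_len(n_tr)) {
      seg <- x[(start[tr] + 1):(start[tr] + nt)]
      if (normalize) {
        b <- seg[b_idx]
        s <- stats::sd(b)
        if (!is.finite(s) || s == 0)
          stop("zero baseline SD in channel ", trace$channels$id[ch],
               ", trial ", tr, call. = FALSE)
        seg <- (seg - mean(b)) / s
      }
      arr[tr, , ch] <- seg
    }
  }
  structure(list(data = arr, fs = fs, window_ms = window_ms,
                 baseline_ms = baseline_ms, normalized = normalize,
                 channels = trace$channels, kind = trace$kind,
                 events = events[ok, , drop = FALSE]),
            class = "epoch_set")
}

#' Gaussian smoothing of epoched traces
#'
#' Convolution along the time axis with a unit-area Gaussian kernel whose
#' total support is \code{width_ms} (sigma = support/6, i.e. +-3 sigma
#' truncation), using reflect padding so the epoch length is preserved.
#'
#' @param epochs an \code{epoch_set}.
#' @param width_ms total kernel support in ms.
#' @return smoothed \code{epoch_set}.
#' @export
gaussian_smooth <- function(epochs, width_ms = 80) {
  fs <- epochs$fs
  nt <- dim(epochs$data)[2]
  support <- ms_to_samples(width_ms, fs)
  if (support >= nt) stop("kernel support exceeds epoch length", call. = FALSE)
  k <- gaussian_kernel(support)
  out <- epochs
  for (ch in seq_len(dim(epochs$data)[3]))
    for (tr in seq_len(dim(epochs$data)[1]))
      out$data[tr, , ch] <- smooth_vec(epochs$data[tr, , ch], k)
  out
}

# Centred moving weighted average with reflect padding (odd-length kernel).
smooth_vec <- function(x, k) {
  half <- (length(k) - 1) / 2
  n <- length(x)
  xp <- c(rev(x[seq_len(half)]), x, rev(x[n - seq_len(half) + 1L]))
  as.numeric(stats::filter(xp, k, sides = 2))[half + seq_len(n)]
}

# Odd-length unit-area Gaussian kernel of given total support; sigma = support/6.
gaussian_kernel <- function(support) {
  half <- floor(support / 2)
  k <- stats::dnorm(seq(-half, half), sd = support / 6)
  k / sum(k)
}
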