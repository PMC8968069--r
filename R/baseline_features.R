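# Comparator feature extractors: autoregressive spectral amplitude,
# short-time Fourier band power, and continuous Morse-wavelet band power,
# each averaged per frequency band per sliding window.  These operate on the
# re-referenced broadband signal (not on the Hilbert power traces).

#' Autoregressive band spectral amplitude
#'
#' Yule-Walker AR spectrum of order \code{order}, evaluated at 1 Hz bins
#' inside \code{band}; the mean spectral amplitude (square root of the PSD by
#' default) across bins is returned.
#'
#' @param x window samples (length must exceed \code{order}).
#' @param fs sampling rate (Hz).
#' @param band \code{c(low, high)} in Hz.
#' @param order AR model order (default 100).
#' @param output \code{"amplitude"} (sqrt PSD, default) or \code{"psd"}.
#' @return scalar band feature.
#' @export
ar_band_amplitude <- function(x, fs, band, order = 100,
                              output = c("amplitude", "psd")) {
  output <- match.arg(output)
  if (length(x) <= order)
    stop("window length must exceed the AR order", call. = FALSE)
  fit <- stats::ar.yw(x, aic = FALSE, order.max = order, demean = TRUE)
  freqs <- seq(ceiling(band[1]), floor(band[2]), by = 1)
  if (length(freqs) == 0) stop("band holds no 1 Hz bins", call. = FALSE)
  a <- fit$ar
  denom <- vapply(freqs, function(f) {
    Mod(1 - sum(a * exp(-2i * pi * f / fs * seq_along(a))))^2
  }, numeric(1))
  psd <- fit$var.pred / (fs * denom)
  mean(if (output == "amplitude") sqrt(psd) else psd)
}

#' Short-time Fourier band power
#'
#' The window is divided into Hamming-windowed sections of length
#' \code{floor(n / 4.5)} with 50\% overlap; periodogram power spectral
#' densities are averaged over the band's frequency bins and over sections.
#'
#' @param x window samples.
#' @param fs sampling rate (Hz).
#' @param band \code{c(low, high)} in Hz.
#' @return scalar band power (PSD units).
#' @export
stft_band_power <- function(x, fs, band) {
  n <- length(x)
  if (n < 9) stop("window too short for STFT sectioning", call. = FALSE)
  seg <- floor(n / 4.5)
  step <- max(1, floor(seg / 2))      # 50% overlap
  w <- signal::hamming(seg)
  u <- sum(w^2) * fs                  # PSD normalisation
  starts <- seq(1, n - seg + 1, by = step)
  freqs <- (seq_len(seg) - 1) * fs / seg
  bins <- which(freqs >= band[1] & freqs <= band[2] & freqs <= fs / 2)
  if (length(bins) == 0)
    stop("band holds no frequency bins at this resolution", call. = FALSE)
  psd <- vapply(starts, function(s) {
    spec <- Mod(stats::fft(x[s:(s + seg - 1)] * w))^2 / u
    mean(spec[bins])
  }, numeric(1))
  mean(psd)
}

# Generalised Morse wavelet in the frequency domain, analytic (omega > 0),
# peak-normalised.  gamma = symmetry parameter, beta = time-bandwidth / gamma.
morse_wavelet_hat <- function(omega, gamma = 3, beta = 20) {
  wp <- (beta / gamma)^(1 / gamma)   # peak (radian) frequency
  out <- numeric(length(omega))
  pos <- omega > 0
  lw <- beta * log(omega[pos] / wp) - (omega[pos]^gamma - wp^gamma) / gamma
  out[pos] <- 2 * exp(lw)
  out
}

#' Continuous Morse-wavelet band power
#'
#' Analytic generalised Morse wavelet (symmetry parameter gamma = 3,
#' time-bandwidth product 60, i.e. beta = 20), implemented from its
#' frequency-domain definition; the mean absolute wavelet coefficient over
#' the band's scales and all time points is returned.
#'
#' @param x window samples (>= 32).
#' @param fs sampling rate (Hz).
#' @param band \code{c(low, high)} in Hz.
#' @param gamma Morse symmetry parameter.
#' @param tbp time-bandwidth product (beta = tbp / gamma).
#' @param voices scales per octave.
#' @return scalar mean absolute coefficient.
#' @export
wavelet_band_power <- function(x, fs, band, gamma = 3, tbp = 60,
                               voices = 12) {
  n <- length(x)
  if (n < 32) stop("window too short for wavelet analysis", call. = FALSE)
  beta <- tbp / gamma
  n_oct <- log2(band[2] / band[1])
  centers <- band[1] * 2^(seq(0, n_oct, length.out = max(2, ceiling(n_oct * voices) + 1)))
  xf <- stats::fft(x - mean(x))
  omega <- 2 * pi * (seq_len(n) - 1) / n          # radian freq per sample
  omega[omega > pi] <- omega[omega > pi] - 2 * pi # negative branch
  wp <- (beta / gamma)^(1 / gamma)
  coef_abs <- vapply(centers, function(fc) {
    s <- wp / (2 * pi * fc / fs)                  # scale mapping peak -> fc
    psi <- morse_wavelet_hat(s * omega, gamma, beta)
    mean(Mod(stats::fft(xf * psi, inverse = TRUE) / n))
  }, numeric(1))
  mean(coef_abs)
}

#' Comparator features over sliding windows
#'
#' Extracts one AR/STFT/wavelet band feature per (band, selected channel)
#' from the notch-filtered, Laplacian re-referenced broadband signal.  Each
#' band reuses the channel selection of the matching band-power trace.
#'
#' @param rec_reref re-referenced broadband [seeg_recording()] (e.g.
#'   \code{laplacian_rereference(comb_notch(rec))}).
#' @param selections named list of \code{channel_selection}s (names =
#'   bands) or channel-id vectors.
#' @param windows a [make_windows()] result.
#' @param method \code{"ar"}, \code{"stft"} or \code{"wavelet"}.
#' @param bands named list of \code{c(low, high)} bands; defaults to the
#'   bands named in \code{selections}.
#' @param labels optional window labels to attach.
#' @param ... extra arguments for the per-window extractor.
#' @return a \code{window_features} object.
#' @export
extract_comparator_features <- function(rec_reref, selections, windows,
                                        method = c("ar", "stft", "wavelet"),
                                        bands = NULL, labels = NULL, ...) {
  method <- match.arg(method)
  bands <- bands %||% BAND_DEFS[names(selections)]
  fun <- switch(method, ar = ar_band_amplitude, stft = stft_band_power,
                wavelet = wavelet_band_power)
  fs <- rec_reref$fs
  cols <- list()
  info <- list()
  for (bname in names(selections)) {
    sel <- selections[[bname]]
    ids <- if (is.character(sel)) sel else sel$channel[sel$selected]
    for (id in ids) {
      xch <- rec_reref$data[match(id, rec_reref$channels$id), ]
      vals <- vapply(seq_len(nrow(windows)), function(i) {
        seg <- xch[(windows$start_sample[i] + 1):windows$end_sample[i]]
        fun(seg, fs, bands[[bname]], ...)
      }, numeric(1))
      cols[[length(cols) + 1L]] <- vals
      info[[length(info) + 1L]] <- data.frame(trace = bname, channel = id,
                                              op = method,
                                              stringsAsFactors = FALSE)
    }
  }
  if (length(cols) == 0L) stop("empty channel selection", call. = FALSE)
  x <- do.call(cbind, cols)
  col_info <- do.call(rbind, info)
  colnames(x) <- paste(col_info$trace, col_info$channel, col_info$op,
                       sep = ".")
  structure(list(x = x, windows = windows, labels = labels,
                 col_info = col_info),
            class = "window_features")
}
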