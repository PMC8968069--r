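# Ground-truthed synthetic SEEG session generator.
#
# Emulates an intermittent auditory-name paradigm: two name stimuli repeated
# in a balanced pseudo-random sequence, 1/f background with 50 Hz line noise,
# evoked high-gamma envelope increases and ERP transients in a subset of
# channels.  Every generated session carries a per-sample ground-truth state
# timeline (active = 300-1000 ms after each stimulus onset).

#' Paradigm configuration for the synthetic session generator
#'
#' Defaults follow the richest variant of the recording paradigm: 120 trials,
#' 1-s stimuli, a 1100-1300 ms jittered inter-trial interval, and a 100-ms
#' attention cue followed by 500 ms of preparation before each name onset.
#'
#' @param n_trials number of stimulus presentations.
#' @param stim_duration_ms stimulus duration (ms).
#' @param iti_ms inter-trial interval in ms; a single value (fixed) or a
#'   length-2 range \code{c(low, high)} from which the jitter is drawn
#'   uniformly.
#' @param cue_ms duration of the attention cue (0 = no cue).
#' @param prep_ms preparation time between cue and stimulus onset (ms).
#' @param stim_types named numeric vector of stimulus-type proportions
#'   (must sum to 1).
#' @param fs sampling rate (Hz).
#' @param lead_in_ms silent time before the first trial (ms).
#' @param lead_out_ms silent time after the last trial's interval (ms).
#' @return list of class \code{paradigm_config}.
#' @export
paradigm_config <- function(n_trials = 120, stim_duration_ms = 1000,
                            iti_ms = c(1100, 1300), cue_ms = 100,
                            prep_ms = 500,
                            stim_types = c(own = 0.5, other = 0.5),
                            fs = 1000, lead_in_ms = 2000,
                            lead_out_ms = 1500) {
  if (n_trials <= 0) stop("n_trials must be positive", call. = FALSE)
  if (stim_duration_ms <= 0) stop("stim_duration_ms must be positive", call. = FALSE)
  if (length(iti_ms) == 1L) iti_ms <- c(iti_ms, iti_ms)
  if (length(iti_ms) != 2L || iti_ms[1] > iti_ms[2] || any(iti_ms < 0))
    stop("iti_ms must be a nonnegative value or low <= high range", call. = FALSE)
  if (cue_ms < 0 || prep_ms < 0) stop("cue_ms/prep_ms must be >= 0", call. = FALSE)
  if (is.null(names(stim_types)) || abs(sum(stim_types) - 1) > 1e-8)
    stop("stim_types must be a named vector of proportions summing to 1",
         call. = FALSE)
  if (fs < 500) stop("fs must be at least 500 Hz", call. = FALSE)
  structure(list(n_trials = as.integer(n_trials),
                 stim_duration_ms = stim_duration_ms, iti_ms = iti_ms,
                 cue_ms = cue_ms, prep_ms = prep_ms, stim_types = stim_types,
                 fs = fs, lead_in_ms = lead_in_ms, lead_out_ms = lead_out_ms),
            class = "paradigm_config")
}

#' Build a balanced pseudo-random event schedule
#'
#' Stimulus types are repeated in equal counts (within one for proportions
#' that do not divide \code{n_trials}) and shuffled.  The onset-to-onset gap
#' of consecutive trials is \code{cue + prep + stim + iti}, with the ITI drawn
#' uniformly from its range.
#'
#' @param cfg a [paradigm_config()].
#' @param seed integer seed; identical seeds give identical schedules.
#' @return an [event_table()] with one row per trial.  The attribute
#'   \code{session_samples} holds the total session length implied by the
#'   schedule (lead-in + trials + lead-out).
#' @export
build_event_schedule <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "paradigm_config"))
  local_seed(seed, {
    n <- cfg$n_trials
    ntypes <- names(cfg$stim_types)
    counts <- floor(cfg$stim_types * n)
    rem <- n - sum(counts)
    if (rem > 0) {  # distribute the remainder to the largest fractional parts
      frac <- cfg$stim_types * n - counts
      add <- order(frac, decreasing = TRUE)[seq_len(rem)]
      counts[add] <- counts[add] + 1
    }
    types <- sample(rep(ntypes, times = counts))
    iti <- stats::runif(n, cfg$iti_ms[1], cfg$iti_ms[2])
    pre <- cfg$cue_ms + cfg$prep_ms
    # onset i = lead_in + pre + sum over previous trials of (stim + iti + pre)
    gaps <- cfg$stim_duration_ms + iti + pre
    onset_ms <- cfg$lead_in_ms + pre + c(0, cumsum(gaps[-n]))
    ev <- event_table(ms_to_samples(onset_ms, cfg$fs), types,
                      cfg$stim_duration_ms, cfg$fs)
    end_ms <- onset_ms[n] + cfg$stim_duration_ms + iti[n] + cfg$lead_out_ms
    attr(ev, "session_samples") <- ms_to_samples(end_ms, cfg$fs)
    attr(ev, "stim_types") <- ntypes   # canonical type order (config order)
    ev
  })
}

#' Generate multichannel background SEEG noise
#'
#' Each channel is independent 1/f-shaped ("pink") noise plus white noise and
#' a common-frequency 50 Hz line component.  A slow multiplicative amplitude
#' modulation (log-normal, ~1 s correlation time) emulates the spontaneous
#' band-power fluctuations of real intracranial recordings; set
#' \code{am_sd = 0} for a stationary background.
#'
#' @param n_channels number of channels.
#' @param duration_s session duration in seconds (or use
#'   \code{n_samples}).
#' @param fs sampling rate, >= 500 Hz.
#' @param line_amp amplitude (uV) of the 50 Hz line component.
#' @param seed integer seed.
#' @param pink_sd,white_sd standard deviations (uV) of the 1/f and white
#'   components.
#' @param am_sd log-amplitude SD of the slow modulation (0 disables it).
#' @param am_tau_s correlation time (s) of the slow modulation.
#' @param burst_rate_hz rate (per channel, per second) of spontaneous
#'   transient bursts: brief (100-300 ms) single-channel high-gamma
#'   envelope bursts with a low-frequency deflection, emulating
#'   interictal-type transients of clinical recordings (0 disables them).
#' @param burst_gain range of the burst envelope gain (uniform draw).
#' @param burst_dur_ms range of burst durations (ms).
#' @param burst_lf amplitude scale (uV) of the burst's slow deflection.
#' @param shaft_size contacts per electrode shaft (8-16 typical).
#' @param n_samples optional explicit sample count overriding
#'   \code{duration_s}.
#' @return a [seeg_recording()].
#' @export
generate_background <- function(n_channels, duration_s, fs = 1000,
                                line_amp = 2, seed = NULL, pink_sd = 10,
                                white_sd = 2, am_sd = 0.25, am_tau_s = 1,
                                burst_rate_hz = 0.02, burst_gain = c(4, 9),
                                burst_dur_ms = c(100, 300), burst_lf = 15,
                                shaft_size = 10, n_samples = NULL) {
  if (fs < 500) stop("fs must be >= 500 Hz", call. = FALSE)
  n <- n_samples %||% as.integer(round(duration_s * fs))
  local_seed(seed, {
    t <- (seq_len(n) - 1) / fs
    line <- line_amp * sin(2 * pi * 50 * t)
    x <- matrix(0, n_channels, n)
    for (ch in seq_len(n_channels)) {
      pink <- pink_noise(n, fs) * pink_sd
      white <- stats::rnorm(n) * white_sd
      env <- if (am_sd > 0) slow_lognormal_env(n, fs, am_sd, am_tau_s) else 1
      x[ch, ] <- (pink + white) * env + line
      if (burst_rate_hz > 0)
        x[ch, ] <- x[ch, ] + burst_train(n, fs, burst_rate_hz, burst_gain,
                                         burst_dur_ms, burst_lf)
    }
    shafts <- LETTERS[((seq_len(n_channels) - 1) %/% shaft_size) + 1]
    contacts <- ((seq_len(n_channels) - 1) %% shaft_size) + 1
    channels <- data.frame(id = sprintf("%s%02d", shafts, contacts),
                           shaft = shafts, contact = contacts,
                           stringsAsFactors = FALSE)
    seeg_recording(x, fs, channels)
  })
}

# Unit-variance 1/f-amplitude noise via spectral shaping (FFT length kept
# 2-3-5-smooth, then trimmed).
pink_noise <- function(n, fs) {
  m <- stats::nextn(n, c(2, 3, 5))
  w <- stats::rnorm(m)
  xf <- stats::fft(w)
  f <- c(0, seq_len(m - 1)) * fs / m
  f <- pmin(f, fs - f)            # fold to physical frequencies
  shape <- ifelse(f < 1, 1, 1 / sqrt(f))  # flat below 1 Hz
  x <- Re(stats::fft(xf * shape, inverse = TRUE))[seq_len(n)] / m
  x / stats::sd(x)
}

# Spontaneous transient bursts at Poisson times: half-sine envelope on
# 60-140 Hz noise plus a random-sign slow deflection.  Single-channel by
# construction (called per channel), unlike the planted evoked responses,
# which are synchronous across responsive channels.
burst_train <- function(n, fs, rate_hz, gain_range, dur_ms, lf_amp) {
  out <- numeric(n)
  n_bursts <- stats::rpois(1, rate_hz * n / fs)
  max_dur <- ms_to_samples(dur_ms[2], fs)
  if (n_bursts == 0 || n <= max_dur + 2L) return(out)
  for (b in seq_len(n_bursts)) {
    dur <- ms_to_samples(stats::runif(1, dur_ms[1], dur_ms[2]), fs)
    s0 <- sample.int(n - dur, 1)
    env <- sin(pi * seq_len(dur) / (dur + 1))
    carrier <- bandlimited_noise(dur, fs, c(60, 140))
    g <- stats::runif(1, gain_range[1], gain_range[2])
    lf <- lf_amp * stats::runif(1, 0.5, 1.5) * sample(c(-1, 1), 1)
    idx <- s0 + seq_len(dur) - 1L
    out[idx] <- out[idx] + env * (g * carrier + lf)
  }
  out
}

# exp(am_sd * s(t) - am_sd^2/2) with s a unit-variance slow Gaussian
# process (correlation time tau_s).  The slow process is built on a coarse
# 50 Hz grid and interpolated, which is exact to visual precision for
# tau_s >= 0.2 s and keeps the cost linear with a tiny constant.
slow_lognormal_env <- function(n, fs, am_sd, tau_s) {
  fs_c <- 50
  n_c <- max(8L, ceiling(n / fs * fs_c) + 2L)
  s <- stats::rnorm(n_c)
  sigma <- max(1, tau_s * fs_c / 2)
  half <- ceiling(3 * sigma)
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  sp <- c(rev(s[seq_len(half)]), s, rev(s[n_c - seq_len(half) + 1]))
  sm <- as.numeric(stats::filter(sp, k, sides = 2))[half + seq_len(n_c)]
  sm <- (sm - mean(sm)) / stats::sd(sm)
  full <- stats::approx(seq(0, by = 1 / fs_c, length.out = n_c), sm,
                        xout = (seq_len(n) - 1) / fs)$y
  exp(am_sd * full - am_sd^2 / 2)
}

#' Describe an evoked response to plant into a channel
#'
#' High-gamma (and alpha/beta) responses are multiplicative envelopes on
#' band-limited noise, so Hilbert power scales with the square of
#' \code{gain}.  ERP responses are sums of damped low-frequency sinusoids
#' (< 15 Hz) with fixed polarity.
#'
#' @param channel channel id (as in the recording metadata).
#' @param kind \code{"high_gamma"}, \code{"beta"}, \code{"alpha"} or
#'   \code{"erp"}.
#' @param latency_ms response onset relative to stimulus onset (ms).
#' @param duration_ms response duration (ms).
#' @param gain unitless envelope multiplier (high-gamma) or amplitude in uV
#'   (ERP); 0 leaves the signal untouched.
#' @param type_gain named multipliers applied per stimulus type (defaults to
#'   1 for every type).
#' @param polarity +1 or -1; fixed ERP polarity for the channel.
#' @return list of class \code{response_profile}.
#' @export
response_profile <- function(channel, kind = "high_gamma", latency_ms = 300,
                             duration_ms = 700, gain = 2,
                             type_gain = NULL, polarity = 1) {
  kind <- match.arg(kind, c("high_gamma", "beta", "alpha", "erp"))
  if (latency_ms < 0) stop("latency_ms must be >= 0", call. = FALSE)
  if (gain < 0) stop("gain must be >= 0", call. = FALSE)
  structure(list(channel = channel, kind = kind, latency_ms = latency_ms,
                 duration_ms = duration_ms, gain = gain,
                 type_gain = type_gain, polarity = polarity),
            class = "response_profile")
}

# Smooth response envelope: raised-cosine ramps (100 ms) at both ends.
response_envelope <- function(n_resp, fs, ramp_ms = 100) {
  ramp <- max(2L, ms_to_samples(ramp_ms, fs))
  ramp <- min(ramp, floor(n_resp / 2))
  env <- rep(1, n_resp)
  up <- 0.5 * (1 - cos(pi * seq_len(ramp) / ramp))
  env[seq_len(ramp)] <- up
  env[n_resp - seq_len(ramp) + 1] <- up
  env
}

#' Plant evoked responses into a background recording
#'
#' Only channels named in the profiles are modified; a profile with
#' \code{gain = 0} leaves its channel bit-identical.  The returned ground
#' truth marks \code{[onset + 300 ms, onset + 1000 ms)} after every stimulus
#' as active, labelled by stimulus type.
#'
#' @param rec background [seeg_recording()].
#' @param events an [event_table()].
#' @param profiles list of [response_profile()] objects.
#' @param seed integer seed (response-carrier noise).
#' @param active_window_ms the ground-truth active interval relative to each
#'   onset (ms, half-open).
#' @return list with the modified \code{recording} and a \code{truth} object
#'   (per-sample state code: 0 idle, i = i-th stimulus type; plus the planted
#'   responsive channel set per trace kind).
#' @export
inject_responses <- function(rec, events, profiles, seed = NULL,
                             active_window_ms = c(300, 1000)) {
  stopifnot(inherits(rec, "seeg_recording"))
  n <- ncol(rec$data)
  fs <- rec$fs
  types <- attr(events, "stim_types") %||% unique(events$type)
  for (p in profiles)
    if (!p$channel %in% rec$channels$id)
      stop("unknown channel id in profile: ", p$channel, call. = FALSE)

  bands <- list(high_gamma = c(60, 140), beta = c(13, 30), alpha = c(8, 12))
  out <- rec
  local_seed(seed, {
    for (p in profiles) {
      if (p$gain == 0) next
      ch <- match(p$channel, rec$channels$id)
      lat <- ms_to_samples(p$latency_ms, fs)
      dur <- ms_to_samples(p$duration_ms, fs)
      tg <- rep(1, length(types)); names(tg) <- types
      if (!is.null(p$type_gain)) tg[names(p$type_gain)] <- p$type_gain
      add <- numeric(n)
      if (p$kind == "erp") {
        resp <- erp_waveform(dur, fs) * p$polarity
      } else {
        carrier <- bandlimited_noise(n, fs, bands[[p$kind]])
        env_shape <- response_envelope(dur, fs)
      }
      for (i in seq_len(nrow(events))) {
        s0 <- events$onset_sample[i] + lat + 1L  # 0-based onset -> 1-based index
        idx <- s0:min(s0 + dur - 1L, n)
        if (length(idx) < 2L) next
        g <- p$gain * tg[[events$type[i]]]
        if (p$kind == "erp") {
          add[idx] <- add[idx] + g * resp[seq_along(idx)]
        } else {
          add[idx] <- add[idx] + g * env_shape[seq_along(idx)] * carrier[idx]
        }
      }
      out$data[ch, ] <- out$data[ch, ] + add
    }
  })

  states <- integer(n)
  a0 <- ms_to_samples(active_window_ms[1], fs)
  a1 <- ms_to_samples(active_window_ms[2], fs)
  for (i in seq_len(nrow(events))) {
    idx <- (events$onset_sample[i] + a0 + 1L):(events$onset_sample[i] + a1)
    idx <- idx[idx >= 1L & idx <= n]
    states[idx] <- match(events$type[i], types)
  }
  responsive <- split(vapply(profiles, `[[`, "", "channel"),
                      vapply(profiles, `[[`, "", "kind"))
  responsive <- lapply(responsive, unique)
  truth <- structure(list(states = states, types = types, fs = fs,
                          responsive = responsive,
                          active_window_ms = active_window_ms),
                     class = "ground_truth")
  list(recording = out, truth = truth)
}

# Unit-variance band-limited Gaussian noise (zero-phase Butterworth).
bandlimited_noise <- function(n, fs, band) {
  w <- stats::rnorm(n)
  bf <- signal::butter(3, band * 2 / fs, type = "pass")
  x <- iir_filtfilt(bf$b, bf$a, w, pad = min(200L, n - 1L))
  x / stats::sd(x)
}

# Damped low-frequency transient: 3 decaying sinusoids below 15 Hz, peak ~1.
# The slow (1 Hz) component decays before completing its negative lobe, so
# the waveform carries a sustained deflection (nonzero mean) over the
# response window, as real evoked potentials do.
erp_waveform <- function(n_resp, fs) {
  t <- (seq_len(n_resp) - 1) / fs
  w <- exp(-t / 0.3) * (sin(2 * pi * 1 * t) + 0.4 * sin(2 * pi * 5 * t) +
                          0.2 * sin(2 * pi * 9 * t))
  w / max(abs(w))
}

#' Default responsive-channel profiles for a simulated session
#'
#' Five responsive channels out of twenty, each carrying a high-gamma
#' envelope response and an ERP transient with heterogeneous gains (some
#' strong, some near detection threshold).
#'
#' @param channel_ids channel id vector of the session.
#' @param responsive indices (into \code{channel_ids}) of responsive channels.
#' @param hg_gain,erp_gain gain per responsive channel (recycled).
#' @param type_gain optional named per-stimulus-type multipliers shared by all
#'   profiles (e.g. \code{c(own = 1.3, other = 0.7)} for type-selective
#'   responses).
#' @return list of [response_profile()] objects.
#' @export
default_profiles <- function(channel_ids,
                             responsive = c(2, 6, 9, 13, 17),
                             hg_gain = c(8, 6.5, 5.5, 4.5, 3.5),
                             erp_gain = c(30, 26, 22, 18, 15),
                             type_gain = NULL) {
  responsive <- responsive[responsive <= length(channel_ids)]
  if (length(responsive) == 0)
    stop("no responsive channel index within range", call. = FALSE)
  hg_gain <- rep_len(hg_gain, length(responsive))
  erp_gain <- rep_len(erp_gain, length(responsive))
  profiles <- list()
  for (i in seq_along(responsive)) {
    ch <- channel_ids[responsive[i]]
    profiles <- c(profiles, list(
      response_profile(ch, "high_gamma", gain = hg_gain[i],
                       type_gain = type_gain),
      response_profile(ch, "erp", gain = erp_gain[i],
                       polarity = if (i %% 2) 1 else -1,
                       type_gain = type_gain)))
  }
  profiles
}

#' Simulate a complete ground-truthed SEEG session
#'
#' Convenience wrapper: schedule, background, and planted responses in one
#' call.  The defaults are the package's reference study conditions: 120
#' trials at 1 kHz, 20 channels on 2 shafts, 5 responsive channels.
#'
#' @param cfg a [paradigm_config()].
#' @param n_channels number of channels.
#' @param profiles list of [response_profile()]s, or \code{NULL} for
#'   [default_profiles()]; use \code{list()} for a null (no-response) session.
#' @param seed integer seed controlling schedule, background and responses.
#' @param ... passed to [generate_background()].
#' @return list with \code{recording}, \code{events}, \code{truth},
#'   \code{profiles}, \code{cfg}.
#' @export
simulate_session <- function(cfg = paradigm_config(), n_channels = 20,
                             profiles = NULL, seed = 1, ...) {
  events <- build_event_schedule(cfg, seed = child_seed(seed, 1))
  n <- attr(events, "session_samples")
  rec <- generate_background(n_channels, fs = cfg$fs, n_samples = n,
                             seed = child_seed(seed, 2), ...)
  if (is.null(profiles)) profiles <- default_profiles(rec$channels$id)
  inj <- inject_responses(rec, events, profiles, seed = child_seed(seed, 3))
  list(recording = inj$recording, events = events, truth = inj$truth,
       profiles = profiles, cfg = cfg)
}
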