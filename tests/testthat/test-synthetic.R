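# Synthetic session generator: schedule, background, planted responses.

test_that("event schedule is balanced, gap-consistent and seeded", {
  cfg <- paradigm_config(n_trials = 120, stim_duration_ms = 1000,
                         iti_ms = c(1100, 1300), cue_ms = 100, prep_ms = 500)
  ev <- build_event_schedule(cfg, seed = 4)
  expect_equal(nrow(ev), 120)
  expect_equal(unname(table(ev$type)["own"]), 60L)
  expect_equal(unname(table(ev$type)["other"]), 60L)
  gaps <- diff(ev$onset_sample)  # ms at fs = 1000
  lo <- 1000 + 1100 + 600
  hi <- 1000 + 1300 + 600
  expect_true(all(gaps >= lo - 1 & gaps <= hi + 1))
  expect_identical(build_event_schedule(cfg, seed = 4), ev)
  expect_false(identical(build_event_schedule(cfg, seed = 5)$type, ev$type))
})

test_that("fixed inter-trial interval gives exactly periodic onsets", {
  cfg <- paradigm_config(n_trials = 2, stim_duration_ms = 2000,
                         iti_ms = 2000, cue_ms = 0, prep_ms = 0)
  ev <- build_event_schedule(cfg, seed = 1)
  expect_equal(diff(ev$onset_sample), 4000)
})

test_that("paradigm validation rejects inconsistent configurations", {
  expect_error(paradigm_config(n_trials = 0), "n_trials")
  expect_error(paradigm_config(stim_duration_ms = -5), "stim_duration")
  expect_error(paradigm_config(iti_ms = c(300, 100)), "iti_ms")
  expect_error(paradigm_config(stim_types = c(own = 0.7, other = 0.5)),
               "proportions")
  expect_error(paradigm_config(fs = 200), "fs")
})

test_that("background has the requested geometry and line component", {
  rec <- generate_background(4, 10, fs = 1000, seed = 2, am_sd = 0,
                             burst_rate_hz = 0)
  expect_equal(dim(rec$data), c(4, 10000))
  expect_equal(length(unique(rec$channels$shaft)), 1)

  pow50 <- function(x) {
    sp <- Mod(stats::fft(x))^2
    f <- (seq_along(x) - 1) * 1000 / length(x)
    c(peak = mean(sp[abs(f - 50) < 0.5]),
      neigh = mean(sp[abs(f - 50) > 2 & abs(f - 50) < 8]))
  }
  clean <- generate_background(1, 10, fs = 1000, line_amp = 0, seed = 3,
                               am_sd = 0, burst_rate_hz = 0)
  p0 <- pow50(clean$data[1, ])
  expect_lt(p0["peak"] / p0["neigh"], 2)

  noisy <- generate_background(1, 10, fs = 1000, line_amp = 40, seed = 3,
                               am_sd = 0, burst_rate_hz = 0)
  p1 <- pow50(noisy$data[1, ])
  expect_gt(p1["peak"] / p1["neigh"], 50)
})

test_that("response injection modifies only listed channels and spans", {
  cfg <- paradigm_config(n_trials = 6, iti_ms = 1000, cue_ms = 0,
                         prep_ms = 0)
  ev <- build_event_schedule(cfg, seed = 1)
  rec <- generate_background(4, n_samples = attr(ev, "session_samples"),
                             fs = 1000, seed = 2)
  prof0 <- list(response_profile("A02", "high_gamma", gain = 0))
  out0 <- inject_responses(rec, ev, prof0, seed = 9)
  expect_identical(out0$recording$data, rec$data)

  prof <- list(response_profile("A02", "high_gamma", gain = 5))
  out <- inject_responses(rec, ev, prof, seed = 9)
  expect_identical(out$recording$data[-2, ], rec$data[-2, ])
  expect_false(identical(out$recording$data[2, ], rec$data[2, ]))

  # ground truth: one 700-ms active span per stimulus
  r <- rle(out$truth$states > 0)
  expect_equal(sum(r$values), 6)
  expect_true(all(r$lengths[r$values] == 700))

  expect_error(inject_responses(rec, ev, list(
    response_profile("nope", gain = 1)), seed = 1), "unknown channel")
})

test_that("planted high-gamma envelope raises Hilbert power in active spans", {
  cfg <- paradigm_config(n_trials = 10, iti_ms = 1500, cue_ms = 0,
                         prep_ms = 0)
  ev <- build_event_schedule(cfg, seed = 3)
  rec <- generate_background(4, n_samples = attr(ev, "session_samples"),
                             fs = 1000, seed = 4, am_sd = 0,
                             burst_rate_hz = 0)
  out <- inject_responses(rec, ev,
                          list(response_profile("A02", "high_gamma",
                                                gain = 6)), seed = 5)
  tr <- band_power_trace(out$recording, "high_gamma")
  active <- out$truth$states > 0
  # Laplacian mixes the response into neighbours; check the planted channel
  ratio <- mean(tr$data["A02", active]) / mean(tr$data["A02", !active])
  expect_gt(ratio, 2)
})

test_that("per-type gain modifiers separate the trial-averaged envelopes", {
  cfg <- paradigm_config(n_trials = 20, iti_ms = 1200, cue_ms = 0,
                         prep_ms = 0)
  ev <- build_event_schedule(cfg, seed = 6)
  rec <- generate_background(3, n_samples = attr(ev, "session_samples"),
                             fs = 1000, seed = 7, am_sd = 0,
                             burst_rate_hz = 0)
  out <- inject_responses(rec, ev, list(
    response_profile("A02", "high_gamma", gain = 6,
                     type_gain = c(own = 1.5, other = 0.3))), seed = 8)
  tr <- band_power_trace(out$recording, "high_gamma")
  mean_by_type <- vapply(c("own", "other"), function(ty) {
    on <- ev$onset_sample[ev$type == ty]
    mean(vapply(on, function(o) mean(tr$data["A02", (o + 301):(o + 1000)]),
                numeric(1)))
  }, numeric(1))
  expect_gt(mean_by_type["own"], 2 * mean_by_type["other"])
})

test_that("sessions are bit-identical under the same seed", {
  cfg <- paradigm_config(n_trials = 4, iti_ms = 1000, cue_ms = 0, prep_ms = 0)
  s1 <- simulate_session(cfg, n_channels = 6, seed = 12)
  s2 <- simulate_session(cfg, n_channels = 6, seed = 12)
  expect_identical(s1$recording$data, s2$recording$data)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$truth$states, s2$truth$states)
})

test_that("session writer and reader round-trip", {
  dir <- withr::local_tempdir()
  cfg <- paradigm_config(n_trials = 3, iti_ms = 1000, cue_ms = 0, prep_ms = 0)
  ses <- simulate_session(cfg, n_channels = 4, seed = 1)
  write_session(ses, dir)
  expect_true(file.exists(file.path(dir, "events.tsv")))
  back <- read_session(dir)
  expect_equal(back$recording$data, ses$recording$data)
  expect_equal(back$events$onset_sample, ses$events$onset_sample)
  expect_equal(back$truth$states, ses$truth$states)
})
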