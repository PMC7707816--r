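# Quantal kernel, evoked/mini simulators, burst injection: shape, latency
# statistics, superposition, driving force, determinism.

test_that("quantal kernel starts at zero and peaks at the model amplitude", {
  acq <- acquisition_spec(sampling_rate_hz = 200000, filter_cutoff_hz = 90000,
                          sweep_duration_s = 1)
  qm <- quantal_model(amplitude_pa = 50, tau_rise_ms = 1, tau_decay_ms = 15)
  k <- quantal_waveform(qm, acq)
  expect_equal(k[1L], 0)
  expect_lt(abs(max(k) - 50) / 50, 0.001)
  # closed-form peak time vs dense numeric argmax
  t_star <- 1 * log(1 + 15 / 1) # ms
  t_num <- (which.max(k) - 1L) / 200000 * 1000
  expect_lt(abs(t_num - t_star), 0.01)
  expect_gte(length(k) / 200000, 5 * 15 / 1000)
})

test_that("with a very fast rise the decay phase is a pure exponential", {
  acq <- acquisition_spec(sampling_rate_hz = 100000, filter_cutoff_hz = 45000,
                          sweep_duration_s = 1)
  td <- 10
  qm <- quantal_model(amplitude_pa = 1, tau_rise_ms = 0.01 * td, tau_decay_ms = td)
  k <- quantal_waveform(qm, acq)
  t_ms <- (seq_along(k) - 1L) / 100 # ms
  sel <- t_ms > 5 * 0.01 * td & t_ms < 5 * td
  # shape comparison: scale the pure exponential to match at the first point
  pure <- exp(-(t_ms[sel] - t_ms[sel][1L]) / td) * k[sel][1L]
  expect_lt(max(abs(k[sel] - pure) / pure), 0.01)
})

test_that("rise slower than decay is rejected", {
  expect_error(quantal_model(tau_rise_ms = 20, tau_decay_ms = 15), "tau_rise")
})

test_that("a silent synapse produces pure noise and an empty truth table", {
  acq <- acquisition_spec(sweep_duration_s = 0.2)
  rel <- release_model(quantal_content = 0)
  sw <- simulate_evoked(rel, acq, n_trials = 3, noise_sd_pa = 2, seed = 1)
  expect_equal(nrow(sw$truth), 0L)
  expect_lt(max(abs(colMeans(sw$current))), 1)
  expect_gt(sd(sw$current[, 1]), 0.5)
})

test_that("sweeps at the reversal potential carry no synaptic current", {
  acq0 <- acquisition_spec(sweep_duration_s = 0.2, holding_mv = 0)
  rel <- release_model(quantal_content = 20)
  sw <- simulate_evoked(rel, acq0, n_trials = 3, noise_sd_pa = 0, seed = 2)
  expect_gt(nrow(sw$truth), 0L)
  expect_equal(max(abs(sw$current)), 0)
})

test_that("synaptic amplitude scales linearly with driving force", {
  rel <- release_model(quantal_content = 10, count_model = "fixed",
                       transmitter_mix = 1, glycine = glycine_quantal(cv = 0),
                       latency = latency_model("synchronous", sigma_sync_ms = 0.05))
  amp_at <- function(h) {
    acq <- acquisition_spec(sweep_duration_s = 0.2, holding_mv = h)
    sw <- simulate_evoked(rel, acq, n_trials = 1, noise_sd_pa = 0, seed = 5)
    max(abs(sw$current))
  }
  a60 <- amp_at(-60); a30 <- amp_at(-30)
  expect_equal(a30 / a60, 0.5, tolerance = 1e-6)
  # inward at -60 mV: negative current
  acq <- acquisition_spec(sweep_duration_s = 0.2, holding_mv = -60)
  sw <- simulate_evoked(rel, acq, n_trials = 1, noise_sd_pa = 0, seed = 5)
  expect_lt(min(sw$current), 0)
  expect_lt(max(sw$current), abs(min(sw$current)) / 10)
})

test_that("noiseless sweeps are exact kernel superpositions", {
  acq <- acquisition_spec(sweep_duration_s = 0.3)
  rel <- release_model(quantal_content = 5, transmitter_mix = 0.5,
                       latency = latency_model("mixed", mix_weight = 0.5))
  sw <- simulate_evoked(rel, acq, n_trials = 2, noise_sd_pa = 0, seed = 7)
  # oracle: rebuild each trial directly from the truth table with signal::filtfilt
  fs <- acq$sampling_rate_hz
  n <- nrow(sw$current)
  kg <- quantal_waveform(gaba_quantal(), acq) / gaba_quantal()$amplitude_pa
  ky <- quantal_waveform(glycine_quantal(), acq) / glycine_quantal()$amplitude_pa
  bf <- signal::butter(4, acq$filter_cutoff_hz / (fs / 2), type = "low")
  for (tr in 1:2) {
    tt <- sw$truth[sw$truth$trial == tr, ]
    expected <- numeric(n)
    for (i in seq_len(nrow(tt))) {
      kern <- if (tt$transmitter[i] == "glycine") ky else kg
      s0 <- round(tt$time_s[i] * fs) + 1L
      s1 <- min(n, s0 + length(kern) - 1L)
      if (s0 <= n)
        expected[s0:s1] <- expected[s0:s1] + tt$amplitude_pa[i] * kern[seq_len(s1 - s0 + 1L)]
    }
    expected <- as.numeric(signal::filtfilt(bf, -expected))
    expect_equal(sw$current[, tr], expected, tolerance = 1e-9)
  }
})

test_that("latency statistics match the configured model", {
  acq <- acquisition_spec(sweep_duration_s = 1.0)
  rel_s <- release_model(quantal_content = 40, count_model = "fixed",
                         latency = latency_model("synchronous", mu_sync_ms = 2,
                                                 sigma_sync_ms = 0.4))
  sw_s <- simulate_evoked(rel_s, acq, n_trials = 30, noise_sd_pa = 0, seed = 8)
  lat <- sw_s$truth$latency_ms
  expect_gt(length(lat), 1000)
  expect_lt(abs(sd(lat) - 0.4), 3 * 0.4 / sqrt(2 * length(lat)) + 0.01)
  rel_a <- release_model(quantal_content = 40, count_model = "fixed",
                         latency = latency_model("asynchronous", tau_async_ms = 50,
                                                 delay_async_ms = 2))
  sw_a <- simulate_evoked(rel_a, acq, n_trials = 30, noise_sd_pa = 0, seed = 9)
  lat_a <- sw_a$truth$latency_ms
  expect_lt(abs(mean(lat_a) - 52), 3 * 50 / sqrt(length(lat_a)))
})

test_that("simulators are deterministic under a fixed seed", {
  acq <- acquisition_spec(sweep_duration_s = 0.2)
  rel <- release_model(quantal_content = 10)
  s1 <- simulate_evoked(rel, acq, n_trials = 3, seed = 42)
  s2 <- simulate_evoked(rel, acq, n_trials = 3, seed = 42)
  expect_identical(s1$current, s2$current)
  expect_identical(s1$truth, s2$truth)
  m1 <- simulate_minis(mini_model(rate_hz = 3), duration_s = 5, seed = 42)
  m2 <- simulate_minis(mini_model(rate_hz = 3), duration_s = 5, seed = 42)
  expect_identical(m1$current, m2$current)
})

test_that("mini event counts follow the Poisson law and superpose linearly", {
  mm <- mini_model(rate_hz = 2)
  sw <- simulate_minis(mm, glycine_quantal(), duration_s = 600, noise_sd_pa = 2, seed = 10)
  expect_lt(abs(nrow(sw$truth) - 1200), 3 * sqrt(1200))
  # lambda = 0 -> no events
  sw0 <- simulate_minis(mini_model(rate_hz = 0), duration_s = 5, seed = 11)
  expect_equal(nrow(sw0$truth), 0L)
  # two events 1 ms apart: trace equals the sum of the single-event traces
  acq <- acquisition_spec(sweep_duration_s = 0.2)
  rel <- release_model(glycine = glycine_quantal(cv = 0), transmitter_mix = 1)
  mk <- function(t0) data.frame(trial = 1L, stimulus = 1L, time_s = t0,
                                latency_ms = 0, amplitude_pa = 60,
                                transmitter = "glycine", component = "sync")
  one <- render_truth(mk(0.05), rel, acq, n_trials = 1, noise_sd_pa = 0)
  two <- render_truth(mk(0.051), rel, acq, n_trials = 1, noise_sd_pa = 0)
  both <- render_truth(rbind(mk(0.05), mk(0.051)), rel, acq, n_trials = 1, noise_sd_pa = 0)
  expect_equal(both$current, one$current + two$current, tolerance = 1e-9)
})

test_that("burst injection is paired, seeded and matched-filter detectable", {
  acq <- acquisition_spec(sweep_duration_s = 0.5, stimulus_times_s = 0.4)
  rel <- release_model(quantal_content = 5)
  sw <- simulate_evoked(rel, acq, n_trials = 4, noise_sd_pa = 1, seed = 12)
  tmpl <- gap_burst_template(acq)
  # rate 0: unchanged
  b0 <- inject_gap_bursts(sw, tmpl, rate_hz = 0, seed = 1)
  expect_identical(b0$current, sw$current)
  # same seed on a paired set injects identical bursts
  sw2 <- simulate_evoked(rel, acquisition_spec(sweep_duration_s = 0.5,
                                               stimulus_times_s = 0.4,
                                               holding_mv = 0),
                         n_trials = 4, noise_sd_pa = 1, seed = 13)
  b1 <- inject_gap_bursts(sw, tmpl, rate_hz = 3, seed = 99)
  b2 <- inject_gap_bursts(sw2, tmpl, rate_hz = 3, seed = 99)
  expect_identical(b1$burst_truth, b2$burst_truth)
  expect_gt(nrow(b1$burst_truth), 0L)
  # matched filter: the sliding dot product of (output - input) with the
  # template peaks at an injection sample (direct-sum oracle)
  tr1 <- b1$burst_truth$trial[1L]
  d <- b1$current[, tr1] - sw$current[, tr1]
  lt <- length(tmpl)
  cc <- vapply(seq_len(length(d) - lt + 1L),
               function(i) sum(d[i:(i + lt - 1L)] * tmpl), 0)
  t_inj <- b1$burst_truth$time_s[b1$burst_truth$trial == tr1]
  expect_true(min(abs((which.max(cc) - 1L) / acq$sampling_rate_hz - t_inj)) < 0.001)
})
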