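# Evoked-IPSC measurements: jitter, half-rise, decay fit, charge,
# component subtraction, burst handling, train analysis.

test_that("identical trials give zero jitter", {
  acq <- acquisition_spec(sweep_duration_s = 0.3)
  rel <- release_model(glycine = glycine_quantal(cv = 0), transmitter_mix = 1)
  tt <- data.frame(trial = 1:3, stimulus = 1L, time_s = 0.06, latency_ms = 10,
                   amplitude_pa = 60, transmitter = "glycine", component = "sync")
  sw <- render_truth(tt, rel, acq, n_trials = 3, noise_sd_pa = 0)
  k <- compute_kinetics(sw, window_ms = 100)
  expect_equal(k$jitter_ms, 0)
})

test_that("jitter is the n-1 sample SD of per-trial peak times and is shift invariant", {
  acq <- acquisition_spec(sweep_duration_s = 0.3)
  rel <- release_model(glycine = glycine_quantal(cv = 0), transmitter_mix = 1)
  mk <- function(lat_ms) data.frame(trial = 1:3, stimulus = 1L,
                                    time_s = 0.05 + lat_ms / 1000,
                                    latency_ms = lat_ms, amplitude_pa = 60,
                                    transmitter = "glycine", component = "sync")
  sw <- render_truth(mk(c(10.0, 10.2, 10.4)), rel, acq, n_trials = 3, noise_sd_pa = 0)
  k <- compute_kinetics(sw, window_ms = 100)
  expect_equal(k$jitter_ms, sd(c(10.0, 10.2, 10.4)), tolerance = 0.05)
  expect_equal(k$jitter_ms, 0.2, tolerance = 0.05)
  # common shift of all trials leaves jitter unchanged
  sw2 <- render_truth(mk(c(15.0, 15.2, 15.4)), rel, acq, n_trials = 3, noise_sd_pa = 0)
  k2 <- compute_kinetics(sw2, window_ms = 100)
  expect_equal(k2$jitter_ms, k$jitter_ms, tolerance = 0.01)
})

test_that("the decay fit recovers a pure exponential appended to an instant rise", {
  fs <- 20000
  t <- seq(0, 0.4, by = 1 / fs)
  tau <- 20 # ms
  trace <- -c(numeric(sum(t < 0.05)), 100 * exp(-(t[t >= 0.05] - 0.05) / (tau / 1000)))
  sw <- make_sweeps(matrix(trace, ncol = 1), fs = fs, stimulus_times_s = 0.05)
  k <- compute_kinetics(sw, window_ms = 300)
  expect_lt(abs(k$decay_tau_ms - tau) / tau, 0.01)
  expect_equal(k$peak_amplitude_pa, 100, tolerance = 1)
})

test_that("half-rise is the interpolated 50% crossing from stimulus onset", {
  fs <- 20000
  n <- round(0.3 * fs)
  acq_ref <- acquisition_spec(sampling_rate_hz = fs, sweep_duration_s = 0.3)
  k_g <- quantal_waveform(glycine_quantal(), acq_ref)
  trace <- numeric(n)
  s0 <- round(0.05 * fs) + 1L
  trace[s0:(s0 + length(k_g) - 1L)] <- -k_g
  sw <- make_sweeps(matrix(trace, ncol = 1), fs = fs, stimulus_times_s = 0.05)
  k <- compute_kinetics(sw, window_ms = 100)
  # oracle: first 50% crossing of the kernel itself, linearly interpolated
  half <- max(k_g) / 2
  i <- which(k_g >= half)[1L]
  t_half <- ((i - 2L) + (half - k_g[i - 1L]) / (k_g[i] - k_g[i - 1L])) / fs * 1000
  expect_equal(k$half_rise_ms, t_half, tolerance = 0.02)
  expect_lt(k$half_rise_ms, k$peak_time_ms)
})

test_that("responses below the noise floor are flagged absent", {
  set.seed(1)
  cur <- matrix(rnorm(6000 * 4, sd = 2), ncol = 4)
  sw <- make_sweeps(cur, stimulus_times_s = 0.05)
  k <- compute_kinetics(sw, window_ms = 100)
  expect_true(k$no_response)
})

test_that("component subtraction obeys charge additivity and detects absence", {
  acq <- acquisition_spec(sweep_duration_s = 0.5)
  rel <- release_model(quantal_content = 10, transmitter_mix = 0.5)
  ctrl <- simulate_evoked(rel, acq, n_trials = 10, noise_sd_pa = 1, seed = 21)
  # inert drug: difference flagged absent
  same <- ctrl
  cr0 <- subtract_components(ctrl, same, blocked = "gaba", window_ms = 150)
  expect_true(cr0$gaba$no_response)
  expect_equal(max(abs(cr0$difference_trace)), 0)
  # complete block: difference equals the control average
  zero <- ctrl; zero$current[] <- 0
  cr1 <- subtract_components(ctrl, zero, blocked = "gaba", window_ms = 150)
  st <- round(0.05 * acq$sampling_rate_hz) + 1L
  base <- colMeans(ctrl$current[(st - 200):(st - 1L), ])
  avg_ctrl <- rowMeans(-(ctrl$current - matrix(base, nrow(ctrl$current), ncol(ctrl$current), byrow = TRUE)))
  expect_equal(cr1$difference_trace, avg_ctrl, tolerance = 1e-9)
  # charge additivity: charge(control) = charge(after drug) + charge(difference)
  gly <- render_truth(ctrl$truth[ctrl$truth$transmitter == "glycine", ], rel, acq,
                      n_trials = 10, noise_sd_pa = 1, seed = 22)
  cr2 <- subtract_components(ctrl, gly, blocked = "gaba", window_ms = 150)
  k_ctrl <- compute_kinetics(ctrl, window_ms = 150)
  k_gly <- compute_kinetics(gly, window_ms = 150)
  expect_equal(k_ctrl$charge_pc, k_gly$charge_pc + cr2$gaba$charge_pc, tolerance = 1e-6)
  # mismatched acquisition is rejected
  acq2 <- acquisition_spec(sweep_duration_s = 0.5, stimulus_times_s = 0.07)
  other <- simulate_evoked(rel, acq2, n_trials = 10, noise_sd_pa = 1, seed = 23)
  expect_error(subtract_components(ctrl, other), "incompatible")
})

test_that("gap bursts are rejected by template correlation and subtracted via 0 mV scaling", {
  acq60 <- acquisition_spec(sweep_duration_s = 0.5, stimulus_times_s = 0.35)
  acq0 <- acquisition_spec(sweep_duration_s = 0.5, stimulus_times_s = 0.35, holding_mv = 0)
  rel <- release_model(quantal_content = 10, transmitter_mix = 1)
  sw60 <- simulate_evoked(rel, acq60, n_trials = 12, noise_sd_pa = 0.5, seed = 31)
  sw0 <- simulate_evoked(rel, acq0, n_trials = 12, noise_sd_pa = 0.5, seed = 32)
  tmpl <- gap_burst_template(acq60, amplitude_pa = 80)
  # clean recordings: nothing rejected, subtraction scale near zero
  rj0 <- handle_gap_bursts(sw60, template = tmpl, mode = "reject")
  expect_length(rj0$rejected, 0L)
  sb0 <- handle_gap_bursts(sw60, sw0, mode = "subtract")
  expect_lt(abs(sb0$scale), 0.2)
  # contaminated: every burst-carrying trial is rejected, clean ones kept
  b60 <- inject_gap_bursts(sw60, tmpl, rate_hz = 2, seed = 33)
  b0 <- inject_gap_bursts(sw0, tmpl, rate_hz = 2, seed = 33)
  rj <- suppressMessages(handle_gap_bursts(b60, template = tmpl, mode = "reject"))
  expect_setequal(rj$rejected, unique(b60$burst_truth$trial))
  # noiseless paired subtraction recovers the synaptic-only average exactly
  nb60 <- simulate_evoked(rel, acq60, n_trials = 6, noise_sd_pa = 0, seed = 34)
  nb0 <- simulate_evoked(release_model(quantal_content = 0), acq0,
                         n_trials = 6, noise_sd_pa = 0, seed = 35)
  c60 <- inject_gap_bursts(nb60, tmpl, rate_hz = 2, seed = 36)
  c0 <- inject_gap_bursts(nb0, tmpl, rate_hz = 2, seed = 36)
  sb <- handle_gap_bursts(c60, c0, mode = "subtract",
                          free_window_s = c(0, 0.3))
  resid <- sb$average - rowMeans(nb60$current)
  expect_lt(max(abs(resid - mean(resid))), 1e-6) # exact up to a DC offset
  expect_lt(abs(mean(resid)), 0.5)
  # with noise, burst subtraction cuts synaptic-free residual RMS by >= 90%
  big <- gap_burst_template(acq60, amplitude_pa = 150)
  n60 <- simulate_evoked(rel, acq60, n_trials = 20, noise_sd_pa = 0.25, seed = 37)
  n0 <- simulate_evoked(release_model(quantal_content = 0), acq0,
                        n_trials = 20, noise_sd_pa = 0.25, seed = 38)
  d60 <- inject_gap_bursts(n60, big, rate_hz = 2, seed = 39)
  d0 <- inject_gap_bursts(n0, big, rate_hz = 2, seed = 39)
  sbn <- handle_gap_bursts(d60, d0, mode = "subtract", free_window_s = c(0, 0.3))
  free <- 1:(round(0.3 * 20000))
  rms_before <- sqrt(mean(rowMeans(d60$current)[free]^2))
  rms_after <- sqrt(mean(sbn$average[free]^2))
  expect_lt(rms_after, 0.1 * rms_before)
})

test_that("train charge is flat without plasticity and follows a depression factor", {
  acq_t <- acquisition_spec(sweep_duration_s = 1.0,
                            stimulus_times_s = 0.05 + (0:9) * 0.02)
  fast <- quantal_model(amplitude_pa = 60, cv = 0, tau_rise_ms = 0.3, tau_decay_ms = 3.5)
  mk_rel <- function(f) release_model(
    glycine = fast, transmitter_mix = 1, quantal_content = 200,
    count_model = "fixed", train_plasticity = f,
    latency = latency_model("synchronous", mu_sync_ms = 1, sigma_sync_ms = 0.1))
  tr1 <- analyze_train(simulate_evoked(mk_rel(1), acq_t, n_trials = 2,
                                       noise_sd_pa = 0, seed = 41))
  expect_lt(max(abs(tr1$normalized_charge - 1)), 0.02)
  tr8 <- analyze_train(simulate_evoked(mk_rel(0.8), acq_t, n_trials = 2,
                                       noise_sd_pa = 0, seed = 42))
  expect_lt(max(abs(tr8$normalized_charge / 0.8^(0:9) - 1)), 0.05)
  expect_equal(tr8$normalized_charge[1L], 1)
  # last-IPSC decay reflects the quantal kernel for a synchronous train
  expect_lt(abs(tr1$last_ipsc_decay_tau_ms - 3.5) / 3.5, 0.15)
})

test_that("asynchronous buildup gives monotonically non-decreasing train charge", {
  acq_t <- acquisition_spec(sweep_duration_s = 1.2,
                            stimulus_times_s = 0.05 + (0:9) * 0.02)
  rel <- release_model(quantal_content = 200, transmitter_mix = 0,
                       latency = latency_model("asynchronous", tau_async_ms = 150))
  sw <- suppressWarnings(simulate_evoked(rel, acq_t, n_trials = 30,
                                         noise_sd_pa = 0, seed = 43))
  tr <- analyze_train(sw)
  expect_false(is.unsorted(tr$normalized_charge))
  expect_gt(tr$normalized_charge[10L], 2)
})
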