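# Synthetic voltage-clamp IPSC recordings: quantal release with synchronous
# (Gaussian latency) or asynchronous (exponential-tail latency) timing, GABA
# vs glycine quantal kinetics, stimulus trains, Poisson miniature events,
# and gap-junction burst contaminants. All generators are deterministic
# under a fixed seed and carry full ground truth.

#' Acquisition parameters for simulated voltage-clamp sweeps
#'
#' @param sampling_rate_hz sampling rate (default 20 kHz).
#' @param filter_cutoff_hz low-pass cutoff applied to simulated sweeps
#'   (default 4 kHz); must be below Nyquist.
#' @param sweep_duration_s sweep length in seconds.
#' @param holding_mv holding potential (mV); -60 for synaptic recordings, 0
#'   at the chloride reversal potential.
#' @param reversal_mv synaptic reversal potential (mV).
#' @param stimulus_times_s stimulus onset times within the sweep (s).
#' @param artifact_blank_ms window after each stimulus blanked to baseline
#'   (0 disables blanking).
#' @return Object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(sampling_rate_hz = 20000, filter_cutoff_hz = 4000,
                             sweep_duration_s = 0.5, holding_mv = -60,
                             reversal_mv = 0, stimulus_times_s = 0.05,
                             artifact_blank_ms = 0) {
  stopifnot(sampling_rate_hz > 0, filter_cutoff_hz < sampling_rate_hz / 2,
            sweep_duration_s > 0,
            all(stimulus_times_s >= 0), all(stimulus_times_s < sweep_duration_s),
            artifact_blank_ms >= 0)
  structure(list(sampling_rate_hz = sampling_rate_hz,
                 filter_cutoff_hz = filter_cutoff_hz,
                 sweep_duration_s = sweep_duration_s,
                 holding_mv = holding_mv, reversal_mv = reversal_mv,
                 stimulus_times_s = as.numeric(stimulus_times_s),
                 artifact_blank_ms = artifact_blank_ms),
            class = "acquisition_spec")
}

#' Quantal current kinetics for one transmitter
#'
#' Defaults encode the qualitative ordering seen at mixed inhibitory
#' synapses: glycinergic quanta are faster (sub-millisecond rise, ~5 ms
#' decay) and larger than GABAergic quanta (~1 ms rise, ~15 ms decay).
#' Numeric values are generator choices.
#'
#' @param amplitude_pa mean quantal peak amplitude (pA, magnitude).
#' @param cv coefficient of variation of the lognormal amplitude
#'   distribution (0 = fixed amplitude).
#' @param tau_rise_ms,tau_decay_ms rise and decay time constants (ms);
#'   rise must be strictly faster than decay.
#' @return Object of class `quantal_model`.
#' @export
quantal_model <- function(amplitude_pa = 40, cv = 0.3,
                          tau_rise_ms = 1.0, tau_decay_ms = 15) {
  if (tau_rise_ms >= tau_decay_ms)
    stop("tau_rise_ms must be smaller than tau_decay_ms", call. = FALSE)
  stopifnot(amplitude_pa > 0, cv >= 0, tau_rise_ms > 0)
  structure(list(amplitude_pa = amplitude_pa, cv = cv,
                 tau_rise_ms = tau_rise_ms, tau_decay_ms = tau_decay_ms),
            class = "quantal_model")
}

#' Default glycinergic quantal model (fast, large)
#' @inheritParams quantal_model
#' @export
glycine_quantal <- function(amplitude_pa = 60, cv = 0.3,
                            tau_rise_ms = 0.3, tau_decay_ms = 5) {
  quantal_model(amplitude_pa, cv, tau_rise_ms, tau_decay_ms)
}

#' Default GABAergic quantal model (slow, small)
#' @inheritParams quantal_model
#' @export
gaba_quantal <- function(amplitude_pa = 40, cv = 0.3,
                         tau_rise_ms = 1.0, tau_decay_ms = 15) {
  quantal_model(amplitude_pa, cv, tau_rise_ms, tau_decay_ms)
}

#' Quantal release latency distribution
#'
#' Synchronous release draws latencies from a Gaussian truncated at zero;
#' asynchronous release from a delayed exponential tail; mixed release draws
#' each quantum asynchronous with probability `mix_weight`.
#'
#' @param mode "synchronous", "asynchronous" or "mixed".
#' @param mu_sync_ms,sigma_sync_ms Gaussian latency mean and SD (ms).
#' @param tau_async_ms exponential tail time constant (ms).
#' @param delay_async_ms fixed delay added to asynchronous latencies (ms).
#' @param mix_weight fraction of quanta released asynchronously (mixed mode
#'   only).
#' @return Object of class `latency_model`.
#' @export
latency_model <- function(mode = c("synchronous", "asynchronous", "mixed"),
                          mu_sync_ms = 1, sigma_sync_ms = 0.3,
                          tau_async_ms = 50, delay_async_ms = 2,
                          mix_weight = NULL) {
  mode <- match.arg(mode)
  stopifnot(sigma_sync_ms > 0, tau_async_ms > 0, delay_async_ms >= 0)
  if (mode == "mixed") {
    if (is.null(mix_weight)) stop("mix_weight required for mixed mode", call. = FALSE)
    stopifnot(mix_weight >= 0, mix_weight <= 1)
  } else if (!is.null(mix_weight)) {
    stop("mix_weight is only meaningful in mixed mode", call. = FALSE)
  }
  structure(list(mode = mode, mu_sync_ms = mu_sync_ms,
                 sigma_sync_ms = sigma_sync_ms, tau_async_ms = tau_async_ms,
                 delay_async_ms = delay_async_ms, mix_weight = mix_weight),
            class = "latency_model")
}

#' Generative model of evoked quantal release
#'
#' @param gaba,glycine [quantal_model()]s for the two transmitters.
#' @param transmitter_mix fraction of quanta that are glycinergic.
#' @param latency a [latency_model()].
#' @param quantal_content mean number of quanta per stimulus.
#' @param count_model "poisson" (quantal counts drawn Poisson) or "fixed"
#'   (deterministic rounded counts; useful for noise-free recovery tests).
#' @param train_plasticity multiplicative per-stimulus factor f: stimulus k
#'   releases with mean content `quantal_content * f^(k-1)`.
#' @param async_buildup optional extra accumulation of asynchronous release
#'   across train stimuli: `list(factor, tau_ms)` scales asynchronous
#'   content at stimulus k by `1 + factor * sum_j exp(-(t_k - t_j)/tau_ms)`
#'   over previous stimuli j. Independently of this, asynchronous latency
#'   tails from successive stimuli overlap and their release rates sum.
#' @return Object of class `release_model`.
#' @export
release_model <- function(gaba = gaba_quantal(), glycine = glycine_quantal(),
                          transmitter_mix = 0.5,
                          latency = latency_model("synchronous"),
                          quantal_content = 10,
                          count_model = c("poisson", "fixed"),
                          train_plasticity = 1,
                          async_buildup = NULL) {
  count_model <- match.arg(count_model)
  stopifnot(transmitter_mix >= 0, transmitter_mix <= 1,
            quantal_content >= 0, train_plasticity > 0)
  if (!is.null(async_buildup))
    stopifnot(is.list(async_buildup), async_buildup$factor >= 0, async_buildup$tau_ms > 0)
  structure(list(gaba = gaba, glycine = glycine,
                 transmitter_mix = transmitter_mix, latency = latency,
                 quantal_content = quantal_content, count_model = count_model,
                 train_plasticity = train_plasticity,
                 async_buildup = async_buildup),
            class = "release_model")
}

#' Miniature-event model
#'
#' @param rate_hz Poisson rate of spontaneous events.
#' @param amplitude_pa,cv lognormal amplitude distribution (NULL amplitude
#'   uses the quantal model's).
#' @param transmitter "glycine" or "gaba" (selects the quantal kinetics
#'   when simulating).
#' @return Object of class `mini_model`.
#' @export
mini_model <- function(rate_hz = 2, amplitude_pa = NULL, cv = 0.3,
                       transmitter = c("glycine", "gaba")) {
  stopifnot(rate_hz >= 0, cv >= 0)
  structure(list(rate_hz = rate_hz, amplitude_pa = amplitude_pa, cv = cv,
                 transmitter = match.arg(transmitter)),
            class = "mini_model")
}

#' Sampled quantal current kernel
#'
#' Returns the quantal waveform
#' `q(t) = A_norm * (1 - exp(-t/tau_r)) * exp(-t/tau_d)`, normalized so its
#' continuous-time peak equals the model amplitude. The peak occurs at
#' `t* = tau_r * log(1 + tau_d/tau_r)`. The sampled kernel starts at
#' `q(0) = 0` and covers at least five decay time constants.
#'
#' @param model a [quantal_model()].
#' @param acquisition an [acquisition_spec()] (sampling rate).
#' @param n_tau kernel length in decay time constants (default 7).
#' @return numeric vector, the positive-going kernel in pA.
#' @export
quantal_waveform <- function(model, acquisition, n_tau = 7) {
  fs <- acquisition$sampling_rate_hz
  tr <- model$tau_rise_ms / 1000; td <- model$tau_decay_ms / 1000
  n <- max(2L, ceiling(n_tau * td * fs))
  t <- (seq_len(n) - 1L) / fs
  t_star <- tr * log(1 + td / tr)
  peak <- (1 - exp(-t_star / tr)) * exp(-t_star / td)
  model$amplitude_pa * (1 - exp(-t / tr)) * exp(-t / td) / peak
}

# driving-force scale relative to the -60 mV reference used throughout
driving_scale <- function(acquisition) {
  (acquisition$holding_mv - acquisition$reversal_mv) / (-60 - acquisition$reversal_mv)
}

# lognormal draw with given mean and CV; cv = 0 returns the mean
draw_amplitudes <- function(n, mean, cv) {
  if (n == 0L) return(numeric(0))
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

draw_latencies_ms <- function(n, lat, component) {
  if (n == 0L) return(numeric(0))
  if (component == "sync") {
    out <- numeric(0)
    while (length(out) < n) {
      cand <- rnorm(n, lat$mu_sync_ms, lat$sigma_sync_ms)
      out <- c(out, cand[cand >= 0])
    }
    out[seq_len(n)]
  } else {
    lat$delay_async_ms + rexp(n, rate = 1 / lat$tau_async_ms)
  }
}

# superpose scaled kernels onto a trace at given onset samples
add_kernels <- function(trace, onsets, amps, kernel) {
  n <- length(trace); lk <- length(kernel)
  for (i in seq_along(onsets)) {
    s0 <- onsets[i]
    if (s0 > n) next
    s1 <- min(n, s0 + lk - 1L)
    trace[s0:s1] <- trace[s0:s1] + amps[i] * kernel[seq_len(s1 - s0 + 1L)]
  }
  trace
}

new_sweep_set <- function(current, acquisition, truth = NULL, burst_truth = NULL) {
  structure(list(current = current, acquisition = acquisition,
                 truth = truth, burst_truth = burst_truth),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set> %d trial(s) x %d samples (%.3f s at %g kHz, holding %g mV)\n",
              ncol(x$current), nrow(x$current),
              x$acquisition$sweep_duration_s,
              x$acquisition$sampling_rate_hz / 1000, x$acquisition$holding_mv))
  if (!is.null(x$truth)) cat(sprintf("  truth: %d quanta/events\n", nrow(x$truth)))
  invisible(x)
}

#' Sample times of a sweep set (seconds)
#' @param sweeps a `sweep_set`.
#' @return numeric vector of sample times.
#' @export
sweep_times <- function(sweeps) {
  (seq_len(nrow(sweeps$current)) - 1L) / sweeps$acquisition$sampling_rate_hz
}

#' Simulate evoked IPSC sweeps from a quantal release model
#'
#' For each trial and stimulus, quantal counts are drawn (Poisson or fixed),
#' latencies are drawn from the latency model (asynchronous tails from
#' successive train stimuli overlap, so asynchronous release accumulates
#' across a train), each quantum is assigned a transmitter and a lognormal
#' amplitude, and quantal kernels are superposed. Synaptic current is scaled
#' by the driving force relative to -60 mV (zero at the reversal potential)
#' with inward currents negative. Gaussian noise is added and the sweep is
#' low-pass filtered at the acquisition cutoff; artifact windows are blanked
#' afterwards.
#'
#' @param release a [release_model()].
#' @param acquisition an [acquisition_spec()].
#' @param n_trials number of trials.
#' @param noise_sd_pa Gaussian noise SD before filtering (pA).
#' @param seed RNG seed (NULL = current state).
#' @return A `sweep_set`; `$truth` is a data.frame (trial, stimulus,
#'   time_s, latency_ms, amplitude_pa, transmitter, component).
#' @export
simulate_evoked <- function(release, acquisition, n_trials = 10,
                            noise_sd_pa = 2, seed = NULL) {
  stopifnot(inherits(release, "release_model"),
            inherits(acquisition, "acquisition_spec"), n_trials >= 1)
  seed_rng(seed)
  fs <- acquisition$sampling_rate_hz
  n <- round(acquisition$sweep_duration_s * fs)
  stims <- acquisition$stimulus_times_s
  kern <- list(gaba = quantal_waveform(release$gaba, acquisition),
               glycine = quantal_waveform(release$glycine, acquisition))
  # unit-peak kernels; amplitudes carried per quantum
  kern <- lapply(names(kern), function(tr)
    kern[[tr]] / c(gaba = release$gaba$amplitude_pa,
                   glycine = release$glycine$amplitude_pa)[[tr]])
  names(kern) <- c("gaba", "glycine")
  scale <- driving_scale(acquisition)
  lat <- release$latency
  w_async <- switch(lat$mode, synchronous = 0, asynchronous = 1, mixed = lat$mix_weight)

  truth <- vector("list", n_trials)
  cur <- matrix(0, nrow = n, ncol = n_trials)
  warned <- FALSE
  for (tr in seq_len(n_trials)) {
    rows <- list()
    pos <- numeric(n)
    for (k in seq_along(stims)) {
      content_k <- release$quantal_content * release$train_plasticity^(k - 1L)
      c_sync <- content_k * (1 - w_async)
      c_async <- content_k * w_async
      if (!is.null(release$async_buildup) && k > 1L) {
        prev <- stims[seq_len(k - 1L)]
        bu <- 1 + release$async_buildup$factor *
          sum(exp(-(stims[k] - prev) * 1000 / release$async_buildup$tau_ms))
        c_async <- c_async * bu
      }
      counts <- if (release$count_model == "poisson") {
        c(sync = rpois(1L, c_sync), async = rpois(1L, c_async))
      } else {
        c(sync = round(c_sync), async = round(c_async))
      }
      for (comp in c("sync", "async")) {
        nq <- counts[[comp]]
        if (nq == 0L) next
        lats <- draw_latencies_ms(nq, lat, comp)
        trans <- ifelse(runif(nq) < release$transmitter_mix, "glycine", "gaba")
        amps <- numeric(nq)
        for (tt in c("gaba", "glycine")) {
          sel <- trans == tt
          amps[sel] <- draw_amplitudes(sum(sel), release[[tt]]$amplitude_pa, release[[tt]]$cv)
        }
        t_q <- stims[k] + lats / 1000
        onset <- round(t_q * fs) + 1L
        late <- onset > n
        if (any(late) && !warned) {
          warning("some quanta fall beyond the sweep end and are truncated", call. = FALSE)
          warned <- TRUE
        }
        for (tt in c("gaba", "glycine")) {
          sel <- trans == tt & !late
          if (any(sel)) pos <- add_kernels(pos, onset[sel], amps[sel], kern[[tt]])
        }
        rows[[length(rows) + 1L]] <- data.frame(
          trial = tr, stimulus = k, time_s = t_q, latency_ms = lats,
          amplitude_pa = amps, transmitter = trans, component = comp)
      }
    }
    tracev <- -scale * pos
    if (noise_sd_pa > 0) tracev <- tracev + rnorm(n, 0, noise_sd_pa)
    cur[, tr] <- tracev
    truth[[tr]] <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  cur <- lowpass(cur, acquisition$filter_cutoff_hz, fs)
  if (acquisition$artifact_blank_ms > 0) {
    for (st in stims) {
      i0 <- round(st * fs) + 1L
      i1 <- min(n, i0 + round(acquisition$artifact_blank_ms / 1000 * fs))
      cur[i0:i1, ] <- 0
    }
  }
  truth <- if (any(!vapply(truth, is.null, TRUE))) do.call(rbind, truth) else
    data.frame(trial = integer(0), stimulus = integer(0), time_s = numeric(0),
               latency_ms = numeric(0), amplitude_pa = numeric(0),
               transmitter = character(0), component = character(0))
  rownames(truth) <- NULL
  new_sweep_set(cur, acquisition, truth = truth)
}

#' Re-render sweeps from a ground-truth quantal table
#'
#' Builds sweeps containing exactly the quanta listed in `truth` (e.g. a
#' transmitter subset, modeling a perfectly selective antagonist), with
#' fresh noise. Useful for constructing matched control/after-drug pairs.
#'
#' @param truth data.frame in the format produced by [simulate_evoked()].
#' @param release the [release_model()] that generated the truth (for
#'   kernel shapes).
#' @param acquisition an [acquisition_spec()].
#' @param n_trials number of trials (must cover the trial ids in truth).
#' @param noise_sd_pa,seed as in [simulate_evoked()].
#' @return A `sweep_set`.
#' @export
render_truth <- function(truth, release, acquisition, n_trials = NULL,
                         noise_sd_pa = 2, seed = NULL) {
  seed_rng(seed)
  fs <- acquisition$sampling_rate_hz
  n <- round(acquisition$sweep_duration_s * fs)
  if (is.null(n_trials)) n_trials <- max(truth$trial, 1L)
  kern <- list(gaba = quantal_waveform(release$gaba, acquisition) / release$gaba$amplitude_pa,
               glycine = quantal_waveform(release$glycine, acquisition) / release$glycine$amplitude_pa)
  scale <- driving_scale(acquisition)
  cur <- matrix(0, nrow = n, ncol = n_trials)
  for (tr in seq_len(n_trials)) {
    tt <- truth[truth$trial == tr, , drop = FALSE]
    pos <- numeric(n)
    for (trans in c("gaba", "glycine")) {
      sel <- tt$transmitter == trans
      if (any(sel)) {
        onset <- round(tt$time_s[sel] * fs) + 1L
        ok <- onset <= n
        pos <- add_kernels(pos, onset[ok], tt$amplitude_pa[sel][ok], kern[[trans]])
      }
    }
    tracev <- -scale * pos
    if (noise_sd_pa > 0) tracev <- tracev + rnorm(n, 0, noise_sd_pa)
    cur[, tr] <- tracev
  }
  cur <- lowpass(cur, acquisition$filter_cutoff_hz, fs)
  new_sweep_set(cur, acquisition, truth = truth)
}

#' Simulate a continuous recording of miniature IPSCs
#'
#' Event times follow a homogeneous Poisson process; amplitudes are
#' lognormal. Kernels are superposed on Gaussian noise and the trace is
#' low-pass filtered.
#'
#' @param mini a [mini_model()].
#' @param quantal a [quantal_model()] giving the event kinetics.
#' @param acquisition an [acquisition_spec()] (its sweep duration is
#'   overridden by `duration_s`).
#' @param duration_s recording length (s).
#' @param noise_sd_pa,seed as in [simulate_evoked()].
#' @return A `sweep_set` with one trial; `$truth` lists every event
#'   (time_s, amplitude_pa, transmitter).
#' @export
simulate_minis <- function(mini, quantal = glycine_quantal(), acquisition = acquisition_spec(),
                           duration_s = 60, noise_sd_pa = 2, seed = NULL) {
  stopifnot(duration_s > 0)
  seed_rng(seed)
  acq <- acquisition
  acq$sweep_duration_s <- duration_s
  acq$stimulus_times_s <- numeric(0)
  fs <- acq$sampling_rate_hz
  n <- round(duration_s * fs)
  n_ev <- rpois(1L, mini$rate_hz * duration_s)
  times <- sort(runif(n_ev, 0, duration_s))
  amp_mean <- mini$amplitude_pa %||% quantal$amplitude_pa
  amps <- draw_amplitudes(n_ev, amp_mean, mini$cv)
  kern <- quantal_waveform(quantal, acq) / quantal$amplitude_pa
  pos <- add_kernels(numeric(n), round(times * fs) + 1L, amps, kern)
  tracev <- -driving_scale(acq) * pos
  if (noise_sd_pa > 0) tracev <- tracev + rnorm(n, 0, noise_sd_pa)
  tracev <- lowpass(tracev, acq$filter_cutoff_hz, fs)
  truth <- data.frame(time_s = times, amplitude_pa = amps,
                      transmitter = rep(mini$transmitter, n_ev))
  new_sweep_set(matrix(tracev, ncol = 1L), acq, truth = truth)
}

#' Gap-junction burst template
#'
#' A stereotyped spikelet burst: `n_spikelets` biphasic transients
#' (derivative-of-Gaussian shape) at a fixed interval. The shape is
#' arbitrary but consistent, which is all the burst-rejection and
#' subtraction analyses rely on. Bursts are carried by gap junctions and do
#' not reverse at 0 mV, so the template is added with the same sign at all
#' holding potentials.
#'
#' @param acquisition an [acquisition_spec()].
#' @param n_spikelets number of spikelets.
#' @param interval_ms spikelet interval (ms).
#' @param amplitude_pa peak magnitude (pA).
#' @param width_ms spikelet width parameter (ms).
#' @return numeric vector template.
#' @export
gap_burst_template <- function(acquisition, n_spikelets = 3, interval_ms = 2,
                               amplitude_pa = 50, width_ms = 0.5) {
  fs <- acquisition$sampling_rate_hz
  dur_s <- (n_spikelets * interval_ms + 6 * width_ms) / 1000
  t <- seq(0, dur_s, by = 1 / fs)
  out <- numeric(length(t))
  s <- width_ms / 1000
  for (k in seq_len(n_spikelets)) {
    t0 <- (k * interval_ms) / 1000
    u <- (t - t0) / s
    out <- out - u * exp(-u^2 / 2) # biphasic, downward first
  }
  amplitude_pa * out / max(abs(out))
}

#' Inject gap-junction bursts into sweeps
#'
#' Adds the burst template at Poisson-distributed times. Calling with the
#' same seed, template and trial/duration layout on paired sweep sets
#' (e.g. -60 mV and 0 mV) injects identical bursts in both, emulating
#' gap-junction currents that do not reverse at the chloride reversal
#' potential.
#'
#' @param sweeps a `sweep_set`.
#' @param template burst waveform (pA), e.g. [gap_burst_template()].
#' @param rate_hz Poisson burst rate per trial.
#' @param seed RNG seed.
#' @return The sweep set with bursts added; `$burst_truth` records
#'   injection times (trial, time_s).
#' @export
inject_gap_bursts <- function(sweeps, template, rate_hz, seed = NULL) {
  stopifnot(inherits(sweeps, "sweep_set"), rate_hz >= 0)
  n <- nrow(sweeps$current)
  if (length(template) >= n)
    stop("burst template longer than the sweep", call. = FALSE)
  seed_rng(seed)
  fs <- sweeps$acquisition$sampling_rate_hz
  dur <- n / fs
  rows <- list()
  for (tr in seq_len(ncol(sweeps$current))) {
    nb <- rpois(1L, rate_hz * dur)
    if (nb == 0L) next
    times <- sort(runif(nb, 0, dur - length(template) / fs))
    sweeps$current[, tr] <- add_kernels(sweeps$current[, tr],
                                        round(times * fs) + 1L,
                                        rep(1, nb), template)
    rows[[length(rows) + 1L]] <- data.frame(trial = tr, time_s = times)
  }
  sweeps$burst_truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trial = integer(0), time_s = numeric(0))
  rownames(sweeps$burst_truth) <- NULL
  sweeps
}
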