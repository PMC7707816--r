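# Evoked-IPSC kinetics: trial jitter, half-rise, decay time constant, peak
# amplitude, charge transfer; pharmacological component subtraction with
# glycine/GABA ratios; gap-junction burst rejection/subtraction; 50 Hz train
# charge analysis. All measurements are made on the magnitude of the
# baseline-subtracted current (inward currents at -60 mV are negative).

# positive-going baseline-subtracted response matrix; baseline = per-trial
# mean over the 10 ms preceding the stimulus (or from sweep start)
response_matrix <- function(sweeps, stimulus_time_s, baseline_ms = 10) {
  fs <- sweeps$acquisition$sampling_rate_hz
  cur <- sweeps$current
  i_stim <- round(stimulus_time_s * fs) + 1L
  i0 <- max(1L, i_stim - round(baseline_ms / 1000 * fs))
  i1 <- max(i0, i_stim - 1L)
  base <- colMeans(cur[i0:i1, , drop = FALSE])
  polarity <- if (sweeps$acquisition$holding_mv < sweeps$acquisition$reversal_mv) -1 else 1
  resp <- polarity * sweep_sub(cur, base)
  list(resp = resp, i_stim = i_stim, fs = fs,
       noise_sd = mean(apply(resp[i0:i1, , drop = FALSE], 2L, sd)))
}

sweep_sub <- function(cur, base) {
  cur - matrix(base, nrow = nrow(cur), ncol = ncol(cur), byrow = TRUE)
}

# kinetics of a single positive-going average trace; times in ms relative
# to the stimulus. The no-response check compares the boxcar-smoothed peak
# against the smoothed pre-stimulus noise, so single-sample noise spikes do
# not register as responses.
trace_kinetics <- function(avg, fs, i_stim, window_ms,
                           noise_k = 3, smooth_ms = 0.5, decay_floor = 0.1) {
  n <- length(avg)
  i_win0 <- i_stim
  i_win1 <- min(n, i_stim + round(window_ms / 1000 * fs))
  seg <- avg[i_win0:i_win1]
  t_ms <- (seq_along(seg) - 1L) / fs * 1000
  w <- max(1L, round(smooth_ms / 1000 * fs))
  sm <- boxcar(avg, w)
  i_b0 <- max(1L, i_stim - round(0.010 * fs))
  i_b1 <- max(i_b0, i_stim - 1L)
  noise_sm <- if (i_b1 > i_b0) sd(sm[i_b0:i_b1]) else 0
  peak_sm <- max(sm[i_win0:i_win1])
  # synaptic responses are unidirectional; pure noise is symmetric, so its
  # positive peak is matched by a comparable opposite-polarity excursion
  neg_excursion <- max(0, -min(sm[i_win0:i_win1]))
  ipk <- which.max(seg)
  peak <- seg[ipk]
  no_response <- !is.finite(peak) ||
    peak_sm < noise_k * noise_sm + 1e-9 ||
    peak_sm < 1.5 * neg_excursion
  if (no_response) {
    return(list(peak_amplitude_pa = peak, peak_time_ms = NA_real_,
                half_rise_ms = NA_real_, decay_tau_ms = NA_real_,
                charge_pc = trapz(t_ms / 1000, seg), no_response = TRUE))
  }
  peak_time <- t_ms[ipk]
  # half-rise: first 50% crossing before the peak, linearly interpolated,
  # measured from stimulus onset
  half <- peak / 2
  pre <- seg[seq_len(ipk)]
  i_cross <- which(pre >= half)[1L]
  half_rise <- if (is.na(i_cross) || i_cross == 1L) t_ms[max(i_cross, 1L)] else {
    y0 <- pre[i_cross - 1L]; y1 <- pre[i_cross]
    t_ms[i_cross - 1L] + (half - y0) / (y1 - y0) * (t_ms[i_cross] - t_ms[i_cross - 1L])
  }
  # decay: single exponential from the peak to the 10%-of-peak crossing
  after <- seg[ipk:length(seg)]
  below <- which(after < decay_floor * peak)
  i_end <- if (length(below)) max(below[1L], 4L) else length(after)
  decay_tau <- tryCatch({
    ft <- fit_exp_decay(t_ms[ipk:(ipk + i_end - 1L)] - peak_time, after[seq_len(i_end)],
                        tau0 = (t_ms[min(ipk + i_end - 1L, length(t_ms))] - peak_time) / 3)
    ft$tau
  }, error = function(e) NA_real_)
  charge <- trapz(t_ms / 1000, seg) # pA * s = pC
  list(peak_amplitude_pa = peak, peak_time_ms = peak_time,
       half_rise_ms = half_rise, decay_tau_ms = decay_tau,
       charge_pc = charge, no_response = FALSE)
}

#' Evoked IPSC kinetics for one input
#'
#' Per trial, the peak time of the boxcar-smoothed baseline-subtracted
#' current within the response window is located; jitter is the sample SD
#' (n-1 denominator) of those peak times. The trial-averaged trace gives
#' peak amplitude and time, half-rise time (first 50%-of-peak crossing from
#' stimulus onset, linearly interpolated), decay time constant (single
#' exponential fitted from the peak to the 10%-of-peak crossing) and charge
#' (trapezoidal integral over the window, pC). A response whose average
#' peak is below `noise_k` baseline-noise SDs is flagged as absent.
#'
#' @param sweeps a `sweep_set`.
#' @param window_ms response window after the stimulus (use ~100 ms for
#'   synchronous, ~500 ms for asynchronous inputs).
#' @param stimulus_index which stimulus in the sweep to analyze.
#' @param smooth_ms boxcar width for per-trial peak search.
#' @param noise_k no-response criterion in baseline-noise SDs.
#' @return list of class `kinetics_result`: `jitter_ms`, `half_rise_ms`,
#'   `decay_tau_ms`, `peak_amplitude_pa`, `peak_time_ms`, `charge_pc`,
#'   `n_trials`, `no_response`, `peak_times_ms` (per trial).
#' @export
compute_kinetics <- function(sweeps, window_ms = 100, stimulus_index = 1L,
                             smooth_ms = 0.5, noise_k = 3) {
  stopifnot(inherits(sweeps, "sweep_set"))
  stims <- sweeps$acquisition$stimulus_times_s
  if (length(stims) < stimulus_index)
    stop("sweep set has no stimulus at the requested index", call. = FALSE)
  st <- stims[stimulus_index]
  rm_ <- response_matrix(sweeps, st)
  fs <- rm_$fs
  n_trials <- ncol(rm_$resp)
  i0 <- rm_$i_stim
  i1 <- min(nrow(rm_$resp), i0 + round(window_ms / 1000 * fs))
  w <- max(1L, round(smooth_ms / 1000 * fs))
  peak_times <- vapply(seq_len(n_trials), function(tr) {
    seg <- boxcar(rm_$resp[i0:i1, tr], w)
    (which.max(seg) - 1L) / fs * 1000
  }, 0)
  jitter <- if (n_trials >= 2L) sd(peak_times) else NA_real_
  avg <- rowMeans(rm_$resp)
  tk <- trace_kinetics(avg, fs, i0, window_ms, noise_k, smooth_ms)
  structure(c(list(jitter_ms = jitter, n_trials = n_trials,
                   peak_times_ms = peak_times), tk),
            class = "kinetics_result")
}

#' @export
print.kinetics_result <- function(x, ...) {
  cat("<kinetics_result>\n")
  cat(sprintf("  n_trials: %d%s\n", x$n_trials,
              if (isTRUE(x$no_response)) " (no detectable response)" else ""))
  cat(sprintf("  jitter: %.3g ms | half-rise: %.3g ms | decay tau: %.3g ms\n",
              x$jitter_ms, x$half_rise_ms, x$decay_tau_ms))
  cat(sprintf("  peak: %.3g pA at %.3g ms | charge: %.3g pC\n",
              x$peak_amplitude_pa, x$peak_time_ms, x$charge_pc))
  invisible(x)
}

#' Pharmacological component subtraction (GABA vs glycine)
#'
#' The drug-sensitive component is the trial-averaged control trace minus
#' the trial-averaged after-drug trace; the after-drug average is the
#' spared component. Kinetics are computed on both components and the
#' glycine/GABA ratios of peak amplitude and charge are reported. A
#' component whose peak fails the no-response criterion contributes zero
#' amplitude and charge to the ratios.
#'
#' @param control `sweep_set` before the antagonist.
#' @param after_drug `sweep_set` in the antagonist.
#' @param blocked which transmitter the antagonist blocks: "gaba"
#'   (gabazine-style, the difference is the GABA component) or "glycine"
#'   (strychnine-style).
#' @param window_ms analysis window after the stimulus.
#' @param stimulus_index stimulus analyzed.
#' @param noise_k no-response criterion (baseline-noise SDs).
#' @return list of class `component_result`: per-transmitter kinetics
#'   (`gaba`, `glycine`), `difference_trace` (signed average), ratios
#'   `ratio_amplitude_gly_gaba`, `ratio_charge_gly_gaba`.
#' @export
subtract_components <- function(control, after_drug,
                                blocked = c("gaba", "glycine"),
                                window_ms = 150, stimulus_index = 1L,
                                noise_k = 3) {
  blocked <- match.arg(blocked)
  a1 <- control$acquisition; a2 <- after_drug$acquisition
  if (a1$sampling_rate_hz != a2$sampling_rate_hz ||
      !isTRUE(all.equal(a1$stimulus_times_s, a2$stimulus_times_s)) ||
      nrow(control$current) != nrow(after_drug$current))
    stop("control and after-drug sweeps have incompatible acquisition parameters",
         call. = FALSE)
  st <- a1$stimulus_times_s[stimulus_index]
  rc <- response_matrix(control, st)
  rd <- response_matrix(after_drug, st)
  avg_ctrl <- rowMeans(rc$resp)
  avg_drug <- rowMeans(rd$resp)
  diff_avg <- avg_ctrl - avg_drug
  fs <- rc$fs
  k_diff <- trace_kinetics(diff_avg, fs, rc$i_stim, window_ms, noise_k)
  k_spared <- trace_kinetics(avg_drug, fs, rd$i_stim, window_ms, noise_k)
  comp <- if (blocked == "gaba") list(gaba = k_diff, glycine = k_spared)
          else list(gaba = k_spared, glycine = k_diff)
  amp <- vapply(comp, function(k) if (isTRUE(k$no_response)) 0 else k$peak_amplitude_pa, 0)
  chg <- vapply(comp, function(k) if (isTRUE(k$no_response)) 0 else k$charge_pc, 0)
  ratio <- function(num, den) {
    if (num == 0) 0 else if (den == 0) Inf else num / den
  }
  structure(list(gaba = comp$gaba, glycine = comp$glycine,
                 difference_trace = diff_avg, blocked = blocked,
                 ratio_amplitude_gly_gaba = ratio(amp[["glycine"]], amp[["gaba"]]),
                 ratio_charge_gly_gaba = ratio(chg[["glycine"]], chg[["gaba"]])),
            class = "component_result")
}

# maximum normalized cross-correlation of a trace with a template
max_template_ncc <- function(x, template) {
  lt <- length(template); n <- length(x)
  if (lt > n) return(0)
  tz <- template - mean(template)
  tn <- sqrt(sum(tz^2))
  if (tn == 0) return(0)
  # sliding dot products; stats::convolve(x, y, "open")[lt:n] aligns y's
  # first sample with each trace position
  num <- stats::convolve(x, tz, type = "open")[lt:n]
  cs <- cumsum(c(0, x)); cs2 <- cumsum(c(0, x^2))
  win_sum <- cs[(lt + 1L):(n + 1L)] - cs[1:(n - lt + 1L)]
  win_sum2 <- cs2[(lt + 1L):(n + 1L)] - cs2[1:(n - lt + 1L)]
  denom <- sqrt(pmax(win_sum2 - win_sum^2 / lt, 0)) * tn
  cc <- ifelse(denom > 0, abs(num - win_sum * mean(tz)) / denom, 0)
  max(cc, na.rm = TRUE)
}

#' Reject or subtract gap-junction burst contamination
#'
#' Gap-junction bursts from electrically coupled neighbors do not reverse
#' at the chloride reversal potential, so paired recordings at 0 mV isolate
#' them. In "reject" mode, trials at -60 mV whose maximum normalized
#' cross-correlation with the burst template exceeds the threshold are
#' discarded. In "subtract" mode, the averaged 0 mV trace is scaled by a
#' least-squares fit over a synaptic-free window and subtracted from the
#' -60 mV average.
#'
#' @param sweeps_m60 `sweep_set` recorded at -60 mV.
#' @param sweeps_0mv optional paired `sweep_set` at 0 mV (required for
#'   subtract mode; in reject mode it supplies the template when
#'   `template` is NULL).
#' @param mode "reject" or "subtract".
#' @param template optional burst waveform for reject mode.
#' @param threshold normalized cross-correlation threshold for rejection.
#' @param free_window_s synaptic-free time window (start, end in s) used to
#'   fit the subtraction scale; defaults to everything before the first
#'   stimulus.
#' @return For reject mode: list(`sweeps`, `rejected` trial indices,
#'   `scores`). For subtract mode: list(`average` cleaned signed average
#'   trace, `scale`, `average_m60`, `average_0mv`).
#' @export
handle_gap_bursts <- function(sweeps_m60, sweeps_0mv = NULL,
                              mode = c("reject", "subtract"),
                              template = NULL, threshold = 0.6,
                              free_window_s = NULL) {
  mode <- match.arg(mode)
  fs <- sweeps_m60$acquisition$sampling_rate_hz
  if (mode == "reject") {
    if (is.null(template)) {
      if (is.null(sweeps_0mv))
        stop("reject mode needs a template or a 0 mV sweep set to derive one",
             call. = FALSE)
      avg0 <- rowMeans(sweeps_0mv$current)
      avg0 <- avg0 - median(avg0)
      ipk <- which.max(abs(avg0))
      i0 <- max(1L, ipk - round(0.005 * fs)); i1 <- min(length(avg0), ipk + round(0.010 * fs))
      template <- avg0[i0:i1]
    }
    scores <- apply(sweeps_m60$current, 2L, function(x)
      max_template_ncc(x - median(x), template))
    rejected <- which(scores > threshold)
    if (length(rejected) == ncol(sweeps_m60$current))
      stop("all trials rejected as burst-contaminated", call. = FALSE)
    out <- sweeps_m60
    out$current <- out$current[, setdiff(seq_len(ncol(out$current)), rejected), drop = FALSE]
    if (length(rejected))
      message(sprintf("handle_gap_bursts: rejected %d of %d trials",
                      length(rejected), length(scores)))
    list(sweeps = out, rejected = rejected, scores = scores)
  } else {
    if (is.null(sweeps_0mv))
      stop("subtract mode requires a paired 0 mV sweep set", call. = FALSE)
    avg60 <- rowMeans(sweeps_m60$current)
    avg0 <- rowMeans(sweeps_0mv$current)
    if (is.null(free_window_s)) {
      st1 <- min(sweeps_m60$acquisition$stimulus_times_s, Inf)
      free_window_s <- c(0, if (is.finite(st1)) st1 else length(avg60) / fs)
    }
    i0 <- max(1L, round(free_window_s[1L] * fs) + 1L)
    i1 <- min(length(avg60), round(free_window_s[2L] * fs))
    seg0 <- avg0[i0:i1] - mean(avg0[i0:i1])
    seg60 <- avg60[i0:i1] - mean(avg60[i0:i1])
    scale <- if (sum(seg0^2) > 0) sum(seg60 * seg0) / sum(seg0^2) else 0
    list(average = avg60 - scale * (avg0 - mean(avg0[i0:i1])),
         scale = scale, average_m60 = avg60, average_0mv = avg0)
  }
}

#' Charge dynamics across a stimulus train
#'
#' Per-stimulus charge is the baseline-subtracted trapezoidal integral of
#' the trial-averaged response over each inter-stimulus window (the last
#' stimulus uses one inter-stimulus interval), normalized to the first
#' stimulus. The decay time constant of the last IPSC is fitted on the
#' average trace after the final stimulus.
#'
#' @param sweeps a `sweep_set` whose acquisition lists >= 2 stimuli at a
#'   constant interval (e.g. 10 at 50 Hz).
#' @param last_decay_window_ms fit window after the final stimulus peak.
#' @param noise_k noise floor multiple for the first-stimulus charge check.
#' @return list of class `train_result`: `charge_pc` (per stimulus),
#'   `normalized_charge`, `last_ipsc_decay_tau_ms`, `isi_s`.
#' @export
analyze_train <- function(sweeps, last_decay_window_ms = NULL, noise_k = 3) {
  stims <- sweeps$acquisition$stimulus_times_s
  if (length(stims) < 2L)
    stop("train analysis needs at least two stimuli", call. = FALSE)
  isi <- diff(stims)
  if (max(abs(isi - isi[1L])) > 1e-9)
    stop("inter-stimulus interval must be constant", call. = FALSE)
  isi <- isi[1L]
  rm_ <- response_matrix(sweeps, stims[1L])
  fs <- rm_$fs
  avg <- rowMeans(rm_$resp)
  n <- length(avg)
  t_s <- (seq_len(n) - 1L) / fs
  charges <- vapply(seq_along(stims), function(k) {
    w0 <- stims[k]; w1 <- stims[k] + isi
    sel <- t_s >= w0 & t_s < w1
    trapz(t_s[sel], avg[sel])
  }, 0)
  noise_avg <- rm_$noise_sd / sqrt(ncol(rm_$resp))
  # charge-scale noise floor over one ISI window
  if (abs(charges[1L]) < noise_k * noise_avg * isi)
    stop("first-stimulus charge below the noise floor; cannot normalize",
         call. = FALSE)
  # last-IPSC decay from the peak after the final stimulus
  if (is.null(last_decay_window_ms)) last_decay_window_ms <- max(isi * 1000, 100)
  i_last <- round(stims[length(stims)] * fs) + 1L
  tk <- trace_kinetics(avg, fs, i_last, last_decay_window_ms, noise_k)
  structure(list(charge_pc = charges, normalized_charge = charges / charges[1L],
                 last_ipsc_decay_tau_ms = tk$decay_tau_ms, isi_s = isi),
            class = "train_result")
}
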