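# Miniature IPSC detection by a combined first-derivative and integration
# threshold, and per-cell summaries (frequency, amplitude, averaged event).

#' Detection parameters for miniature events
#'
#' @param deriv_k derivative threshold in multiples of the robust
#'   (MAD-based) derivative noise scale.
#' @param integ_k integration threshold in multiples of the SD of the
#'   integrated noise over the acceptance window.
#' @param min_interval_ms events with onsets closer than this are merged
#'   into the earlier onset.
#' @param smooth_cutoff_hz low-pass cutoff of the smoothed copy used for
#'   the derivative and amplitude measurements.
#' @param peak_window_ms window after onset searched for the event peak and
#'   integrated for acceptance.
#' @param baseline_ms local pre-onset baseline window.
#' @param max_decay_ms how far past the peak the 1/e decay crossing is
#'   searched.
#' @return list of class `mini_params`.
#' @export
mini_params <- function(deriv_k = 5, integ_k = 3, min_interval_ms = 5,
                        smooth_cutoff_hz = 1000, peak_window_ms = 10,
                        baseline_ms = 2, max_decay_ms = 100) {
  stopifnot(deriv_k > 0, integ_k >= 0, min_interval_ms >= 0,
            smooth_cutoff_hz > 0, peak_window_ms > 0, baseline_ms > 0)
  structure(as.list(environment()), class = "mini_params")
}

#' Detect miniature IPSCs in a continuous recording
#'
#' The trace is low-pass smoothed and differentiated; candidate onsets are
#' upward threshold crossings of the derivative at `deriv_k` robust noise
#' scales (MAD-based). A candidate is accepted when the baseline-subtracted
#' integral of the following `peak_window_ms` exceeds `integ_k` times the
#' SD expected for integrated noise over that window. Onsets closer than
#' `min_interval_ms` are merged into the earlier one. Amplitude is the peak
#' within the window minus the local pre-onset baseline; decay time is the
#' interpolated time from peak to 1/e of the amplitude.
#'
#' @param sweeps a `sweep_set` (first trial analyzed) or numeric trace.
#' @param acquisition an [acquisition_spec()]; taken from `sweeps` when it
#'   is a `sweep_set`.
#' @param params a [mini_params()].
#' @return data.frame of class `mini_events`, one row per event: `onset_s`,
#'   `peak_s`, `amplitude_pa`, `decay_ms`, `charge_pc`; duration and noise
#'   SD carried as attributes.
#' @export
detect_minis <- function(sweeps, acquisition = NULL, params = mini_params()) {
  if (inherits(sweeps, "sweep_set")) {
    acquisition <- sweeps$acquisition
    x <- sweeps$current[, 1L]
  } else {
    x <- as.numeric(sweeps)
    if (is.null(acquisition)) stop("acquisition spec required for a bare trace", call. = FALSE)
  }
  fs <- acquisition$sampling_rate_hz
  if (length(x) < fs)
    stop("trace shorter than 1 s; too short for noise estimation", call. = FALSE)
  polarity <- if (acquisition$holding_mv < acquisition$reversal_mv) -1 else 1
  s <- polarity * (x - median(x))
  s <- lowpass(s, params$smooth_cutoff_hz, fs)
  d <- c(0, diff(s)) * fs # pA/s
  sd_d <- mad(d)
  sd_n <- mad(s)
  if (sd_d <= 0 || sd_n <= 0)
    stop("degenerate trace: zero noise estimate", call. = FALSE)
  thr_d <- params$deriv_k * sd_d
  above <- d > thr_d
  onsets <- which(above & !c(FALSE, above[-length(above)]))
  # merge onsets closer than min_interval into the earlier one
  if (length(onsets) > 1L) {
    min_gap <- round(params$min_interval_ms / 1000 * fs)
    keep <- c(TRUE, diff(onsets) >= min_gap)
    # successive close crossings all collapse onto the earliest of the run
    run_anchor <- onsets[1L]
    for (i in seq_along(onsets)[-1L]) {
      if (onsets[i] - run_anchor < min_gap) keep[i] <- FALSE else run_anchor <- onsets[i]
    }
    onsets <- onsets[keep]
  }
  n_win <- round(params$peak_window_ms / 1000 * fs)
  n_base <- round(params$baseline_ms / 1000 * fs)
  dt <- 1 / fs
  thr_integral <- params$integ_k * sd_n * sqrt(n_win) * dt
  rows <- lapply(onsets, function(o) {
    i1 <- min(length(s), o + n_win)
    b0 <- max(1L, o - n_base)
    base <- mean(s[b0:max(b0, o - 1L)])
    seg <- s[o:i1] - base
    integral <- sum(seg) * dt
    if (integral <= thr_integral) return(NULL)
    ipk <- which.max(seg)
    amp <- seg[ipk]
    if (amp <= 0) return(NULL)
    # decay: first 1/e crossing after the peak (interpolated)
    i_max <- min(length(s), o + round(params$max_decay_ms / 1000 * fs))
    tail_seg <- s[(o + ipk - 1L):i_max] - base
    target <- amp / exp(1)
    below <- which(tail_seg <= target)
    decay_ms <- if (length(below) && below[1L] > 1L) {
      j <- below[1L]
      y0 <- tail_seg[j - 1L]; y1 <- tail_seg[j]
      (j - 2L + (y0 - target) / (y0 - y1)) / fs * 1000
    } else NA_real_
    data.frame(onset_s = (o - 1L) / fs, peak_s = (o + ipk - 2L) / fs,
               amplitude_pa = amp, decay_ms = decay_ms,
               charge_pc = integral)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(onset_s = numeric(0), peak_s = numeric(0),
               amplitude_pa = numeric(0), decay_ms = numeric(0),
               charge_pc = numeric(0))
  rownames(out) <- NULL
  attr(out, "duration_s") <- length(x) / fs
  attr(out, "noise_sd_pa") <- sd_n
  class(out) <- c("mini_events", class(out))
  out
}

#' Summarize detected miniature events
#'
#' @param events a `mini_events` data.frame from [detect_minis()].
#' @param duration_s analyzed duration (s); taken from the events attribute
#'   when NULL.
#' @param sweeps optional source `sweep_set` for the onset-aligned average
#'   waveform.
#' @param align_window_ms window around each onset for the average waveform
#'   (pre, post).
#' @return list of class `mini_summary`: `n_events`, `frequency_hz`,
#'   `mean_amplitude_pa`, `mean_decay_ms`, `waveform` (average, pA,
#'   positive-going) with `waveform_t_ms`, `waveform_decay_ms`.
#' @export
summarize_minis <- function(events, duration_s = NULL, sweeps = NULL,
                            align_window_ms = c(2, 30)) {
  if (is.null(duration_s)) duration_s <- attr(events, "duration_s")
  stopifnot(!is.null(duration_s), duration_s > 0)
  n <- nrow(events)
  out <- list(n_events = n, frequency_hz = n / duration_s,
              mean_amplitude_pa = if (n) mean(events$amplitude_pa) else NA_real_,
              mean_decay_ms = if (n) mean(events$decay_ms, na.rm = TRUE) else NA_real_,
              waveform = NULL, waveform_t_ms = NULL, waveform_decay_ms = NA_real_)
  if (n > 0L && !is.null(sweeps)) {
    fs <- sweeps$acquisition$sampling_rate_hz
    polarity <- if (sweeps$acquisition$holding_mv < sweeps$acquisition$reversal_mv) -1 else 1
    x <- polarity * (sweeps$current[, 1L] - median(sweeps$current[, 1L]))
    pre <- round(align_window_ms[1L] / 1000 * fs)
    post <- round(align_window_ms[2L] / 1000 * fs)
    segs <- lapply(events$onset_s, function(t0) {
      i <- round(t0 * fs) + 1L
      if (i - pre < 1L || i + post > length(x)) return(NULL)
      seg <- x[(i - pre):(i + post)]
      seg - mean(seg[seq_len(pre)])
    })
    segs <- segs[!vapply(segs, is.null, TRUE)]
    if (length(segs)) {
      wf <- Reduce(`+`, segs) / length(segs)
      out$waveform <- wf
      out$waveform_t_ms <- (seq_along(wf) - 1L - pre) / fs * 1000
      ipk <- which.max(wf)
      amp <- wf[ipk]
      below <- which(wf[ipk:length(wf)] <= amp / exp(1))
      if (length(below) && below[1L] > 1L) {
        j <- below[1L]
        y0 <- wf[ipk + j - 2L]; y1 <- wf[ipk + j - 1L]
        tgt <- amp / exp(1)
        out$waveform_decay_ms <- (j - 2L + (y0 - tgt) / (y0 - y1)) / fs * 1000
      }
    }
  }
  structure(out, class = "mini_summary")
}

#' @export
print.mini_summary <- function(x, ...) {
  cat(sprintf("<mini_summary> %d events, %.3g Hz, mean amplitude %.3g pA, mean decay %.3g ms\n",
              x$n_events, x$frequency_hz, x$mean_amplitude_pa, x$mean_decay_ms))
  invisible(x)
}
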