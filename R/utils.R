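# Internal numerical helpers shared across modules.

#' @importFrom stats filter lm mad median rnorm rpois runif rexp rlnorm sd var coef
#' @importFrom utils read.csv write.csv head
NULL

#' Trapezoidal integral of y over x
#' @noRd
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n])) / 2
}

#' Apply a centered 1-d kernel along one axis of a 3-d array.
#' Edges are handled by replicate-padding so the output has no NA border.
#' @noRd
convolve_axis <- function(a, kernel, axis) {
  d <- dim(a)
  r <- (length(kernel) - 1L) %/% 2L
  if (r == 0L) return(a * kernel)
  perm <- c(axis, setdiff(1:3, axis))
  m <- aperm(a, perm)
  dm <- dim(m)
  m <- matrix(m, nrow = dm[1L])
  pad_top <- m[rep(1L, r), , drop = FALSE]
  pad_bot <- m[rep(nrow(m), r), , drop = FALSE]
  mp <- rbind(pad_top, m, pad_bot)
  out <- stats::filter(mp, kernel, sides = 2L)
  out <- out[(r + 1L):(r + nrow(m)), , drop = FALSE]
  out <- array(as.numeric(out), dim = dm)
  aperm(out, order(perm))
}

#' Separable Gaussian smoothing of a 3-d array; sigma in voxels per axis (y, x, z).
#' sigma <= 0 skips the axis.
#' @noRd
gauss_smooth3 <- function(a, sigma) {
  stopifnot(length(dim(a)) == 3L, length(sigma) == 3L)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s > 0) {
      r <- max(1L, ceiling(3 * s))
      k <- exp(-((-r:r)^2) / (2 * s^2))
      k <- k / sum(k)
      a <- convolve_axis(a, k, ax)
    }
  }
  a
}

#' 3x3 running maximum along one axis (replicate edges).
#' @noRd
maxfilt_axis <- function(a, axis) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  m <- aperm(a, perm)
  dm <- dim(m)
  m <- matrix(m, nrow = dm[1L])
  n <- nrow(m)
  up <- m[c(1L, seq_len(n - 1L)), , drop = FALSE]
  dn <- m[c(seq_len(n - 1L) + 1L, n), , drop = FALSE]
  out <- pmax(m, up, dn)
  out <- array(out, dim = dm)
  aperm(out, order(perm))
}

#' 3x3x3 neighborhood maximum filter.
#' @noRd
maxfilt3 <- function(a) {
  for (ax in 1:3) a <- maxfilt_axis(a, ax)
  a
}

#' Zero-phase low-pass Butterworth filter (4-pole) applied per column.
#' @noRd
lowpass <- function(x, cutoff_hz, fs, order = 4L) {
  if (!is.finite(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= fs / 2) return(x)
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  if (is.matrix(x)) {
    apply(x, 2L, function(col) as.numeric(signal::filtfilt(bf, col)))
  } else {
    as.numeric(signal::filtfilt(bf, x))
  }
}

#' Centered boxcar smoothing of a vector, width in samples (>=1).
#' @noRd
boxcar <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width == 1L) return(x)
  r <- width %/% 2L
  xp <- c(rep(x[1L], r), x, rep(x[length(x)], r))
  out <- stats::filter(xp, rep(1 / (2L * r + 1L), 2L * r + 1L), sides = 2L)
  as.numeric(out[(r + 1L):(r + length(x))])
}

#' Single-exponential decay fit y = A exp(-t/tau), nonlinear least squares with
#' a log-linear fallback. t in the same units tau is reported in.
#' @noRd
fit_exp_decay <- function(t, y, tau0 = NULL) {
  keep <- is.finite(t) & is.finite(y)
  t <- t[keep]; y <- y[keep]
  if (length(t) < 4L || max(y) <= 0) {
    stop("decay fit failed: too few points or non-positive response", call. = FALSE)
  }
  t <- t - t[1L]
  if (is.null(tau0) || !is.finite(tau0) || tau0 <= 0) {
    # crude initial guess from the time to fall to 1/e of the first value
    below <- which(y <= y[1L] / exp(1))
    tau0 <- if (length(below)) max(t[below[1L]], diff(range(t)) / 20) else diff(range(t)) / 2
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-t / tau),
                      start = list(A = max(y), tau = tau0),
                      lower = c(A = 0, tau = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- coef(fit)
    return(list(A = unname(cf["A"]), tau = unname(cf["tau"])))
  }
  pos <- y > 0
  if (sum(pos) < 3L) stop("decay fit failed to converge", call. = FALSE)
  ll <- stats::lm(log(y[pos]) ~ t[pos])
  slope <- coef(ll)[2L]
  if (!is.finite(slope) || slope >= 0) stop("decay fit failed to converge", call. = FALSE)
  list(A = exp(unname(coef(ll)[1L])), tau = -1 / unname(slope))
}

#' Seed the RNG if a seed is supplied; used by every stochastic generator.
#' @noRd
seed_rng <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
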