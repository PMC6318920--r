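# Streaming-capable IIR filtering.
#
# All digital filters in the package (band-pass on raw sEMG, 2 Hz smoothing
# of the intention stream, goniometer-speed smoothing) go through the small
# direct-form-I engine below.  Batch and chunk-wise application share the
# same recurrence evaluated in the same order, so a causal pipeline fed
# 20 ms frames with carried state reproduces the one-shot result to
# machine precision -- the property the closed-loop runner relies on.

#' Design a digital Butterworth filter
#'
#' Thin wrapper around [signal::butter()] returning normalized transfer
#' function coefficients.  Cutoffs are given in Hz together with the
#' sampling rate.
#'
#' @param order Filter order (per band edge for band-pass).
#' @param cutoff_hz Scalar cutoff (low/high-pass) or length-2 vector
#'   (band-pass), in Hz.
#' @param rate_hz Sampling rate in Hz.
#' @param type `"low"`, `"high"` or `"pass"`.
#' @return List with numeric vectors `b` (numerator) and `a`
#'   (denominator, `a[1] == 1`).
#' @export
butter_design <- function(order, cutoff_hz, rate_hz, type = "low") {
  nyq <- rate_hz / 2
  if (any(cutoff_hz <= 0) || any(cutoff_hz >= nyq)) {
    stop("cutoff frequencies must lie strictly inside (0, Nyquist = ",
         nyq, " Hz)")
  }
  fl <- signal::butter(order, cutoff_hz / nyq, type = type)
  b <- as.numeric(fl$b)
  a <- as.numeric(fl$a)
  list(b = b / a[1], a = a / a[1])
}

#' Steady-state filter state for a constant input
#'
#' Initial direct-form-I history equivalent to the filter having seen an
#' infinitely long constant input `x0`.  Used to suppress startup
#' transients on short physiological trials.
#'
#' @param coef List with `b`, `a` as from [butter_design()].
#' @param x0 Assumed constant input level.
#' @return An `iir_state` object.
#' @export
iir_state_init <- function(coef, x0 = 0) {
  dc_gain <- sum(coef$b) / sum(coef$a)
  structure(
    list(x = rep(x0, length(coef$b) - 1L),
         y = rep(x0 * dc_gain, length(coef$a) - 1L)),
    class = "iir_state")
}

#' Apply an IIR filter with explicit state
#'
#' Direct-form-I evaluation: the moving-average part runs through
#' `stats::filter(method = "convolution")` on the input extended with the
#' carried input history, the autoregressive part through
#' `stats::filter(method = "recursive")` seeded with the carried output
#' history.  Feeding a signal in chunks while threading the returned state
#' is arithmetically identical to filtering it in one call.
#'
#' @param coef List with `b`, `a`.
#' @param x Numeric input chunk.
#' @param state An `iir_state`, or `NULL` for zero initial conditions.
#' @return List with `y` (filtered chunk) and `state` (to carry forward).
#' @export
iir_filter <- function(coef, x, state = NULL) {
  b <- coef$b
  a <- coef$a
  if (is.null(state)) {
    state <- iir_state_init(coef, 0)
  }
  nxh <- length(state$x)
  xx <- c(state$x, x)
  v <- stats::filter(xx, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[(nxh + 1L):length(xx)]
  if (length(a) > 1L) {
    y <- as.numeric(stats::filter(v, -a[-1L], method = "recursive",
                                  init = rev(state$y)))
  } else {
    y <- v
  }
  n_keep_x <- length(b) - 1L
  n_keep_y <- length(a) - 1L
  all_x <- xx
  all_y <- c(state$y, y)
  new_state <- structure(
    list(x = if (n_keep_x > 0L) all_x[length(all_x) - (n_keep_x - 1L):0] else numeric(0),
         y = if (n_keep_y > 0L) all_y[length(all_y) - (n_keep_y - 1L):0] else numeric(0)),
    class = "iir_state")
  list(y = y, state = new_state)
}

#' Causal filtering with steady-state initialization
#'
#' One-shot causal application; the state is initialized to the steady
#' state for the first sample value so a constant signal passes without a
#' startup transient.
#'
#' @inheritParams iir_filter
#' @return Numeric vector, same length as `x`.
#' @export
iir_causal <- function(coef, x) {
  if (length(x) == 0L) stop("empty input")
  iir_filter(coef, x, iir_state_init(coef, x[1L]))$y
}

#' Zero-phase (forward-backward) filtering
#'
#' Forward causal pass followed by a reversed pass, each with steady-state
#' initialization at its first sample.  The squared magnitude response has
#' no phase delay; used for offline analysis only -- the real-time path is
#' strictly causal.
#'
#' @inheritParams iir_filter
#' @return Numeric vector, same length as `x`.
#' @export
iir_zerophase <- function(coef, x) {
  y1 <- iir_causal(coef, x)
  rev(iir_causal(coef, rev(y1)))
}

#' Frequency-response magnitude of a designed filter
#'
#' Evaluates |H(e^{i 2 pi f / fs})| directly from the transfer-function
#' polynomials; serves as the analytic gain oracle for steady-state
#' sine-probe tests.
#'
#' @param coef List with `b`, `a`.
#' @param f_hz Frequencies at which to evaluate, Hz.
#' @param rate_hz Sampling rate, Hz.
#' @return Numeric vector of gains.
#' @export
filter_gain <- function(coef, f_hz, rate_hz) {
  vapply(f_hz, function(f) {
    w <- 2 * pi * f / rate_hz
    num <- sum(coef$b * exp(-1i * w * (seq_along(coef$b) - 1L)))
    den <- sum(coef$a * exp(-1i * w * (seq_along(coef$a) - 1L)))
    Mod(num / den)
  }, numeric(1))
}
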