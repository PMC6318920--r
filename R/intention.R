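# Motion-intention detection.
#
# The main routine: conditioned sEMG -> RMS envelope over adjacent 20 ms
# windows (50 Hz envelope rate, one window per real-time frame) -> MVC
# normalization -> signed linear combination
#
#     LC = RF_RMS + VM_RMS - BF_RMS - ST_RMS
#
# -> first-order 2 Hz Butterworth smoothing.  Positive LC encodes
# extension intent (the extensors RF, VM dominate), negative LC flexion
# intent; |LC| grows with effort relative to MVC.  Because the envelopes
# are RMS values normalized by MAV-derived maxima and RMS >= MAV, |LC|
# can transiently exceed 2 on MVC-level input; no clipping is applied by
# default.

#' Linear-combination coefficients
#'
#' The per-muscle gains and offsets of the intention statistic,
#' heuristically fixed: +1 gain for the extensors (RF, VM), -1 for the
#' flexors (BF, ST), zero offsets.  Overridable only for experiments.
#'
#' @param a Named per-muscle gains.
#' @param b Named per-muscle offsets.
#' @return An `lc_coefficients` object.
#' @export
lc_coefficients <- function(a = c(RF = 1, VM = 1, BF = -1, ST = -1),
                            b = c(RF = 0, VM = 0, BF = 0, ST = 0)) {
  structure(list(a = a[EMG_CHANNELS], b = b[EMG_CHANNELS]),
            class = "lc_coefficients")
}

#' RMS envelope over adjacent windows
#'
#' Per channel and adjacent (non-overlapping) window,
#' `sqrt(mean(x^2))`; with the default 20 ms window at 1 kHz each window
#' holds 20 samples and the envelope rate is 50 Hz, matching the
#' real-time frame.  Trailing samples not filling a window are dropped.
#'
#' @param rec Conditioned [emg_recording()].
#' @param window_ms Window length, milliseconds.
#' @return Matrix `4 x n_windows` of unnormalized envelopes.
#' @export
rms_envelope <- function(rec, window_ms = 20) {
  if (n_samples(rec) == 0L) stop("empty recording")
  w <- floor(window_ms * rec$rate_hz / 1000)
  if (w < 1L) stop("window shorter than one sample")
  n_win <- ncol(rec$samples) %/% w
  if (n_win == 0L) stop("recording shorter than one window")
  out <- matrix(0, nrow(rec$samples), n_win,
                dimnames = list(rec$channels, NULL))
  for (k in seq_len(nrow(out))) {
    x <- rec$samples[k, seq_len(n_win * w)]
    out[k, ] <- sqrt(colMeans(matrix(x^2, nrow = w)))
  }
  out
}

#' Normalize envelopes by the MVC calibration values
#'
#' @param env Matrix `4 x n_windows` from [rms_envelope()].
#' @param calib A `normalization_values` object.
#' @return Dimensionless envelope matrix (fraction of the MVC-derived
#'   normalization value).
#' @export
normalize_envelope <- function(env, calib) {
  if (any(calib$max_mav <= 0)) stop("calibration values must be positive")
  env / calib$max_mav[rownames(env)]
}

#' The intention linear combination
#'
#' Per window, `sum_m (a_m * env_m + b_m)` over the four muscles; with
#' the default coefficients this is
#' `RF_RMS + VM_RMS - BF_RMS - ST_RMS`.
#'
#' @param env Normalized envelope matrix `4 x n_windows`.
#' @param coef An [lc_coefficients()].
#' @return Numeric vector, one LC value per window.
#' @export
linear_combination <- function(env, coef = lc_coefficients()) {
  as.numeric(colSums(coef$a * env[EMG_CHANNELS, , drop = FALSE] + coef$b))
}

#' Smooth the LC stream
#'
#' Causal first-order Butterworth low-pass (2 Hz by default) applied at
#' the envelope rate, to remove peaks; streaming-capable with carried
#' state.
#'
#' @param lc Numeric LC sequence.
#' @param rate_hz Envelope rate, Hz (50 for 20 ms windows at 1 kHz).
#' @param spec A [filter_spec()] (fields `lp_cut_hz`, `lp_order`).
#' @return Filtered sequence, same length.
#' @export
lowpass_lc <- function(lc, rate_hz = 50, spec = filter_spec()) {
  if (spec$lp_cut_hz >= rate_hz / 2) {
    stop("low-pass cutoff must be below the envelope Nyquist rate")
  }
  coef <- butter_design(spec$lp_order, spec$lp_cut_hz, rate_hz, type = "low")
  iir_causal(coef, lc)
}

#' Run the full intention pipeline on a recording
#'
#' Conditioning -> RMS envelopes -> MVC normalization -> linear
#' combination -> 2 Hz smoothing.  With `filt$mode = "causal"` and a
#' frozen `dc_ref` this reproduces, sample for sample, what the
#' streaming real-time path computes.
#'
#' @param rec Raw [emg_recording()].
#' @param calib `normalization_values` from [compute_normalization()].
#' @param filt A [filter_spec()].
#' @param coef An [lc_coefficients()].
#' @param window_ms Envelope window, milliseconds.
#' @param dc_ref Optional frozen DC reference (defaults to the
#'   calibration's stored reference in causal mode, buffer means in
#'   zero-phase mode).
#' @param clip If `TRUE`, clip the filtered LC to [-2, 2] (off by
#'   default; see the package vignette).
#' @return An `intention_series` with `lc_raw`, `lc_filtered`,
#'   `envelope_rate_hz`.
#' @export
detect_intention <- function(rec, calib, filt = filter_spec(),
                             coef = lc_coefficients(), window_ms = 20,
                             dc_ref = NULL, clip = FALSE) {
  if (is.null(dc_ref) && filt$mode == "causal") dc_ref <- calib$dc_ref
  pp <- emg_preprocess(rec, filt, dc_ref = dc_ref)
  env <- normalize_envelope(rms_envelope(pp, window_ms), calib)
  lc <- linear_combination(env, coef)
  rate <- rec$rate_hz / floor(window_ms * rec$rate_hz / 1000)
  lcf <- lowpass_lc(lc, rate, filt)
  if (clip) lcf <- pmin(pmax(lcf, -2), 2)
  structure(list(lc_raw = lc, lc_filtered = lcf, envelope_rate_hz = rate),
            class = "intention_series")
}

#' @export
print.intention_series <- function(x, ...) {
  cat(sprintf("<intention_series> %d windows @ %g Hz; filtered LC in [%.3f, %.3f]\n",
              length(x$lc_raw), x$envelope_rate_hz,
              min(x$lc_filtered), max(x$lc_filtered)))
  invisible(x)
}

#' Reduce an intention series to a detected orientation
#'
#' The trial-level orientation is the sign of the filtered LC value of
#' maximum magnitude; magnitudes inside the dead-band are reported as
#' `"none"`.
#'
#' @param intent An `intention_series`.
#' @param deadband Dead-band on |LC| below which no intent is declared.
#' @return `"extension"`, `"flexion"` or `"none"`.
#' @export
classify_orientation <- function(intent, deadband = 0.05) {
  i <- which.max(abs(intent$lc_filtered))
  peak <- intent$lc_filtered[i]
  if (abs(peak) < deadband) return("none")
  if (peak > 0) "extension" else "flexion"
}

#' Peak intention intensity relative to MVC
#'
#' `peak |lc_filtered| / 2`: the surrogate intensity on a 0-1 scale,
#' since the two agonist envelopes each reach about 1 at MVC.
#'
#' @param intent An `intention_series`.
#' @return Non-negative scalar.
#' @export
intensity_ratio <- function(intent) max(abs(intent$lc_filtered)) / 2

# ---------------------------------------------------------------------
# Streaming (real-time) intention pipeline: per-channel band-pass state,
# frozen DC reference, one RMS window per frame, low-pass state.
# Arithmetic is identical to the causal batch path.

#' Initialize the streaming intention pipeline
#'
#' @param calib `normalization_values` (supplies the frozen DC
#'   reference).
#' @param filt A [filter_spec()]; the streaming path is always causal.
#' @param coef An [lc_coefficients()].
#' @param rate_hz Raw sampling rate, Hz.
#' @param window_ms Frame/envelope window, milliseconds.
#' @return A `mec_stream` state object.
#' @export
mec_stream_init <- function(calib, filt = filter_spec(mode = "causal"),
                            coef = lc_coefficients(), rate_hz = 1000,
                            window_ms = 20) {
  env_rate <- rate_hz / floor(window_ms * rate_hz / 1000)
  if (filt$lp_cut_hz >= env_rate / 2) {
    stop("low-pass cutoff must be below the envelope Nyquist rate")
  }
  structure(list(
    bp_coef = bandpass_coef(filt, rate_hz),
    lp_coef = butter_design(filt$lp_order, filt$lp_cut_hz, env_rate, "low"),
    bp_state = vector("list", 4L),
    lp_state = NULL,
    calib = calib, coef = coef,
    rate_hz = rate_hz, window_ms = window_ms,
    env_rate_hz = env_rate, n_frames = 0L),
    class = "mec_stream")
}

#' Consume one 20 ms frame and emit one intention value
#'
#' @param stream A `mec_stream` from [mec_stream_init()].
#' @param frame Matrix `4 x window` of raw sEMG samples.
#' @return List with `stream` (updated), `lc_raw`, `lc_filtered`.
#' @export
mec_stream_update <- function(stream, frame) {
  w <- floor(stream$window_ms * stream$rate_hz / 1000)
  if (!is.matrix(frame) || nrow(frame) != 4L || ncol(frame) != w) {
    stop("frame must be a 4 x ", w, " matrix")
  }
  env <- numeric(4L)
  for (k in 1:4) {
    st <- stream$bp_state[[k]]
    if (is.null(st)) st <- iir_state_init(stream$bp_coef, frame[k, 1L])
    res <- iir_filter(stream$bp_coef, frame[k, ], st)
    stream$bp_state[[k]] <- res$state
    x <- abs(res$y - stream$calib$dc_ref[k])
    env[k] <- sqrt(mean(x^2))
  }
  env <- env / stream$calib$max_mav
  lc <- sum(stream$coef$a * env + stream$coef$b)
  if (is.null(stream$lp_state)) {
    stream$lp_state <- iir_state_init(stream$lp_coef, lc)
  }
  res <- iir_filter(stream$lp_coef, lc, stream$lp_state)
  stream$lp_state <- res$state
  stream$n_frames <- stream$n_frames + 1L
  list(stream = stream, lc_raw = lc, lc_filtered = res$y)
}
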