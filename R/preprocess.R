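# Raw sEMG conditioning: band-pass filtering, DC-offset removal and
# full-wave rectification, in that order.  No notch filter exists in any
# code path: powerline interference handling by notch filtering degrades
# the sEMG spectrum and is excluded by the SENIAM/ISEK recommendations
# the acquisition follows.

#' Filtering configuration for the sEMG pipeline
#'
#' @param bp_low_hz Band-pass lower cutoff, Hz (10).
#' @param bp_high_hz Band-pass upper cutoff, Hz (500).  At a 1 kHz
#'   sampling rate 500 Hz sits exactly at Nyquist and cannot be realized;
#'   the design clamps it to 0.99 x Nyquist with a warning.
#' @param bp_order Band-pass Butterworth order (4).
#' @param lp_cut_hz Cutoff of the intention-stream low-pass, Hz (2).
#' @param lp_order Order of that low-pass (1).
#' @param mode `"zero_phase"` for offline analysis (forward-backward) or
#'   `"causal"` for the real-time path.
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(bp_low_hz = 10, bp_high_hz = 500, bp_order = 4,
                        lp_cut_hz = 2, lp_order = 1,
                        mode = c("zero_phase", "causal")) {
  mode <- match.arg(mode)
  if (bp_low_hz <= 0 || bp_low_hz >= bp_high_hz) {
    stop("need 0 < bp_low_hz < bp_high_hz")
  }
  if (lp_order < 1) stop("lp_order must be >= 1")
  structure(list(bp_low_hz = bp_low_hz, bp_high_hz = bp_high_hz,
                 bp_order = bp_order, lp_cut_hz = lp_cut_hz,
                 lp_order = lp_order, mode = mode),
            class = "filter_spec")
}

# Band-pass coefficients for a recording's rate, applying the Nyquist
# clamping rule.
bandpass_coef <- function(spec, rate_hz) {
  nyq <- rate_hz / 2
  if (spec$bp_low_hz >= nyq) {
    stop("bp_low_hz (", spec$bp_low_hz, " Hz) must be below Nyquist (",
         nyq, " Hz)")
  }
  hi <- spec$bp_high_hz
  if (hi >= nyq) {
    hi <- 0.99 * nyq
    warning(sprintf(
      "bp_high_hz = %g Hz is at or above Nyquist (%g Hz); clamped to %g Hz",
      spec$bp_high_hz, nyq, hi))
  }
  butter_design(spec$bp_order, c(spec$bp_low_hz, hi), rate_hz, type = "pass")
}

#' Band-pass filter an sEMG recording
#'
#' Butterworth band-pass per channel; zero-phase or causal per the spec's
#' `mode`.  Causal filtering is initialized at steady state for each
#' channel's first sample.
#'
#' @param rec An [emg_recording()].
#' @param spec A [filter_spec()].
#' @return Filtered [emg_recording()], same shape and rate.
#' @export
emg_bandpass <- function(rec, spec = filter_spec()) {
  if (n_samples(rec) == 0L) stop("empty recording")
  coef <- bandpass_coef(spec, rec$rate_hz)
  f <- if (spec$mode == "zero_phase") iir_zerophase else iir_causal
  out <- t(apply(rec$samples, 1L, function(x) f(coef, x)))
  emg_recording(out, rec$rate_hz, rec$channels, rec$t0)
}

#' Remove the DC offset of each channel
#'
#' Batch use subtracts each channel's own mean over the buffer.  The
#' streaming (real-time) path cannot see a future mean, so it subtracts a
#' frozen per-channel reference estimated during MVC calibration; pass
#' that reference as `dc_ref` to reproduce the streaming arithmetic in
#' batch.
#'
#' @param rec An [emg_recording()].
#' @param dc_ref Optional per-channel reference means to subtract instead
#'   of the buffer means.
#' @return [emg_recording()] with (buffer- or reference-) centred
#'   channels.
#' @export
emg_remove_dc <- function(rec, dc_ref = NULL) {
  if (n_samples(rec) == 0L) stop("empty recording")
  mu <- if (is.null(dc_ref)) rowMeans(rec$samples) else rep_len(dc_ref, nrow(rec$samples))
  emg_recording(rec$samples - mu, rec$rate_hz, rec$channels, rec$t0)
}

#' Full-wave rectification
#'
#' Elementwise absolute value, so amplitude descriptors (MAV, RMS) can be
#' computed on the result.
#'
#' @param rec An [emg_recording()].
#' @return Rectified [emg_recording()]; all samples non-negative.
#' @export
emg_rectify <- function(rec) {
  emg_recording(abs(rec$samples), rec$rate_hz, rec$channels, rec$t0)
}

#' Full sEMG conditioning chain
#'
#' Band-pass -> DC removal -> full-wave rectification, in that block
#' order.
#'
#' @inheritParams emg_bandpass
#' @inheritParams emg_remove_dc
#' @return Conditioned [emg_recording()].
#' @export
emg_preprocess <- function(rec, spec = filter_spec(), dc_ref = NULL) {
  emg_rectify(emg_remove_dc(emg_bandpass(rec, spec), dc_ref))
}
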