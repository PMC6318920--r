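# MVC calibration: the only calibration state of the controller.
#
# The knee extensors (RF, VM) are normalized by their activity in the
# extension MVC trial (exercise 4), the flexors (BF, ST) by the flexion
# MVC trial (exercise 1).  Each normalization value is the maximum mean
# absolute value (MAV) over adjacent 500 ms windows of the conditioned
# signal.

#' MAV over adjacent (non-overlapping) windows
#'
#' Mean of the samples in each full window; trailing samples that do not
#' fill a window are discarded (a short window would bias the MAV under
#' nonstationarity).
#'
#' @param x Single-channel conditioned (rectified) signal.
#' @param window_ms Window length, milliseconds (500 for calibration).
#' @param rate_hz Sampling rate, Hz.
#' @return Numeric vector of per-window MAVs.
#' @export
mav_windows <- function(x, window_ms = 500, rate_hz = 1000) {
  if (length(x) == 0L) stop("empty signal")
  w <- floor(window_ms * rate_hz / 1000)
  if (w < 1L) stop("window shorter than one sample")
  n_win <- length(x) %/% w
  if (n_win == 0L) stop("signal shorter than one window")
  colMeans(matrix(x[seq_len(n_win * w)], nrow = w))
}

#' Compute the four MVC normalization values
#'
#' Conditions both MVC trials, extracts 500 ms adjacent-window MAVs and
#' stores the maximum per channel: RF and VM from the extension trial,
#' BF and ST from the flexion trial.  Alongside, the per-channel mean of
#' the band-passed (pre-rectification) calibration signal is stored as
#' the frozen DC reference used by the causal streaming path.
#'
#' @param trial_flexion [emg_recording()] of the flexion MVC (exercise 1).
#' @param trial_extension [emg_recording()] of the extension MVC
#'   (exercise 4).
#' @param filt A [filter_spec()].
#' @param window_ms MAV window, milliseconds.
#' @param check_quality If `TRUE`, reject calibrations whose maximum MAV
#'   does not exceed 3x the quietest window of the same trial (flat
#'   signal or swapped channels).
#' @return A `normalization_values` object with fields `max_mav` (named,
#'   all positive), `source_trial`, `mav_window_ms`, `dc_ref`.
#' @export
compute_normalization <- function(trial_flexion, trial_extension,
                                  filt = filter_spec(), window_ms = 500,
                                  check_quality = TRUE) {
  bp_flex <- emg_bandpass(trial_flexion, filt)
  bp_ext <- emg_bandpass(trial_extension, filt)
  pp_flex <- emg_rectify(emg_remove_dc(bp_flex))
  pp_ext <- emg_rectify(emg_remove_dc(bp_ext))
  src <- c(RF = "extension", VM = "extension", BF = "flexion", ST = "flexion")
  max_mav <- numeric(4)
  names(max_mav) <- EMG_CHANNELS
  dc_ref <- numeric(4)
  names(dc_ref) <- EMG_CHANNELS
  for (ch in EMG_CHANNELS) {
    rec <- if (src[[ch]] == "extension") pp_ext else pp_flex
    bp <- if (src[[ch]] == "extension") bp_ext else bp_flex
    mav <- mav_windows(rec$samples[ch, ], window_ms, rec$rate_hz)
    max_mav[ch] <- max(mav)
    dc_ref[ch] <- mean(bp$samples[ch, ])
    if (max_mav[ch] <= 0) {
      stop("calibration failed: channel ", ch, " is flat")
    }
    if (check_quality && max(mav) <= 3 * min(mav)) {
      stop("calibration quality check failed for channel ", ch,
           ": maximum MAV does not exceed 3x the quietest window ",
           "(flat signal or swapped channels?)")
    }
  }
  structure(list(max_mav = max_mav,
                 source_trial = c(RF = 4L, VM = 4L, BF = 1L, ST = 1L),
                 mav_window_ms = window_ms,
                 dc_ref = dc_ref),
            class = "normalization_values")
}

#' @export
print.normalization_values <- function(x, ...) {
  cat("<normalization_values> max MAV (500 ms windows):\n")
  for (ch in names(x$max_mav)) {
    cat(sprintf("  %s: %.6g (trial %d)\n", ch, x$max_mav[[ch]],
                x$source_trial[[ch]]))
  }
  invisible(x)
}

#' Persist calibration to a key-value text file
#'
#' One calibration per session: the four maxima, their source trials, the
#' MAV window and the frozen DC references.
#'
#' @param calib A `normalization_values` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(calib, path) {
  lines <- c(
    "format=kneemec-calibration-1",
    sprintf("mav_window_ms=%.10g", calib$mav_window_ms),
    sprintf("max_mav.%s=%.17g", names(calib$max_mav), calib$max_mav),
    sprintf("source_trial.%s=%d", names(calib$source_trial), calib$source_trial),
    sprintf("dc_ref.%s=%.17g", names(calib$dc_ref), calib$dc_ref)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a calibration file written by [write_calibration()]
#'
#' @param path File path.
#' @return A `normalization_values` object.
#' @export
read_calibration <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  if (vals[keys == "format"] != "kneemec-calibration-1") {
    stop("unrecognized calibration file: ", path)
  }
  pick <- function(prefix, as = as.numeric) {
    sel <- startsWith(keys, paste0(prefix, "."))
    out <- as(vals[sel])
    names(out) <- sub(paste0(prefix, "."), "", keys[sel], fixed = TRUE)
    out[EMG_CHANNELS]
  }
  structure(list(max_mav = pick("max_mav"),
                 source_trial = pick("source_trial", as.integer),
                 mav_window_ms = as.numeric(vals[keys == "mav_window_ms"]),
                 dc_ref = pick("dc_ref")),
            class = "normalization_values")
}
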