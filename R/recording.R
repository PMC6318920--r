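# Signal containers and the delimited-text trial dialect.
#
# A "trial" on disk is a tab-separated file in an OpenSignals-like layout:
# one metadata header line, one column-name line, then one row per sample
# with the sample index, the four sEMG channels (RF, VM, BF, ST) and the
# three goniometer angles (hip FE, knee FE, ankle DP), all at 1 kHz.

EMG_CHANNELS <- c("RF", "VM", "BF", "ST")
GONIO_JOINTS <- c("hip", "knee", "ankle")

#' Multichannel sEMG recording
#'
#' @param samples Numeric matrix, channels in rows, samples in columns.
#' @param rate_hz Sampling rate in Hz (1000 for the acquisition setup the
#'   pipeline targets).
#' @param channels Ordered channel labels; defaults to the four knee
#'   muscles RF, VM (extensors) and BF, ST (flexors).
#' @param t0 Time of the first sample, seconds.
#' @return An `emg_recording` object.
#' @export
emg_recording <- function(samples, rate_hz = 1000,
                          channels = EMG_CHANNELS, t0 = 0) {
  samples <- as.matrix(samples)
  if (rate_hz <= 0) stop("rate_hz must be positive")
  if (nrow(samples) != length(channels)) {
    stop("samples must have one row per channel")
  }
  if (anyDuplicated(channels)) stop("channel labels must be unique")
  rownames(samples) <- channels
  structure(list(samples = samples, rate_hz = rate_hz,
                 channels = channels, t0 = t0),
            class = "emg_recording")
}

#' Goniometer recording (hip FE, knee FE, ankle DP)
#'
#' @param angles Numeric matrix `3 x n`, degrees.
#' @param rate_hz Sampling rate in Hz.
#' @param joints Joint labels, in order.
#' @return A `gonio_recording` object.
#' @export
gonio_recording <- function(angles, rate_hz = 1000, joints = GONIO_JOINTS) {
  angles <- as.matrix(angles)
  if (rate_hz <= 0) stop("rate_hz must be positive")
  if (nrow(angles) != length(joints)) stop("angles must have one row per joint")
  rownames(angles) <- joints
  structure(list(angles = angles, rate_hz = rate_hz, joints = joints),
            class = "gonio_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d channel(s) [%s], %d samples @ %g Hz (%.2f s)\n",
              nrow(x$samples), paste(x$channels, collapse = ", "),
              ncol(x$samples), x$rate_hz, ncol(x$samples) / x$rate_hz))
  invisible(x)
}

#' @export
print.gonio_recording <- function(x, ...) {
  cat(sprintf("<gonio_recording> %s; %d samples @ %g Hz\n",
              paste(x$joints, collapse = ", "), ncol(x$angles), x$rate_hz))
  invisible(x)
}

n_samples <- function(rec) {
  ncol(if (inherits(rec, "emg_recording")) rec$samples else rec$angles)
}

#' Write a trial (sEMG + goniometer) to a delimited text file
#'
#' @param emg An [emg_recording()].
#' @param gonio A [gonio_recording()] with the same duration and rate.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(emg, gonio, path) {
  stopifnot(inherits(emg, "emg_recording"), inherits(gonio, "gonio_recording"))
  if (ncol(emg$samples) != ncol(gonio$angles) || emg$rate_hz != gonio$rate_hz) {
    stop("emg and gonio must share duration and rate")
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# kneemec trial rate_hz=%.10g t0=%.10g", emg$rate_hz, emg$t0), con)
  writeLines(paste(c("index", emg$channels, paste0(gonio$joints, "_deg")),
                   collapse = "\t"), con)
  dat <- cbind(seq_len(ncol(emg$samples)) - 1L,
               t(emg$samples), t(gonio$angles))
  utils::write.table(format(dat, digits = 10, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a trial written by [write_trial()]
#'
#' @param path File path.
#' @return List with elements `emg` and `gonio`.
#' @export
read_trial <- function(path) {
  header <- readLines(path, n = 2L)
  if (!grepl("^# kneemec trial", header[1L])) {
    stop("not a kneemec trial file: ", path)
  }
  rate <- as.numeric(sub(".*rate_hz=([0-9.eE+-]+).*", "\\1", header[1L]))
  t0 <- as.numeric(sub(".*t0=([0-9.eE+-]+).*", "\\1", header[1L]))
  cols <- strsplit(header[2L], "\t", fixed = TRUE)[[1L]]
  dat <- utils::read.table(path, sep = "\t", skip = 2L,
                           col.names = cols, check.names = FALSE)
  emg_cols <- cols[2:5]
  gon_cols <- cols[6:8]
  emg <- emg_recording(t(as.matrix(dat[, emg_cols])), rate_hz = rate,
                       channels = emg_cols, t0 = t0)
  gonio <- gonio_recording(t(as.matrix(dat[, gon_cols])), rate_hz = rate,
                           joints = sub("_deg$", "", gon_cols))
  list(emg = emg, gonio = gonio)
}
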