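# Closed-loop runner and evaluation metrics.
#
# Four components per control tick (TS = 0.02 s = one 20 ms frame):
# (1) the signal source emits one 4 x 20 sEMG frame plus the goniometer
# sample at the tick instant; (2) the causal intention pipeline turns it
# into one filtered LC value; (3) the set-point conversion and computed
# torque controller produce a torque command; (4) the leg model
# integrates one tick and the loop acknowledges.  The frame protocol is
# newline-delimited text with %.17g number formatting (lossless for
# doubles), and the in-process transport round-trips every frame through
# the same serializer, so the TCP loopback transport is bit-identical by
# construction.

#' Closed-loop configuration
#'
#' @param tick_period_s Control tick, seconds; must equal the envelope
#'   window of the intention pipeline.
#' @param transport `"in_process"` or `"tcp_loopback"`.
#' @param tcp_port Loopback port for the TCP transport.
#' @param max_ticks Optional cap on the number of ticks to run.
#' @return A `hil_config` object.
#' @export
hil_config <- function(tick_period_s = 0.02,
                       transport = c("in_process", "tcp_loopback"),
                       tcp_port = 30917, max_ticks = Inf) {
  transport <- match.arg(transport)
  if (tick_period_s <= 0) stop("tick_period_s must be positive")
  structure(list(tick_period_s = tick_period_s, transport = transport,
                 tcp_port = tcp_port, max_ticks = max_ticks),
            class = "hil_config")
}

fmt_frame <- function(tag, tick, values) {
  paste(tag, tick, paste(sprintf("%.17g", values), collapse = " "))
}

parse_frame <- function(line, tag, tick, n_values) {
  if (is.null(line) || length(line) == 0L || !nzchar(line)) {
    stop("protocol error: empty or dropped frame at tick ", tick)
  }
  parts <- strsplit(line, " ", fixed = TRUE)[[1L]]
  if (parts[1L] != tag || as.integer(parts[2L]) != tick ||
      length(parts) != n_values + 2L) {
    stop("protocol error: malformed ", tag, " frame at tick ", tick)
  }
  as.numeric(parts[-(1:2)])
}

# Transport abstraction: send a line one way, receive it on the other
# side.  The in-process transport still serializes and re-parses, so
# both transports quantize identically.
transport_open <- function(cfg) {
  if (cfg$transport == "in_process") {
    return(list(kind = "in_process"))
  }
  srv <- serverSocket(cfg$tcp_port)
  cl <- socketConnection("127.0.0.1", cfg$tcp_port, blocking = FALSE,
                         open = "w+b")
  acc <- socketAccept(srv, blocking = TRUE, open = "w+b")
  list(kind = "tcp", srv = srv, cl = cl, acc = acc)
}

transport_close <- function(tr) {
  if (tr$kind == "tcp") {
    close(tr$cl); close(tr$acc); close(tr$srv)
  }
  invisible(NULL)
}

# Round-trip one line from the "client" (simulator) side to the
# "server" (controller) side or back.
transport_pass <- function(tr, line, from_client = TRUE) {
  if (tr$kind == "in_process") return(line)
  a <- if (from_client) tr$cl else tr$acc
  b <- if (from_client) tr$acc else tr$cl
  writeLines(line, a)
  flush(a)
  out <- character(0)
  for (i in 1:200) {
    out <- readLines(b, n = 1L)
    if (length(out) > 0L) break
    Sys.sleep(0.005)
  }
  if (length(out) == 0L) stop("transport timeout: no frame received")
  out
}

#' Run the closed myoelectric control loop on one trial
#'
#' Streams the trial's sEMG in 20 ms frames through the causal intention
#' pipeline, converts each intention value to the knee velocity
#' set-point, tracks the assembled desired trajectory with the computed
#' torque controller, and integrates the leg model -- one full cycle per
#' tick.  Identical inputs give identical results for both transports.
#'
#' @param trial A `mec_trial` (or list with `emg`, `gonio`).
#' @param calib `normalization_values` from MVC calibration.
#' @param filt A [filter_spec()]; the loop always runs causally.
#' @param coef An [lc_coefficients()].
#' @param sp_cfg A [setpoint_config()].
#' @param robot A [robot_params()].
#' @param gains A [controller_gains()].
#' @param cfg A [hil_config()].
#' @return A `sim_result`: per-tick `log` data frame, `mae_position`
#'   (hip/knee/ankle, degrees), `speed_error` (MAE and max, deg/s, knee),
#'   `orientation_detected`, `intensity_ratio`.
#' @export
run_hil <- function(trial, calib, filt = filter_spec(mode = "causal"),
                    coef = lc_coefficients(), sp_cfg = setpoint_config(),
                    robot = robot_params(), gains = controller_gains(),
                    cfg = hil_config()) {
  emg <- trial$emg
  gonio <- trial$gonio
  w <- round(emg$rate_hz * cfg$tick_period_s)
  n_ticks <- min(ncol(emg$samples) %/% w, cfg$max_ticks)
  if (n_ticks < 1L) stop("trial shorter than one control tick")
  filt$mode <- "causal"
  stream <- mec_stream_init(calib, filt, coef, emg$rate_hz,
                            window_ms = 1000 * cfg$tick_period_s)
  lp_gonio <- butter_design(filt$lp_order, filt$lp_cut_hz,
                            1 / cfg$tick_period_s, "low")
  tr <- transport_open(cfg)
  on.exit(transport_close(tr))

  # Initial state: the measured leg starts on the desired posture.
  q0 <- c(gonio$angles["hip", 1L], gonio$angles["knee", 1L],
          gonio$angles["ankle", 1L])
  theta <- deg_to_chain(q0)
  thetadot <- c(0, 0, 0)
  knee_qd <- gonio$angles["knee", 1L]
  hip_prev <- q0[1L]; ankle_prev <- q0[3L]
  hip_lp <- NULL; ankle_lp <- NULL
  qdot_d_prev <- c(0, 0, 0)
  accel_prev <- c(0, 0, 0)

  log <- matrix(NA_real_, n_ticks, 18L)
  colnames(log) <- c("tick", "time", "lc_filtered",
                     "q_d_hip", "q_d_knee", "q_d_ankle",
                     "q_m_hip", "q_m_knee", "q_m_ankle",
                     "qdot_d_hip", "qdot_d_knee", "qdot_d_ankle",
                     "qdot_m_hip", "qdot_m_knee", "qdot_m_ankle",
                     "tau_hip", "tau_knee", "tau_ankle")

  for (k in seq_len(n_ticks)) {
    idx <- ((k - 1L) * w + 1L):(k * w)
    frame <- emg$samples[, idx, drop = FALSE]
    gsamp <- gonio$angles[, k * w]
    line <- fmt_frame("D", k, c(as.numeric(frame), gsamp))
    vals <- parse_frame(transport_pass(tr, line, TRUE), "D", k, 4L * w + 3L)
    frame_rx <- matrix(vals[seq_len(4L * w)], 4L, w)
    rownames(frame_rx) <- emg$channels
    g_rx <- vals[4L * w + (1:3)]

    up <- mec_stream_update(stream, frame_rx)
    stream <- up$stream
    lc_f <- up$lc_filtered

    # Set-point conversion at this tick.
    vk <- knee_speed_setpoint(lc_f, sp_cfg)
    nxt <- knee_qd + vk * sp_cfg$control_period_s
    if (nxt <= sp_cfg$knee_rom[1]) { nxt <- sp_cfg$knee_rom[1]; vk <- 0 }
    if (nxt >= sp_cfg$knee_rom[2]) { nxt <- sp_cfg$knee_rom[2]; vk <- 0 }
    knee_qd <- nxt
    hip_q <- g_rx[1L]; ankle_q <- g_rx[3L]
    hip_raw_v <- if (k == 1L) 0 else (hip_q - hip_prev) / cfg$tick_period_s
    ankle_raw_v <- if (k == 1L) 0 else (ankle_q - ankle_prev) / cfg$tick_period_s
    if (is.null(hip_lp)) hip_lp <- iir_state_init(lp_gonio, hip_raw_v)
    if (is.null(ankle_lp)) ankle_lp <- iir_state_init(lp_gonio, ankle_raw_v)
    rh <- iir_filter(lp_gonio, hip_raw_v, hip_lp); hip_lp <- rh$state
    ra <- iir_filter(lp_gonio, ankle_raw_v, ankle_lp); ankle_lp <- ra$state
    hip_prev <- hip_q; ankle_prev <- ankle_q

    q_d <- c(hip_q, knee_qd, ankle_q)
    qdot_d <- c(rh$y, vk, ra$y)
    accel_raw <- if (k == 1L) c(0, 0, 0) else
      (qdot_d - qdot_d_prev) / cfg$tick_period_s
    qddot_d <- (accel_raw + accel_prev) / 2
    accel_prev <- accel_raw
    qdot_d_prev <- qdot_d

    tau <- ctc_torque(theta, thetadot,
                      deg_to_chain(q_d), degv_to_chain(qdot_d),
                      degv_to_chain(qddot_d), gains, robot)
    tau_rx <- parse_frame(transport_pass(tr, fmt_frame("T", k, tau), FALSE),
                          "T", k, 3L)
    st <- step_dynamics(theta, thetadot, tau_rx, robot,
                        dt = cfg$tick_period_s)
    theta <- st$theta
    thetadot <- st$thetadot
    ack <- transport_pass(tr, fmt_frame("A", k, numeric(0)), TRUE)
    parse_frame(ack, "A", k, 0L)

    q_m <- chain_to_deg(theta)
    qdot_m <- chainv_to_deg(thetadot)
    log[k, ] <- c(k, k * cfg$tick_period_s, lc_f, q_d, q_m, qdot_d,
                  qdot_m, tau_rx)
  }

  log <- as.data.frame(log)
  mae <- c(hip = mae_position(log$q_d_hip, log$q_m_hip),
           knee = mae_position(log$q_d_knee, log$q_m_knee),
           ankle = mae_position(log$q_d_ankle, log$q_m_ankle))
  sp_err <- log$qdot_d_knee - log$qdot_m_knee
  intent <- structure(list(lc_raw = log$lc_filtered,
                           lc_filtered = log$lc_filtered,
                           envelope_rate_hz = 1 / cfg$tick_period_s),
                      class = "intention_series")
  structure(list(log = log, mae_position = mae,
                 speed_error = c(mae = mean(abs(sp_err)),
                                 max = max(abs(sp_err))),
                 orientation_detected = classify_orientation(intent),
                 intensity_ratio = intensity_ratio(intent)),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(paste0("<sim_result> %d ticks; position MAE (deg): hip %.4g, ",
                     "knee %.4g, ankle %.4g; orientation: %s\n"),
              nrow(x$log), x$mae_position["hip"], x$mae_position["knee"],
              x$mae_position["ankle"], x$orientation_detected))
  invisible(x)
}

#' Mean absolute position error
#'
#' @param q_d,q_m Desired and measured angle series, degrees, equal
#'   length.
#' @return Mean of `|q_d - q_m|`, degrees.
#' @export
mae_position <- function(q_d, q_m) {
  if (length(q_d) != length(q_m) || length(q_d) < 1L) {
    stop("series must have equal positive length")
  }
  mean(abs(q_d - q_m))
}

#' Orientation detection rate over a battery of trials
#'
#' @param detected Character vector of detected orientations.
#' @param commanded Character vector of commanded directions.
#' @return Fraction of trials where they agree, in [0, 1].
#' @export
orientation_rate <- function(detected, commanded) {
  if (length(detected) != length(commanded)) stop("length mismatch")
  mean(detected == commanded)
}

#' Epley one-repetition-maximum estimate
#'
#' `1RM = w (1 + r / 30)` from the heaviest weight `w` lifted for `r`
#' repetitions until fatigue, using the exact fraction (not the 0.0333
#' truncation); the dynamic-contraction exercises of the protocol are
#' dosed at 75% and 50% of this estimate.
#'
#' @param w Weight lifted, kg (> 0).
#' @param r Repetitions until fatigue, integer >= 0.
#' @return A `one_rm_estimate` with fields `w`, `r`, `one_rm`.
#' @export
epley_1rm <- function(w, r) {
  if (w <= 0) stop("weight must be positive")
  if (r < 0 || r != round(r)) stop("repetitions must be a non-negative integer")
  structure(list(w = w, r = as.integer(r), one_rm = w * (1 + r / 30)),
            class = "one_rm_estimate")
}

#' @export
print.one_rm_estimate <- function(x, ...) {
  cat(sprintf("<one_rm_estimate> w = %g kg x %d reps -> 1RM = %g kg\n",
              x$w, x$r, x$one_rm))
  invisible(x)
}

#' Write a per-tick simulation log as delimited text
#'
#' @param result A `sim_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sim_log <- function(result, path) {
  utils::write.table(format(result$log, digits = 10, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
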