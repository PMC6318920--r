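# Set-point conversion: intention -> desired joint trajectories.
#
# The knee is commanded in velocity, linearly in the intention value:
#
#     qdot_d_knee = alpha * LC + beta        [deg/s]
#
# with alpha (amplitude scaling) and beta (offset) left to the
# physiotherapist.  The desired knee position is the explicit-Euler
# integral of that velocity from the initial knee angle, clamped to the
# knee range of motion (velocity reported as 0 while clamped).  Hip and
# ankle desired angles follow the goniometer traces resampled to the
# control tick; their speeds come from a backward difference smoothed by
# the same 2 Hz first-order low-pass.  Desired accelerations (needed by
# the computed-torque controller) are backward differences of the
# desired speeds smoothed by a 2-tick moving average.

#' Set-point configuration
#'
#' @param alpha Amplitude scaling, deg/s per unit LC (default 30, so
#'   MVC-level intent maps to roughly +/- 60 deg/s, a gentle therapy
#'   speed).
#' @param beta Velocity offset, deg/s.
#' @param knee_rom,hip_rom,ankle_rom Joint ranges of motion, degrees.
#' @param control_period_s Control tick, seconds (0.02 = the 20 ms
#'   frame).
#' @return A `setpoint_config` object.
#' @export
setpoint_config <- function(alpha = 30, beta = 0,
                            knee_rom = c(0, 120), hip_rom = c(-20, 120),
                            ankle_rom = c(-40, 20),
                            control_period_s = 0.02) {
  if (control_period_s <= 0) stop("control_period_s must be positive")
  for (rom in list(knee_rom, hip_rom, ankle_rom)) {
    if (length(rom) != 2L || rom[1] >= rom[2]) stop("each ROM must be [min, max]")
  }
  structure(list(alpha = alpha, beta = beta, knee_rom = knee_rom,
                 hip_rom = hip_rom, ankle_rom = ankle_rom,
                 control_period_s = control_period_s),
            class = "setpoint_config")
}

#' Knee velocity set-point from the intention stream
#'
#' @param lc_filtered Filtered LC sequence.
#' @param cfg A [setpoint_config()].
#' @return Desired knee speed, deg/s, elementwise `alpha * LC + beta`.
#' @export
knee_speed_setpoint <- function(lc_filtered, cfg = setpoint_config()) {
  cfg$alpha * lc_filtered + cfg$beta
}

#' Integrate a knee velocity command with ROM clamping
#'
#' Explicit Euler from `q0`; when the integrated angle hits a ROM limit
#' the position clamps there and the reported velocity for that tick is
#' zero.
#'
#' @param qdot Commanded speeds, deg/s, one per tick.
#' @param q0 Initial angle, degrees.
#' @param cfg A [setpoint_config()].
#' @return List with `q` (degrees) and `qdot` (deg/s, zeroed while
#'   clamped), each of length `length(qdot)`.
#' @export
integrate_knee_setpoint <- function(qdot, q0, cfg = setpoint_config()) {
  n <- length(qdot)
  q <- numeric(n)
  v <- numeric(n)
  cur <- q0
  for (k in seq_len(n)) {
    nxt <- cur + qdot[k] * cfg$control_period_s
    if (nxt <= cfg$knee_rom[1]) {
      nxt <- cfg$knee_rom[1]
      v[k] <- 0
    } else if (nxt >= cfg$knee_rom[2]) {
      nxt <- cfg$knee_rom[2]
      v[k] <- 0
    } else {
      v[k] <- qdot[k]
    }
    q[k] <- nxt
    cur <- nxt
  }
  list(q = q, qdot = v)
}

#' Hip and ankle set-points from goniometer traces
#'
#' Angles are decimated to the control tick (the source sample at each
#' tick instant); speeds are backward differences smoothed by a
#' first-order 2 Hz low-pass at the tick rate.
#'
#' @param gonio A [gonio_recording()].
#' @param cfg A [setpoint_config()].
#' @param filt A [filter_spec()] (smoothing cutoff).
#' @return List of per-joint lists `hip`, `ankle`, each with `q`
#'   (degrees) and `qdot` (deg/s) at tick rate, plus `knee_q` (the
#'   decimated knee goniometer trace, for reference).
#' @export
gonio_setpoints <- function(gonio, cfg = setpoint_config(),
                            filt = filter_spec()) {
  dec <- round(gonio$rate_hz * cfg$control_period_s)
  if (dec < 1L) stop("goniometer rate below the tick rate")
  n_ticks <- ncol(gonio$angles) %/% dec
  if (n_ticks < 1L) stop("goniometer trace shorter than one control tick")
  idx <- seq_len(n_ticks) * dec
  tick_rate <- 1 / cfg$control_period_s
  lp <- butter_design(filt$lp_order, filt$lp_cut_hz, tick_rate, "low")
  one <- function(joint) {
    q <- gonio$angles[joint, idx]
    raw_speed <- c(0, diff(q)) / cfg$control_period_s
    list(q = unname(q), qdot = iir_causal(lp, raw_speed))
  }
  list(hip = one("hip"), ankle = one("ankle"),
       knee_q = unname(gonio$angles["knee", idx]))
}

# Backward-difference acceleration smoothed by a 2-tick moving average.
fd_accel <- function(qdot, dt) {
  a <- c(0, diff(qdot)) / dt
  (a + c(0, a[-length(a)])) / 2
}

#' Assemble the full desired trajectory for the controller
#'
#' Knee velocity from the intention stream, knee position by clamped
#' Euler integration, hip/ankle from the goniometers; accelerations by
#' smoothed finite differences.
#'
#' @param intent An `intention_series` (envelope rate must equal the
#'   tick rate).
#' @param gonio A [gonio_recording()] covering the same time span.
#' @param q_knee_init Initial desired knee angle, degrees.
#' @param cfg A [setpoint_config()].
#' @param filt A [filter_spec()] for the goniometer-speed smoothing.
#' @return A `setpoint_trajectory`: matrices `q_d`, `qdot_d`, `qddot_d`
#'   (`3 x n_ticks`, rows hip/knee/ankle, degrees) and `tick_period_s`.
#' @export
assemble_trajectory <- function(intent, gonio, q_knee_init,
                                cfg = setpoint_config(),
                                filt = filter_spec()) {
  if (abs(intent$envelope_rate_hz - 1 / cfg$control_period_s) > 1e-9) {
    stop("intention envelope rate must match the control tick rate")
  }
  ga <- gonio_setpoints(gonio, cfg, filt)
  n <- min(length(intent$lc_filtered), length(ga$hip$q))
  if (n < 1L) stop("intention and goniometer spans do not overlap")
  if (abs(length(intent$lc_filtered) - length(ga$hip$q)) > 1L) {
    stop("intention and goniometer traces cover different time spans")
  }
  vcmd <- knee_speed_setpoint(intent$lc_filtered[seq_len(n)], cfg)
  knee <- integrate_knee_setpoint(vcmd, q_knee_init, cfg)
  q_d <- rbind(hip = ga$hip$q[seq_len(n)], knee = knee$q,
               ankle = ga$ankle$q[seq_len(n)])
  qdot_d <- rbind(hip = ga$hip$qdot[seq_len(n)], knee = knee$qdot,
                  ankle = ga$ankle$qdot[seq_len(n)])
  qddot_d <- rbind(hip = fd_accel(qdot_d["hip", ], cfg$control_period_s),
                   knee = fd_accel(qdot_d["knee", ], cfg$control_period_s),
                   ankle = fd_accel(qdot_d["ankle", ], cfg$control_period_s))
  structure(list(q_d = q_d, qdot_d = qdot_d, qddot_d = qddot_d,
                 tick_period_s = cfg$control_period_s),
            class = "setpoint_trajectory")
}
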