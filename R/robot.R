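# Planar three-link leg dynamics and computed torque control.
#
# One exoskeleton leg is modelled as a serial planar chain -- thigh,
# shank, foot -- with pure rotational hip, knee and ankle joints in the
# sagittal plane (the polycentric human knee is deliberately simplified
# to a revolute joint).  Dynamics are the closed-form Lagrangian of a 3R
# planar manipulator with per-link point mass at a COM offset plus a
# rotational inertia; the Coriolis matrix comes from the Christoffel
# symbols of the analytic inertia-matrix gradient, so passivity
# (skew-symmetry of Mdot - 2C) holds to machine precision.
#
# Sign conventions (single source of truth, used everywhere):
#   * Chain coordinates theta (rad): theta1 = thigh angle from the
#     horizontal bench axis, theta2 = shank relative to thigh, theta3 =
#     foot relative to shank.  The subject is supine; gravity acts in
#     -y, the bench axis is +x.
#   * Anatomical coordinates q (deg): hip flexion (0 = thigh on the
#     bench), knee flexion (0 = full extension, positive = flexion),
#     ankle dorsiflexion (0 = foot perpendicular to the shank).
#   * Mapping: theta = CHAIN_SIGN * q * pi/180 + CHAIN_OFFSET with
#     CHAIN_SIGN = (1, -1, 1) and CHAIN_OFFSET = (0, 0, pi/2).

CHAIN_SIGN <- c(1, -1, 1)
CHAIN_OFFSET <- c(0, 0, pi / 2)

#' Convert anatomical joint angles (degrees) to chain coordinates (rad)
#' @param q_deg Numeric length-3 vector (hip, knee, ankle), degrees.
#' @return Chain angles, rad.
#' @export
deg_to_chain <- function(q_deg) CHAIN_SIGN * q_deg * pi / 180 + CHAIN_OFFSET

#' Convert chain coordinates (rad) back to anatomical degrees
#' @param theta Numeric length-3 vector, rad.
#' @return Anatomical angles, degrees.
#' @export
chain_to_deg <- function(theta) (theta - CHAIN_OFFSET) / CHAIN_SIGN * 180 / pi

#' Velocity conversion between anatomical (deg/s) and chain (rad/s)
#' @param qdot_deg Length-3 vector, deg/s.
#' @return rad/s in chain coordinates.
#' @export
degv_to_chain <- function(qdot_deg) CHAIN_SIGN * qdot_deg * pi / 180

#' @rdname degv_to_chain
#' @param thetadot Length-3 vector, rad/s.
#' @export
chainv_to_deg <- function(thetadot) thetadot / CHAIN_SIGN * 180 / pi

#' Physical parameters of one exoskeleton leg
#'
#' Defaults sit inside the anthropometric design envelope of an adult
#' lower limb: thigh 0.40 m / 8 kg, shank 0.40 m / 4 kg, foot 0.10 m /
#' 1 kg, COM at mid-link, slender-rod inertias.
#'
#' @param link_lengths Thigh, shank, foot lengths, m.
#' @param link_masses Link masses, kg.
#' @param com_offsets COM distance from the proximal joint, m.
#' @param link_inertias Rotational inertias about each COM, kg m^2;
#'   default slender rod `m l^2 / 12`.
#' @param gravity Gravitational acceleration, m/s^2.
#' @param viscous_friction Per-joint viscous coefficients, N m s/rad.
#' @param joint_rom Anatomical ROM per joint, degrees (mechanical
#'   stops).
#' @return A `robot_params` object.
#' @export
robot_params <- function(link_lengths = c(0.40, 0.40, 0.10),
                         link_masses = c(8, 4, 1),
                         com_offsets = link_lengths / 2,
                         link_inertias = link_masses * link_lengths^2 / 12,
                         gravity = 9.81,
                         viscous_friction = c(0, 0, 0),
                         joint_rom = list(hip = c(-20, 120),
                                          knee = c(0, 120),
                                          ankle = c(-40, 20))) {
  if (any(link_lengths <= 0) || any(link_masses <= 0) || any(link_inertias <= 0)) {
    stop("lengths, masses and inertias must be positive")
  }
  structure(list(l = link_lengths, m = link_masses, r = com_offsets,
                 inertia = link_inertias, g = gravity,
                 friction = viscous_friction, joint_rom = joint_rom),
            class = "robot_params")
}

#' Computed-torque controller gains
#'
#' @param kp Per-joint proportional gains, 1/s^2.
#' @param kv Per-joint derivative gains, 1/s; default critically damped
#'   `2 sqrt(kp)`.
#' @return A `controller_gains` object.
#' @export
controller_gains <- function(kp = c(100, 100, 100), kv = 2 * sqrt(kp)) {
  if (any(kp <= 0) || any(kv <= 0)) stop("gains must be positive")
  structure(list(kp = kp, kv = kv), class = "controller_gains")
}

#' Manipulator matrices of the three-link leg
#'
#' Returns the inertia matrix `M(theta)` (symmetric positive definite),
#' the Coriolis/centrifugal matrix `C(theta, thetadot)` built from
#' Christoffel symbols (so `Mdot - 2C` is skew-symmetric), and the
#' gravity vector `G(theta)` (gradient of the potential energy).
#'
#' @param theta Chain joint angles, rad (length 3).
#' @param thetadot Chain joint velocities, rad/s.
#' @param p A [robot_params()].
#' @return List with `M`, `C`, `G`.
#' @export
dynamics_matrices <- function(theta, thetadot, p) {
  m <- p$m; l <- p$l; r <- p$r; I <- p$inertia
  P1 <- I[1] + m[1] * r[1]^2 + (m[2] + m[3]) * l[1]^2
  P2 <- I[2] + m[2] * r[2]^2 + m[3] * l[2]^2
  P3 <- I[3] + m[3] * r[3]^2
  b12 <- (m[2] * r[2] + m[3] * l[2]) * l[1]
  b13 <- m[3] * r[3] * l[1]
  b23 <- m[3] * r[3] * l[2]
  c2 <- cos(theta[2]); s2 <- sin(theta[2])
  c3 <- cos(theta[3]); s3 <- sin(theta[3])
  c23 <- cos(theta[2] + theta[3]); s23 <- sin(theta[2] + theta[3])
  # Kinetic energy in absolute link rates w = L thetadot (L lower ones):
  # T = 1/2 w' W w.
  L <- matrix(c(1, 1, 1, 0, 1, 1, 0, 0, 1), 3, 3)
  W <- matrix(c(P1,        b12 * c2, b13 * c23,
                b12 * c2,  P2,       b23 * c3,
                b13 * c23, b23 * c3, P3), 3, 3)
  M <- t(L) %*% W %*% L
  dW2 <- matrix(c(0,          -b12 * s2, -b13 * s23,
                  -b12 * s2,  0,         0,
                  -b13 * s23, 0,         0), 3, 3)
  dW3 <- matrix(c(0,          0,         -b13 * s23,
                  0,          0,         -b23 * s3,
                  -b13 * s23, -b23 * s3, 0), 3, 3)
  dM <- array(0, c(3, 3, 3))
  dM[, , 2] <- t(L) %*% dW2 %*% L
  dM[, , 3] <- t(L) %*% dW3 %*% L
  C <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    C[i, j] <- 0.5 * sum((dM[i, j, ] + dM[i, , j] - dM[j, , i]) * thetadot)
  }
  a1 <- theta[1]; a12 <- theta[1] + theta[2]; a123 <- a12 + theta[3]
  g1 <- m[1] * r[1] + (m[2] + m[3]) * l[1]
  g2 <- m[2] * r[2] + m[3] * l[2]
  g3 <- m[3] * r[3]
  G <- p$g * c(g1 * cos(a1) + g2 * cos(a12) + g3 * cos(a123),
               g2 * cos(a12) + g3 * cos(a123),
               g3 * cos(a123))
  list(M = M, C = C, G = G)
}

#' Total mechanical energy (oracle for conservation tests)
#'
#' Kinetic plus gravitational potential energy in chain coordinates,
#' consistent with the same Lagrangian that generates
#' [dynamics_matrices()].
#'
#' @inheritParams dynamics_matrices
#' @return Scalar energy, J.
#' @export
total_energy <- function(theta, thetadot, p) {
  dyn <- dynamics_matrices(theta, thetadot, p)
  m <- p$m; l <- p$l; r <- p$r
  a1 <- theta[1]; a12 <- theta[1] + theta[2]; a123 <- a12 + theta[3]
  U <- p$g * ((m[1] * r[1] + (m[2] + m[3]) * l[1]) * sin(a1) +
              (m[2] * r[2] + m[3] * l[2]) * sin(a12) +
              m[3] * r[3] * sin(a123))
  0.5 * sum(thetadot * (dyn$M %*% thetadot)) + U
}

#' Computed-torque control law
#'
#' `tau = M(theta) (qddot_d + Kv edot + Kp e) + C thetadot + G +
#' F thetadot` with `e = theta_d - theta`; an exact model yields the
#' decoupled linear error dynamics `eddot + Kv edot + Kp e = 0`.  All
#' arguments in chain coordinates (rad).
#'
#' @param theta,thetadot Measured chain state (rad, rad/s).
#' @param theta_d,thetadot_d,thetaddot_d Desired chain trajectory at
#'   this tick.
#' @param gains A [controller_gains()].
#' @param p A [robot_params()].
#' @return Torque vector `tau_u` (N m, length 3).
#' @export
ctc_torque <- function(theta, thetadot, theta_d, thetadot_d, thetaddot_d,
                       gains = controller_gains(), p = robot_params()) {
  if (!all(is.finite(c(theta, thetadot, theta_d, thetadot_d, thetaddot_d)))) {
    stop("non-finite state or set-point")
  }
  dyn <- dynamics_matrices(theta, thetadot, p)
  e <- theta_d - theta
  edot <- thetadot_d - thetadot
  v <- thetaddot_d + gains$kv * edot + gains$kp * e
  as.numeric(dyn$M %*% v + dyn$C %*% thetadot + dyn$G + p$friction * thetadot)
}

# Joint accelerations under a torque (forward dynamics).
forward_dynamics <- function(theta, thetadot, tau, p) {
  dyn <- dynamics_matrices(theta, thetadot, p)
  as.numeric(solve(dyn$M, tau - dyn$C %*% thetadot - dyn$G -
                     p$friction * thetadot))
}

#' Integrate the leg dynamics over one control tick
#'
#' Fixed-step RK4 with `substeps` sub-steps and the torque held constant
#' over the tick (zero-order hold).  Mechanical ROM stops are enforced
#' after every sub-step: at a limit the (anatomical) position clamps and
#' the joint velocity zeroes.
#'
#' @param theta,thetadot Chain state at tick start (rad, rad/s).
#' @param tau Torque command, N m.
#' @param p A [robot_params()].
#' @param dt Tick duration, seconds.
#' @param substeps RK4 sub-steps per tick.
#' @param rom_stops Enforce the mechanical stops (disable for free-swing
#'   energy checks).
#' @return List with `theta`, `thetadot`, `thetaddot` at tick end.
#' @export
step_dynamics <- function(theta, thetadot, tau, p = robot_params(),
                          dt = 0.02, substeps = 10, rom_stops = TRUE) {
  if (dt <= 0) stop("dt must be positive")
  h <- dt / substeps
  for (s in seq_len(substeps)) {
    k1q <- thetadot
    k1v <- forward_dynamics(theta, thetadot, tau, p)
    k2q <- thetadot + h / 2 * k1v
    k2v <- forward_dynamics(theta + h / 2 * k1q, thetadot + h / 2 * k1v, tau, p)
    k3q <- thetadot + h / 2 * k2v
    k3v <- forward_dynamics(theta + h / 2 * k2q, thetadot + h / 2 * k2v, tau, p)
    k4q <- thetadot + h * k3v
    k4v <- forward_dynamics(theta + h * k3q, thetadot + h * k3v, tau, p)
    theta <- theta + h / 6 * (k1q + 2 * k2q + 2 * k3q + k4q)
    thetadot <- thetadot + h / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
    if (rom_stops) {
      q_deg <- chain_to_deg(theta)
      lims <- rbind(p$joint_rom$hip, p$joint_rom$knee, p$joint_rom$ankle)
      low <- q_deg < lims[, 1]
      high <- q_deg > lims[, 2]
      if (any(low | high)) {
        q_deg[low] <- lims[low, 1]
        q_deg[high] <- lims[high, 2]
        thetadot[low | high] <- 0
        theta <- deg_to_chain(q_deg)
      }
    }
  }
  list(theta = theta, thetadot = thetadot,
       thetaddot = forward_dynamics(theta, thetadot, tau, p))
}
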