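# Three-link leg dynamics and computed torque control.

p_default <- robot_params()

test_that("the inertia matrix is symmetric positive definite everywhere", {
  set.seed(13)
  for (i in 1:100) {
    q <- runif(3, -pi, pi)
    M <- dynamics_matrices(q, c(0, 0, 0), p_default)$M
    expect_lt(max(abs(M - t(M))), 1e-12)
    expect_gt(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("Mdot - 2C is skew-symmetric (passivity)", {
  set.seed(14)
  worst <- 0
  for (i in 1:50) {
    q <- runif(3, -pi, pi)
    qd <- runif(3, -3, 3)
    x <- runif(3, -1, 1)
    h <- 1e-6  # finite-difference Mdot oracle along the flow
    Mp <- dynamics_matrices(q + h * qd, qd, p_default)$M
    Mm <- dynamics_matrices(q - h * qd, qd, p_default)$M
    Mdot <- (Mp - Mm) / (2 * h)
    C <- dynamics_matrices(q, qd, p_default)$C
    worst <- max(worst, abs(sum(x * ((Mdot - 2 * C) %*% x))))
  }
  expect_lt(worst, 1e-8)
})

test_that("the gravity vector is the potential-energy gradient", {
  zero_g <- robot_params(gravity = 0)
  expect_equal(dynamics_matrices(c(0.3, -0.5, 1), c(0, 0, 0), zero_g)$G,
               c(0, 0, 0))
  set.seed(15)
  for (i in 1:10) {
    q <- runif(3, -pi, pi)
    G <- dynamics_matrices(q, c(0, 0, 0), p_default)$G
    h <- 1e-6
    num <- vapply(1:3, function(j) {
      e <- replace(c(0, 0, 0), j, h)
      (total_energy(q + e, c(0, 0, 0), p_default) -
         total_energy(q - e, c(0, 0, 0), p_default)) / (2 * h)
    }, numeric(1))
    expect_equal(G, num, tolerance = 1e-6)
  }
})

test_that("the control law reduces to its algebraic special cases", {
  gains <- controller_gains()
  th <- deg_to_chain(c(20, 60, -10))
  # static, zero error, zero feedforward: pure gravity compensation
  tau <- ctc_torque(th, c(0, 0, 0), th, c(0, 0, 0), c(0, 0, 0),
                    gains, p_default)
  expect_equal(tau, dynamics_matrices(th, c(0, 0, 0), p_default)$G,
               tolerance = 1e-12)
  # zero gravity, zero velocity, position error only: tau = M Kp e
  zg <- robot_params(gravity = 0)
  e <- c(0.1, 0, 0)
  tau2 <- ctc_torque(th, c(0, 0, 0), th + e, c(0, 0, 0), c(0, 0, 0),
                     gains, zg)
  M <- dynamics_matrices(th, c(0, 0, 0), zg)$M
  expect_equal(tau2, as.numeric(M %*% (gains$kp * e)), tolerance = 1e-12)
  expect_error(ctc_torque(c(NA, 0, 0), c(0, 0, 0), th, c(0, 0, 0),
                          c(0, 0, 0), gains, p_default), "finite")
})

test_that("an unforced, gravity-free leg at rest stays at rest", {
  zg <- robot_params(gravity = 0)
  th <- deg_to_chain(c(30, 45, 5))
  st <- step_dynamics(th, c(0, 0, 0), c(0, 0, 0), zg, dt = 0.02)
  expect_equal(st$theta, th, tolerance = 1e-14)
  expect_equal(st$thetadot, c(0, 0, 0), tolerance = 1e-14)
})

test_that("free swing conserves mechanical energy", {
  th <- deg_to_chain(c(30, 40, 5))
  thd <- c(0, 0, 0)
  e0 <- total_energy(th, thd, p_default)
  for (i in 1:1000) {  # 5 s at dt = 5 ms, RK4 sub-step 0.5 ms
    st <- step_dynamics(th, thd, c(0, 0, 0), p_default, dt = 0.005,
                        rom_stops = FALSE)
    th <- st$theta
    thd <- st$thetadot
  }
  expect_lt(abs(total_energy(th, thd, p_default) - e0) / abs(e0), 1e-6)
})

test_that("inverse dynamics invert forward dynamics at random states", {
  set.seed(20)
  for (i in 1:20) {
    q <- runif(3, -pi, pi)
    qd <- runif(3, -2, 2)
    a <- runif(3, -3, 3)
    dyn <- dynamics_matrices(q, qd, p_default)
    tau <- as.numeric(dyn$M %*% a + dyn$C %*% qd + dyn$G)
    recovered <- as.numeric(solve(dyn$M, tau - dyn$C %*% qd - dyn$G))
    expect_equal(recovered, a, tolerance = 1e-10)
  }
})

test_that("a compensated constant-acceleration command integrates to the closed form", {
  zg <- robot_params(gravity = 0)
  a <- c(0.4, 0, 0)
  th0 <- deg_to_chain(c(10, 40, 0))
  th <- th0
  thd <- c(0, 0, 0)
  for (k in 1:4000) {  # 1 s; torque recomputed each 0.25 ms tick (ZOH)
    dyn <- dynamics_matrices(th, thd, zg)
    tau <- as.numeric(dyn$M %*% a + dyn$C %*% thd)
    st <- step_dynamics(th, thd, tau, zg, dt = 2.5e-4, substeps = 1,
                        rom_stops = FALSE)
    th <- st$theta
    thd <- st$thetadot
  }
  # residual is the zero-order hold on the velocity-product torque term
  expect_equal(th, th0 + 0.5 * a * 1^2, tolerance = 1e-3)
  expect_equal(thd, a * 1, tolerance = 1e-3)
})

test_that("mechanical stops clamp position and zero velocity", {
  th <- deg_to_chain(c(-15, 10, 0))
  thd <- c(0, 0, 0)
  for (i in 1:100) {  # gravity plus a hip torque driving into the stop
    st <- step_dynamics(th, thd, c(-50, 0, 0), p_default, dt = 0.02)
    th <- st$theta
    thd <- st$thetadot
    q <- chain_to_deg(th)
    expect_gte(q[1], p_default$joint_rom$hip[1] - 1e-9)
    expect_gte(q[2], p_default$joint_rom$knee[1] - 1e-9)
  }
  expect_equal(chain_to_deg(th)[1], p_default$joint_rom$hip[1],
               tolerance = 1e-9)
  expect_equal(thd[1], 0)
})

test_that("exact-model CTC follows the analytic critically damped error decay", {
  gains <- controller_gains()  # kp = 100, kv = 20 -> lambda = 10
  qd <- deg_to_chain(c(20, 50, 0))
  e0 <- c(0.1, -0.08, 0.05)
  th <- qd - e0
  thd <- c(0, 0, 0)
  dt <- 0.002
  worst <- 0
  for (k in 1:1000) {
    tau <- ctc_torque(th, thd, qd, c(0, 0, 0), c(0, 0, 0), gains, p_default)
    st <- step_dynamics(th, thd, tau, p_default, dt = dt, substeps = 4)
    th <- st$theta
    thd <- st$thetadot
    t <- k * dt
    e_analytic <- e0 * (1 + 10 * t) * exp(-10 * t)
    worst <- max(worst, max(abs((qd - th) - e_analytic)))
  }
  expect_lt(worst, 1e-3)  # sampled-data ZOH residual only
  expect_lt(max(abs(qd - th)), 1e-6)
})

test_that("tracking a smooth sinusoid converges below 1e-3 rad within 2 s", {
  gains <- controller_gains()
  base <- deg_to_chain(c(10, 30, 0))
  w <- pi / 4
  A <- 0.2
  th <- base + 0.1
  thd <- c(0, 0, 0)
  dt <- 0.002
  for (k in 1:1000) {
    t <- k * dt
    ph <- c(0, 1, 2)
    tau <- ctc_torque(th, thd, base + A * sin(w * t + ph),
                      A * w * cos(w * t + ph), -A * w^2 * sin(w * t + ph),
                      gains, p_default)
    st <- step_dynamics(th, thd, tau, p_default, dt = dt, substeps = 4)
    th <- st$theta
    thd <- st$thetadot
  }
  expect_lt(max(abs(base + A * sin(w * 2 + c(0, 1, 2)) - th)), 1e-3)
})

test_that("anatomical and chain coordinates convert consistently", {
  q <- c(35, 80, -10)
  expect_equal(chain_to_deg(deg_to_chain(q)), q, tolerance = 1e-12)
  v <- c(10, -20, 5)
  expect_equal(chainv_to_deg(degv_to_chain(v)), v, tolerance = 1e-12)
  # full knee extension: shank collinear with thigh
  th <- deg_to_chain(c(0, 0, 0))
  expect_equal(th[2], 0)
})
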