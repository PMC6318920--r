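# Synthetic sEMG / goniometer generator.
#
# Emulates the statistical structure the intention detector assumes:
# amplitude-modulated band-limited (20-450 Hz) Gaussian sEMG on four
# channels whose agonist group dominates for the intended direction, plus
# goniometer kinematics consistent with a 12-exercise knee-rehabilitation
# protocol (MVC and submaximal isometric holds, 1RM tests, concentric
# dynamic flexion/extension).  No motor-unit, crosstalk or fatigue
# modelling is attempted: amplitude modulation is the contract.

#' Exercise descriptor
#'
#' One entry of the 12-exercise protocol: contraction type, movement
#' direction, intensity as a fraction of MVC/1RM, and the joint
#' configuration it is performed in.
#'
#' @param exercise_id Integer 1-12.
#' @param contraction_type One of `"MVC"`, `"isometric"`, `"dynamic"`,
#'   `"one_rm_test"`.
#' @param direction `"flexion"` or `"extension"`.
#' @param intensity_fraction Effort in (0, 1]; forced to 1 for MVC and
#'   1RM tests.
#' @param knee_start_angle Initial knee flexion, degrees (0 = full
#'   extension).
#' @param hip_config_angle Hip flexion of the posture, degrees (0 = hip
#'   neutral; 90 = hip flexed).  The bench-configuration angle quoted in
#'   protocol tables is `180 - hip_config_angle` (see [hip_to_br()]).
#' @param duration Trial length, seconds (default 10 s for isometric
#'   holds, 6 s for dynamic movements).
#' @return An `exercise_spec` object.
#' @export
exercise_spec <- function(exercise_id, contraction_type, direction,
                          intensity_fraction = 1,
                          knee_start_angle = 90, hip_config_angle = 0,
                          duration = NULL) {
  contraction_type <- match.arg(contraction_type,
                                c("MVC", "isometric", "dynamic", "one_rm_test"))
  direction <- match.arg(direction, c("flexion", "extension"))
  if (contraction_type %in% c("MVC", "one_rm_test")) intensity_fraction <- 1
  if (intensity_fraction <= 0 || intensity_fraction > 1) {
    stop("intensity_fraction must be in (0, 1]")
  }
  if (is.null(duration)) {
    duration <- if (contraction_type %in% c("dynamic", "one_rm_test")) 6 else 10
  }
  if (duration <= 0) stop("duration must be positive")
  structure(list(exercise_id = as.integer(exercise_id),
                 contraction_type = contraction_type,
                 direction = direction,
                 intensity_fraction = intensity_fraction,
                 knee_start_angle = knee_start_angle,
                 hip_config_angle = hip_config_angle,
                 duration = duration),
            class = "exercise_spec")
}

#' Bench-configuration angle of a posture
#'
#' Protocol tables quote the posture as the thigh-trunk angle `B_r`:
#' 180 degrees for hip neutral, 90 degrees for hip flexed 90 degrees.
#'
#' @param hip_config_angle Hip flexion, degrees.
#' @return `B_r` in degrees.
#' @export
hip_to_br <- function(hip_config_angle) 180 - hip_config_angle

#' Agonist muscles for a movement direction
#'
#' Knee extension is driven by RF and VM, flexion by BF and ST.
#'
#' @param direction `"flexion"` or `"extension"`.
#' @return Character vector of two channel names.
#' @export
agonists_for <- function(direction) {
  switch(match.arg(direction, c("flexion", "extension")),
         extension = c("RF", "VM"),
         flexion   = c("BF", "ST"))
}

#' Per-muscle activation profile
#'
#' Activation envelopes are fractions of each muscle's own MVC amplitude:
#' the agonist pair of the intended direction ramps to `agonist_level`
#' with a half-cosine of `ramp_time`, holds, and ramps down; the
#' antagonist pair follows the same time course at `antagonist_level`.
#'
#' @param agonist_level Plateau level of the agonists, in [0, 1].
#' @param antagonist_level Plateau level of the antagonists; must be
#'   below `agonist_level` for a directional trial.
#' @param ramp_time Half-cosine ramp duration, seconds.
#' @param onset Rest period before the ramp starts, seconds.
#' @return An `activation_profile` object.
#' @export
activation_profile <- function(agonist_level, antagonist_level = 0.05,
                               ramp_time = 0.5, onset = 0.5) {
  if (agonist_level < 0 || agonist_level > 1 ||
      antagonist_level < 0 || antagonist_level > 1) {
    stop("activation levels must lie in [0, 1]")
  }
  if (agonist_level > 0 && antagonist_level >= agonist_level) {
    stop("antagonist_level must be below agonist_level for a directional trial")
  }
  structure(list(agonist_level = agonist_level,
                 antagonist_level = antagonist_level,
                 ramp_time = ramp_time, onset = onset),
            class = "activation_profile")
}

# Unit-height trapezoid with half-cosine shoulders: rest [0, onset],
# ramp up, plateau, ramp down ending `onset` before the trial end.
ramp_envelope <- function(t, duration, onset, ramp_time) {
  t_up0 <- onset
  t_up1 <- onset + ramp_time
  t_dn1 <- duration - onset
  t_dn0 <- t_dn1 - ramp_time
  env <- numeric(length(t))
  up <- t >= t_up0 & t < t_up1
  env[up] <- 0.5 * (1 - cos(pi * (t[up] - t_up0) / ramp_time))
  env[t >= t_up1 & t <= t_dn0] <- 1
  dn <- t > t_dn0 & t <= t_dn1
  env[dn] <- 0.5 * (1 + cos(pi * (t[dn] - t_dn0) / ramp_time))
  env
}

#' Plateau ("hold") window of a generated trial
#'
#' @param spec An [exercise_spec()].
#' @param profile An [activation_profile()].
#' @return `c(start, end)` in seconds of the constant-activation phase.
#' @export
hold_window <- function(spec, profile = activation_profile(spec$intensity_fraction)) {
  c(profile$onset + profile$ramp_time,
    spec$duration - profile$onset - profile$ramp_time)
}

# Band-limited (20-450 Hz) unit-variance Gaussian process at rate_hz,
# from white noise through a 4th-order Butterworth band-pass, then
# standardized so the closed-form E|X| = sqrt(2/pi) applies per
# realization.
bandlimited_noise <- function(n, rate_hz) {
  coef <- butter_design(4, c(20, 450), rate_hz, type = "pass")
  x <- iir_causal(coef, stats::rnorm(n))
  x / stats::sd(x)
}

#' Generate a synthetic 4-channel sEMG recording
#'
#' Channel c is `amplitude_mvc[c] * envelope_c(t) * n_c(t) +
#' noise_floor * m_c(t) + dc_offset[c]` with `n`, `m` independent
#' zero-mean unit-variance band-limited (20-450 Hz) noise processes;
#' bit-identical for identical arguments and seed.
#'
#' @param spec An [exercise_spec()].
#' @param profile An [activation_profile()]; defaults to the spec's
#'   intensity with a 0.05 MVC antagonist floor.
#' @param amplitude_mvc Named per-muscle MVC-level amplitude, signal
#'   units (default 1 for all four channels).
#' @param noise_floor Baseline noise amplitude, signal units.
#' @param dc_offset Per-channel DC offset; defaults to 1% of
#'   `amplitude_mvc` so the DC-removal stage is exercised nontrivially.
#' @param rate_hz Sampling rate, Hz.
#' @param seed Integer RNG seed.
#' @return An [emg_recording()].
#' @export
generate_emg <- function(spec, profile = NULL,
                         amplitude_mvc = c(RF = 1, VM = 1, BF = 1, ST = 1),
                         noise_floor = 0.01, dc_offset = NULL,
                         rate_hz = 1000, seed = 1) {
  if (is.null(profile)) profile <- activation_profile(spec$intensity_fraction)
  if (any(amplitude_mvc <= 0)) stop("amplitude_mvc must be positive per channel")
  if (noise_floor < 0) stop("noise_floor must be non-negative")
  if (spec$duration <= 0 || rate_hz <= 0) stop("duration and rate must be positive")
  if (is.null(dc_offset)) dc_offset <- 0.01 * amplitude_mvc
  dc_offset <- rep_len(dc_offset, 4L)
  n <- round(spec$duration * rate_hz)
  t <- (seq_len(n) - 1L) / rate_hz
  ago <- agonists_for(spec$direction)
  base_env <- ramp_envelope(t, spec$duration, profile$onset, profile$ramp_time)
  set.seed(seed)
  samples <- matrix(0, 4L, n, dimnames = list(EMG_CHANNELS, NULL))
  for (k in seq_along(EMG_CHANNELS)) {
    ch <- EMG_CHANNELS[k]
    level <- if (ch %in% ago) profile$agonist_level else profile$antagonist_level
    env <- level * base_env
    carrier <- if (any(env > 0)) bandlimited_noise(n, rate_hz) else numeric(n)
    floor_n <- if (noise_floor > 0) bandlimited_noise(n, rate_hz) else numeric(n)
    samples[k, ] <- amplitude_mvc[[ch]] * env * carrier +
      noise_floor * floor_n + dc_offset[k]
  }
  emg_recording(samples, rate_hz = rate_hz)
}

#' Generate synthetic goniometer traces for a trial
#'
#' Hip and ankle hold their configuration angles with a slow (< 0.5 Hz)
#' sinusoidal drift of 0.5 degree amplitude; the knee holds
#' `knee_start_angle` for isometric trials and performs one smooth
#' monotone half-cosine excursion (toward 0 degrees for extension, 90
#' degrees for flexion) for dynamic trials.  Motion onset lags the sEMG
#' envelope onset by the electromechanical delay `emd_s`.
#'
#' @param spec An [exercise_spec()].
#' @param seed Integer RNG seed (drift phases).
#' @param rate_hz Sampling rate, Hz.
#' @param emd_s Electromechanical delay, seconds.
#' @param drift_amp Drift amplitude, degrees.
#' @param profile Activation profile (for onset/ramp timing).
#' @return A [gonio_recording()].
#' @export
generate_goniometer <- function(spec, seed = 1, rate_hz = 1000,
                                emd_s = 0.05, drift_amp = 0.5,
                                profile = NULL) {
  if (is.null(profile)) profile <- activation_profile(spec$intensity_fraction)
  if (spec$duration <= 0) stop("duration must be positive")
  n <- round(spec$duration * rate_hz)
  t <- (seq_len(n) - 1L) / rate_hz
  set.seed(seed + 1L)
  phases <- stats::runif(3, 0, 2 * pi)
  freqs <- stats::runif(3, 0.1, 0.4)
  drift <- function(i) drift_amp * sin(2 * pi * freqs[i] * t + phases[i])
  hip <- spec$hip_config_angle + drift(1)
  ankle <- 0 + drift(3)
  if (spec$contraction_type %in% c("MVC", "isometric")) {
    knee <- spec$knee_start_angle + drift(2)
  } else if (spec$contraction_type %in% c("dynamic", "one_rm_test")) {
    target <- if (spec$direction == "extension") 0 else 90
    m0 <- profile$onset + emd_s
    m1 <- spec$duration - profile$onset + emd_s
    m1 <- min(m1, spec$duration)
    knee <- numeric(n)
    pre <- t < m0
    mov <- t >= m0 & t <= m1
    post <- t > m1
    knee[pre] <- spec$knee_start_angle
    frac <- 0.5 * (1 - cos(pi * (t[mov] - m0) / (m1 - m0)))
    knee[mov] <- spec$knee_start_angle + frac * (target - spec$knee_start_angle)
    knee[post] <- target
  } else {
    stop("unknown contraction_type: ", spec$contraction_type)
  }
  gonio_recording(rbind(hip = hip, knee = knee, ankle = ankle),
                  rate_hz = rate_hz)
}

#' Generate one complete synthetic trial
#'
#' @inheritParams generate_emg
#' @inheritParams generate_goniometer
#' @return A `mec_trial` list with `emg`, `gonio`, `spec`, `seed`.
#' @export
generate_trial <- function(spec, profile = NULL,
                           amplitude_mvc = c(RF = 1, VM = 1, BF = 1, ST = 1),
                           noise_floor = 0.01, rate_hz = 1000,
                           emd_s = 0.05, seed = 1) {
  if (is.null(profile)) profile <- activation_profile(spec$intensity_fraction)
  emg <- generate_emg(spec, profile, amplitude_mvc = amplitude_mvc,
                      noise_floor = noise_floor, rate_hz = rate_hz, seed = seed)
  gonio <- generate_goniometer(spec, seed = seed, rate_hz = rate_hz,
                               emd_s = emd_s, profile = profile)
  structure(list(emg = emg, gonio = gonio, spec = spec, seed = seed,
                 profile = profile),
            class = "mec_trial")
}

#' The 12-exercise knee rehabilitation protocol
#'
#' Builds the full protocol: MVC, 75% and 50% isometric holds for flexion
#' (knee flexed 90 degrees, hip neutral) and extension (knee flexed 90
#' degrees, hip flexed 90 degrees), then 1RM tests and concentric dynamic
#' contractions at 75% and 50% of 1RM for each direction.  Trials 1 and 4
#' are the flexion and extension MVC trials consumed by calibration.
#'
#' @param subject_seed Integer seed; per-trial seeds are derived from it.
#' @param ... Passed on to [generate_trial()] (e.g. `noise_floor`).
#' @return List of 12 `mec_trial` objects.
#' @export
generate_protocol <- function(subject_seed = 1, ...) {
  rows <- list(
    list(1L, "MVC",        "flexion",   1.00, 0),
    list(2L, "isometric",  "flexion",   0.75, 0),
    list(3L, "isometric",  "flexion",   0.50, 0),
    list(4L, "MVC",        "extension", 1.00, 90),
    list(5L, "isometric",  "extension", 0.75, 90),
    list(6L, "isometric",  "extension", 0.50, 90),
    list(7L, "one_rm_test", "flexion",   1.00, 0),
    list(8L, "dynamic",    "flexion",   0.75, 0),
    list(9L, "dynamic",    "flexion",   0.50, 0),
    list(10L, "one_rm_test", "extension", 1.00, 90),
    list(11L, "dynamic",   "extension", 0.75, 90),
    list(12L, "dynamic",   "extension", 0.50, 90)
  )
  lapply(rows, function(r) {
    spec <- exercise_spec(r[[1]], r[[2]], r[[3]], intensity_fraction = r[[4]],
                          knee_start_angle = 90, hip_config_angle = r[[5]])
    trial_seed <- (subject_seed * 131L + r[[1]]) %% .Machine$integer.max
    generate_trial(spec, seed = trial_seed, ...)
  })
}

#' @export
print.mec_trial <- function(x, ...) {
  cat(sprintf("<mec_trial> exercise %d: %s %s at %.0f%% (%.1f s, seed %d)\n",
              x$spec$exercise_id, x$spec$contraction_type, x$spec$direction,
              100 * x$spec$intensity_fraction, x$spec$duration, x$seed))
  invisible(x)
}
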