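---
title: "Myoelectric knee motion-intention detection and closed-loop control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Myoelectric knee motion-intention detection and closed-loop control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneemec)
```

## The problem

Active knee rehabilitation — after anterior cruciate ligament (ACL)
reconstruction in particular — benefits from robotic exercise in which
the device moves only when, and in the direction that, the patient
intends. Surface electromyography (sEMG) over the knee extensors
(rectus femoris, RF; vastus medialis, VM) and flexors (biceps femoris,
BF; semitendinosus, ST) carries that intent a few tens of milliseconds
before any motion. `kneemec` implements a deliberately simple,
"grey-box" proportional myoelectric controller: it needs no torque
sensors, no machine-learning training set, and is calibrated by nothing
more than two maximum-voluntary-contraction (MVC) tests.

## The detection pipeline

Each 4-channel sEMG buffer, sampled at 1 kHz, passes through:

1. **Band-pass filtering.** A 4th-order Butterworth with the 10–500 Hz
   pass-band that covers the sEMG spectrum. No notch filter is used
   anywhere — SENIAM/ISEK recommendations exclude powerline notching
   because it removes signal along with interference.
2. **DC-offset removal.** The channel mean is subtracted. The batch
   path uses the buffer mean; the real-time path cannot see a future
   mean, so it subtracts a per-channel reference frozen during the MVC
   calibration.
3. **Full-wave rectification.** Elementwise absolute value, so that
   amplitude statistics (MAV, RMS) are meaningful.

**Calibration** (once per session) conditions the two MVC trials —
extension MVC for RF and VM, flexion MVC for BF and ST — computes the
mean absolute value (MAV) over adjacent, non-overlapping 500 ms
windows, and stores the maximum per muscle. These four numbers are the
controller's entire calibration state.

**Detection** (every 20 ms) computes the RMS envelope of each
conditioned channel over one 20-sample window, divides by the stored
normalization values, and combines:

$$LC = RF_{RMS} + VM_{RMS} - BF_{RMS} - ST_{RMS}$$

Positive $LC$ means extension intent (extensors dominate), negative
means flexion; magnitude grows with effort relative to MVC. A causal
first-order Butterworth low-pass at 2 Hz, running at the 50 Hz envelope
rate, removes envelope peaks. The per-muscle gains $(+1, +1, -1, -1)$
and zero offsets are heuristic by design: identifying them against a
torque sensor would turn the detector into a torque estimator, which is
deliberately out of scope.

Two consequences are worth knowing:

* **$|LC|$ can exceed 2.** For a Gaussian-like signal the windowed RMS
  exceeds the windowed MAV (power-mean inequality; the ratio is
  $\sqrt{\pi/2} \approx 1.25$ for a Gaussian), so RMS envelopes
  normalized by MAV-derived maxima can exceed 1 at MVC effort. We do
  not clip; a `clip = TRUE` option exists for users who want the
  nominal $[-2, 2]$ range.
* **"Sliding adjacent" windows are implemented as adjacent.** One
  20-sample window per 20 ms frame gives a 50 Hz envelope stream that
  is exactly one value per real-time tick; an overlapping-window
  reading would break that one-to-one correspondence.

## From intention to motion

The knee is commanded in **velocity**:
$\dot q_d^{knee} = \alpha\, LC + \beta$, with $\alpha$ (deg/s per unit
LC) and $\beta$ (deg/s) chosen by the physiotherapist per exercise.
Defaults are $\alpha = 30$, $\beta = 0$: MVC-level intent maps to
roughly $\pm 60$ deg/s, a gentle therapy speed. The desired knee
*position* is the explicit-Euler integral of that speed, clamped to the
knee range of motion (ROM, default 0–120° flexion) with the commanded
speed reported as zero while clamped. Hip and ankle desired angles
follow the goniometer traces, resampled to the 0.02 s control tick;
their speeds are backward differences smoothed by the same 2 Hz
first-order low-pass (raw differentiation of a drifting goniometer
would amplify noise), and desired accelerations are backward
differences of the speeds smoothed by a 2-tick moving average.

On the sign convention: the knee angle is measured flexion-positive
(0° = full extension), and the velocity command is applied literally in
that coordinate, so positive $LC$ with positive $\alpha$ drives the
commanded angle upward. Whether "upward" is anatomical flexion or
extension of the mounted leg is exactly the orientation choice the
scaling factor $\alpha$ (including its sign) gives the physiotherapist;
the detector's own sign convention (positive = extension intent) is
unaffected.

## The simulated robot and controller

One exoskeleton leg is a planar three-link serial chain — thigh, shank,
foot — with revolute hip, knee and ankle joints in the sagittal plane
(the polycentric human knee is simplified to a pure rotation, as the
mechanical design itself does). The subject is supine, so gravity acts
vertically in the sagittal plane. Dynamics are the closed-form
Lagrangian of a 3R planar manipulator:
$M(q)\ddot q + C(q, \dot q)\dot q + G(q) = \tau$, with $C$ built from
the Christoffel symbols of the analytic $\partial M/\partial q$ — which
makes $\dot M - 2C$ skew-symmetric to machine precision, a property the
test-suite verifies against a finite-difference oracle.

Default parameters sit inside the anthropometric envelope of the
device: thigh 0.40 m / 8 kg, shank 0.40 m / 4 kg, foot 0.10 m / 1 kg,
COM at mid-link, slender-rod inertias, all configurable.

The **computed torque controller**
$$\tau_u = M(q)\left(\ddot q_d + K_v \dot e + K_p e\right) + C(q,\dot q)\dot q + G(q), \qquad e = q_d - q,$$
feedback-linearizes the chain: with an exact model the error obeys
$\ddot e + K_v \dot e + K_p e = 0$ per joint. Default gains
$K_p = 100\,\mathrm{s^{-2}}$, $K_v = 20\,\mathrm{s^{-1}}$ are
critically damped ($K_v = 2\sqrt{K_p}$, time constant 0.1 s).

Integration is fixed-step RK4 with 10 sub-steps per 0.02 s tick and the
torque held over the tick (zero-order hold) — deterministic and cheap.
ROM stops are enforced after every sub-step: position clamps at the
mechanical limit and the joint velocity zeroes.

## The closed loop

Each tick, the loop (a) consumes one 4×20 sEMG frame plus the
goniometer sample at the tick instant, (b) updates the causal intention
pipeline by exactly one envelope value, (c) converts to set-points, (d)
computes the CTC torque, (e) integrates the leg, and (f) acknowledges.
Frames travel either in-process or over a TCP loopback socket using a
newline-delimited text protocol with `%.17g` number formatting
(lossless for IEEE doubles). The in-process transport round-trips every
frame through the same serializer, so the two transports produce
bit-identical logs by construction. Real time is simulated — the loop
runs on logical ticks as fast as possible; correctness, not latency, is
the testable contract on desk hardware.

Streaming/batch equivalence is a load-bearing design property: the
filter engine carries explicit direct-form-I state across 20 ms chunks
and evaluates the identical recurrence as the one-shot path, so the
real-time intention stream equals the offline causal analysis to
machine precision (the suite asserts < 1e-9).

## The synthetic-data generator

No recordings ship with the package, so a generator produces signals
with the statistical structure the algorithm assumes. Each sEMG
channel is amplitude-modulated, band-limited Gaussian noise — the
standard surrogate for interference-pattern sEMG:
$x_c(t) = A_c\, e_c(t)\, n_c(t) + \nu\, m_c(t) + d_c$, where $e_c$ is a
trapezoidal activation envelope with half-cosine ramps (0.5 s), $n_c$
and $m_c$ are independent unit-variance 20–450 Hz processes (white
noise through a 4th-order band-pass, standardized per realization, so
the rectified mean has the closed form $\sqrt{2/\pi}$ used as a test
oracle), $\nu$ a 1% noise floor and $d_c$ a 1% DC offset that keeps the
DC-removal stage honest. Agonists of the intended direction ramp to
the trial's intensity fraction; antagonists to 0.05 MVC.

Goniometer traces hold the posture angles with a slow (< 0.5 Hz)
sinusoidal drift of 0.5° (so differentiation smoothing is exercised);
dynamic trials move the knee through one smooth monotone half-cosine
excursion whose onset lags the sEMG envelope by a configurable 50 ms
electromechanical delay. The 12-exercise protocol (MVC, 75%, 50%
isometric holds and 1RM-dosed dynamic contractions, each direction in
its prescribed posture) is generated with per-trial seeds derived from
a subject seed. Trial durations are not prescribed by any protocol
table; the package defaults to 10 s isometric holds and 6 s dynamic
movements.

What the generator does **not** emulate: motor-unit firing statistics,
inter-channel crosstalk, fatigue-induced spectral compression,
electrode-lift artifacts, or inter-subject variability in
muscle-to-channel gain. Passing tests therefore demonstrate that the
pipeline is correct under its own assumptions (amplitude-coded
activation with agonist dominance), not that it is robust to every
failure mode of real recordings.

## Numerical choices

* **Nyquist clamp.** The nominal 500 Hz upper cutoff equals Nyquist at
  1 kHz and cannot be realized; the design clamps it to 0.99 × Nyquist
  (495 Hz) and warns. This preserves the pass-band intent without an
  unstable design.
* **Filter initialization.** Causal filters initialize at the steady
  state for the first sample, suppressing startup transients on short
  trials; a constant input passes a low-pass exactly and dies through
  the band-pass immediately.
* **Trailing windows.** MAV/RMS windows that are not completely filled
  are discarded (a short window would bias the statistic upward under
  nonstationarity).
* **Calibration quality.** The maximum MAV must exceed 3× the quietest
  window of its own trial, a cheap dead-electrode detector
  (`check_quality = FALSE` disables it).
* **Orientation reduction.** A trial's orientation is the sign of the
  filtered LC value of maximum magnitude, with a dead-band
  $|LC| < 0.05$ reported as "none".
* **Verification step sizes.** The energy-conservation and
  error-dynamics checks integrate at finer steps (0.5 ms / 2 ms ticks)
  than the production loop, because they verify the conservative
  structure of the model and the analytic error law, not the loop
  discretization; at the default 2 ms sub-step the 5 s free-swing
  energy drift is ~1e-4 relative, a pure RK4 discretization artifact.
* **Problem sizes.** The shipped verification suite uses a 100-trial
  intention battery, single 6 s closed-loop runs (300 ticks), and
  40 replicate triplets for the intensity-ordering property — sizes
  chosen so the whole suite runs in well under a minute on one core
  while keeping every statistical margin wide.

## Known limitations

* The LC coefficients are fixed signs, not subject-calibrated gains;
  the controller detects direction and relative intensity, it does not
  estimate torque.
* MVC-based normalization presumes a usable MVC, which frail or
  post-surgical patients may not produce; submaximal normalization
  schemes are out of scope.
* The exact-model CTC is the best case; model mismatch on a physical
  device would degrade tracking below the figures the simulation
  reports.
* Intensity tracking is reported as a surrogate ratio (peak
  $|LC|/2$); no claim is made about clinical intensity-detection
  rates.
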