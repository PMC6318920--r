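# Shared fixtures, built once per test run.
#
# The Nyquist clamp of the default 10-500 Hz band at 1 kHz warns by
# design; `quiet()` keeps that expected warning out of unrelated tests.

quiet <- function(expr) suppressWarnings(expr)

# Flexion (exercise 1) and extension (exercise 4) MVC trials and the
# calibration derived from them -- the state every downstream test needs.
mvc_flexion <- generate_trial(
  exercise_spec(1, "MVC", "flexion", hip_config_angle = 0), seed = 101)
mvc_extension <- generate_trial(
  exercise_spec(4, "MVC", "extension", hip_config_angle = 90), seed = 104)
test_calib <- quiet(compute_normalization(mvc_flexion$emg, mvc_extension$emg))

# A short dynamic extension trial at half effort, reused across modules.
ext_trial <- generate_trial(
  exercise_spec(11, "dynamic", "extension", 0.5, hip_config_angle = 90),
  profile = activation_profile(0.5), seed = 7)

# Envelope index range of the constant-activation hold phase.
hold_idx <- function(spec, profile, env_rate = 50) {
  hw <- hold_window(spec, profile)
  ceiling(hw[1] * env_rate):floor(hw[2] * env_rate)
}
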