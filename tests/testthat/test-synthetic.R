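# Synthetic sEMG / goniometer generator.

test_that("all-zero profile with no noise and no offset yields silence", {
  spec <- exercise_spec(2, "isometric", "extension", 0.5, duration = 2)
  rec <- generate_emg(spec, activation_profile(0, 0), noise_floor = 0,
                      dc_offset = 0, seed = 3)
  expect_true(all(rec$samples == 0))
})

test_that("generation is bit-identical for identical spec and seed", {
  spec <- exercise_spec(11, "dynamic", "extension", 0.75, duration = 2)
  a <- generate_trial(spec, seed = 42)
  b <- generate_trial(spec, seed = 42)
  expect_identical(a$emg$samples, b$emg$samples)
  expect_identical(a$gonio$angles, b$gonio$angles)
  c <- generate_trial(spec, seed = 43)
  expect_false(identical(a$emg$samples, c$emg$samples))
})

test_that("agonists dominate antagonists during the hold phase", {
  spec <- exercise_spec(4, "MVC", "extension", duration = 4)
  prof <- activation_profile(1.0, 0.05)
  rec <- generate_emg(spec, prof, noise_floor = 0, dc_offset = 0, seed = 5)
  hold <- round(hold_window(spec, prof) * rec$rate_hz)
  idx <- hold[1]:hold[2]
  # direct-summation MAV on the generated samples
  mav_rf <- sum(abs(rec$samples["RF", idx])) / length(idx)
  mav_bf <- sum(abs(rec$samples["BF", idx])) / length(idx)
  expect_gte(mav_rf / mav_bf, 5)
})

test_that("channel MAV scales linearly with its MVC amplitude", {
  spec <- exercise_spec(4, "MVC", "extension", duration = 2)
  prof <- activation_profile(1.0, 0.05)
  base <- generate_emg(spec, prof, noise_floor = 0, dc_offset = 0, seed = 6)
  doubled <- generate_emg(spec, prof,
                          amplitude_mvc = c(RF = 2, VM = 1, BF = 1, ST = 1),
                          noise_floor = 0, dc_offset = 0, seed = 6)
  expect_equal(mean(abs(doubled$samples["RF", ])),
               2 * mean(abs(base$samples["RF", ])), tolerance = 1e-12)
  expect_equal(doubled$samples["VM", ], base$samples["VM", ])
})

test_that("the 12-exercise protocol matches the experimental table", {
  prot <- generate_protocol(3)
  expect_length(prot, 12L)
  specs <- lapply(prot, `[[`, "spec")
  expect_identical(vapply(specs, `[[`, 0L, "exercise_id"), 1:12)
  # MVC trials: 1 flexion, 4 extension, both maximal
  expect_identical(specs[[1]]$contraction_type, "MVC")
  expect_identical(specs[[1]]$direction, "flexion")
  expect_identical(specs[[4]]$contraction_type, "MVC")
  expect_identical(specs[[4]]$direction, "extension")
  expect_equal(specs[[4]]$intensity_fraction, 1.0)
  # submaximal dynamic flexion at 75% and 50% of 1RM
  expect_equal(specs[[8]]$intensity_fraction, 0.75)
  expect_equal(specs[[9]]$intensity_fraction, 0.50)
  # postures: flexion exercises hip neutral, extension hip flexed 90
  expect_equal(specs[[1]]$hip_config_angle, 0)
  expect_equal(specs[[4]]$hip_config_angle, 90)
  expect_equal(hip_to_br(specs[[1]]$hip_config_angle), 180)
  expect_equal(hip_to_br(specs[[4]]$hip_config_angle), 90)
})

test_that("goniometer traces respect posture, drift bound and kinematics", {
  iso <- exercise_spec(2, "isometric", "flexion", 0.75, duration = 3,
                       knee_start_angle = 90, hip_config_angle = 0)
  g <- generate_goniometer(iso, seed = 9)
  expect_lte(max(abs(g$angles["knee", ] - 90)), 0.5 + 1e-9)
  expect_lte(max(abs(g$angles["hip", ] - 0)), 0.5 + 1e-9)

  dyn <- exercise_spec(11, "dynamic", "extension", 0.75, duration = 4,
                       knee_start_angle = 90, hip_config_angle = 90)
  gd <- generate_goniometer(dyn, seed = 9)
  expect_lte(mean(abs(gd$angles["hip", ] - 90)), 0.5)
  # knee excursion toward full extension, monotone after motion onset
  knee <- gd$angles["knee", ]
  expect_lte(max(diff(knee)), 1e-9)
  expect_equal(knee[length(knee)], 0, tolerance = 1e-6)

  flex <- exercise_spec(8, "dynamic", "flexion", 0.75, duration = 4,
                        knee_start_angle = 10)
  gf <- generate_goniometer(flex, seed = 9)
  expect_gte(min(diff(gf$angles["knee", ])), -1e-9)
})

test_that("the MVC trial attains the largest envelope among intensities", {
  mavs <- vapply(c(0.5, 0.75, 1.0), function(f) {
    spec <- exercise_spec(5, "isometric", "extension", f, duration = 3)
    rec <- generate_emg(spec, activation_profile(f), noise_floor = 0.01,
                        seed = 21)
    max(mav_windows(abs(rec$samples["RF", ] - mean(rec$samples["RF", ])),
                    500, rec$rate_hz))
  }, numeric(1))
  expect_true(all(diff(mavs) > 0))
})

test_that("trial files round-trip through the delimited text dialect", {
  spec <- exercise_spec(11, "dynamic", "extension", 0.5, duration = 1)
  tr <- generate_trial(spec, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trial(tr$emg, tr$gonio, path)
  back <- read_trial(path)
  expect_equal(back$emg$samples, tr$emg$samples, tolerance = 1e-8)
  expect_equal(back$gonio$angles, tr$gonio$angles, tolerance = 1e-8)
  expect_identical(back$emg$channels, tr$emg$channels)
  expect_equal(back$emg$rate_hz, 1000)
})

test_that("degenerate configurations are rejected", {
  expect_error(exercise_spec(1, "MVC", "flexion", duration = -1), "duration")
  expect_error(exercise_spec(2, "isometric", "flexion", 0), "intensity")
  expect_error(activation_profile(0.5, 0.6), "antagonist")
  spec <- exercise_spec(2, "isometric", "flexion", 0.5, duration = 1)
  expect_error(generate_emg(spec, amplitude_mvc = c(RF = -1, VM = 1, BF = 1, ST = 1),
                            seed = 1), "positive")
})
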