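# Motion-intention pipeline: envelopes, normalization, LC, smoothing.

test_that("RMS envelope matches analytic values and a summation oracle", {
  const <- emg_recording(matrix(1.5, 4, 100), 1000)
  expect_true(all(abs(rms_envelope(const) - 1.5) < 1e-12))
  # one full sine period inside a 20-sample window: RMS = 1/sqrt(2)
  s <- sin(2 * pi * (0:19) / 20)
  rec <- emg_recording(matrix(rep(s, 4), 4, byrow = TRUE), 1000)
  expect_equal(unname(rms_envelope(rec)[, 1]), rep(1 / sqrt(2), 4),
               tolerance = 1e-12)
  set.seed(6)
  x <- matrix(abs(rnorm(4 * 200)), 4)
  env <- rms_envelope(emg_recording(x, 1000))
  oracle <- sqrt(sum(x[2, 21:40]^2) / 20)
  expect_equal(unname(env[2, 2]), oracle, tolerance = 1e-12)
})

test_that("MVC normalization divides channelwise", {
  calib <- test_calib
  env <- matrix(calib$max_mav, 4, 5,
                dimnames = list(names(calib$max_mav), NULL))
  expect_true(all(abs(normalize_envelope(env, calib) - 1) < 1e-12))
  expect_true(all(normalize_envelope(env * 0, calib) == 0))
  calib2 <- calib
  calib2$max_mav <- 2 * calib$max_mav
  expect_equal(normalize_envelope(env, calib2),
               normalize_envelope(env, calib) / 2, tolerance = 1e-12)
  calib_bad <- calib
  calib_bad$max_mav["RF"] <- 0
  expect_error(normalize_envelope(env, calib_bad), "positive")
})

test_that("the linear combination realizes the signed four-muscle sum", {
  env <- function(v) matrix(v, 4, 1, dimnames = list(EMG_CHANNELS, NULL))
  expect_identical(linear_combination(env(c(1, 1, 0, 0))), 2)
  expect_identical(linear_combination(env(c(0, 0, 1, 1))), -2)
  expect_identical(linear_combination(env(c(0.5, 0.5, 0.5, 0.5))), 0)
})

test_that("exchanging extensor and flexor channels negates LC exactly", {
  set.seed(7)
  e <- matrix(abs(rnorm(4 * 50)), 4, dimnames = list(EMG_CHANNELS, NULL))
  swapped <- e[c("BF", "ST", "RF", "VM"), ]
  rownames(swapped) <- EMG_CHANNELS
  expect_identical(linear_combination(swapped), -linear_combination(e))
})

test_that("the 2 Hz smoother has unity DC gain, no overshoot, less variance", {
  expect_equal(lowpass_lc(rep(0.8, 200)), rep(0.8, 200), tolerance = 1e-12)
  step <- lowpass_lc(c(0, rep(1, 199)))
  expect_true(all(diff(step) > -1e-12))
  expect_lte(max(step), 1 + 1e-9)
  set.seed(8)
  noise <- rnorm(2000)
  expect_lt(var(lowpass_lc(noise)), var(noise))
  expect_error(lowpass_lc(1:10, rate_hz = 3), "Nyquist")
})

test_that("per-window MAV never exceeds RMS (power-mean inequality)", {
  set.seed(9)
  for (i in 1:20) {
    x <- abs(rnorm(20))
    expect_lte(mean(x), sqrt(mean(x^2)))
  }
})

test_that("intent sign tracks the commanded direction through the hold", {
  spec_e <- exercise_spec(11, "dynamic", "extension", 0.5, duration = 4)
  spec_f <- exercise_spec(8, "dynamic", "flexion", 0.5, duration = 4)
  prof <- activation_profile(0.5, 0.05)
  idx <- hold_idx(spec_e, prof)
  for (cfg in list(list(spec_e, 1), list(spec_f, -1))) {
    tr <- generate_trial(cfg[[1]], profile = prof, seed = 31)
    it <- quiet(detect_intention(tr$emg, test_calib,
                                 filter_spec(mode = "causal")))
    expect_true(all(sign(it$lc_filtered[idx]) == cfg[[2]]))
  }
})

test_that("orientation classification uses the peak with a dead-band", {
  mk <- function(v) structure(list(lc_raw = v, lc_filtered = v,
                                   envelope_rate_hz = 50),
                              class = "intention_series")
  expect_identical(classify_orientation(mk(c(0.1, 0.6, -0.3))), "extension")
  expect_identical(classify_orientation(mk(c(-0.7, 0.2))), "flexion")
  expect_identical(classify_orientation(mk(c(0.01, -0.02))), "none")
})

test_that("streaming frames reproduce the causal batch pipeline", {
  filt <- filter_spec(mode = "causal")
  it <- quiet(detect_intention(ext_trial$emg, test_calib, filt))
  stream <- quiet(mec_stream_init(test_calib, filt))
  lcs <- numeric(length(it$lc_filtered))
  raws <- numeric(length(lcs))
  for (k in seq_along(lcs)) {
    fr <- ext_trial$emg$samples[, ((k - 1) * 20 + 1):(k * 20)]
    up <- mec_stream_update(stream, fr)
    stream <- up$stream
    lcs[k] <- up$lc_filtered
    raws[k] <- up$lc_raw
  }
  expect_lt(max(abs(lcs - it$lc_filtered)), 1e-9)
  expect_lt(max(abs(raws - it$lc_raw)), 1e-9)
})

test_that("silence maps to zero intent", {
  rec <- emg_recording(matrix(0, 4, 1000), 1000)
  calib <- test_calib
  calib$dc_ref[] <- 0
  it <- quiet(detect_intention(rec, calib, filter_spec(mode = "causal")))
  expect_true(all(abs(it$lc_raw) < 1e-12))
  expect_true(all(abs(it$lc_filtered) < 1e-12))
})

test_that("mean hold intensity is monotone in effort for both directions", {
  for (dir in c("extension", "flexion")) {
    m <- vapply(c(0.5, 0.75, 1.0), function(f) {
      spec <- exercise_spec(2, "isometric", dir, f, duration = 4)
      prof <- activation_profile(f)
      tr <- generate_trial(spec, profile = prof, seed = 57)
      it <- quiet(detect_intention(tr$emg, test_calib,
                                   filter_spec(mode = "causal")))
      mean(abs(it$lc_filtered[hold_idx(spec, prof)]))
    }, numeric(1))
    expect_true(all(diff(m) > 0))
  }
})
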