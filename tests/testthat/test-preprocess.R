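test_that("blink detection covers bad runs, pads and merges intervals", {
  # clean trace -> no intervals
  s <- make_series(rep(5, 240))
  expect_equal(nrow(detect_blinks(s)), 0)

  # one 0.2 s gap with 50 ms padding -> one interval of width 0.3 s
  s <- make_series(rep(5, 240))
  s$pupil_mm[s$t_s >= 0.5 & s$t_s < 0.7] <- NA
  iv <- detect_blinks(s, pad = 0.05)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$end_s - iv$start_s, 0.3, tolerance = 1e-9)

  # two gaps separated by less than 2 x padding merge into one interval;
  # oracle: merge sorted padded endpoints by hand
  s <- make_series(rep(5, 480))
  s$pupil_mm[s$t_s >= 1.0 & s$t_s < 1.1] <- NA
  s$pupil_mm[s$t_s >= 1.17 & s$t_s < 1.3] <- NA
  iv <- detect_blinks(s, pad = 0.05)
  expect_equal(nrow(iv), 1)
  # oracle over sorted endpoints: pad the grid samples of each run, merge
  first_bad1 <- min(s$t_s[s$t_s >= 1.0])
  last_bad2 <- max(s$t_s[s$t_s < 1.3])
  expect_equal(iv$start_s, first_bad1 - 0.05, tolerance = 1e-9)
  expect_equal(iv$end_s, last_bad2 + 1 / 120 + 0.05, tolerance = 1e-9)

  # distant gaps stay separate
  s <- make_series(rep(5, 480))
  s$pupil_mm[10:12] <- NA
  s$pupil_mm[400:404] <- NA
  expect_equal(nrow(detect_blinks(s)), 2)

  # device-artifact jumps (> 1 mm between samples) are flagged too
  s <- make_series(rep(5, 240))
  s$pupil_mm[100] <- 7.5
  expect_gte(nrow(detect_blinks(s)), 1)
})

test_that("spline repair restores polynomial traces and touches nothing else", {
  # linear trace: filled values on the line
  s <- make_series(4 + 0.5 * (0:239) / 120)
  truth <- s$pupil_mm
  s$pupil_mm[100:110] <- NA
  iv <- detect_blinks(s)
  out <- interpolate_gaps(s, iv)
  expect_lt(max(abs(out$pupil_mm - truth)), 1e-9)

  # cubic trace: restored to < 1e-6 via the generating polynomial
  tt <- (0:359) / 120
  poly <- 5 + 0.3 * tt - 0.2 * tt^2 + 0.05 * tt^3
  s <- make_series(poly)
  s$pupil_mm[150:170] <- NA
  out <- interpolate_gaps(s, detect_blinks(s))
  expect_lt(max(abs(out$pupil_mm - poly)), 1e-6)

  # samples outside detected intervals are untouched, exactly
  s <- make_series(5 + sin((0:239) / 10))
  truth <- s$pupil_mm
  s$pupil_mm[50:60] <- NA
  iv <- detect_blinks(s)
  out <- interpolate_gaps(s, iv)
  inside <- s$t_s >= iv$start_s[1] & s$t_s < iv$end_s[1]
  expect_identical(out$pupil_mm[!inside], truth[!inside])

  # no intervals -> unchanged values
  s <- make_series(rep(5, 100))
  out <- interpolate_gaps(s, detect_blinks(s))
  expect_identical(out$pupil_mm, s$pupil_mm)

  # edge gap with insufficient anchors stays missing, with a warning
  s <- make_series(rep(5, 120))
  s$pupil_mm[1:10] <- NA
  expect_warning(out <- interpolate_gaps(s, detect_blinks(s)), "edge")
  expect_true(anyNA(out$pupil_mm))
})

test_that("Savitzky-Golay smoothing is exact on low-order polynomials", {
  # constant in, identical constant out
  s <- make_series(rep(5.3, 200))
  expect_equal(smooth_pupil(s)$pupil_mm, rep(5.3, 200), tolerance = 1e-12)

  # degree-3 polynomial reproduced to < 1e-9 (SG of matching order)
  tt <- (0:299) / 120
  poly <- 5 + 0.4 * tt - 0.3 * tt^2 + 0.08 * tt^3
  out <- smooth_pupil(make_series(poly))
  expect_lt(max(abs(out$pupil_mm - poly)), 1e-9)

  # white noise is attenuated
  withr::with_seed(1, {
    noise <- rnorm(600, 5, 0.2)
    out <- smooth_pupil(make_series(noise))
    expect_lt(var(out$pupil_mm), var(noise))
  })

  expect_error(smooth_pupil(make_series(rep(5, 10))), "shorter")
  expect_error(smooth_pupil(make_series(rep(5, 100)), window = 20), "odd")
})

test_that("decimation keeps every k-th sample with timestamps intact", {
  s <- make_series(rep(5, 480))
  out <- downsample_pupil(s, sample_rate = 120, target_rate = 30)
  expect_equal(nrow(out), 120)
  expect_equal(out$pupil_mm, rep(5, 120))
  expect_equal(diff(out$t_s)[1], 1 / 30, tolerance = 1e-12)

  # 1 Hz sinusoid: decimated samples equal the closed form at kept times
  tt <- (0:479) / 120
  s <- make_series(5 + 0.3 * sin(2 * pi * tt))
  out <- downsample_pupil(s, 120, 30)
  expect_lt(max(abs(out$pupil_mm - (5 + 0.3 * sin(2 * pi * out$t_s)))),
            1e-12)

  expect_error(downsample_pupil(s, 120, 50), "integer multiple")
})

test_that("trial validity applies the strict 20% rule and the gaze flag", {
  s <- make_series(rep(5, 1000))
  v <- validate_trial(s)
  expect_true(v$valid)
  expect_equal(v$missing_fraction, 0)
  expect_equal(v$reason, "ok")

  # 25% missing -> invalid
  s <- make_series(rep(5, 1000))
  s$pupil_mm[1:250] <- NA
  v <- validate_trial(s)
  expect_false(v$valid)
  expect_equal(v$reason, "missing_exceeds_20pct")

  # exactly 20% -> still valid (the rule is strictly "exceeded")
  s <- make_series(rep(5, 1000))
  s$pupil_mm[1:200] <- NA
  expect_true(validate_trial(s)$valid)

  # displaced gaze beyond 100 ms -> invalid even with clean pupil data
  s <- make_series(rep(5, 1000), gaze_valid = rep(TRUE, 1000))
  s$gaze_valid[100:150] <- FALSE   # ~0.42 s at 120 Hz
  v <- validate_trial(s)
  expect_false(v$valid)
  expect_equal(v$reason, "gaze_displaced")

  # sub-threshold gaze flicker is tolerated
  s$gaze_valid <- TRUE; s$gaze_valid[100:105] <- FALSE
  expect_true(validate_trial(s)$valid)
})

test_that("clean traces pass through the chain essentially unchanged", {
  # blink-free smooth trace: detect -> interpolate -> validate is identity
  tt <- (0:599) / 120
  s <- make_series(5 + 0.2 * sin(2 * pi * 0.2 * tt))
  iv <- detect_blinks(s)
  expect_equal(nrow(iv), 0)
  out <- interpolate_gaps(s, iv)
  expect_identical(out$pupil_mm, s$pupil_mm)
  expect_true(validate_trial(s)$valid)
  # SG attenuation on this slow signal is bounded by the filter gain
  sm <- smooth_pupil(s)
  expect_lt(max(abs(sm$pupil_mm - s$pupil_mm)), 1e-3)
})

test_that("synthetic defaults exclude a low single-digit trial fraction", {
  ds <- simulate_dataset(sim_config(n_participants = 6,
                                    n_trials_per_participant = 48,
                                    seed = 31))
  v <- validate_trials(ds$samples)
  frac <- mean(!v$valid)
  expect_gt(frac, 0.005)
  expect_lt(frac, 0.15)
})
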