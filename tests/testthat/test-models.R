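test_that("likelihood-ratio test matches its defining formula", {
  sm <- small_sim()
  m_full <- fit_feature_model(sm$features, "peak_dilation",
                              conf_method = "Wald")
  m_red <- fit_feature_model(sm$features, "peak_dilation",
                             predictors = c("valence_intensity",
                                            "confidence", "duration",
                                            "response_time"),
                             conf_method = "Wald")

  # identical models: L = 0, p = 1
  same <- likelihood_ratio_test(m_full, m_full)
  expect_equal(same$L, 0)
  expect_equal(same$p.value, 1)

  # direct evaluation oracle from the two log-likelihoods
  lrt <- likelihood_ratio_test(m_full, m_red)
  expect_equal(lrt$L,
               2 * (as.numeric(logLik(m_full$fit)) -
                      as.numeric(logLik(m_red$fit))),
               tolerance = 1e-10)
  expect_equal(lrt$df, 1)
  # chi-squared reference: df = 1, L = 3.84 sits at p ~ 0.05
  expect_equal(pchisq(3.84, 1, lower.tail = FALSE), 0.05, tolerance = 1e-3)
  expect_equal(lrt$p.value, pchisq(lrt$L, 1, lower.tail = FALSE))

  # guards: different rows and non-nested models are rejected
  m_subset <- fit_feature_model(sm$features[-(1:5), ], "peak_dilation",
                                conf_method = "Wald")
  expect_error(likelihood_ratio_test(m_full, m_subset),
               "different numbers of rows")
  m_other <- fit_feature_model(sm$features, "peak_dilation",
                               predictors = c("valence_sign"),
                               conf_method = "Wald")
  expect_error(likelihood_ratio_test(m_red, m_other), "not nested")
})

test_that("zero-noise simulation gives exact coefficient recovery", {
  ds <- simulate_dataset(noiseless_config(n_participants = 6,
                                          n_trials = 30, seed = 21))
  f <- features_from_raw(ds)
  m <- suppressMessages(suppressWarnings(
    fit_feature_model(f, "peak_dilation", conf_method = "Wald")))
  est <- setNames(m$coefficients$estimate, m$coefficients$term)
  expect_equal(est[["valence_intensity"]], 0.07, tolerance = 1e-6)
  expect_equal(est[["confidence"]], -0.07, tolerance = 1e-6)
  expect_equal(est[["duration"]], 0.22, tolerance = 1e-6)
  expect_equal(est[["response_time"]], 0.20, tolerance = 1e-6)
  expect_equal(est[["pretrial_baseline"]], 2.39, tolerance = 1e-6)
})

test_that("coefficients follow the predictor scaling algebra", {
  sm <- small_sim()
  r1 <- pc_scaling_ranges()
  r2 <- r1
  # a coefficient reads "outcome change over the stated range", so
  # doubling the range width doubles the scaled coefficient
  r2$confidence <- c(0, 200)
  m1 <- fit_feature_model(sm$features, "peak_dilation",
                          scaling_ranges = r1, conf_method = "Wald")
  m2 <- fit_feature_model(sm$features, "peak_dilation",
                          scaling_ranges = r2, conf_method = "Wald")
  c1 <- setNames(m1$coefficients$estimate, m1$coefficients$term)
  c2 <- setNames(m2$coefficients$estimate, m2$coefficients$term)
  expect_equal(c2[["confidence"]], c1[["confidence"]] * 2,
               tolerance = 1e-8)
  expect_equal(c2[["duration"]], c1[["duration"]], tolerance = 1e-8)

  # the LRT statistic is invariant to affine predictor rescaling
  expect_equal(m1$coefficients$statistic, m2$coefficients$statistic,
               tolerance = 1e-8)
})

test_that("intensity is detected while the valence sign stays null", {
  # generated effects are pure |valence|: the sign adds nothing
  hits_sign <- 0; hits_int <- 0
  for (s in 1:3) {
    ds <- simulate_dataset(sim_config(n_participants = 8,
                                      n_trials_per_participant = 48,
                                      seed = 600 + s, blink_rate = 0,
                                      dropout_prob = 0,
                                      gaze_displaced_prob = 0))
    f <- features_from_raw(ds)
    m <- fit_feature_model(
      f, "peak_dilation",
      predictors = c("valence_sign", "valence_intensity", "confidence",
                     "duration", "response_time", "pretrial_baseline"),
      conf_method = "Wald")
    co <- m$coefficients
    if (co$p.value[co$term == "valence_sign"] > 0.05) hits_sign <- hits_sign + 1
    if (co$p.value[co$term == "valence_intensity"] < 0.05) hits_int <- hits_int + 1
  }
  expect_gte(hits_sign, 2)
  expect_gte(hits_int, 2)
})

test_that("beta rating model recovers located means and Fig-1 structure", {
  # symmetric ratings around the neutral point fit to ~0 valence
  withr::with_seed(5, {
    sym <- tidyr::expand_grid(participant_id = sprintf("p%02d", 1:8),
                              stimulus_id = sprintf("s%02d", 1:12)) |>
      dplyr::mutate(emotion_category = rep(c("neutral", "fear"),
                                           length.out = dplyr::n()),
                    perceived_valence = runif(dplyr::n(), -20, 20),
                    induced_valence = runif(dplyr::n(), -20, 20))
    m <- fit_rating_model(sym)
    expect_true(all(abs(m$fitted$valence_fit) < 8))
    expect_setequal(unique(m$fitted$valence_type),
                    c("perceived", "induced"))
  })

  # beta(mu = 0.8, phi = 10) ratings: mu recovered within the interval
  withr::with_seed(6, {
    n <- 500
    mu <- 0.8; phi <- 10
    y <- rbeta(n, mu * phi, (1 - mu) * phi)
    dat <- tibble::tibble(
      participant_id = rep(sprintf("p%02d", 1:10), each = n / 10),
      stimulus_id = rep(sprintf("s%02d", 1:25), times = n / 25),
      emotion_category = "joy",
      perceived_valence = 100 * y - 50,
      induced_valence = 100 * y - 50)
    m <- fit_rating_model(dat)
    row <- m$fitted[m$fitted$valence_type == "perceived", ]
    target <- 100 * mu - 50
    expect_gte(target, row$conf.low - 1)
    expect_lte(target, row$conf.high + 1)
    expect_equal(row$valence_fit, target, tolerance = 3)
  })

  # correlated perceived/induced generation shows up in fitted medians
  sm <- small_sim()
  m <- fit_rating_model(sm$ds$trials)
  wide <- tidyr::pivot_wider(m$fitted |>
                               dplyr::select(emotion, valence_type,
                                             valence_fit),
                             names_from = valence_type,
                             values_from = valence_fit)
  expect_gt(cor(wide$perceived, wide$induced), 0.7)
})

test_that("response surface reproduces a separable noiseless field", {
  # build traces whose percent change is exactly f(t) * g(valence)
  withr::with_seed(9, {
    trials <- tidyr::expand_grid(participant_id = sprintf("p%02d", 1:6),
                                 trial_id = sprintf("t%02d", 1:12)) |>
      dplyr::mutate(response_s = 8,
                    sound_onset_s = 6,
                    duration_s = 1.5,
                    perceived_valence = rep(seq(-50, 50, length.out = 12),
                                            times = 6))
    f_t <- function(t) exp(-(t - 0.4)^2 / 2)
    g_v <- function(v) 4 + 6 * abs(v) / 50
    samples <- trials |>
      dplyr::rowwise() |>
      dplyr::reframe(participant_id = participant_id,
                     trial_id = trial_id,
                     t_s = seq(4, 12, by = 1 / 30),
                     pupil_mm = 5 * (1 + f_t(t_s - response_s) *
                                       g_v(perceived_valence) / 100))
    feats <- trials |>
      dplyr::mutate(pretrial_baseline = 5)
    sf <- fit_response_surface(samples, feats, trials,
                               time_range = c(-2, 2))
    truth <- f_t(sf$grid$t_lock) * g_v(sf$grid$perceived_valence)
    rmse <- sqrt(mean((sf$grid$pct_fit - truth)^2))
    expect_lt(rmse, 0.02 * diff(range(truth)))

    # constant pupil data -> flat surface
    flat <- samples |> dplyr::mutate(pupil_mm = 5)
    sf0 <- fit_response_surface(flat, feats, trials, time_range = c(-2, 2))
    expect_lt(diff(range(sf0$grid$pct_fit)), 1e-6)
  })
})

test_that("surface from synthetic defaults peaks after the keypress at high |valence|", {
  sm <- small_sim()
  clean <- preprocess_samples(
    sm$ds$samples |> dplyr::semi_join(sm$features,
                                      by = c("participant_id", "trial_id")))
  sf <- fit_response_surface(clean, sm$features, sm$ds$trials)
  ridge <- sf$grid |>
    dplyr::filter(abs(perceived_valence) > 35) |>
    dplyr::group_by(perceived_valence) |>
    dplyr::slice_max(pct_fit, n = 1) |>
    dplyr::ungroup()
  expect_gt(mean(ridge$t_lock), 0)
})

test_that("recovery harness reports bias, rmse and interval coverage", {
  # zero-noise single replicate: bias vanishes to numerical tolerance
  cfg <- noiseless_config(n_participants = 5, n_trials = 20, seed = 55)
  rec <- suppressMessages(suppressWarnings(recover_parameters(cfg, 1)))
  expect_setequal(rec$term,
                  c("valence_intensity", "confidence", "duration",
                    "response_time", "pretrial_baseline"))
  # full pipeline includes smoothing and 30 Hz decimation, so "zero
  # bias" is bounded by the grid and filter error, not 1e-6
  expect_lt(max(abs(rec$bias)), 0.02)
  expect_true(all(rec$rmse < 0.03))

  # noisy replicates: intervals usually cover the generative truth
  cfg2 <- sim_config(n_participants = 8, n_trials_per_participant = 36,
                     seed = 100)
  rec2 <- recover_parameters(cfg2, 3)
  expect_true(all(rec2$coverage >= 2 / 3 - 1e-9))
  reps <- attr(rec2, "replicates")
  expect_equal(nrow(reps), 15)
})
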