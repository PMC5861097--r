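#' Simulation configuration
#'
#' Bundles every tunable of the synthetic eye-tracking data generator.
#' Defaults emulate the study conditions the downstream analysis assumes:
#' 33 participants x 72 trials sampled at 120 Hz, a non-ageing 5-11 s
#' foreperiod, decision-locked dilations peaking shortly after the
#' response keypress, a pre-trial/resting baseline ratio of 0.99 +/- 0.09,
#' and effect sizes (in mm over each predictor's full scaled range) for
#' valence intensity, confidence, sound duration, response time and
#' pre-trial baseline.
#'
#' `effect_sizes` are expressed on the *outcome* scale: each entry is the
#' expected change in peak pupil diameter (mm) when the predictor moves
#' across its full range in [pc_scaling_ranges()], holding the others
#' fixed. Because peak diameter mechanically contains the pre-trial
#' baseline itself, the generator internally gives the evoked response a
#' baseline loading of `effect_sizes$baseline` minus the baseline range
#' width, so that a regression of peak diameter on scaled baseline
#' recovers `effect_sizes$baseline`.
#'
#' @param n_participants Number of participants.
#' @param n_trials_per_participant Trials per participant (the stimulus
#'   set is recycled/truncated to this length).
#' @param sample_rate Eye-tracker sampling rate, Hz.
#' @param effect_sizes Named numeric vector with entries
#'   `valence_intensity`, `confidence`, `duration`, `response_time`,
#'   `baseline`: outcome-scale coefficients in mm over the scaled \[0,1\]
#'   predictor ranges.
#' @param amplitude_intercept Baseline evoked-response amplitude (mm) at
#'   the origin of the scaled covariates; the default puts the mean
#'   evoked peak near 10% of a typical baseline diameter.
#' @param amplitude_sd Trial-to-trial SD of the evoked amplitude, mm.
#' @param participant_intercept_sd SD of per-participant amplitude
#'   intercepts, mm.
#' @param peak_lag_mean Target lag (s) from response keypress to peak of
#'   the noiseless response curve for a typical trial; used to calibrate
#'   the pupil kernel's time-to-peak.
#' @param kernel_shape Shape parameter `n` of the pupil impulse-response
#'   kernel.
#' @param resting_baseline_mean,resting_baseline_sd Population mean/SD of
#'   participant resting pupil diameter, mm.
#' @param baseline_ratio_mean,baseline_ratio_sd Mean/SD of the per-trial
#'   ratio of pre-trial baseline to resting baseline.
#' @param foreperiod_hazard Constant hazard (1/s) of the non-ageing
#'   foreperiod beyond 5 s.
#' @param blink_rate Blink events per minute.
#' @param blink_duration_median Median blink duration, s (lognormal).
#' @param blink_duration_sdlog Lognormal sdlog of blink durations.
#' @param dropout_prob Per-trial probability of one long tracking dropout
#'   (2-6 s), emulating occasional signal loss.
#' @param gaze_displaced_prob Per-trial probability of a gaze-displacement
#'   episode (gaze leaves fixation for 0.2-1 s).
#' @param noise_sd Stationary SD (mm) of the slow AR(1) physiological
#'   pupil noise.
#' @param ar1_coefficient AR(1) coefficient of that noise at the native
#'   sample step, in \[0, 1).
#' @param measurement_noise_sd SD (mm) of additive white measurement
#'   noise.
#' @param resting_duration Length of the per-participant resting
#'   recording, s.
#' @param post_response_window Recording continues this long (s) after
#'   the response keypress.
#' @param seed Integer seed; identical seed and config give bit-identical
#'   output.
#'
#' @return A list of class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(n_participants = 2, n_trials_per_participant = 4, seed = 1)
#' cfg$effect_sizes
sim_config <- function(n_participants = 33,
                       n_trials_per_participant = 72,
                       sample_rate = 120,
                       effect_sizes = c(valence_intensity = 0.07,
                                        confidence        = -0.07,
                                        duration          = 0.22,
                                        response_time     = 0.20,
                                        baseline          = 2.39),
                       amplitude_intercept = 0.65,
                       amplitude_sd = 0.15,
                       participant_intercept_sd = 0.15,
                       peak_lag_mean = 0.37,
                       kernel_shape = 10.1,
                       resting_baseline_mean = 5.2,
                       resting_baseline_sd = 0.5,
                       baseline_ratio_mean = 0.99,
                       baseline_ratio_sd = 0.09,
                       foreperiod_hazard = 0.3,
                       blink_rate = 12,
                       blink_duration_median = 0.15,
                       blink_duration_sdlog = 0.5,
                       dropout_prob = 0.03,
                       gaze_displaced_prob = 0.02,
                       noise_sd = 0.03,
                       ar1_coefficient = 0.96,
                       measurement_noise_sd = 0.02,
                       resting_duration = 45,
                       post_response_window = 4.5,
                       seed = NULL) {
  cfg <- list(
    n_participants = n_participants,
    n_trials_per_participant = n_trials_per_participant,
    sample_rate = sample_rate,
    effect_sizes = effect_sizes,
    amplitude_intercept = amplitude_intercept,
    amplitude_sd = amplitude_sd,
    participant_intercept_sd = participant_intercept_sd,
    peak_lag_mean = peak_lag_mean,
    kernel_shape = kernel_shape,
    resting_baseline_mean = resting_baseline_mean,
    resting_baseline_sd = resting_baseline_sd,
    baseline_ratio_mean = baseline_ratio_mean,
    baseline_ratio_sd = baseline_ratio_sd,
    foreperiod_hazard = foreperiod_hazard,
    blink_rate = blink_rate,
    blink_duration_median = blink_duration_median,
    blink_duration_sdlog = blink_duration_sdlog,
    dropout_prob = dropout_prob,
    gaze_displaced_prob = gaze_displaced_prob,
    noise_sd = noise_sd,
    ar1_coefficient = ar1_coefficient,
    measurement_noise_sd = measurement_noise_sd,
    resting_duration = resting_duration,
    post_response_window = post_response_window,
    seed = seed
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  check_positive_scalar(cfg$sample_rate, "sample_rate")
  if (cfg$n_participants < 1) abort("`n_participants` must be >= 1.")
  if (cfg$ar1_coefficient < 0 || cfg$ar1_coefficient >= 1) {
    abort("`ar1_coefficient` must be in [0, 1).")
  }
  sds <- c("amplitude_sd", "participant_intercept_sd", "resting_baseline_sd",
           "baseline_ratio_sd", "noise_sd", "measurement_noise_sd",
           "blink_duration_sdlog")
  for (s in sds) {
    if (cfg[[s]] < 0) abort(sprintf("`%s` must be >= 0.", s))
  }
  needed <- c("valence_intensity", "confidence", "duration",
              "response_time", "baseline")
  if (!all(needed %in% names(cfg$effect_sizes))) {
    abort(sprintf("`effect_sizes` must name: %s",
                  paste(needed, collapse = ", ")))
  }
  invisible(cfg)
}

#' Non-ageing foreperiod sampler
#'
#' Draws pre-stimulus delays of 5 + E seconds, where E is exponential
#' with constant hazard, right-truncated so the total never exceeds 11 s.
#' The hazard of stimulus onset is therefore constant on (5, 11) s, which
#' makes onset time unpredictable for the participant.
#'
#' @param n Number of draws.
#' @param hazard Constant hazard rate beyond 5 s, 1/s. `Inf` gives the
#'   degenerate 5 s limit.
#' @return Numeric vector of foreperiods in \[5, 11\] s.
#' @export
#' @examples
#' set.seed(1)
#' range(sample_foreperiod(1000, hazard = 0.3))
sample_foreperiod <- function(n = 1, hazard = 0.3) {
  if (!is.numeric(hazard) || length(hazard) != 1L || hazard <= 0) {
    abort("`hazard` must be a single positive number (Inf allowed).")
  }
  if (is.infinite(hazard)) return(rep(5, n))
  u <- runif(n)
  # inverse CDF of an exponential right-truncated at 6 s past the 5 s floor
  5 - log(1 - u * (1 - exp(-hazard * 6))) / hazard
}

#' Pupil impulse-response kernel
#'
#' Erlang-family kernel `h(t) = (t/t_max)^n * exp(n * (1 - t/t_max))`,
#' normalised so its unique maximum is `h(t_max) = 1`. This is the
#' standard parametric form for the pupil's response to a brief
#' attentional impulse; convolved with a boxcar of sustained attention it
#' yields the slow dilation-and-return shape of task-evoked responses.
#'
#' @param t Time points, s (values < 0 return 0).
#' @param n Shape parameter, > 0.
#' @param t_max Time-to-peak, s, > 0.
#' @return Numeric vector of kernel values (unitless).
#' @export
#' @examples
#' pupil_kernel(0.93, n = 10.1, t_max = 0.93)
pupil_kernel <- function(t, n = 10.1, t_max = 0.93) {
  check_positive_scalar(n, "n")
  check_positive_scalar(t_max, "t_max")
  out <- numeric(length(t))
  pos <- !is.na(t) & t > 0
  x <- t[pos] / t_max
  out[pos] <- exp(n * (log(x) + 1 - x))
  out[is.na(t)] <- NA_real_
  out
}

# noiseless response->peak lag of boxcar (length boxcar_len) (*) kernel,
# evaluated on a dense grid
kernel_response_lag <- function(t_max, shape, boxcar_len = 2.5, dt = 1 / 240) {
  t_end <- boxcar_len + 6 * t_max
  tt <- seq(0, t_end, by = dt)
  kern <- pupil_kernel(tt, n = shape, t_max = t_max)
  box <- as.numeric(tt <= boxcar_len)
  cv <- convolve(box, rev(kern), type = "open")[seq_along(tt)]
  tt[which.max(cv)] - boxcar_len
}

# find the kernel time-to-peak whose noiseless response->peak lag,
# averaged over a representative spread of attention-boxcar lengths
# (response-time quantiles), equals `peak_lag_mean`. A single reference
# length would miss that long boxcars saturate the convolution and pull
# their peak before the response.
# `wander_compensation` offsets the systematic pull of the realized
# argmax toward the flat pre-peak plateau once measurement noise breaks
# near-ties on the broad response top (approx. 0.3 s at realistic noise);
# calibrating the noiseless lag to peak_lag_mean + compensation makes the
# realized trial-level mean lag land near peak_lag_mean.
calibrate_kernel_tmax <- function(peak_lag_mean, shape,
                                  boxcar_lens = c(1.4, 2.0, 2.6, 3.2, 4.2),
                                  wander_compensation = 0.28) {
  target <- peak_lag_mean + wander_compensation
  f <- function(tm) {
    mean(vapply(boxcar_lens, function(L) kernel_response_lag(tm, shape, L),
                numeric(1))) - target
  }
  stats::uniroot(f, lower = 0.2, upper = 8, tol = 1e-3)$root
}

#' Synthetic stimulus set
#'
#' Builds a 72-sound stimulus table emulating the composition of a
#' nonverbal-vocalization corpus: eight emotion categories with
#' category-typical durations (clamped to \[0.5, 6\] s), true valences on
#' the -50..+50 scale, and an ambiguity score in \[0, 1\] that drives
#' simulated confidence and response times.
#'
#' @param n_stimuli Number of stimuli (category counts are scaled
#'   proportionally; default 72).
#' @return Tibble with columns `stimulus_id`, `emotion_category`,
#'   `duration_s`, `true_valence`, `ambiguity`.
#' @export
#' @examples
#' set.seed(1)
#' dplyr::count(stimulus_set(), emotion_category)
stimulus_set <- function(n_stimuli = 72) {
  cats <- tibble(
    emotion_category = c("amusement", "joy", "pleasure", "neutral",
                         "disgust", "fear", "pain", "sadness"),
    n        = c(6, 11, 15, 8, 9, 12, 3, 8),
    dur_mean = c(3.4, 2.5, 2.8, 1.5, 1.1, 1.7, 1.4, 2.9),
    dur_sd   = c(1.9, 1.4, 1.9, 0.7, 0.7, 0.9, 0.2, 1.3),
    valence  = c(40, 30, 25, 0, -30, -35, -20, -40),
    # low recognisability -> high ambiguity (pain, neutral hardest)
    ambiguity = c(0.10, 0.33, 0.57, 0.50, 0.23, 0.38, 0.83, 0.10)
  )
  if (n_stimuli != 72) {
    cats$n <- pmax(1L, round(cats$n * n_stimuli / 72))
  }
  rows <- cats[rep(seq_len(nrow(cats)), cats$n), ]
  m <- nrow(rows)
  tibble(
    stimulus_id = sprintf("stim%03d", seq_len(m)),
    emotion_category = rows$emotion_category,
    duration_s = clamp(rnorm(m, rows$dur_mean, rows$dur_sd), 0.5, 6),
    true_valence = clamp(rnorm(m, rows$valence, 8), -50, 50),
    ambiguity = clamp(rnorm(m, rows$ambiguity, 0.08), 0.02, 1)
  )
}

# stationary AR(1) + white measurement noise, length n
sim_noise <- function(n, cfg) {
  phi <- cfg$ar1_coefficient
  if (cfg$noise_sd > 0) {
    innov_sd <- cfg$noise_sd * sqrt(1 - phi^2)
    ar <- as.numeric(stats::filter(rnorm(n, 0, innov_sd), phi,
                                   method = "recursive",
                                   init = rnorm(1, 0, cfg$noise_sd)))
  } else {
    ar <- numeric(n)
  }
  if (cfg$measurement_noise_sd > 0) {
    ar <- ar + rnorm(n, 0, cfg$measurement_noise_sd)
  }
  ar
}

# kernel sampled on the native grid out to its effective support
kernel_samples <- function(cfg, t_max) {
  dt <- 1 / cfg$sample_rate
  # support: out past the peak until the tail is negligible
  t_end <- t_max * (1 + 12 / sqrt(cfg$kernel_shape))
  tt <- seq(dt, t_end, by = dt)
  kern <- pupil_kernel(tt, n = cfg$kernel_shape, t_max = t_max)
  kern[kern > 1e-8 | tt <= t_max]
}

#' Simulate one trial
#'
#' Generates the pupil trace and trial metadata for a single stimulus
#' presentation: pre-trial baseline (resting diameter times a ratio
#' draw), plus an evoked component equal to an attention boxcar spanning
#' sound onset to the response keypress convolved with the pupil kernel
#' and normalised to unit maximum on the trial's sample grid, plus AR(1)
#' and white noise; blink and dropout gaps are masked as missing.
#'
#' @param config A [sim_config()].
#' @param stimulus One row of [stimulus_set()].
#' @param participant_state List with `participant_id`,
#'   `resting_baseline` (mm) and `intercept` (mm, amplitude offset).
#' @param kernel Optional precomputed kernel samples (internal use).
#' @return List with `samples` (tibble: `t_s`, `pupil_mm`, `gaze_valid`)
#'   and `trial` (one-row tibble of trial metadata).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' set.seed(1)
#' stim <- stimulus_set()[1, ]
#' st <- list(participant_id = "p01", resting_baseline = 5.2, intercept = 0)
#' tr <- simulate_trial(cfg, stim, st)
#' nrow(tr$samples)
simulate_trial <- function(config, stimulus, participant_state,
                           kernel = NULL) {
  cfg <- config
  if (stimulus$duration_s < 0.5 || stimulus$duration_s > 6) {
    abort("stimulus duration must be within [0.5, 6] s.")
  }
  fs <- cfg$sample_rate
  dt <- 1 / fs
  if (is.null(kernel)) {
    t_max <- calibrate_kernel_tmax(cfg$peak_lag_mean, cfg$kernel_shape)
    kernel <- kernel_samples(cfg, t_max)
  }

  amb <- stimulus$ambiguity
  dur <- stimulus$duration_s
  onset <- sample_foreperiod(1, cfg$foreperiod_hazard)
  perceived <- clamp(stimulus$true_valence + rnorm(1, 0, 5 + 15 * amb),
                     -50, 50)
  induced <- clamp(0.8 * perceived + rnorm(1, 0, 8), -50, 50)
  confidence <- clamp(100 * (1 - amb) + rnorm(1, 0, 10), 0, 100)
  rt <- clamp(0.5 * dur + 1.2 + 1.5 * amb + rnorm(1, 0, 0.4), 0.6, 9)
  response_s <- onset + rt

  t_end <- response_s + cfg$post_response_window
  n <- floor(t_end * fs) + 1L
  t_s <- (seq_len(n) - 1L) * dt

  ratio <- rnorm(1, cfg$baseline_ratio_mean, cfg$baseline_ratio_sd)
  baseline <- participant_state$resting_baseline * ratio

  rng <- pc_scaling_ranges()
  eff <- cfg$effect_sizes
  # Baseline attenuation is state-dependent: the evoked amplitude loads on
  # the pre-trial deviation from the participant's own resting diameter.
  # Because peak diameter mechanically contains the baseline (slope equal
  # to the baseline range width on the scaled metric), the loading is
  # eff["baseline"] minus that width, so the outcome-scale coefficient of
  # peak diameter on scaled pre-trial baseline equals eff["baseline"]
  # (see ?sim_config).
  bl_width <- diff(rng$pretrial_baseline)
  amp <- cfg$amplitude_intercept +
    eff[["valence_intensity"]] * scale_range(abs(perceived), rng$valence_intensity) +
    eff[["confidence"]] * scale_range(confidence, rng$confidence) +
    eff[["duration"]] * scale_range(dur, rng$duration) +
    eff[["response_time"]] * scale_range(rt, rng$response_time) +
    (eff[["baseline"]] - bl_width) *
      (baseline - participant_state$resting_baseline) / bl_width +
    participant_state$intercept +
    rnorm(1, 0, cfg$amplitude_sd)

  box <- as.numeric(t_s >= onset & t_s < response_s)
  shape <- convolve(box, rev(kernel), type = "open")[seq_len(n)]
  mx <- max(shape)
  if (mx > 0) shape <- shape / mx

  pupil <- baseline + amp * shape + sim_noise(n, cfg)
  pupil <- clamp(pupil, 0.5, 11.5)

  # blinks: Poisson arrivals, lognormal durations, masked as missing
  n_blinks <- rpois(1, cfg$blink_rate / 60 * t_end)
  miss <- rep(FALSE, n)
  if (n_blinks > 0) {
    starts <- runif(n_blinks, 0, t_end)
    durs <- rlnorm(n_blinks, log(cfg$blink_duration_median),
                   cfg$blink_duration_sdlog)
    for (b in seq_len(n_blinks)) {
      miss <- miss | (t_s >= starts[b] & t_s < starts[b] + durs[b])
    }
  }
  if (cfg$dropout_prob > 0 && runif(1) < cfg$dropout_prob) {
    d_start <- runif(1, 0, max(t_end - 2, 0.1))
    d_dur <- runif(1, 2, 6)
    miss <- miss | (t_s >= d_start & t_s < d_start + d_dur)
  }
  pupil[miss] <- NA_real_

  gaze_valid <- rep(TRUE, n)
  if (cfg$gaze_displaced_prob > 0 && runif(1) < cfg$gaze_displaced_prob) {
    g_start <- runif(1, onset, max(t_end - 1, onset + 0.1))
    g_dur <- runif(1, 0.2, 1)
    gaze_valid[t_s >= g_start & t_s < g_start + g_dur] <- FALSE
  }

  samples <- tibble(t_s = t_s, pupil_mm = pupil, gaze_valid = gaze_valid)
  trial <- tibble(
    participant_id = participant_state$participant_id,
    stimulus_id = stimulus$stimulus_id,
    emotion_category = stimulus$emotion_category,
    foreperiod_s = onset,
    sound_onset_s = onset,
    sound_offset_s = onset + dur,
    duration_s = dur,
    response_s = response_s,
    arrow_key = ifelse(perceived >= 0, "right", "left"),
    perceived_valence = perceived,
    induced_valence = induced,
    confidence = confidence,
    true_baseline_mm = baseline,
    true_amplitude_mm = amp
  )
  list(samples = samples, trial = trial)
}

#' Simulate a complete dataset
#'
#' Generates the three standard tables for a full study: long-format
#' pupil samples, per-trial events/ratings, and a per-participant resting
#' recording. Trial order is shuffled per participant; all randomness
#' flows from the single seed in the config, so identical configs give
#' bit-identical output.
#'
#' @param config A [sim_config()].
#' @return List of class `"pupil_dataset"` with tibbles `samples`
#'   (`participant_id`, `trial_id`, `t_s`, `pupil_mm`, `gaze_valid`),
#'   `trials` (events and ratings per trial) and `resting`
#'   (`participant_id`, `t_s`, `pupil_mm`).
#' @export
#' @examples
#' ds <- simulate_dataset(sim_config(n_participants = 2,
#'                                   n_trials_per_participant = 3, seed = 1))
#' nrow(ds$trials)
simulate_dataset <- function(config) {
  cfg <- config
  validate_sim_config(cfg)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  stimuli <- stimulus_set()
  n_tr <- cfg$n_trials_per_participant
  idx_pool <- rep(seq_len(nrow(stimuli)),
                  length.out = max(n_tr, nrow(stimuli)))

  t_max <- calibrate_kernel_tmax(cfg$peak_lag_mean, cfg$kernel_shape)
  kernel <- kernel_samples(cfg, t_max)
  fs <- cfg$sample_rate

  all_samples <- vector("list", cfg$n_participants)
  all_trials <- vector("list", cfg$n_participants)
  all_resting <- vector("list", cfg$n_participants)

  for (p in seq_len(cfg$n_participants)) {
    pid <- sprintf("p%02d", p)
    state <- list(
      participant_id = pid,
      resting_baseline = rnorm(1, cfg$resting_baseline_mean,
                               cfg$resting_baseline_sd),
      intercept = rnorm(1, 0, cfg$participant_intercept_sd)
    )

    n_rest <- floor(cfg$resting_duration * fs) + 1L
    t_rest <- (seq_len(n_rest) - 1L) / fs
    rest_pupil <- state$resting_baseline + sim_noise(n_rest, cfg)
    n_bl <- rpois(1, cfg$blink_rate / 60 * cfg$resting_duration)
    if (n_bl > 0) {
      starts <- runif(n_bl, 0, cfg$resting_duration)
      durs <- rlnorm(n_bl, log(cfg$blink_duration_median),
                     cfg$blink_duration_sdlog)
      for (b in seq_len(n_bl)) {
        rest_pupil[t_rest >= starts[b] & t_rest < starts[b] + durs[b]] <-
          NA_real_
      }
    }
    all_resting[[p]] <- tibble(participant_id = pid, t_s = t_rest,
                               pupil_mm = rest_pupil)

    order_idx <- sample(idx_pool[seq_len(n_tr)])
    p_samples <- vector("list", n_tr)
    p_trials <- vector("list", n_tr)
    for (k in seq_len(n_tr)) {
      tr <- simulate_trial(cfg, stimuli[order_idx[k], ], state,
                           kernel = kernel)
      tid <- sprintf("t%03d", k)
      p_samples[[k]] <- bind_cols(
        tibble(participant_id = pid, trial_id = tid), tr$samples)
      p_trials[[k]] <- bind_cols(tibble(trial_id = tid), tr$trial)
    }
    all_samples[[p]] <- bind_rows(p_samples)
    all_trials[[p]] <- bind_rows(p_trials)
  }

  trials <- bind_rows(all_trials) |>
    relocate("participant_id", "trial_id")
  structure(
    list(samples = bind_rows(all_samples),
         trials = trials,
         resting = bind_rows(all_resting),
         provenance = list(seed = cfg$seed,
                           config_hash = rlang::hash(unclass(cfg)),
                           package_version = tryCatch(
                             as.character(utils::packageVersion("pupilcurve")),
                             error = function(e) "unknown"))),
    class = "pupil_dataset")
}
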