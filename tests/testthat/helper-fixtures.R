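# shared fixtures, built in code

# uniform series tibble at `rate` Hz
make_series <- function(values, rate = 120, gaze_valid = NULL) {
  n <- length(values)
  out <- tibble::tibble(t_s = (seq_len(n) - 1) / rate, pupil_mm = values)
  if (!is.null(gaze_valid)) out$gaze_valid <- gaze_valid
  out
}

# small noiseless config: every stochastic nuisance off, effects on
noiseless_config <- function(n_participants = 6, n_trials = 24, seed = 11,
                             ...) {
  sim_config(n_participants = n_participants,
             n_trials_per_participant = n_trials, seed = seed,
             noise_sd = 0, measurement_noise_sd = 0, amplitude_sd = 0,
             participant_intercept_sd = 0, blink_rate = 0,
             dropout_prob = 0, gaze_displaced_prob = 0, ...)
}

# features straight from raw (noiseless) samples, bypassing smoothing
features_from_raw <- function(ds) {
  rest <- ds$resting |>
    dplyr::group_by(participant_id) |>
    dplyr::summarise(resting_baseline = mean(pupil_mm, na.rm = TRUE),
                     .groups = "drop")
  compute_features(ds$samples, ds$trials, rest)
}

# small realistic dataset cached per session for model tests
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- simulate_dataset(sim_config(n_participants = 8,
                                        n_trials_per_participant = 40,
                                        seed = 402))
      cache <<- list(ds = ds, features = features_from_raw(ds))
    }
    cache
  }
})
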