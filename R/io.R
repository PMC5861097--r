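required_sample_cols <- c("participant_id", "trial_id", "t_s", "pupil_mm",
                          "gaze_valid")
required_trial_cols <- c("participant_id", "trial_id", "foreperiod_s",
                         "sound_onset_s", "sound_offset_s", "response_s",
                         "arrow_key", "perceived_valence", "induced_valence",
                         "confidence", "emotion_category", "stimulus_id")
required_resting_cols <- c("participant_id", "t_s", "pupil_mm")

check_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    abort(sprintf("%s is missing column(s): %s", what,
                  paste(miss, collapse = ", ")))
  }
}

check_monotone <- function(df, what) {
  bad <- df |>
    group_by(dplyr::across(dplyr::any_of(c("participant_id", "trial_id")))) |>
    summarise(ok = all(diff(.data$t_s) > 0), .groups = "drop")
  if (!all(bad$ok)) abort(sprintf("non-monotone timestamps in %s.", what))
}

check_units <- function(df, what) {
  d <- df$pupil_mm[!is.na(df$pupil_mm)]
  if (length(d) && (any(d <= 0) || any(d >= 12))) {
    abort(sprintf(
      "pupil diameters in %s outside (0, 12) mm; check units.", what))
  }
}

#' Read a pupillometry dataset from delimited files
#'
#' Loads the three standard tables (samples, trials, resting), checks
#' required columns, per-trial timestamp monotonicity, unit sanity
#' (diameters in mm, times in s) and the trial cross-reference between
#' the sample and trial tables. Missing diameters are encoded as empty
#' fields.
#'
#' @param samples_path,trials_path,resting_path CSV paths.
#' @param delim Field delimiter.
#' @return List of class `"pupil_dataset"` with tibbles `samples`,
#'   `trials`, `resting` and a `provenance` list.
#' @export
read_dataset <- function(samples_path, trials_path, resting_path,
                         delim = ",") {
  rd <- function(p) readr::read_delim(p, delim = delim,
                                      show_col_types = FALSE,
                                      progress = FALSE)
  samples <- rd(samples_path)
  trials <- rd(trials_path)
  resting <- rd(resting_path)

  check_cols(samples, required_sample_cols, "sample table")
  check_cols(trials, required_trial_cols, "trial table")
  check_cols(resting, required_resting_cols, "resting table")
  check_monotone(samples, "sample table")
  check_monotone(resting, "resting table")
  check_units(samples, "sample table")
  check_units(resting, "resting table")

  key_s <- distinct(samples, .data$participant_id, .data$trial_id)
  key_t <- distinct(trials, .data$participant_id, .data$trial_id)
  if (nrow(anti_join(key_s, key_t, by = c("participant_id", "trial_id"))) ||
      nrow(anti_join(key_t, key_s, by = c("participant_id", "trial_id")))) {
    abort("sample and trial tables reference different trials.")
  }

  prov_path <- file.path(dirname(samples_path), "provenance.json")
  provenance <- if (file.exists(prov_path)) {
    jsonlite::read_json(prov_path, simplifyVector = TRUE)
  } else {
    list()
  }
  structure(list(samples = samples, trials = trials, resting = resting,
                 provenance = provenance),
            class = "pupil_dataset")
}

#' Write a pupillometry dataset to a directory
#'
#' Writes `samples.csv`, `trials.csv`, `resting.csv` and
#' `provenance.json` (UTF-8, header row, missing as empty field).
#'
#' @param dataset A `"pupil_dataset"` (e.g. from [simulate_dataset()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(dataset$samples, file.path(dir, "samples.csv"),
                   progress = FALSE)
  readr::write_csv(dataset$trials, file.path(dir, "trials.csv"),
                   progress = FALSE)
  readr::write_csv(dataset$resting, file.path(dir, "resting.csv"),
                   progress = FALSE)
  jsonlite::write_json(dataset$provenance %||% list(),
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(dir)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or read) -> validate -> preprocess -> features ->
#' aggregate -> models from a single configuration and optionally writes
#' `features.csv`, `curves.csv`, `models.csv` and `log.json` to a
#' directory. The configuration is a nested list (or a YAML file path)
#' with blocks `simulate` (arguments of [sim_config()]) *or* `input`
#' (paths for [read_dataset()]), plus optional `preprocess`, `features`,
#' `aggregate` (`lock_events`, `groupings`) and `model` (`outcomes`)
#' blocks; omit `model` to stop after aggregation.
#'
#' @param config Nested list or YAML path.
#' @param out_dir Optional output directory.
#' @return List of class `"pupil_results"`: `features`, `curves`
#'   (named list of [aggregate_curves()] outputs), `models` (long
#'   coefficient tibble), `model_fits`, `validity`, `log`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }

  if (!is.null(config$simulate)) {
    cfg <- do.call(sim_config, config$simulate)
    ds <- simulate_dataset(cfg)
  } else if (!is.null(config$input)) {
    ds <- do.call(read_dataset, config$input)
  } else {
    abort("config needs a `simulate` or `input` block.")
  }

  pp <- config$preprocess %||% list()
  sample_rate <- pp$sample_rate %||% 120
  target_rate <- pp$target_rate %||% 30

  validity <- validate_trials(ds$samples,
                              max_missing = pp$max_missing %||% 0.20)
  keep <- validity |> filter(.data$valid) |>
    select("participant_id", "trial_id")
  clean <- preprocess_samples(
    ds$samples |> inner_join(keep, by = c("participant_id", "trial_id")),
    sample_rate = sample_rate, target_rate = target_rate,
    sg_window = pp$sg_window %||% 21, sg_order = pp$sg_order %||% 3,
    pad = pp$pad %||% 0.05)
  rest <- preprocess_resting(ds$resting, sample_rate = sample_rate,
                             target_rate = target_rate)

  fa <- config$features %||% list()
  feats <- compute_features(
    clean, ds$trials, resting_baselines(rest),
    baseline_window = fa$baseline_window %||% 1.3,
    contraction_window = fa$contraction_window %||% 2,
    min_peak_time = fa$min_peak_time %||% 0.25,
    baseline_subtract = fa$baseline_subtract %||% TRUE)

  ag <- config$aggregate %||% list()
  lock_events <- ag$lock_events %||% c("sound_onset", "response_keypress")
  groupings <- ag$groupings %||% c("valence_sign")
  curves <- list()
  for (ev in lock_events) {
    for (g in groupings) {
      curves[[paste(ev, g, sep = ".")]] <-
        aggregate_curves(clean, feats, ds$trials, lock_event = ev,
                         grouping = g)
    }
  }

  models <- NULL
  model_fits <- list()
  if (!is.null(config$model)) {
    outcomes <- config$model$outcomes %||%
      c("peak_dilation", "peak_time", "dilation_rate", "contraction_rate")
    model_fits <- purrr::map(
      setNames(outcomes, outcomes),
      ~ fit_feature_model(feats, .x,
                          conf_method = config$model$conf_method %||%
                            "profile"))
    models <- purrr::imap(model_fits,
                          ~ tidy(.x) |> mutate(outcome = .y)) |>
      bind_rows() |>
      relocate("outcome")
  }

  n_excl <- sum(!validity$valid)
  log <- list(
    seed = ds$provenance$seed,
    config_hash = rlang::hash(config),
    n_trials = nrow(ds$trials),
    n_excluded = n_excl,
    excluded_fraction = n_excl / nrow(ds$trials),
    exclusion_reasons = as.list(table(validity$reason[!validity$valid]))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(feats, file.path(out_dir, "features.csv"),
                     progress = FALSE)
    curves_long <- purrr::imap(curves, function(cv, nm) {
      as_tibble(cv) |> mutate(curve_set = nm)
    }) |> bind_rows() |> relocate("curve_set")
    readr::write_csv(curves_long, file.path(out_dir, "curves.csv"),
                     progress = FALSE)
    if (!is.null(models)) {
      readr::write_csv(models, file.path(out_dir, "models.csv"),
                       progress = FALSE)
    }
    jsonlite::write_json(log, file.path(out_dir, "log.json"),
                         auto_unbox = TRUE, null = "null")
  }

  structure(list(features = feats, curves = curves, models = models,
                 model_fits = model_fits, validity = validity, log = log),
            class = "pupil_results")
}

#' @export
print.pupil_results <- function(x, ...) {
  cat(sprintf(
    "Pupillometry pipeline results: %d trials (%.1f%% excluded), %d curve set(s)%s\n",
    nrow(x$validity), 100 * x$log$excluded_fraction, length(x$curves),
    if (!is.null(x$models)) sprintf(", %d model(s)", length(x$model_fits))
    else ""))
  invisible(x)
}
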