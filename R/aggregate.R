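#' Time-lock samples to a trial event
#'
#' Shifts every trial's time axis so the chosen event is at t = 0 and
#' snaps the shifted times to a common grid at `target_rate` by
#' nearest-sample assignment (snapping error at most half a sample
#' period).
#'
#' @param clean_samples Preprocessed sample tibble.
#' @param trials Trial table carrying the event columns.
#' @param event `"sound_onset"` or `"response_keypress"`.
#' @param target_rate Grid rate, Hz.
#' @return The sample tibble with a `t_lock` column (s, on the grid).
#' @export
time_lock <- function(clean_samples, trials,
                      event = c("sound_onset", "response_keypress"),
                      target_rate = 30) {
  event <- match.arg(event)
  col <- switch(event, sound_onset = "sound_onset_s",
                response_keypress = "response_s")
  if (!col %in% names(trials)) {
    abort(sprintf("trial table is missing event column `%s`.", col))
  }
  ev <- trials |>
    select("participant_id", "trial_id", event_s = dplyr::all_of(col))
  if (any(is.na(ev$event_s))) abort("missing event timestamps.")
  clean_samples |>
    inner_join(ev, by = c("participant_id", "trial_id")) |>
    mutate(t_lock = round((.data$t_s - .data$event_s) * target_rate) /
             target_rate) |>
    select(-"event_s")
}

#' Grouping labels for aggregate curves
#'
#' @noRd
curve_groups <- function(features, grouping, valence_cuts, n_bins) {
  switch(
    grouping,
    none = rep("all", nrow(features)),
    valence_sign = dplyr::case_when(
      features$perceived_valence < valence_cuts[1] ~ "negative",
      features$perceived_valence > valence_cuts[2] ~ "positive",
      TRUE ~ "neutral"),
    valence_intensity = {
      br <- quantile(features$valence_intensity,
                     probs = seq(0, 1, length.out = n_bins + 1), na.rm = TRUE)
      br[1] <- -Inf; br[length(br)] <- Inf
      paste0("intensity_q", as.integer(cut(features$valence_intensity, br)))
    },
    baseline_ratio = {
      br <- quantile(features$baseline_ratio,
                     probs = seq(0, 1, length.out = n_bins + 1), na.rm = TRUE)
      br[1] <- -Inf; br[length(br)] <- Inf
      paste0("ratio_q", as.integer(cut(features$baseline_ratio, br)))
    },
    abort(sprintf("unknown grouping `%s`.", grouping))
  )
}

#' Event-locked grand-average percent-change curves
#'
#' Converts each trial to percent change relative to its pre-trial
#' baseline, time-locks to the chosen event, and aggregates per group
#' and grid timepoint: mean, SD, per-timepoint n and SEM (sample SD over
#' the trials contributing a sample at that timepoint divided by
#' sqrt(n)). Ragged trial lengths are handled by aggregating whichever
#' trials have data at a timepoint; timepoints with fewer than
#' `min_trials` contributions are dropped.
#'
#' @param clean_samples Preprocessed sample tibble (30 Hz).
#' @param features [compute_features()] output (supplies baselines and
#'   grouping variables).
#' @param trials Trial table (event timestamps).
#' @param lock_event `"sound_onset"` or `"response_keypress"`.
#' @param grouping `"valence_sign"`, `"valence_intensity"`,
#'   `"baseline_ratio"` or `"none"`.
#' @param valence_cuts Lower/upper perceived-valence cuts separating
#'   negative / neutral / positive (default -10, +10).
#' @param n_bins Number of quantile bins for the binned groupings.
#' @param target_rate Grid rate, Hz.
#' @param min_trials Minimum trials per timepoint (SEM needs >= 2).
#' @return Tibble of class `"pupil_curves"`: `group_label`, `t_lock`,
#'   `mean_pct`, `sem_pct`, `n`.
#' @export
aggregate_curves <- function(clean_samples, features, trials,
                             lock_event = c("sound_onset",
                                            "response_keypress"),
                             grouping = "valence_sign",
                             valence_cuts = c(-10, 10), n_bins = 3,
                             target_rate = 30, min_trials = 2) {
  lock_event <- match.arg(lock_event)
  features$group_label <- curve_groups(features, grouping, valence_cuts,
                                       n_bins)
  base <- features |>
    select("participant_id", "trial_id", "pretrial_baseline", "group_label")

  locked <- time_lock(clean_samples, trials, event = lock_event,
                      target_rate = target_rate) |>
    inner_join(base, by = c("participant_id", "trial_id")) |>
    mutate(pct = percent_change(.data$pupil_mm, .data$pretrial_baseline)) |>
    filter(!is.na(.data$pct))

  empty <- setdiff(unique(features$group_label),
                   unique(locked$group_label))
  if (length(empty)) {
    warn(sprintf("empty group(s) omitted: %s", paste(empty, collapse = ", ")))
  }

  out <- locked |>
    group_by(.data$group_label, .data$t_lock) |>
    summarise(mean_pct = mean(.data$pct),
              sd_pct = sd(.data$pct),
              n = dplyr::n(), .groups = "drop") |>
    filter(.data$n >= min_trials) |>
    mutate(sem_pct = .data$sd_pct / sqrt(.data$n)) |>
    select("group_label", "t_lock", "mean_pct", "sem_pct", "n") |>
    arrange(.data$group_label, .data$t_lock)
  attr(out, "lock_event") <- lock_event
  attr(out, "grouping") <- grouping
  class(out) <- c("pupil_curves", class(out))
  out
}
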