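#' Resting baseline of a participant
#'
#' Mean pupil diameter over the valid samples of a preprocessed resting
#' recording.
#'
#' @param series Data frame with `t_s`, `pupil_mm` (cleaned resting
#'   trace).
#' @param min_valid_s Minimum total duration of valid samples, s.
#' @return Mean diameter, mm.
#' @export
resting_baseline <- function(series, min_valid_s = 30) {
  check_series(series)
  ok <- !is.na(series$pupil_mm)
  dt <- median(diff(series$t_s))
  if (sum(ok) * dt < min_valid_s) {
    abort(sprintf("resting recording has < %g s of valid samples.",
                  min_valid_s))
  }
  mean(series$pupil_mm[ok])
}

#' Pre-trial baseline
#'
#' Mean pupil diameter over the window `[sound_onset - window,
#' sound_onset)` at the end of the foreperiod.
#'
#' @param series Data frame with `t_s`, `pupil_mm`.
#' @param sound_onset_s Sound onset, s (trial clock).
#' @param window Baseline window length, s (default 1.3).
#' @return Mean diameter, mm.
#' @export
pretrial_baseline <- function(series, sound_onset_s, window = 1.3) {
  check_series(series)
  sel <- series$t_s >= sound_onset_s - window & series$t_s < sound_onset_s
  if (!any(sel) || series$t_s[1] > sound_onset_s - window + 1e-9) {
    abort("insufficient samples before sound onset for the baseline window.")
  }
  mean(series$pupil_mm[sel], na.rm = TRUE)
}

#' Peak pupil dilation and its latency
#'
#' Maximum diameter over `[sound_onset, end]` with its time reported
#' relative to sound onset; ties are broken by the earliest sample.
#'
#' @param series Data frame with `t_s`, `pupil_mm`.
#' @param sound_onset_s Sound onset, s.
#' @param end_s End of the search window, s (default: end of trace).
#' @return One-row tibble: `peak_dilation` (mm, absolute diameter),
#'   `peak_time` (s from onset).
#' @export
extract_peak <- function(series, sound_onset_s, end_s = NULL) {
  check_series(series)
  end_s <- end_s %||% max(series$t_s)
  sel <- series$t_s >= sound_onset_s & series$t_s <= end_s
  d <- series$pupil_mm[sel]
  if (!any(!is.na(d))) abort("no valid samples in the peak search window.")
  i <- which.max(d)  # first index at the maximum: earliest-tie rule
  tibble(peak_dilation = d[i],
         peak_time = series$t_s[sel][i] - sound_onset_s)
}

#' Pre-peak dilation rate
#'
#' Slope of the rise to peak: peak height over peak latency. Trials
#' peaking earlier than `min_peak_time` are flagged `rate_excluded`
#' (ratios with near-zero denominators are outlier-prone), not dropped.
#'
#' @param peak_dilation Peak diameter, mm.
#' @param peak_time Peak latency from onset, s.
#' @param pretrial_baseline Pre-trial baseline, mm.
#' @param baseline_subtract Use peak height above baseline as the
#'   numerator (default); `FALSE` uses the absolute peak diameter.
#' @param min_peak_time Exclusion threshold for the latency, s.
#' @return One-row tibble: `dilation_rate` (mm/s), `rate_excluded`.
#' @export
dilation_rate <- function(peak_dilation, peak_time, pretrial_baseline,
                          baseline_subtract = TRUE, min_peak_time = 0.25) {
  num <- if (baseline_subtract) peak_dilation - pretrial_baseline else
    peak_dilation
  tibble(dilation_rate = ifelse(peak_time > 0, num / peak_time, NA_real_),
         rate_excluded = peak_time < min_peak_time)
}

#' Post-peak contraction rate
#'
#' Drop in diameter over a fixed window after the peak, divided by the
#' window length; positive values mean the pupil is shrinking. Flagged
#' unavailable when the recording ends less than `window` s after the
#' peak.
#'
#' @param series Data frame with `t_s`, `pupil_mm`.
#' @param peak_time_abs Peak time on the trial clock, s.
#' @param window Contraction window, s (default 2).
#' @return One-row tibble: `contraction_rate` (mm/s),
#'   `contraction_unavailable`.
#' @export
contraction_rate <- function(series, peak_time_abs, window = 2) {
  check_series(series)
  dt <- median(diff(series$t_s))
  if (max(series$t_s) < peak_time_abs + window - dt / 2) {
    return(tibble(contraction_rate = NA_real_,
                  contraction_unavailable = TRUE))
  }
  i0 <- which.min(abs(series$t_s - peak_time_abs))
  i1 <- which.min(abs(series$t_s - (peak_time_abs + window)))
  tibble(
    contraction_rate = (series$pupil_mm[i0] - series$pupil_mm[i1]) / window,
    contraction_unavailable = FALSE)
}

#' Percent change relative to a baseline
#'
#' @param pupil_mm Diameters, mm.
#' @param baseline Reference diameter, mm (> 0).
#' @return Percent change per sample: `100 * (d - baseline) / baseline`.
#' @export
#' @examples
#' percent_change(5.5, 5)
percent_change <- function(pupil_mm, baseline) {
  if (!is.numeric(baseline) || any(baseline <= 0)) {
    abort("`baseline` must be positive.")
  }
  100 * (pupil_mm - baseline) / baseline
}

#' Per-participant resting baselines for a resting table
#'
#' @param resting_clean Preprocessed resting tibble
#'   (`participant_id`, `t_s`, `pupil_mm`).
#' @param min_valid_s Passed to [resting_baseline()].
#' @return Tibble: `participant_id`, `resting_baseline` (mm).
#' @export
resting_baselines <- function(resting_clean, min_valid_s = 30) {
  resting_clean |>
    group_by(.data$participant_id) |>
    summarise(resting_baseline = resting_baseline(
      dplyr::pick("t_s", "pupil_mm"), min_valid_s = min_valid_s),
      .groups = "drop")
}

#' Pupil-response-curve statistics for every trial
#'
#' Computes, per trial, the baselines and the four curve statistics —
#' peak dilation, peak time, pre-peak dilation rate, post-peak
#' contraction rate — plus the response-to-peak lag, percent peak change
#' and the analysis flags, and joins the trial ratings (valence
#' intensity, confidence, duration).
#'
#' @param clean_samples Preprocessed sample tibble (30 Hz).
#' @param trials Trial table with events and ratings.
#' @param resting Per-participant resting baselines
#'   ([resting_baselines()] output) or a preprocessed resting table.
#' @param baseline_window Pre-trial baseline window, s.
#' @param contraction_window Post-peak window, s.
#' @param min_peak_time Dilation-rate exclusion threshold, s.
#' @param baseline_subtract Dilation-rate numerator convention, see
#'   [dilation_rate()].
#' @return Tibble with one row per trial (class `"trial_features"`).
#' @export
compute_features <- function(clean_samples, trials, resting,
                             baseline_window = 1.3, contraction_window = 2,
                             min_peak_time = 0.25, baseline_subtract = TRUE) {
  check_series(clean_samples,
               c("participant_id", "trial_id", "t_s", "pupil_mm"))
  if (!"resting_baseline" %in% names(resting)) {
    resting <- resting_baselines(resting)
  }

  keys <- paste(clean_samples$participant_id, clean_samples$trial_id,
                sep = "\r")
  parts <- split(seq_len(nrow(clean_samples)),
                 factor(keys, levels = unique(keys)))
  ev <- trials
  ev_key <- paste(ev$participant_id, ev$trial_id, sep = "\r")

  rows <- lapply(parts, function(idx) {
    s <- clean_samples[idx, , drop = FALSE]
    tr <- ev[match(paste(s$participant_id[1], s$trial_id[1], sep = "\r"),
                   ev_key), , drop = FALSE]
    if (nrow(tr) != 1L) return(NULL)
    onset <- tr$sound_onset_s
    pre <- tryCatch(pretrial_baseline(s, onset, window = baseline_window),
                    error = function(e) NA_real_)
    pk <- tryCatch(extract_peak(s, onset), error = function(e) NULL)
    if (is.null(pk) || is.na(pre)) return(NULL)
    dr <- dilation_rate(pk$peak_dilation, pk$peak_time, pre,
                        baseline_subtract = baseline_subtract,
                        min_peak_time = min_peak_time)
    cr <- contraction_rate(s, onset + pk$peak_time,
                           window = contraction_window)
    rt <- tr$response_s - onset
    tibble(
      participant_id = tr$participant_id,
      trial_id = tr$trial_id,
      pretrial_baseline = pre,
      peak_dilation = pk$peak_dilation,
      peak_time = pk$peak_time,
      dilation_rate = dr$dilation_rate,
      rate_excluded = dr$rate_excluded,
      contraction_rate = cr$contraction_rate,
      contraction_unavailable = cr$contraction_unavailable,
      response_time = rt,
      peak_lag = pk$peak_time - rt,
      percent_peak = percent_change(pk$peak_dilation, pre)
    )
  })

  feats <- bind_rows(rows) |>
    left_join(resting, by = "participant_id") |>
    mutate(baseline_ratio = .data$pretrial_baseline / .data$resting_baseline)

  meta <- trials |>
    select(dplyr::any_of(c("participant_id", "trial_id", "stimulus_id",
                           "emotion_category", "duration_s", "arrow_key",
                           "perceived_valence", "induced_valence",
                           "confidence")))
  out <- feats |>
    left_join(meta, by = c("participant_id", "trial_id")) |>
    mutate(
      valence_intensity = abs(.data$perceived_valence),
      valence_sign = sign(.data$perceived_valence)
    )
  class(out) <- c("trial_features", class(out))
  out
}
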