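#' Detect blink and artifact intervals in a pupil trace
#'
#' Flags runs of missing, zero/out-of-range, or jump-adjacent samples
#' (instantaneous diameter changes larger than `jump_threshold`, a device
#' artifact signature), extends each run by a symmetric padding margin,
#' and merges overlapping intervals. Intervals are half-open on the time
#' axis: `[start_s, end_s)`.
#'
#' @param series Data frame with columns `t_s` (s, uniform step) and
#'   `pupil_mm`.
#' @param pad Padding added to each side of a detected run, s.
#' @param jump_threshold Absolute between-sample diameter change (mm)
#'   above which both neighbouring samples are flagged.
#' @param diameter_limits Physiologically plausible open interval for
#'   valid diameters, mm.
#' @return Tibble with columns `start_s`, `end_s` (possibly zero rows).
#' @export
#' @examples
#' s <- tibble::tibble(t_s = (0:99) / 100, pupil_mm = 5)
#' s$pupil_mm[40:45] <- NA
#' detect_blinks(s)
detect_blinks <- function(series, pad = 0.05, jump_threshold = 1,
                          diameter_limits = c(0, 12)) {
  check_series(series)
  t_s <- series$t_s
  d <- series$pupil_mm
  n <- length(d)
  if (n == 0L) return(tibble(start_s = numeric(), end_s = numeric()))
  dt <- if (n > 1L) t_s[2] - t_s[1] else 0

  bad <- is.na(d) | d <= diameter_limits[1] | d >= diameter_limits[2]
  if (n > 1L && jump_threshold > 0) {
    jmp <- abs(diff(d)) > jump_threshold
    jmp[is.na(jmp)] <- FALSE
    bad[which(jmp)] <- TRUE
    bad[which(jmp) + 1L] <- TRUE
  }
  if (!any(bad)) return(tibble(start_s = numeric(), end_s = numeric()))

  r <- runs_of(bad)
  start_s <- t_s[r$start] - pad
  end_s <- t_s[r$end] + dt + pad
  # merge overlapping / touching padded intervals
  o <- order(start_s)
  start_s <- start_s[o]; end_s <- end_s[o]
  ms <- start_s[1]; me <- end_s[1]
  out_s <- numeric(); out_e <- numeric()
  for (i in seq_along(start_s)[-1]) {
    if (start_s[i] <= me) {
      me <- max(me, end_s[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start_s[i]; me <- end_s[i]
    }
  }
  tibble(start_s = c(out_s, ms), end_s = c(out_e, me))
}

#' Repair gap intervals by cubic-spline interpolation
#'
#' Replaces samples inside each interval with values from a cubic spline
#' fitted through valid anchor samples flanking the gap (`n_anchor` per
#' side, FMM end conditions, so traces that are locally polynomial up to
#' degree three are restored exactly). Anchors are spaced
#' `anchor_spacing` seconds apart rather than taken from adjacent
#' samples: end derivatives estimated from neighbouring samples amplify
#' measurement noise by the inverse sample step and make the spline
#' overshoot across the gap, inflating downstream peak estimates.
#' Samples outside the intervals are never altered. Gaps touching the
#' trace edge with fewer than two anchors on a side are left missing
#' with a warning.
#'
#' @param series Data frame with `t_s`, `pupil_mm`.
#' @param intervals Tibble from [detect_blinks()] (`start_s`, `end_s`).
#' @param n_anchor Valid anchor samples used on each side of a gap.
#' @param anchor_spacing Spacing between anchor samples, s.
#' @return The series tibble with `pupil_mm` repaired and a logical
#'   column `interpolated` marking replaced samples.
#' @export
interpolate_gaps <- function(series, intervals, n_anchor = 4,
                             anchor_spacing = 0.05) {
  check_series(series)
  series <- as_tibble(series)
  series$interpolated <- FALSE
  if (is.null(intervals) || nrow(intervals) == 0L) return(series)
  t_s <- series$t_s
  d <- series$pupil_mm

  in_any <- rep(FALSE, length(t_s))
  for (i in seq_len(nrow(intervals))) {
    in_any <- in_any | (t_s >= intervals$start_s[i] & t_s < intervals$end_s[i])
  }
  anchor_ok <- !in_any & !is.na(d)

  dt <- if (length(t_s) > 1L) t_s[2] - t_s[1] else anchor_spacing
  stride <- max(1L, as.integer(round(anchor_spacing / dt)))

  for (i in seq_len(nrow(intervals))) {
    inside <- which(t_s >= intervals$start_s[i] & t_s < intervals$end_s[i])
    if (!length(inside)) next
    left <- which(anchor_ok & t_s < intervals$start_s[i])
    right <- which(anchor_ok & t_s >= intervals$end_s[i])
    if (length(left) < 2L || length(right) < 2L) {
      warn(sprintf(
        "gap [%.3f, %.3f) touches the trace edge; samples left missing",
        intervals$start_s[i], intervals$end_s[i]))
      next
    }
    pick <- function(idx, from_end) {
      sel <- seq(1L, by = stride, length.out = n_anchor)
      ordered <- if (from_end) rev(idx) else idx
      sort(ordered[sel[sel <= length(ordered)]])
    }
    anchors <- c(pick(left, from_end = TRUE), pick(right, from_end = FALSE))
    fit <- spline(t_s[anchors], d[anchors], xout = t_s[inside],
                  method = "fmm")
    series$pupil_mm[inside] <- fit$y
    series$interpolated[inside] <- TRUE
  }
  series
}

#' Savitzky-Golay smoothing of a pupil trace
#'
#' Local least-squares polynomial smoothing over the full trace. A
#' filter of order `p` reproduces polynomial signal up to degree `p`
#' exactly, so the canonical window-21, order-3 setting denoises without
#' flattening the slow evoked response.
#'
#' @param series Data frame with `t_s`, `pupil_mm` (gaps already
#'   repaired).
#' @param window Filter window length, samples (odd).
#' @param order Polynomial order, < `window`.
#' @return The series tibble with smoothed `pupil_mm`.
#' @export
smooth_pupil <- function(series, window = 21, order = 3) {
  check_series(series)
  series <- as_tibble(series)
  n <- nrow(series)
  if (window %% 2 == 0) abort("`window` must be odd.")
  if (order >= window) abort("`order` must be smaller than `window`.")
  if (n < window) abort("trial shorter than the smoothing window.")
  d <- series$pupil_mm
  nas <- is.na(d)
  if (any(nas)) {
    # fill residual gaps for filtering only; restore missingness after
    filled <- approx(series$t_s[!nas], d[!nas], xout = series$t_s,
                     rule = 2)$y
    sm <- signal::sgolayfilt(filled, p = order, n = window)
    sm[nas] <- NA_real_
  } else {
    sm <- signal::sgolayfilt(d, p = order, n = window)
  }
  series$pupil_mm <- sm
  series
}

#' Downsample a pupil trace by decimation
#'
#' Keeps every k-th sample, where k is the (integer) ratio of native to
#' target rate. Applied after smoothing, which plays the anti-aliasing
#' role. Event timestamps are untouched (they live in the trial table).
#'
#' @param series Data frame with `t_s`, `pupil_mm`.
#' @param sample_rate Native rate, Hz; inferred from `t_s` when `NULL`.
#' @param target_rate Output rate, Hz.
#' @return The decimated series tibble.
#' @export
downsample_pupil <- function(series, sample_rate = NULL, target_rate = 30) {
  check_series(series)
  series <- as_tibble(series)
  if (is.null(sample_rate)) {
    sample_rate <- 1 / median(diff(series$t_s))
  }
  k <- sample_rate / target_rate
  if (abs(k - round(k)) > 1e-6) {
    abort("native rate must be an integer multiple of `target_rate`.")
  }
  series[seq(1L, nrow(series), by = as.integer(round(k))), , drop = FALSE]
}

#' Trial validity under the missing-data and gaze rules
#'
#' Computes the fraction of missing/artifact samples over the trial
#' window (before any interpolation) and applies the exclusion rules: a
#' trial is invalid when more than `max_missing` of its samples are bad
#' (strictly exceeded) or when gaze left the fixation target for longer
#' than `gaze_run_s`.
#'
#' @param series Data frame with `t_s`, `pupil_mm`, optionally
#'   `gaze_valid` (logical) and `gaze_dev_deg`.
#' @param max_missing Missing-fraction threshold (default 0.20).
#' @param gaze_dev_threshold Gaze deviation (degrees) counted as
#'   displaced when `gaze_dev_deg` is present.
#' @param gaze_run_s Minimum duration of a displaced-gaze run, s.
#' @param jump_threshold,diameter_limits Passed to the artifact
#'   definition (see [detect_blinks()]).
#' @return One-row tibble: `valid`, `missing_fraction`, `gaze_displaced`,
#'   `reason`.
#' @export
validate_trial <- function(series, max_missing = 0.20,
                           gaze_dev_threshold = 2, gaze_run_s = 0.1,
                           jump_threshold = 1, diameter_limits = c(0, 12)) {
  check_series(series)
  d <- series$pupil_mm
  n <- length(d)
  bad <- is.na(d) | d <= diameter_limits[1] | d >= diameter_limits[2]
  if (n > 1L && jump_threshold > 0) {
    jmp <- abs(diff(d)) > jump_threshold
    jmp[is.na(jmp)] <- FALSE
    bad[which(jmp)] <- TRUE
    bad[which(jmp) + 1L] <- TRUE
  }
  missing_fraction <- mean(bad)

  gaze_displaced <- FALSE
  dt <- if (n > 1L) series$t_s[2] - series$t_s[1] else 0
  displaced <- NULL
  if ("gaze_dev_deg" %in% names(series)) {
    displaced <- series$gaze_dev_deg > gaze_dev_threshold
  } else if ("gaze_valid" %in% names(series)) {
    displaced <- !series$gaze_valid
  }
  if (!is.null(displaced) && any(displaced, na.rm = TRUE)) {
    r <- runs_of(displaced)
    gaze_displaced <- any((r$end - r$start + 1L) * dt > gaze_run_s)
  }

  valid <- missing_fraction <= max_missing && !gaze_displaced
  reason <- if (valid) {
    "ok"
  } else if (missing_fraction > max_missing) {
    "missing_exceeds_20pct"
  } else {
    "gaze_displaced"
  }
  tibble(valid = valid, missing_fraction = missing_fraction,
         gaze_displaced = gaze_displaced, reason = reason)
}

preprocess_one <- function(series, sample_rate, target_rate, sg_window,
                           sg_order, pad, jump_threshold, n_anchor) {
  iv <- detect_blinks(series, pad = pad, jump_threshold = jump_threshold)
  s <- interpolate_gaps(series, iv, n_anchor = n_anchor)
  s <- smooth_pupil(s, window = sg_window, order = sg_order)
  downsample_pupil(s, sample_rate = sample_rate, target_rate = target_rate)
}

#' Preprocess a long-format sample table
#'
#' Runs the per-trial cleaning chain — blink detection, cubic-spline
#' repair, Savitzky-Golay smoothing, decimation to the target rate — for
#' every (participant, trial) trace in a long sample table.
#'
#' @param samples Tibble with `participant_id`, `trial_id`, `t_s`,
#'   `pupil_mm` and optional gaze columns.
#' @param sample_rate Native rate, Hz.
#' @param target_rate Output rate, Hz.
#' @param sg_window,sg_order Savitzky-Golay settings.
#' @param pad Blink padding, s.
#' @param jump_threshold Artifact jump threshold, mm.
#' @param n_anchor Spline anchors per gap side.
#' @return Tibble of cleaned samples at `target_rate` with an
#'   `interpolated` flag.
#' @export
preprocess_samples <- function(samples, sample_rate = 120, target_rate = 30,
                               sg_window = 21, sg_order = 3, pad = 0.05,
                               jump_threshold = 1, n_anchor = 4) {
  check_series(samples, c("participant_id", "trial_id", "t_s", "pupil_mm"))
  keys <- paste(samples$participant_id, samples$trial_id, sep = "\r")
  parts <- split(seq_len(nrow(samples)), factor(keys, levels = unique(keys)))
  out <- lapply(parts, function(idx) {
    preprocess_one(samples[idx, , drop = FALSE], sample_rate, target_rate,
                   sg_window, sg_order, pad, jump_threshold, n_anchor)
  })
  bind_rows(out)
}

#' Preprocess per-participant resting recordings
#'
#' Same cleaning chain as [preprocess_samples()] applied to the resting
#' table (one continuous trace per participant).
#'
#' @inheritParams preprocess_samples
#' @param resting Tibble with `participant_id`, `t_s`, `pupil_mm`.
#' @return Tibble of cleaned resting samples at `target_rate`.
#' @export
preprocess_resting <- function(resting, sample_rate = 120, target_rate = 30,
                               sg_window = 21, sg_order = 3, pad = 0.05,
                               jump_threshold = 1, n_anchor = 4) {
  check_series(resting, c("participant_id", "t_s", "pupil_mm"))
  parts <- split(seq_len(nrow(resting)),
                 factor(resting$participant_id,
                        levels = unique(resting$participant_id)))
  out <- lapply(parts, function(idx) {
    preprocess_one(resting[idx, , drop = FALSE], sample_rate, target_rate,
                   sg_window, sg_order, pad, jump_threshold, n_anchor)
  })
  bind_rows(out)
}

#' Validate every trial in a sample table
#'
#' Applies [validate_trial()] per (participant, trial) on the raw
#' (pre-interpolation) samples.
#'
#' @param samples Raw long-format sample tibble.
#' @param ... Passed to [validate_trial()].
#' @return Tibble with one row per trial: ids plus the validity fields.
#' @export
validate_trials <- function(samples, ...) {
  check_series(samples, c("participant_id", "trial_id", "t_s", "pupil_mm"))
  samples |>
    group_by(.data$participant_id, .data$trial_id) |>
    dplyr::group_modify(function(s, key) validate_trial(s, ...)) |>
    ungroup()
}
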