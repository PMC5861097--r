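default_predictors <- function(outcome) {
  base <- c("valence_intensity", "confidence", "duration",
            "response_time", "pretrial_baseline")
  switch(outcome,
         contraction_rate = c(base, "peak_dilation"),
         response_time = "duration",
         base)
}

predictor_column <- function(p) {
  switch(p, duration = "duration_s", p)
}

#' Mixed-effects regression of a pupil-curve statistic
#'
#' Fits a Gaussian linear mixed model of one trial-level curve statistic
#' on \[0, 1\]-scaled predictors with a random intercept per participant,
#' by maximum likelihood. Each coefficient is the expected change in the
#' outcome over the predictor's full stated range, which makes fitted
#' values directly comparable across predictors. Significance of each
#' predictor is assessed by a likelihood-ratio test against the model
#' without it; 95% intervals come from the profile likelihood (Wald on
#' request or when profiling fails).
#'
#' Outcome-specific exclusions are applied automatically: trials flagged
#' `rate_excluded` are dropped for `dilation_rate`, trials flagged
#' `contraction_unavailable` for `contraction_rate`.
#'
#' @param features [compute_features()] output.
#' @param outcome One of `peak_dilation`, `peak_time`, `dilation_rate`,
#'   `contraction_rate`, `peak_lag`, `response_time`.
#' @param predictors Character vector of predictor names; defaults
#'   depend on the outcome (the five standard predictors, plus
#'   `peak_dilation` for the contraction model).
#' @param scaling_ranges Named list of `c(lo, hi)` ranges; see
#'   [pc_scaling_ranges()].
#' @param conf_method `"profile"` (default) or `"Wald"`.
#' @return Object of class `"pupil_model"`; see [tidy.pupil_model()].
#' @export
fit_feature_model <- function(features, outcome,
                              predictors = NULL,
                              scaling_ranges = pc_scaling_ranges(),
                              conf_method = c("profile", "Wald")) {
  conf_method <- match.arg(conf_method)
  outcomes <- c("peak_dilation", "peak_time", "dilation_rate",
                "contraction_rate", "peak_lag", "response_time")
  if (!outcome %in% outcomes) {
    abort(sprintf("`outcome` must be one of: %s",
                  paste(outcomes, collapse = ", ")))
  }
  predictors <- predictors %||% default_predictors(outcome)

  dat <- as_tibble(features)
  if (outcome == "dilation_rate" && "rate_excluded" %in% names(dat)) {
    dat <- dat |> filter(!.data$rate_excluded)
  }
  if (outcome == "contraction_rate" &&
      "contraction_unavailable" %in% names(dat)) {
    dat <- dat |> filter(!.data$contraction_unavailable)
  }

  mf <- tibble(.y = dat[[outcome]], .participant = dat$participant_id)
  for (p in predictors) {
    col <- predictor_column(p)
    if (!col %in% names(dat)) {
      abort(sprintf("predictor `%s` (column `%s`) not found.", p, col))
    }
    x <- dat[[col]]
    if (p %in% names(scaling_ranges)) {
      x <- scale_range(x, scaling_ranges[[p]])
    } else if (is.character(x)) {
      x <- as.numeric(factor(x)) - 1
    }
    mf[[p]] <- x
  }
  mf <- mf[complete.cases(mf), ]
  if (length(unique(mf$.participant)) < 2L) {
    abort("need at least 2 participants.")
  }

  fml <- as.formula(paste(".y ~", paste(predictors, collapse = " + "),
                          "+ (1 | .participant)"))
  fit <- lme4::lmer(fml, data = mf, REML = FALSE)
  singular <- lme4::isSingular(fit)

  est <- lme4::fixef(fit)[predictors]

  ci <- NULL
  if (conf_method == "profile") {
    ci <- tryCatch(
      suppressMessages(stats::confint(fit, parm = "beta_",
                                      method = "profile", quiet = TRUE)),
      error = function(e) NULL)
  }
  if (is.null(ci)) {
    ci <- suppressMessages(stats::confint(fit, parm = "beta_",
                                          method = "Wald"))
    conf_method <- "Wald"
  }
  ci <- ci[predictors, , drop = FALSE]

  lrt <- purrr::map(predictors, function(p) {
    red <- update(fit, as.formula(paste(". ~ . -", p)))
    likelihood_ratio_test(fit, red)
  })
  lrt <- bind_rows(lrt)

  coefs <- tibble(
    term = predictors,
    estimate = unname(est),
    conf.low = ci[, 1],
    conf.high = ci[, 2],
    statistic = lrt$L,
    df = lrt$df,
    p.value = lrt$p.value
  )

  structure(list(
    fit = fit,
    coefficients = coefs,
    outcome = outcome,
    predictors = predictors,
    scaling_ranges = scaling_ranges,
    fit_method = "ml_lrt",
    conf_method = conf_method,
    singular = singular,
    n_obs = nrow(mf),
    n_groups = length(unique(mf$.participant))
  ), class = "pupil_model")
}

#' Likelihood-ratio test of two nested model fits
#'
#' `L = 2 * (logLik_full - logLik_reduced)` referred to a chi-squared
#' distribution with df equal to the number of dropped parameters. The
#' reduced model must be nested in the full model and fitted to the same
#' rows.
#'
#' @param full,reduced Fitted models (`lmerMod`, `lm`, or
#'   `"pupil_model"`).
#' @return One-row tibble: `L`, `df`, `p.value`.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  get_fit <- function(m) if (inherits(m, "pupil_model")) m$fit else m
  full <- get_fit(full); reduced <- get_fit(reduced)
  n_full <- stats::nobs(full); n_red <- stats::nobs(reduced)
  if (n_full != n_red) {
    abort("models were fitted to different numbers of rows.")
  }
  tf <- attr(stats::terms(full), "term.labels")
  tr <- attr(stats::terms(reduced), "term.labels")
  if (!all(tr %in% tf)) {
    abort("`reduced` is not nested in `full`.")
  }
  ll_f <- logLik(full); ll_r <- logLik(reduced)
  df <- attr(ll_f, "df") - attr(ll_r, "df")
  if (df < 0) abort("`reduced` has more parameters than `full`.")
  L <- max(0, 2 * (as.numeric(ll_f) - as.numeric(ll_r)))
  p <- if (df == 0) 1 else pchisq(L, df = df, lower.tail = FALSE)
  tibble(L = L, df = df, p.value = p)
}

#' @export
print.pupil_model <- function(x, ...) {
  cat(sprintf(
    "Mixed model of %s (%d trials, %d participants; ML + LRT, %s CIs%s)\n",
    x$outcome, x$n_obs, x$n_groups, x$conf_method,
    if (x$singular) "; singular random-effect fit" else ""))
  print(x$coefficients, ...)
  invisible(x)
}

#' Tidy a fitted pupil-curve model
#'
#' @param x A `"pupil_model"`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `conf.low`, `conf.high`,
#'   `statistic` (LRT L), `df`, `p.value`; estimates are on the
#'   scaled-predictor metric (outcome units per full predictor range).
#' @method tidy pupil_model
#' @export
tidy.pupil_model <- function(x, ...) {
  x$coefficients
}

#' One-row summary of a fitted pupil-curve model
#'
#' @param x A `"pupil_model"`.
#' @param ... Unused.
#' @return Tibble: `outcome`, `n_obs`, `n_groups`, `logLik`, `AIC`,
#'   `sigma`, `singular`, `fit_method`.
#' @method glance pupil_model
#' @export
glance.pupil_model <- function(x, ...) {
  tibble(outcome = x$outcome, n_obs = x$n_obs, n_groups = x$n_groups,
         logLik = as.numeric(logLik(x$fit)), AIC = stats::AIC(x$fit),
         sigma = stats::sigma(x$fit), singular = x$singular,
         fit_method = x$fit_method)
}

#' Mixed beta regression of valence ratings
#'
#' Models perceived and induced valence ratings jointly on the open unit
#' interval with a beta-distributed response, an emotion-by-rating-type
#' interaction, and crossed random intercepts for participant and
#' stimulus. Ratings are mapped from the -50..+50 scale to (0, 1) with
#' the boundary compression `y' = (y * (n - 1) + 0.5) / n`. Fitted
#' per-emotion central valences with 95% intervals are returned on the
#' -50..+50 scale for each rating type.
#'
#' @param trials Trial table with `perceived_valence`, `induced_valence`,
#'   `emotion_category`, `participant_id`, `stimulus_id`.
#' @return Object of class `"pupil_rating_model"` with elements `fit`
#'   (glmmTMB) and `fitted` (per emotion x type tibble).
#' @export
fit_rating_model <- function(trials) {
  need <- c("participant_id", "stimulus_id", "emotion_category",
            "perceived_valence", "induced_valence")
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    abort(sprintf("trial table is missing: %s", paste(miss, collapse = ", ")))
  }
  long <- trials |>
    select(dplyr::all_of(need)) |>
    tidyr::pivot_longer(c("perceived_valence", "induced_valence"),
                        names_to = "valence_type", values_to = "valence") |>
    mutate(valence_type = sub("_valence$", "", .data$valence_type))
  n <- nrow(long)
  long$y <- ((long$valence + 50) / 100 * (n - 1) + 0.5) / n

  # degenerate designs (a single emotion level) drop the interaction
  fixed <- if (length(unique(long$emotion_category)) > 1L) {
    "emotion_category * valence_type"
  } else {
    "valence_type"
  }
  fit <- glmmTMB::glmmTMB(
    as.formula(paste("y ~", fixed,
                     "+ (1 | participant_id) + (1 | stimulus_id)")),
    family = glmmTMB::beta_family(), data = long)

  spec_rhs <- if (grepl("emotion", fixed)) {
    ~ emotion_category | valence_type
  } else {
    ~ valence_type
  }
  emm <- emmeans::emmeans(fit, spec_rhs, type = "response")
  fitted <- as_tibble(as.data.frame(emm))
  if (!"emotion_category" %in% names(fitted)) {
    fitted$emotion_category <- unique(long$emotion_category)
  }
  fitted <- fitted |>
    rename(emotion = "emotion_category") |>
    mutate(valence_fit = 100 * .data$response - 50,
           conf.low = 100 * .data$asymp.LCL - 50,
           conf.high = 100 * .data$asymp.UCL - 50) |>
    select("emotion", "valence_type", "valence_fit", "conf.low",
           "conf.high")

  structure(list(fit = fit, fitted = fitted),
            class = "pupil_rating_model")
}

#' @export
print.pupil_rating_model <- function(x, ...) {
  cat("Mixed beta regression of valence ratings",
      "(emotion x type, random intercepts: participant, stimulus)\n")
  print(x$fitted, ...)
  invisible(x)
}

#' @rdname fit_rating_model
#' @param x A `"pupil_rating_model"`.
#' @param ... Unused.
#' @method tidy pupil_rating_model
#' @export
tidy.pupil_rating_model <- function(x, ...) {
  x$fitted
}

#' Smooth time-by-valence response surface
#'
#' Fits a generalized additive model of percent pupil change, locked to
#' the response keypress, with a single bivariate smooth over (time,
#' perceived valence) and a linear term for the pre-trial baseline, and
#' returns predictions over a rectangular (time, valence) grid at the
#' mean baseline.
#'
#' @param clean_samples Preprocessed sample tibble.
#' @param features [compute_features()] output.
#' @param trials Trial table.
#' @param time_range Window around the keypress to fit, s.
#' @param k Basis dimension of the tensor-product smooth.
#' @param max_rows Sample rows are thinned deterministically to at most
#'   this many before fitting.
#' @param grid_n Grid resolution per axis for predictions.
#' @return Object of class `"pupil_surface"`: `fit` (gam) and `grid`
#'   (tibble `t_lock`, `valence`, `pct_fit`).
#' @export
fit_response_surface <- function(clean_samples, features, trials,
                                 time_range = c(-3, 3), k = 30,
                                 max_rows = 20000, grid_n = 41) {
  base <- features |>
    select("participant_id", "trial_id", "pretrial_baseline",
           "perceived_valence")
  dat <- time_lock(clean_samples, trials, event = "response_keypress") |>
    inner_join(base, by = c("participant_id", "trial_id")) |>
    filter(.data$t_lock >= time_range[1], .data$t_lock <= time_range[2]) |>
    mutate(pct = percent_change(.data$pupil_mm, .data$pretrial_baseline)) |>
    filter(!is.na(.data$pct))
  if (nrow(dat) > max_rows) {
    dat <- dat[unique(as.integer(round(
      seq(1, nrow(dat), length.out = max_rows)))), ]
  }

  grid <- tidyr::expand_grid(
    t_lock = seq(time_range[1], time_range[2], length.out = grid_n),
    perceived_valence = seq(-50, 50, length.out = grid_n)) |>
    mutate(pretrial_baseline = mean(dat$pretrial_baseline))

  # a degenerate (constant) response admits only the flat surface
  if (stats::var(dat$pct) < 1e-12) {
    grid$pct_fit <- mean(dat$pct)
    return(structure(
      list(fit = NULL,
           grid = grid |> select("t_lock", "perceived_valence",
                                 "pct_fit")),
      class = "pupil_surface"))
  }

  # a near-constant baseline is collinear with the intercept
  with_baseline <- stats::var(dat$pretrial_baseline) > 1e-10
  fit_once <- function(kk) {
    fml <- if (with_baseline) {
      pct ~ te(t_lock, perceived_valence, k = kk) + pretrial_baseline
    } else {
      pct ~ te(t_lock, perceived_valence, k = kk)
    }
    mgcv::gam(fml, data = dat, method = "REML")
  }
  kk <- max(3, floor(sqrt(k)))
  fit <- tryCatch(fit_once(kk), error = function(e) {
    warn(sprintf("smooth basis reduced after: %s", conditionMessage(e)))
    fit_once(max(3, kk - 2))
  })

  grid$pct_fit <- as.numeric(predict(fit, newdata = grid))

  structure(list(fit = fit,
                 grid = grid |> select("t_lock", "perceived_valence",
                                       "pct_fit")),
            class = "pupil_surface")
}

#' @export
print.pupil_surface <- function(x, ...) {
  rng <- range(x$grid$pct_fit)
  cat(sprintf(
    "Time x valence pupil surface: fitted %% change in [%.2f, %.2f]%s\n",
    rng[1], rng[2],
    if (is.null(x$fit)) " (degenerate constant input)" else ""))
  invisible(x)
}

#' Simulation-based parameter recovery
#'
#' For each replicate: simulate a dataset from `config` (seed advanced
#' per replicate), run the full pipeline (validate, preprocess, extract
#' features), fit the peak-dilation mixed model, and compare the
#' recovered scaled coefficients with the generative effect sizes.
#'
#' @param config A [sim_config()].
#' @param n_replicates Number of simulated studies.
#' @param conf_method Interval method passed to [fit_feature_model()].
#' @return Tibble with one row per coefficient: `term`, `truth`, `bias`,
#'   `rmse`, `coverage` (fraction of replicates whose 95% interval
#'   covered the truth). Per-replicate estimates are attached as
#'   attribute `"replicates"`.
#' @export
recover_parameters <- function(config, n_replicates = 3,
                               conf_method = "Wald") {
  truth <- c(valence_intensity = unname(config$effect_sizes["valence_intensity"]),
             confidence = unname(config$effect_sizes["confidence"]),
             duration = unname(config$effect_sizes["duration"]),
             response_time = unname(config$effect_sizes["response_time"]),
             pretrial_baseline = unname(config$effect_sizes["baseline"]))
  base_seed <- config$seed %||% 1L

  reps <- purrr::map(seq_len(n_replicates), function(r) {
    cfg <- config
    cfg$seed <- base_seed + r - 1L
    ds <- simulate_dataset(cfg)
    validity <- validate_trials(ds$samples)
    keep <- validity |> filter(.data$valid) |>
      select("participant_id", "trial_id")
    samples <- ds$samples |>
      inner_join(keep, by = c("participant_id", "trial_id"))
    clean <- preprocess_samples(samples, sample_rate = cfg$sample_rate)
    rest <- preprocess_resting(ds$resting, sample_rate = cfg$sample_rate)
    feats <- compute_features(clean, ds$trials, resting_baselines(rest))
    m <- fit_feature_model(feats, "peak_dilation",
                           conf_method = conf_method)
    tidy(m) |> mutate(replicate = r)
  })
  reps <- bind_rows(reps) |>
    mutate(truth = truth[.data$term])

  out <- reps |>
    group_by(.data$term) |>
    summarise(truth = first(.data$truth),
              bias = mean(.data$estimate - .data$truth),
              rmse = sqrt(mean((.data$estimate - .data$truth)^2)),
              coverage = mean(.data$conf.low <= .data$truth &
                                .data$truth <= .data$conf.high),
              .groups = "drop")
  attr(out, "replicates") <- reps
  out
}
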