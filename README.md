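# pupilcurve

Analysis of task-evoked pupillary responses (TEPRs) during perceptual
decisions about emotional stimuli, for psychophysiologists working with
eye-tracking data. When a listener judges the emotional valence of a
nonverbal vocalization under isoluminant conditions, the pupil dilates
slowly while evidence accumulates, peaks shortly after the decision
keypress, and contracts back to baseline. `pupilcurve` turns raw
eye-tracker samples — real recordings via a documented CSV contract, or
simulated studies with a known effect structure — into cleaned traces,
per-trial curve statistics, event-locked grand-average curves, and
mixed-effects estimates of what shapes the response.

## The model at the core

Each trial yields four curve statistics: peak dilation, peak latency,
pre-peak dilation rate (peak height over latency) and post-peak
contraction rate (diameter drop over 2 s). Each is modelled as a
Gaussian linear mixed regression on predictors scaled to their observed
ranges,

```
y_ij = beta_0 + beta_VI * VI_ij/50 + beta_C * C_ij/100
     + beta_D * (D_ij - 0.5)/5.5 + beta_RT * (RT_ij - 0.6)/8.4
     + beta_B * (B_ij - 3)/4 + u_i + e_ij,     u_i ~ N(0, tau^2)
```

with a random intercept `u_i` per participant. `VI` is valence intensity
(|rating| on the −50..+50 scale), `C` confidence, `D` sound duration,
`RT` response time, `B` the pre-trial baseline diameter (mean over the
1.3 s before onset). Because predictors are range-scaled, each
coefficient reads directly as "mm of extra peak dilation across this
predictor's full range". Significance comes from likelihood-ratio tests
of nested ML fits; 95% intervals from the profile likelihood.

Preprocessing follows the standard pupillometry chain: blink/artifact
detection (missing samples, >1 mm jumps; 50 ms padding), cubic-spline
repair through spaced anchor samples, Savitzky–Golay smoothing
(window 21, order 3), decimation 120 Hz → 30 Hz, and exclusion of trials
with more than 20% bad samples or displaced gaze. The simulator
generates decision-locked dilations as an attention boxcar (onset →
keypress) convolved with an Erlang pupil kernel, on top of AR(1) + white
noise, with blinks, dropouts, a non-ageing 5–11 s foreperiod and a
72-sound, eight-category stimulus set.

## Worked example

Simulate a small study, run the pipeline, and fit the peak-dilation
model:

```r
library(pupilcurve)

res <- run_pipeline(list(
  simulate  = list(n_participants = 8, n_trials_per_participant = 48,
                   seed = 1),
  aggregate = list(lock_events = "response_keypress",
                   groupings = "valence_sign"),
  model     = list(outcomes = "peak_dilation")))

res
#> Pupillometry pipeline results: 384 trials (4.4% excluded), 1 curve set(s), 1 model(s)

res$model_fits$peak_dilation
#> Mixed model of peak_dilation (367 trials, 8 participants; ML + LRT, profile CIs)
#> # A tibble: 5 x 7
#>   term              estimate conf.low conf.high statistic    df   p.value
#>   <chr>                <dbl>    <dbl>     <dbl>     <dbl> <int>     <dbl>
#> 1 valence_intensity   0.0402  -0.0192   0.0997       1.77     1 1.84e-  1
#> 2 confidence         -0.0958  -0.184   -0.00770      4.54     1 3.31e-  2
#> 3 duration            0.191    0.0730   0.310        9.95     1 1.61e-  3
#> 4 response_time       0.444    0.124    0.764        7.36     1 6.68e-  3
#> 5 pretrial_baseline   2.28     2.15     2.41       530.       1 2.95e-117
```

Reading the output: with only 8 participants the study is underpowered
for the small valence-intensity effect (0.04 mm over the full intensity
range, p = 0.18), while the strong dependence of peak diameter on the
pre-trial baseline (2.28 mm over the 3–7 mm range — below the mechanical
4.0 mm passthrough, i.e. a ceiling effect on the evoked response) and
the duration and response-time effects are already clear. Derived
summaries carry their defining identities:

```r
f <- res$features
mean(f$baseline_ratio)   # pre-trial / resting baseline
#> 0.991
mean(f$peak_lag)         # keypress -> peak, seconds
#> 0.32
```

so the pupil peaks about a third of a second after the decision is
expressed. `autoplot(res$curves[[1]])` draws the decision-locked
grand-average percent-change curves with SEM ribbons;
`fit_rating_model()`, `fit_response_surface()` and `autoplot()` on their
results reproduce the per-emotion rating panels and the time-by-valence
surface. `tidy()` and `glance()` work on every fitted model object. Real
recordings enter through `read_dataset()` (samples/trials/resting CSVs;
see `?read_dataset` for the column contract).

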