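# spindlepp — point-process GLMs for sleep-spindle timing

Sleep spindles are brief (~10–16 Hz) oscillatory bursts in the NREM-sleep
EEG, reduced here to a point event per spindle. Their moment-to-moment
occurrence is shaped simultaneously by sleep stage, the phase and power of
the cortical slow oscillation (SO, 0.4–1.5 Hz), and — dominantly — by the
timing of the previous spindle itself (a refractory period followed by a
window of rebound excitation). `spindlepp` models all of these influences
jointly so that their separate contributions, interactions and goodness of
fit can be quantified per recording, and then compared across a population.

## The model

The spindle train is a temporal point process with conditional intensity
λ(t|Hₜ) (instantaneous spindle density, events/s, given the event history
Hₜ). On a discrete grid of width Δ = 0.1 s, the binary bin counts are fitted
as a Poisson GLM with log link and exposure Δ:

```
log λ(t|Hₜ) = Σ_s β_s I_s(t)                      sleep stage (one-hot)
            + β₁ cos φₜ + β₂ sin φₜ               SO phase
            + Σ_s I_s(t)[β_{s,1} cos φₜ + β_{s,2} sin φₜ]   stage×phase
            [ + α₁ SOP(t) + α₂ SOP(t)²  ]          quadratic SO power
            [ + SOP(t)(γ₁ cos φₜ + γ₂ sin φₜ) ]    SOP×phase
            + Σ_k h_k g_k(Hₜ)                      spline history
```

The phase pair is equivalent to `M·cos(φ − φ_pref)` with coupling magnitude
`M = √(β₁²+β₂²)` and preferred phase `φ_pref = atan2(β₂, β₁)` (phase 0 = SO
peak / up-state). The `g_k` are cardinal-spline (Catmull-Rom) interpolation
basis functions of the lag since the most recent previous spindle, with
knots dense over 0–15 s (optionally extended to 90 s to cover infraslow,
~0.02 Hz, dynamics); `exp(Σ h_k g_k(lag))` is the *history modulation
curve*: the multiplicative effect on the rate of having had a spindle `lag`
seconds ago.

On top of the fit, the package provides: history-curve summary features
(refractory period, excitatory period, peak height/time, infraslow
multiplier over 40–70 s lags), stage- and depth-resolved phase coupling
with circular delta-method CIs, nested-model χ² tests, deviance
decomposition (sequential and single-factor), a phase/history synergy index
in bits/event, time-rescaling Kolmogorov–Smirnov goodness of fit, and
population tools (curve Pearson correlations, Welch t tests with Bonferroni
correction, Watson–Williams circular tests, global max-|t| permutation
tests on curve families). A registered synthetic-night generator
(`paper_like_scenario()`) produces hypnograms, SO covariates and
history-dependent spindle trains from known parameters, so every estimator
has a parameter-recovery test surface without any data download.

## Worked example

```r
library(spindlepp)
scenario <- paper_like_scenario("paper_default")   # 8-h night, N2 ≈ 11/min
night <- simulate_night(scenario, seed = 42)
night
#> <recording_bundle> 'paper_default': 3553 events over 8.0 h

fit <- fit_point_process_glm(
  build_design_matrix(night$cov, parse_spec_token("full")))
fit
#> <spindle_ppglm> stage + phase + stage_phase + history | 3553 events in 288000 bins (dt = 0.1 s)
#>   logLik -17545.48, deviance 27984.96, 30 estimated coefficients (2 constrained to 0)

extract_history_features(history_modulation_curve(fit))
#> <history_features> refractory 1.71 s | excitatory 5.14 s | peak 2.12 at 3.40 s | ...

phase_tuning(fit, "N2")
#> <phase_coupling> N2: M = 0.218, phi_pref = 0.065 rad (95% CI half-width 0.239 rad)

time_rescaling_ks(fit, night$train, night$cov)
#> <gof_result> KS = 0.0141 on 3552 intervals (5% band 0.0228): PASS
```

The fitted night was generated with a 1.8-s refractory period, a history
peak of 1.9 at 3.5 s and an N2 preferred phase of 0; the single-night
estimates above scatter around those values, and averaging over replicates
recovers them (see `tests/testthat/test-acceptance.R`). The history
likelihood-ratio test on this night gives χ² = 1760.3 on 15 df — history
dependence carries most of the timing information, which is also what the
deviance decomposition shows (`single_factor_fractions()`).

## Analysis workflow

`analysis/01_simulate_nights.R` … `06_population.R` is a numbered driver
sequence over the package: simulate a two-group synthetic cohort (12
subjects × 2 nights), fit the model menu to every night, extract history
curves/features and phase coupling, compare factor contributions (deviance
fractions, χ² pervasiveness, KS pass rates, synergy), and run the
population comparisons (intra- vs inter-subject curve correlations, group
feature tests, global permutation tests). Each script prints what it found
and writes tables/figures under `results/`.

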