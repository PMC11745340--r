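---
title: "Modeling sleep-spindle timing with point-process GLMs"
author: "spindlepp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling sleep-spindle timing with point-process GLMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its assumptions

`spindlepp` treats the spindles of one recording as a temporal point
process and models the conditional intensity λ(t|Hₜ) — the instantaneous
spindle rate given everything observed up to t — as log-linear in a set of
covariate terms: per-stage baselines, a cosine-tuned slow-oscillation (SO)
phase term, stage×phase offsets, optionally a quadratic function of
normalized SO power (SOP) with an SOP×phase interaction, and a spline
expansion of the lag since the previous spindle.

The assumptions worth keeping in mind:

* **Discrete-time likelihood.** The night is binned at Δ = 0.1 s and the
  0/1 bin counts are fitted as Poisson with exposure Δ (log link). This is
  the standard approximation of the continuous point-process likelihood and
  is accurate while λΔ ≪ 1; at typical spindle rates λΔ stays below ~0.05.
  Δ = 0.1 s is much finer than the shortest structure of interest (the
  ~1.8-s refractory period) while keeping an 8-h night at ~3 × 10⁵ bins,
  which fits comfortably in memory and fits in about two seconds with the
  package's Newton/IRLS optimizer (exact IRLS for the canonical link, with
  step halving; validated in the tests against `glm.fit` and a direct
  likelihood optimization).
* **Renewal-style history.** The history term depends on the lag since the
  most recent event only, evaluated causally: the lag for a bin is measured
  from the last event strictly before the bin start to the bin center. The
  synthetic generator uses the same convention by default
  (`history_mode = "last"`), and offers a summed-kernel variant
  (`history_mode = "sum"`, all in-range past events add on the log scale)
  as a robustness condition in which the fitted model is deliberately
  misspecified.
* **One history curve per night.** No stage×history interaction is fitted;
  the history structure is assumed stage-invariant (spindle rates outside
  N2/N3 are near zero, so those stages contribute little history
  information either way).

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| model bin Δ | 0.1 s | λΔ ≪ 1; refractory scale ≫ Δ |
| simulation bin | 0.05 s | keeps P(2 events/bin) negligible in generation |
| SO band | 0.4–1.5 Hz | standard slow-oscillation band |
| SOP band / window | 0.3–1.5 Hz, 4 s | resolves the band; dB scale |
| short history knots | 0, 0.5, …, 15 s (15 knots) | dense where refractory/excitatory structure lives |
| long history knots | + 20, 30, 40, 50, 60, 75, 90 s | sparse coverage of the infraslow range |
| spline tension | 0.5 | Catmull-Rom interpolation |
| CI level | 95 % everywhere | convention |

The cardinal-spline basis interpolates its control values: the fitted curve
passes exactly through (knot, hₖ), weights at any interior lag sum to 1,
and the basis is identically 0 beyond the last knot so the multiplicative
modulation returns to exactly 1 at long lags.

## Identifiability of the stage×phase block

The model equation carries a global phase pair *and* a phase pair for every
stage; together these are rank-deficient (the stage indicators sum to one).
The design matrix keeps the full block so that its column layout matches
the equation term for term, and the fitter resolves the aliasing by
constraining the interaction pair of the *reference stage* — the occupied
stage with the most events, N2 in practice — to zero. Stage-specific
coupling is then read out as (β₁+β_{s,1}, β₂+β_{s,2}), which for the
reference stage is just the global pair. Stages with zero scored time are
dropped entirely (with a warning), and stages with a handful of events are
handled by a Levenberg ridge fallback in the Newton iteration: their
baselines drift toward −∞ along a flat likelihood direction, their standard
errors blow up accordingly, and the phase-coupling read-out flags them as
having "no statistically relevant preferred phase" when the CI arc reaches
2π.

## Read-outs and their numerical choices

* **History modulation curve**: exp of the fitted spline, with pointwise
  95% CIs from the delta method on the history-coefficient covariance
  (`exp(linear ± 1.96 SE)`). No simultaneous-band correction is applied;
  the curve CIs are pointwise by design and documented as such.
* **Features**: the refractory period is the length of the maximal run
  *starting at lag 0* with upper CI < 1; the excitatory period is the
  longest run anywhere with lower CI > 1 (runs are not required to be
  contiguous with the main peak — the longest-run rule decides ties); the
  peak is the modulation maximum inside that run. All crossings of 1 are
  located by linear interpolation between grid points, so halving the grid
  step moves features by less than a coarse step.
* **Infraslow multiplier**: trapezoidal mean of the 90-s curve over lags
  40–70 s; exactly 1 for a null curve.
* **Preferred phase**: φ_pref = atan2 of the effective pair, with a
  delta-method CI on the angle. Along a SOP grid the curve is unwrapped
  before CI construction (and re-wrapped for reporting) to avoid ±π seam
  artifacts. Angular CIs use the delta method rather than resampling; a CI
  arc of width ≥ 2π is reported as "none".
* **Deviance decomposition**: sequential fractions telescope to 100% by
  construction and depend on the factor ordering, which is recorded in the
  output; single-factor fractions (each factor alone over the null) are
  computed alongside so both views are always available.
* **Synergy index**: per-event log-likelihood gains over the null in
  bits/event; index = (I_AB − I_A − I_B)/I_AB. It is exactly 0 when the
  gains are additive, −I_A/I_AB for a duplicated covariate, and its
  distribution across independently generated nights is centered at 0.
  This deviance-based definition satisfies the zero-at-independence
  property; other normalizations exist in the information-theoretic
  literature and could differ by a monotone factor.
* **Goodness of fit**: inter-event intervals rescaled by the integrated
  fitted intensity (cumulative sum of λΔ, interpolated at event times,
  which equals the trapezoid rule for piecewise-constant λ), mapped through
  1 − exp(−τ) and compared to Uniform(0,1) with the KS statistic and its
  5%-level band 1.36/√n.
* **Population tests**: Welch t tests with Bonferroni correction across the
  four history features (group sizes and variances differ, so pooled-SD t
  tests are avoided); the Watson–Williams circular test with the standard
  1 + 3/(8κ̂) concentration correction (a warning fires when the mean
  resultant length drops below 0.45, where the approximation degrades); and
  a global permutation test whose statistic is the maximum over lags of the
  absolute Welch t (an area-above-threshold statistic is available behind a
  flag), with the pointwise mask thresholded at the permuted max-statistic's
  95th percentile so the family-wise error over lags is controlled at 0.05.

## The synthetic-data generator

`paper_like_scenario()` returns registered scenarios
(`inst/extdata/scenarios.json`) that emulate a night of sleep: a Markov
hypnogram on 30-s epochs (transition matrix `d·I + (1−d)·1πᵀ` with dwell
d = 0.9 and stationary occupancy 6/48/24/16/6% for N1/N2/N3/REM/Wake — mean
bout length five minutes), a 0.85-Hz SO proxy whose phase is exact by
construction, a stage-tied SOP level (deeper stage → higher SOP, so stage
and depth are correlated as in real sleep), and a spindle train sampled
bin-by-bin (Δ = 0.05 s) from the same conditional-intensity model the
fitter estimates, with the history evaluated causally from the events
already generated.

The default (`"paper_default"`) scenario was calibrated once, analytically,
to sit at the field's reference values: the N2 baseline log-rate was set by
numerically inverting the renewal-process mean-rate integral so the
*realized* N2 density is ≈ 11 events/min under the refractory mass
(baseline 11.66/min); the history control values were chosen so the true
curve crosses 1 near 1.8 s and peaks at 1.90 at 3.50 s; the coupling
magnitude M = 0.22 reproduces a ~7.5–11.8 events/min swing of the rate over
SO phase (exp(2M) ≈ 1.57); and the N3 interaction pair rotates the
preferred phase from 0 (SO peak) in N2 to −π/8 (rising slope) in N3 at
constant M. Variants: `null_history`, `phase_shift` (history-free,
M = 0.35), `history_only` (equal stage rates, no coupling), and
`phase_depth` (SOP sweeps 0→1 over the night with φ_pref drifting linearly
in the effective-pair sense from 0 to −π/8).

What the generator does *not* emulate: waveform-level EEG (no spindle
morphology, no artifacts, no scoring noise), within-stage SOP fluctuation
(SOP is a deterministic function of stage except in the sweep scenario),
non-sinusoidal or amplitude-varying SOs, and detector errors (missed or
spurious events — the "skipped-event" secondary peak seen in real
population curves therefore never appears here). Passing the recovery tests
demonstrates that the estimators are correct and calibrated *under the
model*, not that the model captures every property of real sleep EEG.

## Problem sizes used by the tests

The recovery study uses 100 independent 8-h nights (~3,000–3,500 events
each): pooled 95%-CI coverage across all estimated coefficients, the mean
recovered N2 preferred phase (±0.1 rad of truth) and the mean recovered
history features (within 15% of the generative-truth features). Coverage is
pooled rather than assessed per coefficient because at 100 replicates a
per-coefficient ±4% band would be violated by binomial noise alone. The
calibration studies use 200 constant-rate trains for the KS test, 500 small
fits for the likelihood-ratio size, 20 nights for the synergy
distribution, and 1,000/500 replicates for the circular and permutation
tests. The full suite runs in roughly a quarter hour on one CPU.

## Known limitations

* The refractory feature is sensitive to the pointwise CI at very short
  lags: when a night yields almost no short-lag information, the upper CI
  at lag 0 can touch 1 and the CI-based refractory collapses to 0 even
  though the point estimate is deeply suppressed. Averages over nights (or
  medians) should be preferred for population statements.
* The CI-based excitatory period is systematically shorter than the
  true-curve region above 1 (pointwise CIs shrink the significant run), so
  it is a conservative read-out; refractory length, peak height and peak
  time recover within 15% at realistic event counts.
* SOP normalization (5th–95th percentile of the windowed band power in dB,
  clipped to [0, 1]) is a robust recording-relative convention, not a
  physiological absolute; analyses across recordings compare relative
  depth.
* The exact likelihood is approximated on the Δ grid; covariates are
  evaluated at bin centers. At Δ = 0.1 s the induced bias is far below the
  sampling noise of a single night (the CI-coverage study is the direct
  check).
* Long-range (90-s) history fits are noisy at the sparse tail knots with
  single-night data; the infraslow multiplier inherits an upward Jensen
  bias from exponentiating noisy estimates and is best interpreted across
  many recordings.

## Serialization and reproducibility

Events, hypnograms, covariates, curves and comparison tables are CSV;
fitted models and run manifests are JSON (coefficients with term labels,
covariance, spec, seeds, package version). Every simulation entry point
takes an integer seed, restores the caller's RNG state, and reproduces
bit-identical outputs under the same seed.
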