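---
title: "Methods: sleep depth, arousal, and metabolic downscaling in flies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sleep depth, arousal, and metabolic downscaling in flies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flysleepr)
```

This vignette is the package's own account of the models it implements, the
parameters that matter, the numerical conventions it fixes, and what its
validation does and does not demonstrate.

## The behavioural sleep model

All scoring rests on per-minute beam-cross counts anchored to Zeitgeber
time (ZT; minutes since lights-on under a 12:12 light:dark cycle). The
conventions are fixed once and used everywhere:

* a minute is **active** iff its count is > 0; minute *t* (0-based) covers
  the half-open interval [*t*, *t*+1);
* **sleep** is a maximal run of ≥ `min_bout` (default 5) consecutive
  inactive minutes — the standard fly criterion;
* ZT minutes [0, 720) of each day are **day**, [720, 1440) **night**, with
  half-open boundaries, so ZT 720 itself is night and ZT 1440 is day again.

Several rules are genuinely underdetermined by common practice and are
fixed here as documented decisions:

* **Edge truncation.** A qualifying immobile run touching either end of the
  recording is counted as a bout and flagged (`truncated_start`/`_end`).
  Excluding such runs would systematically undercount night sleep, since
  recordings conventionally start at ZT 0; the flags preserve
  auditability.
* **Boundary-spanning bouts.** A bout crossing ZT 720 contributes its
  minutes to each phase by overlap, and is counted in the bout number of
  every phase it intersects. Mean bout length per phase is the ratio
  of the two, keeping the three metrics mutually consistent.
* **Waking activity** is total counts divided by waking minutes within the
  phase — an intensity measure independent of sleep amount.

## Transition propensities

P(Doze) and P(Wake) are the conditional frequencies of state switches over
consecutive minute pairs: P(Doze) = #(active→inactive)/#(active), P(Wake) =
#(inactive→active)/#(inactive). A pair (*t*, *t*+1) is assigned to the
phase of minute *t*; the final minute starts no pair. Ratios with zero
denominators (e.g. P(Wake) for a fly that never rests) propagate as
flagged missing values, never as zero — coercing them to 0 would bias group
summaries toward apparent stability. These conditional-frequency
definitions are the standard maximum-likelihood estimators of a two-state
Markov chain's transition probabilities, and the synthetic generator (below)
is exactly that chain, so generator and estimator are mutual inverses by
construction.

## Arousal threshold and reactivity

The escalating assay delivers stimuli of strictly increasing intensity
(default 0.3–1.2 g in 0.3 g steps) to each fly once per hour; the threshold
is the first intensity that elicits movement within 15 s, reported as a
proportion of the maximal force (so 0.3 g → 0.25). Decisions:

* **Sleeping at stimulus** means an immobile run of ≥ 5 min ending at the
  assay minute — the causal application of the sleep rule; the minute of
  the assay itself is not counted.
* **The 0 g step is a sham.** A "response" to zero force is spontaneous
  waking, recorded but never a threshold.
* **Non-responders are censored.** A sleeping fly that ignores even the
  maximal stimulus yields a censored record, excluded from per-fly means by
  default with the censored fraction reported. The alternative
  (`censored = "assign_max"`) scores them at 1.0; both are biased in
  opposite directions and the default is the conservative one (it biases
  *against* finding high thresholds in deeply sleeping genotypes).
* **Reactivity** uses the fixed maximal stimulus with a 60 s window, keeps
  only sleeping-fly trials, and regresses per-trial outcomes coded 0/100 on
  prior time asleep. The trial — not the binned percentage — is the default
  observational unit: published reactivity regressions carry thousands of
  denominator degrees of freedom, which only trial-level data provide.
  Binned curves (5-min half-open bins over [5, 40) plus an overflow bin)
  are retained for display and as an optional regression mode.

## Metabolic downscaling

VCO₂ arrives as 5-minute bins. A bin is **sleep** if all five of its
minutes lie inside one bout, **wake** if none does, otherwise **mixed**;
mixed bins are excluded from state means and from bout profiles so that
partial wakefulness cannot dilute state contrasts. For a bout whose
successive sleep bins are v₁, v₂, …, the downscaling statistic is

Δₖ = (v₁ − vₖ)/v₁ × 100,

positive when metabolism is suppressed relative to the bout's first bin.
Δ is scale-invariant, so the pipeline is agnostic to instrument units.
Numerical decisions:

* **Alignment.** Bins live on the instrument's fixed grid. By default only
  bouts starting on that grid are profiled (`allow_offset = 0`);
  re-binning by interpolation would manufacture data. `allow_offset = m`
  accepts bouts whose first full bin starts within *m* minutes of bout
  onset, at the cost of shifting the effective time-in-bout origin.
* **v₁ ≤ 0** makes Δ undefined; such profiles are dropped with a message,
  never treated as infinite change.
* **Bounded series.** Per-fly mean Δ is reported at time-asleep bins 10,
  15, …, up to 40 min by default. Beyond the length of all but the rarest
  bouts, a time bin is occupied by one or two bouts whose Δ values all
  share a single reference bin v₁; such points are almost perfectly
  correlated with their neighbours and would let a handful of long bouts
  dominate a regression while ordinary least squares overstates their
  information (empirically, unbounded series inflate the true sampling
  variance of the slope to ~2.5× its nominal standard error). The 40-min
  bound matches the range used for reactivity analysis; `max_time_min =
  Inf` restores the full series.

## Regression and ANCOVA

`ols_fit()` is closed-form simple regression; the slope test is the F
statistic on (1, n−2) df, identical to the squared slope *t*. `ancova()`
compares g group lines sequentially, mirroring how genotype contrasts are
reported: first equal slopes (separate-slopes vs common-slope model,
F on (g−1, n−2g) df), then — meaningful only under a common slope — equal
intercepts (common-slope vs single-line model, F on (g−1, n−g−1) df). Both
are residual-sum-of-squares comparisons computed from within-group sums, an
independent implementation cross-checked against `lm()`/`anova()` model
refits in the tests. Exact fits (zero residual variance, as arise on
constructed noiseless data) are reported with an `exact_fit` flag and an
infinite F rather than a division by zero; a constant response gives slope
0 and F = 0. No multiple-testing correction is applied here.

## The synthetic cohort generator

The generator exists so that every estimator has ground truth. Its model:

* **Activity**: a two-state Markov chain at 1-min resolution; active →
  inactive with probability p_doze(phase), inactive → active with
  p_wake(phase); the first minute is active. Active minutes emit
  zero-truncated Poisson(λ) counts, so the active/inactive dichotomy the
  scorer assumes is exact and scoring inverts simulation.
* **Arousal**: a fly asleep for *k* minutes has threshold
  θ(k) = θ₀ + β·k and responds to intensity *s* with probability
  logistic((s − θ)/σ). Escalating assays stop at the first response;
  responders are set active for the following minute (toggleable), as a
  tracking system would observe. The logistic form is a modelling choice
  made for testability, not a measured response function.
* **VCO₂**: per-minute rate v_wake/5 while active;
  (v_sleep0/5)·max(1 − δ·t, floor) after *t* minutes of inactivity. Bin
  values get multiplicative lognormal noise with mean 1 and CV `cv_noise`
  (positivity plus exact scale-invariance of Δ). Under this model the
  expected statistic is E[Δₖ] = 100·(1 − (1 + cv²)·(1 − δ(5k−3))/(1 − 2δ))
  ≈ 100·δ·5(k−1): bin k averages decline factors over minutes
  5(k−1)…5k−1, and the (1 + cv²) factor is the exact expectation of the
  ratio of two independent mean-1 lognormals. The recovery tests check
  this exact expression.

Reproducibility: every per-fly, per-arm random stream is seeded by an
integer derived from (cohort seed, fly index, arm), so a fixed seed gives
byte-identical output files and enlarging a cohort never perturbs existing
flies. The stimulated (escalating, fixed) arms re-simulate behaviour
independently of the calorimetry arm, as the corresponding instruments
record different individuals in practice.

### Preset parameter values

The `control_like` / `nf1_like` presets are *invented emulations* of the
qualitative contrasts reported for short-sleeping mutants — none of these
numbers is a measured value:

| parameter | control_like | nf1_like | rationale |
|---|---|---|---|
| p_doze (day, night) | 0.04, 0.07 | 0.03, 0.05 | stationary sleep occupancy p_doze/(p_doze+p_wake) ≈ 0.5 day / 0.78 night for controls (~360 / ~560 min), matching typical wild-type architecture |
| p_wake (day, night) | 0.04, 0.02 | 0.08, 0.08 | elevated waking propensity is the mutant's defining fragmentation phenotype; night occupancy drops to ≈ 0.38 (~280 min) |
| λ (counts/active min) | 2 | 3 | mutant hyperactivity (waking activity) |
| θ₀ (g) | 0.30 | 0.20 | baseline threshold at 25% / 17% of the 1.2 g maximum |
| β (g/min) | 0.02 | 0 | control thresholds roughly treble over a 40-min bout (sleep deepens); mutant thresholds stay flat |
| σ (g) | 0.15 | 0.15 | response noise ~half a staircase step |
| v_wake, v_sleep0 (per bin) | 1.0, 0.8 | 1.4, 1.2 | mutant VCO₂ elevated in both states; sleep ~20% below wake at onset |
| δ (/min), floor | 0.01, 0.5 | 0, 0.5 | control sleep suppresses VCO₂ ~1%/min of time asleep, to at most half the onset rate; mutants show no decline |
| cv_noise | 0.05 | 0.05 | instrument-scale bin noise |

### What the generator does *not* emulate

Real recordings have circadian structure beyond a two-level day/night
dichotomy (anticipatory activity peaks, siesta), inter-fly parameter
heterogeneity, positional micro-movements below the beam, stimulus
habituation, and slow drifts in calorimetry baselines. Passing the
recovery tests therefore shows that the estimators are correct *for the
stated model at the stated scale*; it does not certify performance on the
quirks of any particular rig.

## Validation scales

The test suite runs entirely on data generated in code, at sizes chosen to
give stable Monte-Carlo verdicts at desk scale: 500 random day-long traces
for scorer/oracle equivalence; 100 flies for transition-propensity
recovery; 200 seeded replicates of 50 flies for the reactivity slope
contrasts and of 8 flies for the downscaling null calibration; 2000 null
replicates for ANCOVA type-I calibration (expected 5% ± 2%); and 50
replicates of 30 flies per genotype for the preset direction-of-effect
checks (night sleep, arousal threshold, ANCOVA slope difference), each
required in ≥ 90–95% of replicates as appropriate to the property.

## Known limitations

* Group-level inferential statistics beyond regression/ANCOVA (ANOVA
  families, mixed models, survival analysis) are deliberately out of scope;
  the pipeline produces tidy per-fly tables ready for any such analysis.
* The DAM file dialect (ten metadata fields, 32 channels) is fixed and
  documented; vendor variants with extra sensor columns are not parsed.
* Bout/bin alignment is conservative by default; studies whose instrument
  grid is offset from behaviour onset should consider `allow_offset`
  explicitly, understanding the time-origin shift it introduces.
* P(Doze)/P(Wake) are first-order Markov summaries; real sleep shows
  longer-range dependence that these two numbers compress.
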