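---
title: "Modelling circadian behaviour in pregnant and non-pregnant mice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling circadian behaviour in pregnant and non-pregnant mice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

Mice housed under a 12:12 light–dark cycle organise feeding, drinking,
locomotion and sleep into strong circadian rhythms: roughly 65–80% of food
intake falls in the dark (active) phase, and cage activity rises sharply
after lights-off (Zeitgeber time ZT12). Pregnancy perturbs these rhythms —
intake increases, activity falls, and the *timing* of behaviours shifts —
but group-mean comparisons at fixed clock hours cannot say *when* behaviour
peaks or whether a peak has moved. `circacage` implements a pipeline that
answers those timing questions for metabolic-cage data:

1. **Preprocessing** of raw per-interval records into hourly per-mouse
   series (5-min blocks, then hours), with the standard event filter for
   food (< 0.002 g excluded) and stillness-based sleep scoring (stillness
   runs ≥ 40 s count as sleep).
2. **Dark-phase activity-onset detection**: each mouse's threshold is its
   mean dark-phase activity during acclimation, and onset is the first run
   of three consecutive 5-min blocks strictly above threshold after
   lights-off (censored at 12 h). Group differences per study day are tested
   with a linear mixed model.
3. **Bayesian natural-spline multilevel models** of each behaviour,
   producing posterior fitted curves per group × study block.
4. **Posterior peak inference**: local maxima within five ZT windows are
   found in every posterior draw; presence, timing, amplitude and group
   differences are summarised with 95% credible intervals.

A synthetic-cohort generator with known circadian structure and pregnancy
effects provides ground truth for every stage.

# Study layout and time conventions

Time is counted in decimal study days with integer boundaries at lights-on
(ZT0), so day 0.5 is the first lights-off of the study. The default cohort
mirrors a typical design: 12 non-pregnant and 31 pregnant mice, 7 days of
acclimation (days −6.5 to 0.5), and terminations at days 6.5, 12.5 and
17.5 that define three study blocks (days 0.5–6.5, 6.5–12.5, 12.5–17.5,
thirds of mouse pregnancy). Block boundaries are half-open with boundary
days in the later block, consistent with terminations ending a block.

The circadian axis is *unwrapped* to ZT6 → ZT30: calendar hours ZT0–ZT6 of
day *d* map to ZT24–ZT30 of day *d* − 1. This keeps the dark phase
(ZT12–ZT24) and the early-light window interior to the modelling axis, so
no periodicity constraint is needed. Peaks are assessed in five windows:
I ZT8–12 (late light), II ZT12–15, III ZT15–18, IV ZT18–24 (dark), and
V ZT24–28 (early light of the next cycle).

# The behavioural model

For each behaviour the hourly value $y_{ijt}$ (mouse $i$, block $j$, hour
$t$) is modelled as

* **Intake and activity** (non-negative): $\sqrt{y} \sim
  \mathcal N(\mu_{g(i)j}(t) + a_i + u_i + v_{ij},\ \sigma^2)$. The square
  root resolves the right skew of count-like hourly totals; the fitted mean
  is back-transformed *exactly* as $E[y] = \mu^2 + \sigma^2$ (the mean of a
  squared normal), applied per posterior draw with that draw's $\sigma^2$.
* **Wakefulness** (a fraction in (0, 1)): $y \sim
  \mathrm{Beta}(\mu\phi, (1-\mu)\phi)$ with
  $\mathrm{logit}(\mu) = \mu_{g(i)j}(t) + a_i + u_i + v_{ij}$. Fractions of
  exactly 0 or 1 are nudged by $\varepsilon = 1/600$ (half a second of a
  300 s block) into the open interval.

The group × block mean curve $\mu_{gj}(t)$ is a natural cubic spline over
the unwrapped axis with 13 knots evenly spaced from ZT8.5 to ZT28.5
(spacing 5/3 h; the extremes act as boundary knots, with linear tails), in
full interaction with group and block. $u_i$ and $v_{ij}$ are nested random
intercepts (mouse, and block within mouse). $a_i$ is the **acclimation
covariate**: each mouse's acclimation-period profile at the matching ZT
hour, estimated on the link/transform scale by a glmmTMB model
(spline × group + mouse intercept) of the acclimation data, then centred
within group × hour. The centring matters: the raw profile contains the
group curve itself and is collinear with the spline fixed effects; centred,
it carries only each mouse's deviation from its group's acclimation curve,
which is what "correcting for individual variation" means here.

## Posterior computation

Posterior sampling follows the reported recipe — three chains of 10,000
iterations, the first half discarded and the remainder thinned by keeping
every fourth draw (3 × 1250 = 3750 retained draws) — using samplers written
for these two model families:

* the Gaussian model uses an exact conjugate **Gibbs sampler** (all full
  conditionals closed-form; weakly-informative priors
  $\beta \sim \mathcal N(0, 10^2)$,
  $\sigma^2, \tau^2 \sim \mathrm{InvGamma}(0.01, 0.01)$);
* the beta model uses **Metropolis-within-Gibbs**: fixed effects move in
  whitened coordinates (Cholesky of the Fisher covariance from an
  in-package ridge-penalised Fisher-scoring beta regression that also
  provides starting values), random intercepts are updated simultaneously
  across their conditionally independent units, variance components are
  conjugate, and the precision $\phi$ takes a log-scale random walk.
  Proposal scales adapt only during burn-in.

Both samplers add Metropolis "recentring sweeps" along the
near-likelihood-invariant ridge directions of this design (intercept vs the
mean of the mouse intercepts; group/block indicators and the
within-mouse-constant acclimation covariate vs the corresponding
random-intercept means). These directions are identified only through the
priors; without the sweeps their autocorrelation dominates and split-R̂
stays far above 1. Convergence is summarised by split-R̂ over all
fixed-effect coefficients and the dispersion parameter; a fit with any
R̂ > 1.05 is flagged and peak analysis refuses it unless forced.

A **reduced preset** (2 chains × 2,000 iterations, 500 retained draws) is
used for the test suite and quick exploration; the full preset is the
default for inference. At reduced settings the beta sampler is routinely
flagged (coefficient-level R̂ up to ~1.1 even though the fitted curves of
the two chains agree closely); this is reported honestly rather than
hidden.

## Peak inference

Curves are evaluated on a 0.05 h grid (3 min, finer than any reported
timing difference). In each posterior draw and each window a peak is a grid
point strictly greater than both neighbours and inside the half-open
window; window-edge maxima never count (a monotone stretch is a trend, not
a peak). Among several local maxima the largest wins, ties going to the
earliest. Presence is the share of draws with a peak; timing and amplitude
are summarised (mean, 2.5/97.5% quantiles) over draws with a peak; group
differences are computed per draw over draws in which **both** groups show
a peak — the coherent posterior analogue of reporting differences "among
mice with a detected peak" — and are undefined (with a note) below 1%
joint presence. An effect is significant when its credible interval
excludes zero; a closed endpoint at zero counts as crossing.

## Onset analysis

Onset thresholds use all available acclimation dark-phase blocks (the
alternative — only the final two nights — is a configuration choice).
"Exceeds" is strict: a mouse sitting exactly at its acclimation mean is not
clearly active. Censored nights enter the mixed model as their recorded
12 h value (no survival treatment), mirroring the source convention. The
model is `onset ~ group * day + (1 | mouse)` via lmerTest with Satterthwaite
degrees of freedom; per-day contrasts are two-sided Wald tests without
multiplicity correction. On balanced complete data this reproduces two-way
repeated-measures results.

# The synthetic cohort

Each behaviour's population mean curve is a periodic cubic-spline baseline
through control points plus raised-cosine peak bumps, blended as
$v \leftarrow v + s\,(A - v)$ so the curve attains exactly amplitude $A$
with zero derivative at the peak time — injected peak delays therefore echo
exactly in the truth table even when a delayed peak rides the dark-onset
rise. The baseline interpolant is deliberately a different basis from the
natural-spline model, so recovery tests never test the model against its
own basis.

Default profiles encode a realistic non-pregnant female: nocturnally biased
(the noiseless food curve puts ~72% of intake in the dark phase), with
local peaks near ZT9, ZT13.5, ZT16.5–17.3, ZT22 and ZT1.6–2 whose heights
follow the reported non-pregnant point estimates (food up to ~0.24 g/h,
activity up to ~26 m/h, wakefulness up to ~0.85). Water shares food's peak
times by default, reflecting the tight coupling of drinking to eating.
Baseline shapes were chosen after an explicit representability analysis:
features narrower than the ~1.67 h knot spacing, or inside the linear tail
before the ZT8.5 boundary knot, cannot be represented by the model basis at
hourly sampling, so the default curves use a broad light-phase trough and a
sharp dark-onset rise wide enough for the basis to resolve the peaks that
ride on them.

Generation: per mouse-hour, intake/activity totals are
$(\sqrt{\text{curve}} + b_i + \epsilon)^2$ (intercept $b_i$ drawn once per
mouse, noise per hour, negative square-root draws truncated at zero),
distributed evenly over the hour's recording intervals; wake fractions are
drawn per 5-min block from a beta distribution around the logit-shifted
curve. Pregnancy effects apply from day 0.5 (acclimation precedes mating):
window-wise peak delays and amplitude folds for intake behaviours,
multiplicative dark-phase scaling for activity (~50–70% reduction) and
wakefulness, and a per-day onset delay implemented as a time shift of the
night-time activity rhythm — the mean follows curve(zt − δ), so the
detected onset moves by exactly δ.

Noise defaults (sqrt-scale SD 0.05 g/h for intake, 0.5 m/h for activity;
mouse-intercept SDs 0.04/0.3; beta precision 30) are synthetic choices —
the source study reports no per-hour variances — set at the scale where the
study's effects are recoverable at its sample sizes, and are not estimates
from real data.

## What the generator does and does not emulate

It emulates the light–dark structure, nocturnal bias, localised behavioural
peaks, individual baseline differences, block-wise pregnancy effects,
progressive onset delay, and mid-study terminations. It does **not**
emulate meal-bout microstructure, 1-s event streams, ultradian rhythm,
drifting free-running periods, or missing-data patterns of real cage
systems; passing recovery tests therefore show the pipeline recovers known
effects under clean conditions, not that real data meet the model's
assumptions.

## The parameter-recovery experiment

Recovery experiments inject a 1.5 h delay and ×2 amplitude change into the
window-I food peak in block 2 (n = 12/group) and ask whether the
peak-difference credible intervals contain the truth and exclude zero. They
use a dedicated `recovery_food_profile()`: one broad late-light feeding
elevation (ZT9.4, half-width 3.6 h), a dark plateau and a late-dark peak.
With the default profile the window-I peak is deliberately marginal — in
the source analysis only about a third of posterior draws detected the
pregnant window-I peak in mid-pregnancy — so recovery there would measure
noise, not the pipeline. The dedicated profile makes both the original and
the delayed bout representable by the model basis (projection bias ≈ 0 h in
timing and −0.015 g/h in the amplitude difference), so failures indicate
pipeline defects rather than basis-resolution limits.

# Problem sizes and numerical choices

The test suite uses the reduced sampler preset throughout; the
null-calibration experiment runs 20 replicate cohorts of 8 + 8 mice, the
recovery experiment 20 replicates of 12 + 12 mice, and the onset-ramp
experiment one cohort of 12 + 12 mice; unit tests use 2–6 mice per group.
Other choices: wake nudging ε = 1/600; significance requires strict sign
agreement of CrI endpoints; grid step 0.05 h; "thinned by a quarter" is
read as keeping every fourth draw (the alternative — discarding a quarter —
is available via the `thin` setting); the acclimation covariate coefficient
is estimated rather than fixed at 1; the beta precision is constant rather
than modelled. Degenerate inputs: all-zero acclimation activity yields a
zero threshold (any positive activity triggers onset); wake streams that
are constant 0/1 are nudged before fitting; duplicate records within a
5-min block are an error rather than silently averaged.

# Known limitations

* Peaks narrower than the knot spacing (5/3 h), or within the linear tails
  outside ZT8.5–ZT28.5, are invisible to the model — a property of the
  13-knot natural-spline design itself, inherited by any analysis that uses
  it.
* The beta sampler's coefficient-level mixing at reduced settings is slow;
  inference should use the full preset.
* The back-transformed intake/activity curve estimates $E[y]$ and is
  therefore shifted upward by the residual variance relative to the
  noiseless population curve; the shift (~0.002 g/h at default noise) is
  far below the credible-interval width but is visible in exacting
  comparisons.
* Censored onsets enter the mixed model at 12 h, which understates late
  onsets; this mirrors the source convention rather than a survival
  treatment.
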