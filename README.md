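# circacage

Circadian analysis of metabolic-cage behaviour in pregnant and
non-pregnant mice.

Mice under a 12:12 light–dark cycle (lights-on = Zeitgeber time ZT0)
concentrate feeding, drinking, locomotion and wakefulness in the dark
phase. Pregnancy changes both *how much* and *when*: intake rises, dark-phase
activity collapses, and behavioural peaks and the onset of dark-phase
activity drift later as gestation progresses. Answering the *when*
questions needs more than hour-by-hour group means — it needs a model of
the whole 24 h curve and a way to compare peak timing between groups with
honest uncertainty.

`circacage` provides that pipeline for anyone analysing Promethion-style
metabolic-cage studies (or simulating them):

* **Preprocessing** — raw per-interval records → 5-min blocks → hourly
  per-mouse series; food events < 0.002 g excluded; sleep scored as
  stillness runs ≥ 40 s; study days 0.5–6.5 / 6.5–12.5 / 12.5–17.5 assigned
  to blocks (thirds of mouse pregnancy).
* **Activity onset** — per-mouse thresholds (mean dark-phase acclimation
  activity), onset = first 3 consecutive 5-min blocks strictly above
  threshold after lights-off (censored at 12 h), and a
  pregnancy × study-day linear mixed model of onset times.
* **Curve model** — Bayesian multilevel model per behaviour: a natural
  cubic spline over the unwrapped ZT6→ZT30 axis with 13 knots evenly
  spaced ZT8.5→ZT28.5, in full interaction with group and study block;
  nested random intercepts (block within mouse); each mouse's acclimation
  profile as a covariate. Intake/activity are Gaussian on the square-root
  scale (back-transformed exactly as mean² + variance); wakefulness is a
  logit-link beta regression. Sampling: 3 chains × 10,000 iterations, half
  burn-in, thinned by four (3750 draws), via a conjugate Gibbs sampler
  (Gaussian) or Metropolis-within-Gibbs (beta), with split-R̂ diagnostics.
* **Peak inference** — per posterior draw, local maxima within five ZT
  windows (I ZT8–12, II ZT12–15, III ZT15–18, IV ZT18–24, V ZT24–28);
  presence %, peak time and amplitude with 95% credible intervals, and
  pregnant-minus-non-pregnant differences conditioned on joint presence;
  significant iff the CrI excludes zero.
* **Synthetic cohorts** — a generator with known circadian structure,
  per-mouse intercepts, block-wise pregnancy effects and a progressive
  onset delay, plus a truth table for parameter-recovery studies.

## Worked example: recovering an injected peak delay

Simulate a cohort of 12 + 12 mice in which the pregnant group's late-light
feeding peak is delayed by 1.5 h and doubled in amplitude during study
block 2 (days 6.5–12.5), then recover the effect:

```r
library(circacage)

eff <- null_effects()
eff$blocks[["2"]]$peak_delay["I"] <- 1.5
eff$blocks[["2"]]$amplitude_fold["I"] <- 2
profiles <- list(food = recovery_food_profile())

cfg <- cohort_config(
  n_nonpregnant = 12, n_pregnant = 12,
  termination_schedule = list(nonpregnant = c(0, 0, 12),
                              pregnant = c(0, 0, 12)),
  random_seed = 62)

rec  <- filter_food_events(generate_cohort(cfg, profiles, eff, "food"))
h    <- aggregate_records(rec)
accl <- fit_acclimation(h, "food")
fit  <- fit_behaviour_model(h, accl,
                            model_spec("food", sampler_settings("reduced")),
                            seed = 62)
pk   <- summarise_peaks(draw_peaks(posterior_curves(fit, force = TRUE)))
pk[window == "I" & block == 2,
   .(presence_pregnant, diff_time, diff_time_lo, diff_time_hi, sig_time)]
#>    presence_pregnant diff_time diff_time_lo diff_time_hi sig_time
#> 1:               100    1.3728         1.15         1.55     TRUE
```

The posterior mean delay is 1.37 h with 95% CrI [1.15, 1.55] — containing
the injected 1.5 h and excluding zero — and the pregnant peak is present in
100% of draws. (`sampler_settings("full")` gives the 3 × 10,000-iteration
run used for real inference; the reduced preset here keeps the example
fast.)

The whole pipeline (simulate → preprocess → onset → fit → peaks → figures
→ manifest) runs as one call:

```r
run_pipeline("out/demo", seed = 1, behaviours = c("food", "activity"))
```

## Layout

```
R/                 implementation (generator, ingest, onset, model, peaks, pipeline)
tests/testthat/    unit, property and acceptance tests
scripts/           acceptance script
vignettes/         methods vignette (model, priors, design choices, limits)
```
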