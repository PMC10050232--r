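---
title: "Designing and simulating prediction-driven comparative-effectiveness trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and simulating prediction-driven comparative-effectiveness trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The setting

Two treatments A and B are both approved for a cancer indication, and a
biomarker signature dichotomizes patients into positives (M = 1), for whom the
proposed strategy prescribes B, and negatives (M = 0), who get A.  Whether the
strategy should enter practice is a *comparative effectiveness* question, and
it hinges on three distinct contrasts of the time-to-event outcome T:

* **Treatment effect within a subgroup** — `g(T_B | M = m)` vs
  `g(T_A | M = m)` for a summary functional `g` (hazard, survival probability
  at `t`, restricted mean survival time at `t`).
* **Differential treatment effect (clinical validity)** — the difference (or
  ratio) of the two subgroup effects.
* **Clinical utility** — the improvement from *knowing* the marker.  In the
  comparative form, biomarker-directed assignment is compared with what a
  physician would prescribe *without* the marker result (physician's choice);
  in the experimental form — the definition inherited from the experimental
  treatment setting — it is compared with randomized assignment.

The package simulates the four standard designs (enrichment,
biomarker-stratified, biomarker-strategy, modified biomarker-strategy),
estimates these contrasts with standard survival machinery, and computes
Monte-Carlo operating characteristics.  The core scientific point it
operationalizes: the comparative and experimental forms of clinical utility
are different estimands, and only the biomarker-strategy design randomizes
against physician's choice and hence identifies the comparative form.  When a
physician can already reconstruct the marker from routine data ("ideal
physician's choice"), true comparative utility is exactly null while the
experimental contrast is not, so a trial targeting the wrong form badly
inflates its nominal type I error for the question actually being asked.

## Generative model

Event times are exponential, with the median set per (marker, treatment) cell
and converted to a rate by `median_to_rate()` (`rate = log(2) / median`).  All
times are in months and continuous; ties have probability zero in generation,
but the estimators still handle them (files round-tripped through CSV at
finite precision can collide).  The default cell medians are 9 (pos, A),
9 (pos, B), 12 (neg, A) and 9 (neg, B) months, the null configuration in which
the directed rule and an ideal physician agree cell by cell.

Accrual is uniform on `[0, accrual_duration]` (default 0: everyone enters at
calendar zero) and follow-up is censored administratively at the analysis
calendar time `admin_censor_time` (default 60 months).  This is the simplest
mechanism satisfying *completely independent censoring* — censoring depends
only on the accrual calendar, never on event time, marker or treatment — which
is the condition under which pseudo-observation regression is consistent.
Informative censoring is deliberately out of scope.

Each trial enrolls `2 * n_per_arm` patients (default 500 per arm) with
individual-level randomization, so realized arm sizes are binomial.  The
enrichment design screens marker-negative candidates and discards them,
recording the number screened.  Under the strategy design the physician arm's
marker value is generated (it drives the physician model and the outcome) but
flagged unmeasured, and the CSV export hides it: exported data reflect the
trial analyst's information set, not the simulator's.

The physician-choice model is Bernoulli given the marker
(`p_B_given_pos`, `p_B_given_neg`); the `"ideal"` kind is the degenerate case
(1, 0) in which choice coincides with the directed rule.  This is the
configuration under which true comparative clinical utility is exactly zero —
`true_contrast_value()` returns HR 1 and SD/RMST 0 without simulation —
making it the natural null for studying both utility contrasts.

## Designs and identifiability

`identifiable_contrasts()` encodes which contrasts each design estimates
without extra assumptions: enrichment gives the positive-subgroup effect only;
the stratified design gives both subgroup effects and their difference; the
strategy design gives comparative clinical utility only; the modified strategy
design (directed arm vs fully randomized arm) with marker testing matches the
stratified design and also realizes the experimental utility contrast at the
arm level.  Without marker testing in the randomized arm, only the arm-level
experimental comparison survives, and the function says so with a warning
rather than silently choosing a side, since published treatments of that
design differ on whether to count it.

A modified-strategy design with directed-arm probability `r_strat` and
within-randomized-arm B-probability `r_pos2` assigns a positive patient to B
with probability `r_strat + (1 - r_strat) * r_pos2`
(`matched_stratified_probability()`); setting the stratified design's
`r_pos1` to that value (and `r_neg1 = (1 - r_strat) * r_neg2`) makes the two
designs' joint (marker, treatment) laws identical, which
`design_joint_table()` verifies by exact enumeration.

One asymmetry is deliberate: `estimate_contrast()` computes experimental
utility only from a modified-strategy cohort, by regressing on its arm
indicator.  A stratified cohort identifies the same estimand in principle, but
through mixture plug-ins rather than the arm-level working models the package
fits; requesting it there errors with a pointer to the modified design instead
of silently switching estimators.

## Estimators

* **Logrank** (`logrank_test()`): the standard two-sample test; it tests
  equality of whole survival distributions, carries no magnitude, and is
  refused for the differential contrast, whose null does not fix all four
  cell distributions.
* **Hazard ratio** (`cox_fit()`): Cox partial likelihood with the Efron tie
  correction; three working models — a treatment indicator (fit within one
  subgroup), treatment x marker interaction, or an arm indicator — reporting
  `exp(b)` for the model's target coefficient with two-sided Wald inference on
  the log scale.  Replicates with separation or no events in a group are
  recorded as non-estimable rather than imputed.
* **Survival difference and RMST** (`pseudo_observations()` +
  `glm_identity()`): jackknife pseudo-values of the pooled Kaplan-Meier
  functional — `I(T > t)` for survival at `t`, `min(T, t)` for RMST — fed to
  an identity-link least-squares regression with sandwich (HC0) standard
  errors.  Pseudo-values are computed from the pooled, covariate-ignoring
  curve (the standard construction; a per-arm variant would change the
  estimand) and the robust variance is used because pseudo-values are not
  independent given the pooled estimate.

The pseudo-values are the *exact* leave-one-out jackknife, evaluated in
closed form: deleting subject i changes each event time's risk/event counts by
at most one, so every leave-one-out curve is a prefix of "at-risk" factors, an
optional own-event factor, and a suffix of unchanged factors, all computable
with cumulative products and sums in `O(n log n)` rather than n curve refits.
Tests verify equality with brute-force deletion to 1e-12, with and without
ties, and the uncensored identities (pseudo-value = `I(T > t)` or
`min(T, t)` exactly).

Numerical conventions: Kaplan-Meier evaluation is right-continuous; censoring
tied with an event is ordered after it; a functional requested beyond the last
observed time carries the last value with a warning (kept deterministic rather
than erroring, since it is legitimately reachable at small n); a pseudo-value
horizon beyond follow-up errors because no risk set defines the functional
there.  Wald tests are used throughout for Cox and pseudo-value regressions —
the working-model nulls are single-coefficient — and the logrank chi-square is
the score-test route to the same null, whose equality on tie-free data is a
cross-check in the test suite.

Direction conventions: indicators are coded exactly as in the working models
(1 = treatment B, or 1 = biomarker-directed arm), so a beneficial B gives
HR < 1 and positive SD/RMST coefficients.  Arm-level hazard ratios are
reported in both directions (`estimate` and `hr_reciprocal`): published
tables for the experimental contrast conventionally print the
randomized-over-directed ratio (> 1 when the directed arm is better), and the
grid's `hr_mean_exp` column follows that convention while `hr_mean_comp` is
direction-free under the null.

## The simulation engine

`run_replicate()` regenerates its cohorts from `(seed, replicate index)` via
a fixed integer mixing function, so any replicate can be reproduced in
isolation and results are independent of execution order.  When a replicate
needs both utility contrasts, it simulates one strategy trial and one
modified-strategy trial under the same scenario — separate patients, shared
parameters; a three-arm trial sharing a directed arm would be an alternative
but couples the two estimates.  `operating_characteristics()` aggregates
rejection rates (two-sided p < alpha, default 0.05), mean estimates, empirical
SEs, and bias against `true_contrast_value()`, each with Monte-Carlo standard
errors; non-estimable replicates are dropped and counted.

`utility_contrast_grid()` runs the ideal-physician grid: median survival for
positives on B at 9, 12 and 21 months crossed with prevalence 0.25 and 0.50,
six scenarios, comparing the two utility contrasts across all four estimands.
Scenario rows derive child seeds from the base seed, so the whole grid is
bit-identical across runs at the same seed.  Defaults — 500 patients per arm,
1000 replicates per scenario, horizon t = 36 months for SD/RMST (inside the
60-month follow-up for every scenario median, late enough for event-rate
differences to accumulate) — are the package's declared study conditions;
at that scale the full grid runs in a few minutes on one core.

## What the simulations do and do not show

The generator emulates exponential, proportional-hazards survival with
marker- and treatment-specific rates, independent censoring and perfect
marker measurement.  Real trials feature non-proportional hazards,
covariate-dependent censoring, marker misclassification and accrual dynamics,
none of which are generated here (the pseudo-observation estimators do not
*assume* proportional hazards, but the scenarios do not exercise that
robustness).  Passing operating-characteristic checks therefore demonstrates
internal validity of design/estimator/contrast logic under a clean generative
model — not performance guarantees for any particular real trial.  The
intended use for design work is to re-parameterize the scenario to the
application (medians, prevalence, physician behaviour, horizon) and rerun the
engine, favouring conservative (larger) sample sizes.

## Known limitations

Two treatments and two marker levels only; exponential event times only
(the scenario interface would admit other families, but none is implemented);
no covariate adjustment beyond marker and treatment in the shipped scenarios;
no adaptive randomization or platform-trial features; no proportional-hazards
diagnostics.  The comparative-vs-experimental grid reproduces the *comparative*
contrast's null behaviour quantitatively; for the experimental contrast the
inflation of type I error and the direction of distortion are the reproducible
facts at these study conditions, as its exact magnitudes depend on design
minutiae (per-arm size, censoring, horizon) that are application-specific.
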