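---
title: "From urinary peptide peak lists to prognostic classification of acute coronary syndrome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From urinary peptide peak lists to prognostic classification of acute coronary syndrome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acspredict)
```

## The problem

Acute coronary syndrome (ACS) — myocardial infarction or unstable angina —
is usually the first overt manifestation of coronary disease in people who
were asymptomatic when they could still have been treated preventively.
Urine is an attractive matrix for finding early warning signals: peptides
shed by remodelling atherosclerotic plaques (largely collagen fragments)
pass the kidney and accumulate in urine, and capillary electrophoresis
coupled to mass spectrometry (CE-MS) resolves thousands of them per sample
in a single run.

`acspredict` implements the complete desk-side analysis for this study
design: deconvoluted CE-MS peak lists in, prognostic performance
statistics out. Because the cohorts such analyses run on are not publicly
depositable, the package pairs every stage with a synthetic-cohort
generator that reproduces the statistical structure the stage assumes, so
the whole workflow is testable end to end.

## Peak-list processing

A raw profile is a list of detections, each a triple (mass in Da, CE
migration time in minutes, signal amplitude). Three steps turn a set of
profiles into a sample × peptide amplitude matrix.

**Migration-time calibration.** Electrophoretic mobility drifts between
runs. Each profile is anchored to reference peptides (matched by mass) and
a locally weighted regression of reference time on observed time —
local-linear, tricube weights, one robustness iteration, span 0.3 of the
anchors — re-maps every detection. Because an anchor matched by mass alone
can occasionally hit the wrong peptide, anchors whose first-pass residual
is a gross outlier (beyond max(0.35 min, 6·MAD)) are discarded and the map
refitted. The maximum surviving anchor residual must stay below 0.35 min;
a violation flags the profile rather than silently passing or failing it.
Fewer than 10 usable anchors is an error.

**Housekeeping normalization.** Urine concentration varies several-fold
between voids, scaling every amplitude in a sample by a nuisance factor.
Twenty-nine "housekeeping" peptides with stable excretion serve as an
internal standard: observed housekeeping amplitudes are regressed on their
reference amplitudes *without intercept*, and all amplitudes are divided
by the slope. The estimator is exactly scale-equivariant, so multiplying a
sample by any constant leaves its normalized row unchanged (the dilution
invariance the tests verify to 1e-9). A median-of-ratios estimator is
available behind `method = "median_ratio"`; with only 29 calibrators and
occasionally heavy-tailed amplitudes the regression form is the default
because it weights the high-amplitude (best-measured) calibrators more.
Fewer than three detected housekeeping peptides is an error.

**Catalogue matching.** Detections from different samples are considered
the same peptide when the mass deviation is strictly below 50 ppm and the
migration time falls inside a window that widens linearly with time —
diffusion broadens CE peaks — from 2% of the migration time at 19 min to
5% at 45 min, clamped outside that range. The published description does
not say whether the percentage is a full or half window, nor its centre;
here it is a *full* relative window centred on the catalogue time
(`|t − t_p| ≤ width(t_p)·t_p/2`), configurable. Among several eligible
catalogue peptides the smallest ppm deviation wins, ties broken by the
smaller time deviation, then the lexicographically lower peptide id, so
matching is deterministic and order-independent. Several detections of one
peptide within one sample are summed, conserving total signal. The
boundary conventions are deliberate: strict `<` at 50 ppm, inclusive `≤`
at the time window.

```{r}
cluster_width(c(19, 32, 45))
```

## Biomarker discovery

On the discovery split, each peptide is summarized by its detection
frequency per group (fraction of samples with amplitude > 0) and a
two-sided Wilcoxon rank-sum p-value comparing case and control amplitudes,
with undetected values entering as zeros (tied at the bottom of the
ranking). The exact null distribution is used for combined n ≤ 25 without
ties — the regime the enumeration oracle in the test suite covers — and
the normal approximation with mid-rank tie correction otherwise.
Benjamini–Hochberg adjustment corrects for the thousands of peptides
tested. The panel keeps peptides detected in at least 70% of one group
(inclusive) with adjusted p below 0.05 (exclusive). Whether the
significance cut applies to raw or adjusted p is ambiguous in the source
description; the adjusted value is the default (the adjustment is stated
as *the* multiple-testing correction) with a raw-p mode behind
`use_adjusted = FALSE`.

Housekeeping peptides are never biomarker candidates: normalization pins
their values by construction, so their apparent stability is an artefact
of the processing, and as always-detected columns they would otherwise be
the only null features able to pass the frequency filter.

Differential excretion (DE) summarizes effect direction and size: with
group means taken over *all* samples (zeros included) and multiplied by
the group's own detection frequency,

DE = (mean_case · freq_case) / (mean_ctrl · freq_ctrl) when the case
product is larger, and −(mean_ctrl · freq_ctrl)/(mean_case · freq_case)
when smaller; equal products give +1, and a zero product is flagged
undefined rather than returned as ±∞. So |DE| ≥ 1 always, and swapping the
group labels maps DE to −DE.

## Pattern and composite scoring

The panel is combined into one score by a soft-margin support vector
machine with radial basis kernel on the log2-transformed intensities,
`K(u,v) = exp(−γ‖u−v‖²)`. A sample's classification score is its signed
distance to the maximal-margin separating hyperplane; cases are trained on
the positive side. Undetected amplitudes are encoded as feature value 0 —
consistent with the zeros-for-undetected convention of the DE formula, at
the cost of colliding with amplitude 1 (`undetected = "log1p"` avoids the
collision). Features are *not* standardized: the published kernel
parameters C = 1638.4 and γ = 0.000256 are tied to the raw log2 intensity
scale, and they are the defaults. `tune_hyperparameters()` performs the
stratified k-fold grid search (5 folds by default; ties to the smallest C,
then smallest γ) when retuning is wanted.

The composite predictor is a linear combination of the pattern score, a
previously established coronary-artery-disease pattern score (consumed as
an input covariate), and age:

score = 0.2 · pattern + 2.6 · CAD pattern + 0.15 · age, threshold 10.256.

Those published weights are the `composite_weights()` defaults;
`fit_composite_weights()` re-derives weights on a named dataset by
logistic regression, falling back to a ridge-penalized fit (λ = 1e-4) under
perfect separation.

## Prognostic evaluation

* **Thresholds** maximize Youden's J = sensitivity + specificity − 1 over
  midpoints between consecutive distinct scores plus the two trivial
  classifiers (so J ≥ 0 always); ties prefer the higher specificity, then
  the lower threshold. Positive call: score strictly above the threshold.
* **Exact binomial (Clopper–Pearson) intervals** from Beta quantiles
  accompany every sensitivity and specificity; percentages are reported to
  one decimal.
* **Harrell's c** for censored outcomes counts pairs with distinct
  observed times whose earlier member had an event; tied scores count 1/2.
  Pairs tied on time are excluded entirely. The interval comes from the
  asymptotic U-statistic variance of Somers' D (c = (D+1)/2) estimated
  from per-subject mean pair contributions; the exact variance estimator
  used by the original software is not recoverable, and this choice is
  documented rather than hidden.
* **Kaplan–Meier** curves are tabulated as cumulative event percentage
  100·(1 − S(t)); **Cox** models use Breslow tie handling (Efron behind a
  switch). Backwards step-down removes the covariate with the largest Wald
  p while it is ≥ 0.05; the description of the procedure prints several
  removal thresholds in different places, and the methods-section value
  (0.05) is followed, configurable via `removal_alpha`.
* **IDI / NRI** compare nested logistic risk models (centre + Framingham
  score, plus the pattern or composite score). Risk categories are
  [0, 10%), [10%, 20%), [20%, 1] — closed on the left, so 10% is
  intermediate and 20% is high. Standard errors treat events and
  non-events as independent samples.

## What the synthetic cohorts emulate — and what they do not

`sim_config()` defaults are the emulated study's design: 126 cases with an
ACS event within the five-year follow-up and 126 event-free controls,
roughly two thousand catalogued peptides of which 75 carry planted
differential excretion, and 29 housekeeping peptides. Choices the study
description leaves open were fixed once, on biological plausibility:

* **Amplitude law.** Detected amplitudes are log-normal around a
  per-peptide baseline (log2 sd 1.0), with the planted effect additive on
  the log2 scale — the scale the classifier works on. Mean planted effect
  1 log2 unit (two-fold), random sign, since urinary markers move in both
  directions. Housekeeping peptides get log2 sd 0.1: being selected for
  small relative standard deviation is precisely what makes them usable
  as calibrators.
* **Dropout.** Detection is Bernoulli per peptide per sample with a
  per-peptide frequency drawn from (0.35, 0.95); planted biomarkers
  default to frequency 0.9 so they are discoverable under the 70% filter.
* **Dilution.** One multiplicative factor per sample, log-uniform in
  [0.5, 2], applied to every amplitude — the nuisance housekeeping
  normalization must remove.
* **Outcomes.** A latent log relative risk r ~ N(0, 1) drives an
  exponential event time with hazard 0.10·exp(r)/year, independent
  exponential censoring at 0.02/year, administrative censoring at five
  years; subjects are drawn until the case and control quotas fill. The
  synthetic Framingham score is a noisy logistic transform of r — real
  prognostic signal, imperfectly observed — and the CAD pattern score is
  likewise risk-correlated.
* **Jitter.** Observed masses carry uniform error within ±15 ppm and
  migration times within 20% of the half cluster width, so generated
  detections are matchable by construction; the configuration validator
  rejects jitter that could cross the matching tolerances.
* **Randomness** flows from one integer seed; the catalogue, cohort, and
  profiles use documented sub-streams (seed, seed+1, seed+2) so each
  stage reproduces in isolation.

The generator deliberately omits multi-centre batch effects beyond
dilution, correlations between peptides (each is drawn independently),
charge states, isotope envelopes, and any non-log-normal amplitude tails.
Consequently, passing tests demonstrate that the *pipeline machinery* is
correct and calibrated — they say nothing about how strongly real urinary
peptides separate future ACS cases. Indeed, with 40–75 independent planted
two-fold markers the synthetic validation split is typically separated
almost perfectly (AUC near 1), far beyond what real cohorts show; treat
those numbers as a sanity ceiling.

Two test scenarios fix generator parameters by a-priori arithmetic rather
than the defaults. Exact panel recovery (planted set = selected set in at
least 95% of seeds) requires background peptides that cannot cross the
70% frequency filter by sampling noise: with a group of 84, a peptide at
true frequency 0.5 crosses with probability ≈ 1.6e-4, while at 0.65 it
crosses ≈ 17% of the time — so the sporadic background is drawn from
(0.25, 0.5) there. Any eligible null feature would instead be admitted by
Benjamini–Hochberg in about α of the seeds, which is the false-discovery
rate working as designed, not a recovery failure. The null-calibration
check asserts exactly that: with no planted effects the seed-averaged
false-discovery proportion stays within Monte-Carlo error of α.

## Problem sizes

The narrative scripts under `analysis/` run 252 samples × 600 peptides;
the recovery suites use 84 + 84 samples × 150 peptides over 50 seeds and
25 + 25 × 400 over 20–40 null seeds; oracle equivalences run at n ≤ 200.
These sizes were chosen so the whole battery completes in a few minutes on
a laptop while keeping every statistical check well-powered.

## Known limitations

* The calibration and matching steps assume the catalogue's migration
  times are on a common reference timeline; no attempt is made to build a
  catalogue de novo from unaligned profiles.
* Harrell's c intervals use an asymptotic variance; at validation-split
  sizes (n ≈ 84) they are approximate.
* The stepwise Cox procedure inherits the known instabilities of
  stepwise selection; it is provided because the emulated analysis used
  it, with the removal trace exposed for scrutiny.
* Under perfect separation (common on strongly planted synthetic data)
  logistic weights come from a ridge-penalized refit and Wald p-values
  are not reported; the NRI of a perfect reclassifier is 1 with a
  degenerate standard error.
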