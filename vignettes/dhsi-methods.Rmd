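---
title: "Constructing a Depression Health State Index from primary-care records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing a Depression Health State Index from primary-care records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhsi)
library(dplyr)
```

## Overview

Routine primary-care databases record prescriptions, diagnoses, and visits, but
no direct measure of how a depressed patient is doing. This package implements
a *Depression Health State Index* (DHSI): a continuous 0–100 score per
treatment episode, built entirely from such event records. The construction
has five stages:

1. **Cohort selection** — identify incident antidepressant (AD) treatment
   episodes satisfying clinical and data-quality criteria.
2. **Parameter detection** — derive 29 binary indicators per episode: 10
   improvement markers (X1–X10) and 19 worsening markers (Y1–Y19), comparing a
   baseline period around treatment start with a follow-up period.
3. **Scoring** — combine the indicators into positive and negative pre-scores
   using base-6 weights, rank episodes on both, and normalize the mean rank to
   0–100.
4. **Model distillation** — approximate the rank-based index with a linear
   model in the 29 indicators, augmented with interaction terms discovered by
   a regression tree.
5. **Evaluation** — held-out residual dispersion, and a face-validity check
   against a prescription-gap remission proxy.

A synthetic event-stream generator supplies reproducible data for the whole
pipeline; no real patient data are used or required.

## Cohort selection

`select_episodes()` scans each patient's event stream for AD prescription
dates that can serve as an episode *index date*. The criteria, each applied
independently:

* **Monotherapy**: exactly one distinct AD molecule prescribed on the index
  date.
* **Washout**: no AD prescription in the 183 days before the index date.
  Because every AD date is screened as a candidate, an AD shortly before a
  tentative index does not simply delete the episode — if a qualifying
  depression diagnosis lies within 61 days of the *earlier* date, the episode
  anchors there instead.
* **Incident depression**: at least one depression diagnosis within ±61 days
  of the index date, and none in the interval [index − 183, index − 62] days.
* **Adult**: age ≥ 18 at the index year, computed from a birth-year record
  with a mid-year (July 1) convention.
* **Data coverage**: at least 183 days of recorded data before the index and
  275 days after; the post-index requirement is waived when the patient dies
  within 275 days (the follow-up is then truncated at the death date).
* **Lifetime exclusions**: any bipolar or schizophrenia diagnosis, whenever
  recorded, removes the patient.

Each episode carries two comparison windows: a **baseline** of
[index − 152, index + 31] days and a **follow-up** of
[index + 92, index + 275] days. The gap between them avoids attributing the
immediate titration phase to either period.

## The 29 parameters

`detect_parameters()` computes per-window summaries (visit counts,
inter-visit intervals, distinct psychiatric molecules, hypnotic and somatic
prescription counts, somatic comorbidity codes, coverage-weighted mean daily
dose of the index molecule) and turns them into binary flags. A few
design points worth noting:

* **Count comparisons are strict** (X4/Y9 visits, X6/Y16 psychiatric
  molecules, X7/Y17 hypnotics, X8/Y18 somatic prescriptions): equality sets
  neither the improvement nor the worsening flag.
* **Visit-interval flags (X3/Y14)** require at least three visits in each
  window so that a mean and a standard deviation are defined; X3 fires when
  the follow-up mean interval exceeds the baseline mean by more than one
  baseline standard deviation, Y14 symmetrically below.
* **X5 (no depression code at last visit)** is vacuously true when the
  follow-up contains no visits at all; absence of contact is read as absence
  of a recorded depression code.
* **X1/X2 (prescription-free consecutive visits)** look for a consecutive
  visit pair in follow-up without an AD (X1) or psychiatric co-prescription
  (X2) on either date, and additionally require no later AD *or* psychiatric
  co-prescription within the follow-up.
* **Dose flags (X10/Y15)** apply only when every AD prescription between
  baseline start and follow-up end is the index molecule; the follow-up
  coverage-weighted mean daily dose is compared strictly against a reference
  dose taken from the last 30 days of baseline.
* **Treatment-pattern flags**: Y7 (switch) detects a different AD molecule
  starting near the end of the index molecule's coverage; Y11 (combination)
  a second AD overlapping well before that end; Y12 (augmentation) an
  antipsychotic added during AD coverage; Y13 (relapse) a psychiatric
  treatment restarted 45–183 days after all AD coverage lapses.
* **Incident-event flags** (self-harm, hospitalization, and similar) are
  presence-in-follow-up; Y10 (new psychiatric comorbidity) additionally
  requires the code to be absent from baseline.

## Weights and scoring

Each parameter has a *value code* (1–3, clinical importance) and an
*exponent* (0–10, severity tier); its weight is `value_code * 6^exponent`.
Base 6 makes the weight tiers lexicographic: any flag in a higher tier
outweighs all flags of lower tiers combined, so the pre-score orders episodes
first by their most severe marker. The most severe worsening marker (Y1,
suicide attempt/self-harm) carries `3 * 6^10 = 181,398,528`; the full
positive scheme tops out at 51,078.

`pre_scores()` produces a positive and a negative pre-score per episode.
`rank_episodes()` ranks episodes ascending on the positive pre-score and
*descending* on the negative pre-score (ties share average ranks), then
averages the two ranks. `normalize_dhsi()` maps mean ranks linearly onto
[0, 100]. Two consequences of this design that users should keep in mind:

* The index is **relative to the scored set**: ranks, and therefore scores,
  change when episodes are added or removed. Held-out episodes are ranked and
  normalized among themselves, never against the learning sample.
* Normalization requires at least two distinct mean ranks; a degenerate set
  raises an error rather than returning arbitrary values.

A worked example:

```{r}
scores <- tibble::tibble(pos_prescore = c(50000, 45000, 60000, 55000),
                         neg_prescore = c(1000, 15000, 2500, 10000))
ranked <- rank_episodes(scores)
ranked$dhsi <- normalize_dhsi(ranked$mean_rank)
ranked
```

## Model distillation

The rank-based index cannot score a new episode in isolation, so it is
approximated with linear models that can.

* `fit_initial_model()` regresses the index on the 29 indicators by ordinary
  least squares. Exactly collinear columns are detected by a rank-revealing QR
  decomposition (tolerance `1e-8`) and dropped, with the dropped terms
  recorded on the fitted object.
* `grow_interaction_tree()` grows a binary regression tree on the learning
  sample. At each node the candidate split on each parameter is evaluated by
  the absolute difference in child means; a split is admissible only if both
  children contain at least `min_node_size` episodes (default 50) and is
  accepted only if its error-sum-of-squares reduction exceeds `delta_r2`
  (default 0.01) of the root total sum of squares. Ties prefer the larger SSE
  reduction, then parameter order, making growth deterministic.
* `derive_interactions()` reads interaction pairs off the tree as all
  ancestor–descendant splitter pairs along root-to-leaf paths, deduplicated.
  The ancestor (rather than parent–child only) reading is chosen because a
  variable deep in a branch is still conditioned on every split above it; a
  `parent_child` mode is available for the narrower reading.
* `fit_improved_model()` refits with the product columns appended.
  `predict_dhsi()` applies either model and clamps predictions to [0, 100],
  reporting how many values were clamped — the linear approximation can
  extrapolate outside the meaningful score range, the index itself cannot.

`tidy()` and `glance()` methods expose coefficients and fit statistics;
`autoplot()` draws observed-versus-predicted and quartile-remission charts.

## Evaluation

`split_learning_test()` makes a deterministic, seeded 90/10 split.
`evaluate_on_test()` scores the held-out episodes among themselves, predicts
them from the fitted model, and summarizes the residuals (dispersion as
`sqrt(sum(r^2) / (n - 1))`, plus mean, median, IQR, and range).

`remission_proxy()` flags an episode as remitted when the follow-up window
contains a gap of at least 45 days free of AD coverage, with prescription
coverage intervals merged first; gaps at the window edges count.
`quartile_report()` cuts scores at the conventional (type-7) quartiles with
ties assigned to the lower quartile and reports remission rates per quartile.
Rising remission across quartiles is the face-validity check: a higher index
should mean a better-off episode.

```{r}
cfg <- dhsi_sim_config(seed = 42)
m <- generate_parameter_matrix(5000, cfg)
sc <- score_episodes(m)
quartile_report(sc$dhsi, m$remission_truth)
```

## The synthetic generator

`generate_event_stream()` simulates per-patient registration spans, visit
streams with exponential gaps, AD initiation with repeats, dose titration,
switching, combination and augmentation patterns, co-prescriptions,
diagnoses, rare adverse events, pregnancy, and death. It is a study
environment, not a calibrated CPRD emulator: event rates are plausible but
not fitted to real data, and within-patient correlation is limited to a
single latent severity.

`generate_parameter_matrix()` skips the event level: each episode draws a
latent severity `N(0, severity_sd)`; each flag fires with probability
`prevalence + loading * severity` (clamped to [0, 1]), with negative loadings
for X flags and positive for Y flags; remission truth is Bernoulli with
probability `base − slope * severity` (defaults 0.65 and 0.18). This couples
the indicators and the outcome through severity, so a well-constructed index
should—and does—stratify remission without the generator ever seeing the
weighting scheme.

All generator parameters live in `dhsi_sim_config()` and every run is fully
determined by its `seed`.

## Numerical and design choices

* Weights reach `3 * 6^10 ≈ 1.8e8`, far inside exact double-precision integer
  range; pre-scores are computed by matrix multiplication and are exact.
* Tie handling uses average ranks throughout, matching `rank(...,
  ties.method = "average")`.
* Tree tie-breaks use a `1e-12` tolerance so floating-point noise cannot
  reorder splits.
* Problem sizes in tests and the acceptance script (e.g. 20,000 episodes for
  the quartile check, 90/10 splits, 50-episode node floor) were chosen for
  statistical stability within the runtime budget and are package choices,
  not external requirements.
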