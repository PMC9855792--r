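---
title: "A Bayesian-network treatment-decision model for laryngeal carcinoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Bayesian-network treatment-decision model for laryngeal carcinoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laryngobn)
```

## Why a network, and why this one

Tumor-board decisions for laryngeal carcinoma weigh staging, prerequisites
and guideline knowledge under time pressure. A discrete Bayesian network is
a natural formalism for an *expert-built* decision aid in this setting:
every edge is an explicit clinical causality, every conditional probability
table (CPT) cell is inspectable, and inference is exact and reproducible —
properties machine-learned models struggle to offer when, as is typical in
oncology, only double-digit case numbers are available for training.

This package implements such a model end to end: a generic discrete-network
engine, a rule compiler for eliciting CPTs from guideline-style statements,
a packaged larynx model, the validation workflow, and a synthetic cohort
generator that stands in for clinical records, which are not distributable.

## Model structure

The packaged network (`larynx_model()`) has nine nodes and eighteen edges.

* `T` with states TX, T0, TIS, T1, T1a, T1b, T2, T3, T4a, T4b; `N` with
  NX, N0, N1, N2a, N2b, N2c, N3a, N3b; `M` with MX, M0, M1. These are
  *observable* nodes: evidence is entered here.
* `chemo_tolerance` (tolerant/intolerant), the prerequisite node for
  treatments with a systemic chemotherapy component.
* Five binary *target* nodes: `larynx_surgery`, `radiotherapy`,
  `radiochemotherapy`, `chemotherapy`, `immunotherapy`. Each has `T`, `N`,
  `M` as parents (15 edges). The tolerance node feeds `larynx_surgery`,
  `chemotherapy` and `radiochemotherapy` (3 edges).

Two structural choices deserve comment, since the node/edge counts pin them
down only jointly. First, `M` includes the `M1` state: the model's own
worked example (the 17% anchor below) conditions on distant metastasis, so
a two-state M node could not express it. Second, with eighteen edges and
fifteen used by staging, exactly three tolerance edges exist; we attach
them to the three treatments for which chemotherapy tolerance is clinically
a prerequisite or a major modifier (surgery via fitness for multimodal
therapy, chemotherapy, radiochemotherapy). Both choices are configurable in
custom models; the packaged model fixes them.

`T0` is retained as a declared state for completeness even though the
reference cohort never observes it; with the default empirical T prior its
mass is 0, so entering `T=T0` as evidence raises the explicit
impossible-evidence error rather than returning NaNs.

## From guideline rules to CPTs

The treatment CPTs are large (up to `10 x 8 x 3 x 2 = 480` columns), and
filling them cell by cell is neither transparent nor maintainable. Instead
they are compiled from an ordered set of declarative rules
(`guideline_rule()`, `compile_cpts()`): each rule names a subset of T/N/M
states and a tolerance condition and asserts `P(treatment = true)` for the
matching cells, with an integer priority. Per cell the highest-priority
matching rule wins; among equal priorities the last listed wins (a
disagreement at equal priority is reported); unmatched cells fall back to a
per-treatment default. `P(false)` is always the complement, so compiled
columns are normalized by construction.

The packaged rule file (`inst/extdata/larynx_nccn_like.yaml`) contains two
kinds of entries:

* **Anchors** (priority 5): `P(surgery | T2, N2a, M0, tolerant) = 0.74`
  and `P(surgery | T2, N2a, M1, tolerant) = 0.17`. These two cells are the
  published reference points of the model; `larynx_model()` refuses to
  build the packaged model if a supplied rule set omits or overrides them
  (`require_anchors = FALSE` lifts the check for custom models). We read
  the second published statement — that the metastatic patient "would not
  receive surgical therapy with a probability of 17%" — as
  `P(surgery = true) = 0.17`, consistent with its role as the contrast to
  74%.
* **Guideline-flavored rules** (priorities 1–3): early-stage disease
  (TIS–T2, M0) favors surgery and, if node-negative, radiotherapy;
  locally advanced disease (T3/T4a, M0) favors surgery plus
  radiochemotherapy; unresectable (T4b) or metastatic (M1) disease shifts
  mass to systemic options; chemotherapy intolerance forces
  `P(chemotherapy) = P(radiochemotherapy) = 0` — a hard prerequisite: a
  therapy whose precondition fails is not selectable. All values other
  than the two anchors are our own documented elicitation in the spirit of
  the NCCN-style recommendations, **not** a published table; they are
  deliberately round numbers and should be re-elicited for any clinical
  use.

Root priors: the `T` prior defaults to the empirical T-state distribution
of the reference cohort (counts over 97 cases, e.g. `P(T4a) = 23/97`); no
empirical N/M/tolerance marginals are published, so these default to
uniform and are configurable. Priors are irrelevant once full staging
evidence is entered — the posterior of a treatment node given all its
parents is the CPT column itself — but they matter for partial evidence
and for cohort simulation.

## Inference

`bn_posterior()` implements sum-product variable elimination: CPT factors
are reduced by the evidence, hidden variables are summed out one at a time
(min-degree ordering, a pure cost heuristic — results are identical for
any ordering, which the tests exercise), and the result is normalized.
Evidence with probability zero raises a typed condition
(`bn_impossible_evidence`) rather than returning NaNs.

`bn_enumerate_posterior()` is the correctness oracle: it sums the
chain-rule joint over every completion of the evidence — at most 15,360
states in the packaged model — and must agree with variable elimination to
within `1e-9` on any input. The test suite checks this on 120 seeded random
evidence/query pairs. All distributions use double precision; `1e-9` is
far above accumulated rounding error at this model size and far below any
clinically meaningful probability difference.

Predictions use the argmax rule (`map_state()`), with ties broken by the
declared state order. Treatment nodes declare `false` before `true`, so an
exact 0.5 posterior predicts *against* the treatment; for binary nodes the
rule coincides with a 0.5 threshold.

## Validation workflow

`predict()` on a network and a cohort produces one record per
(case, target): evidence is the case's non-missing observables (missing
staging is marginalized, not imputed), targets are never used as evidence
for one another, and invalid state labels flag the case rather than
silently dropping it. On 92 cases this yields the familiar
`92 x 5 = 460` decision denominators. From these records:

* `accuracy()` — per-target and pooled fraction correct; the pooled counts
  are by construction the sums of the per-target counts.
* `f1_scores()` — F1 with each class in turn as positive, plus the
  true-class-frequency-weighted average. A class with no true and no
  predicted members has undefined F1, reported as 0 by convention; this
  matters because realistic cohorts contain treatments with zero positive
  cases.
* `roc_curve()` / `pr_curve()` — threshold sweeps over the distinct
  posterior values; AUC is trapezoidal, average precision is the
  step-interpolated area (no linear interpolation, matching standard
  practice). Single-class targets return explicit *undefined*/*omitted*
  markers instead of numbers, mirroring how such curves are omitted in
  reports. The micro-averaged AP pools the (score, label) pairs of both
  class orientations.
* `bn_fit()` — parameter learning on the fixed structure: with complete
  data, Dirichlet-uniform posterior-mean counting (`prior_strength`
  pseudo-counts per cell, default 1); with missing data, EM from uniform
  CPTs, jointly enumerating each row's missing variables, stopping when
  the largest CPT change falls below `1e-6` or after 200 iterations (the
  rule is a conventional choice; the fixtures converge in far fewer).
* `kfold_cv()` — seeded shuffle into `k` near-equal folds (remainder
  spread over the first folds, no stratification), learn on `k-1`, score
  the held-out fold.

## The synthetic cohort generator

Real tumor-board records cannot be shipped, so `generate_cohort()` /
`simulate()` draws cohorts that emulate the reference dataset's published
statistics: gender (83:14 of 97), age-group and T-state marginals are the
published empirical frequencies; N, M and tolerance marginals default to
the model priors. Staging and demographics are drawn independently;
treatment truth labels come from one of two modes:

* `"sample"` — each treatment drawn from its CPT given the case's staging.
  This is the *realistic* mode: even the generating model cannot reach
  100% accuracy on it, and with ~92 cases a counting-learned model
  reliably underperforms the expert model, reproducing the qualitative
  cross-validation finding.
* `"argmax_noise"` — truth is the model's own argmax recommendation,
  flipped with probability `epsilon`. This is the *calibration* mode: at
  `epsilon = 0` prediction accuracy is exactly 1, and at `epsilon` the
  expected accuracy is `1 - epsilon`, giving a sharp statistical check of
  the whole harness.

Missingness and inconsistency injection run last: inconsistent records
mark chemotherapy as performed in an intolerant patient, which the
consistency screen (`screen_cohort()`) must catch. The screen's three
rules — invalid label, prerequisite violation, all staging missing — are a
documented reconstruction; the published analysis states only that five of
97 records were excluded as inconsistent, not why. Summaries
(`summarize_cohort()`) report counts and `count/n` fractions against the
pre-exclusion denominator, the convention of the published tables.

What the generator deliberately does **not** emulate: T–N–M dependence
(real staging variables are correlated), demographic–staging association,
site/comorbidity/molecular covariates, and any outcome process. Passing
validation on synthetic cohorts therefore demonstrates the correctness and
calibration of the machinery, not clinical performance; the published
per-treatment accuracies depend on the real, unavailable cohort and are
explicitly out of reach.

## Numerical and design choices

* CPT columns must sum to 1 within `1e-9` (checked on construction and by
  `bn_validate()`); posteriors are normalized before return.
* Network files are JSON with doubles at 17 significant digits, so
  load → save → load round trips are bit-exact. Rule files are YAML
  (written at 17 significant digits as well); rule condition keys are
  `t_states`/`n_states`/`m_states` — a bare `n` key is a YAML-1.1
  boolean and would be silently mangled.
* The GeNIe XDSL exporter is write-only and best effort, for opening the
  model in the GUI modeller; the package never reads XDSL.
* Cross-validation, simulation and the CLI take a single integer seed;
  identical seeds give byte-identical cohorts, fold assignments and
  reports.
* Test and fixture problem sizes: oracle equivalence on 120 random
  queries; marginal calibration at n = 100,000 (tolerance ±0.005);
  noise calibration at n = 2,000 (±3 standard errors); learning-vs-expert
  comparison on ten cohorts of n = 92; parameter-recovery curves at
  n = 500 / 5,000 / 20,000.

## Known limitations

* The packaged rule set is a reconstruction around two published anchor
  probabilities; it is guideline-flavored, not guideline-faithful, and is
  clearly marked as such in the rule file.
* Per-cell parameter recovery from counting is hopeless at realistic
  sample sizes: the three four-parent treatment CPTs have 480 columns
  each, so a 20,000-case cohort leaves the rarest observed columns with a
  handful of cases and per-cell errors of order 0.1–0.5 even though the
  frequency-weighted mean CPT error is below 0.02. This is a property of
  the problem, not of the estimator, and it is the quantitative face of
  why the expert-built model beats cross-validated learning here.
* Only preoperative primary-treatment decisions are modelled; adjuvant
  therapy, recurrence, utilities/decision nodes, continuous variables and
  approximate inference are out of scope.
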