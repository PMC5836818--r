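---
title: "Cumulative prognostic power of gene sets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cumulative prognostic power of gene sets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(progsig)
```

## The problem

A single prognostic gene is rarely a good biomarker on its own, and a gene
family (for example the laminins in colorectal cancer, whose analysis shaped
this package's design) may carry prognostic information *cumulatively* that
none of its members carries alone. `progsig` quantifies that cumulative
prognostic power: it exhaustively trains classifiers on subsets of a gene
family across a multi-cohort expression meta-set, discards weak classifiers
on held-out cohorts, and measures what survives on a final, untouched testing
cohort.

The design guards against the two classic failure modes of signature
discovery: overfitting (the filtration cohorts are never used for training,
and the testing cohort is touched only by classifiers that already passed
filtration) and optimistic significance (significance is assessed by label
permutation with the *most conservative* of three strategies reported).

## The procedure

1. **Ingest.** Per-cohort log2 expression matrices (plain TSV or the GEO
   Series Matrix table section) and clinical tables. Inputs must already be
   normalized onto one scale (e.g. jointly RMA-processed arrays or
   equivalently normalized RNA-seq); `check_cohort_scale()` warns when cohort
   medians differ by more than 2 log2 units. When a platform carries several
   probes per gene, `collapse_probes()` keeps the probe with the highest mean
   log2 signal across the joint meta-set (ties broken by smallest probe id).
   Genes whose 95th percentile of log2 expression across the joint meta-set
   is strictly below 7 are removed as stably low-expressed
   (`filter_low_expression()`).

2. **Label.** `label_cohort()` maps clinical records to classes: patients
   with recurrence within 36 months are positives; patients without
   recurrence and at least 48 months of follow-up are negatives; patients
   with unknown recurrence status, or any usable time of at most 1 month, are
   excluded everywhere. Late recurrences (after 36 months) and
   short-follow-up patients are excluded from classification but retained in
   the survival population, so Kaplan-Meier comparisons run on the complete
   cohort.

3. **Train.** For each gene subset, a soft-margin linear SVM
   (`train_linear_svm()`, libsvm via e1071) is fit on the training cohort.
   Features are z-scored per gene on the training samples and the transform
   is frozen into the classifier, so independent cohorts are scored on
   exactly the training scale. The recurrence class maps to +1: a positive
   weight means higher expression goes with higher recurrence risk.

4. **Filter.** The trained classifier is applied unchanged to each
   filtration cohort. It survives iff training AUC ≥ 0.6 *and* every
   filtration AUC ≥ 0.55, boundary equality passing ("not less than"). AUC
   uses midrank tie handling, so it equals the probability that a random
   positive outscores a random negative with ties worth one half.

5. **Test.** Only survivors touch the testing cohort: testing AUC on the
   classified samples, plus a Kaplan-Meier comparison of the two predicted
   risk groups over the complete testing survival population, split at the
   classifier's decision boundary (score 0), with a two-tailed log-rank test.

6. **Significance.** `permutation_test()` permutes class labels under three
   strategies — training cohort only (with retraining), testing cohort only,
   and both independently — recomputes the testing AUC for every permutation,
   and reports per strategy `p = (r + 1) / (n + 1)` where `r` counts permuted
   AUCs at least as large as the observed one. The reported p-value is the
   maximum over strategies. Filtration is *not* reapplied inside
   permutations: it conditions on fixed cohorts, and re-filtering would
   conflate subset selection with the hypothesis being tested.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `train_threshold` | 0.6 | AUC | minimum training AUC to survive filtration |
| `filter_threshold` | 0.55 | AUC | minimum AUC on *each* filtration cohort |
| `recurrence_window` | 36 | months | recurrence at or before this time = positive |
| `followup_min` | 48 | months | event-free follow-up needed for a negative |
| `early_exclusion` | 1 | months | usable time at or below this = excluded |
| `cost` | 1 | — | SVM soft-margin penalty |
| `percentile` / `expression_threshold` | 0.95 / 7 | — / log2 | low-expression gene filter |
| `n` (permutations) | 10000 | — | Monte Carlo draws per strategy |

The SVM cost is deliberately left at 1 and recorded in every output: the
filtration cascade, not the regularization path, is the overfitting control
in this design, and the results of interest (pass/fail, rankings) are stable
over moderate cost changes because all cohorts are scored with the same
frozen classifier.

## Numerical choices

* **Probe collapse statistic.** "Highest signal intensity" is
  operationalized as the highest *mean* log2 signal across the joint
  meta-set. The mean is deterministic and scale-stable; max or median across
  samples would be defensible too, and the choice is frozen in one place
  (`collapse_probes()`).
* **Percentile rule.** The low-expression filter uses `stats::quantile()`
  type 7 (linear interpolation between order statistics), computed on the
  pooled meta-set rather than per cohort, because one filter governs the
  whole analysis. Removal is strict (`< 7`): a gene sitting exactly at 7
  stays.
* **Boundary semantics.** Calendar phrases are frozen as months: 3 years =
  36.0, 4 years = 48.0, first month = 1.0, with recurrence ≤ 36 positive,
  follow-up ≥ 48 negative, usable time ≤ 1 excluded. The first-month
  exclusion is applied to censored records as well, so every survival record
  has time > 1 month.
* **Ties.** AUC uses midranks; the product-limit estimator processes events
  before censorings at tied times (both standard).
* **Two-tailed log-rank.** Realized as the upper tail of the chi-square(1)
  distribution of the squared standardized log-rank statistic — the standard
  two-sided form; stated explicitly because "two-tailed" is ambiguous for a
  chi-square statistic. This p-value is asymptotic: in very small groups
  (a dozen subjects) it can differ from the exact permutation p by ~0.01–0.02,
  which is a property of the approximation, not of the implementation.
* **Solver determinism.** libsvm with a fixed termination tolerance of 1e-3
  (its default). On non-separable problems — every permuted-label refit —
  a much tighter tolerance inflates solve time by two orders of magnitude
  while moving weights by less than 1e-5, far below any quantity this
  pipeline reports. There is no randomized initialization anywhere; all
  randomness flows from explicit seeds.
* **Sign convention.** libsvm orients its decision values toward the first
  label it encounters in the data, so training rows are always ordered
  positives-first; the convention (positive score = predicted recurrence) is
  structural, never patched after the fact.
* **Degenerate inputs.** Zero-variance genes get scale 1 with a warning;
  single-class cohorts are errors; a risk-group split that puts every sample
  on one side warns and yields no log-rank p.

## The synthetic meta-set generator

`generate_meta_set()` emulates the structure of a four-cohort recurrence
meta-set: one training, two filtration, one testing cohort; a gene family
(default 10 genes, N(8, 1.5²) log2 units), decoy genes with the same law,
and stably low-expressed genes (N(4, 0.5²)) constructed to fall below the
95th-percentile/7 filter. A latent risk score — the planted weight vector
dotted with the family expression, standardized by its theoretical moments —
enters an exponential recurrence-time model:
log hazard = log(baseline) + `hazard_log_ratio` × risk. Censoring is an
independent exponential whose rate is chosen so the expected censored
fraction at baseline equals `censoring_rate`, truncated by an administrative
follow-up window drawn uniformly on 6–120 months. The window is what makes
all four labeling categories (positive, negative, short-follow-up censored,
late event) occur with non-trivial frequency. Per-cohort batch offsets
(default ±0.25 log2 units) exercise the frozen standardization.

What the generator does **not** emulate: probe-level noise, realistic gene
co-expression (family genes are independent given the batch), non-exponential
hazards, and informative censoring. Passing tests on synthetic data therefore
demonstrate that the machinery is correct and calibrated under the stated
model, not that any particular real signature will validate.

### Presets

`presets()` freezes four configurations. `null`, `weak` and `strong` share
simulation-study cohort sizes (180/80/80/160) — large enough that every
labeling category is well populated, small enough that hundreds of replicates
are routine — and differ only in `hazard_log_ratio` (0 / 0.5 / 1.5). The
planted signature lives on FAM01 (weight 1.0) and FAM02 (0.8). The strong
preset's effect size was fixed by a recovery simulation — the preset is
*defined* as the configuration where the planted pair is reliably the
top-ranked pair, and the routine suite re-verifies recovery in at least 90%
of 100 seeds; the baseline hazard of
0.01 events/month gives a ~30% three-year recurrence probability, typical of
stage II–III colorectal cohorts. `table1_scale` keeps the strong parameters
at the cohort sizes of the four-cohort colorectal meta-set that motivated
this design (519/129/144/225).

## Validation summary

The test suite validates each stage against independent oracles: exhaustive
pair counting for AUC, hand-computed product-limit tables, a permutation
reference for the log-rank test, a brute-force margin maximizer for the SVM,
direct counting for the permutation p estimator; plus calibration studies on
synthetic data (type-I error of the log-rank at the 5% level, uniformity of
null permutation p-values, planted-signature recovery, null survivors
centered at AUC 0.5). Problem sizes in the routine suite are the preset
sizes above; all statements above about calibration are recomputed by the
suite, not quoted.

## Known limitations

* The exact SVM configuration behind any particular published signature
  (solver, cost, standardization) is typically unreported; weight *signs*
  and orderings transfer, exact weight values do not. Treat published
  weights as orientation checks.
* The log-rank p is asymptotic (see above); for groups of a few dozen or
  fewer, prefer the permutation machinery.
* No multiple-testing correction is applied across subsets — by design the
  cascade plus conservative permutation p is the error control; the
  per-subset `km_p` values in the report are descriptive.
* The filtration decision applies the training-cohort classifier unchanged
  to filtration cohorts (no per-cohort retraining): with a fixed classifier
  this is the only reading under which "evaluated independently on held-out
  cohorts" is meaningful, but it is an interpretation.
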