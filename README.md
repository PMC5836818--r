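# progsig

Cross-cohort prognostic power of gene-set classifiers.

## What it does and for whom

Expression of a single gene is often a weak prognostic biomarker, while a
*set* of related genes — a gene family such as the laminins in colorectal
cancer — can carry substantial cumulative prognostic power. `progsig` is for
computational biologists who want to quantify that cumulative power honestly
across a multi-cohort transcriptomic meta-set, with held-out filtration
cohorts, a fully independent testing cohort, and permutation-based
significance.

For a gene family *G* and a meta-set with one training cohort, one or more
filtration cohorts, and one testing cohort, the pipeline, for every subset
*S ⊆ G* (singletons, pairs, triples, and the full family):

1. trains a soft-margin linear SVM on per-gene z-scored expression of *S*,
   with the recurrence class mapped to +1 — the decision score is
   *f(x) = wᵀ(x − μ)/σ + b*, and a positive weight means higher expression,
   higher recurrence risk;
2. keeps *S* only if AUC ≥ 0.6 on the training cohort **and** AUC ≥ 0.55 on
   every filtration cohort (the trained classifier applied unchanged; AUC is
   the midrank Mann–Whitney form, so ties count one half);
3. for survivors only, computes the testing-cohort AUC and a Kaplan–Meier /
   two-tailed log-rank comparison of the two predicted risk groups (split at
   decision score 0) over the complete testing survival population;
4. estimates significance by Monte Carlo label permutation under three
   strategies (training labels only with retraining, testing labels only,
   both independently), reporting per strategy *p = (r+1)/(n+1)* and, as the
   headline value, the **maximum** (most conservative) of the three.

Patients enter classification as positives (recurrence within 36 months) or
negatives (no recurrence, ≥ 48 months follow-up); unknown-status and
first-month records are excluded everywhere, and late recurrences /
short-follow-up patients stay in the survival analysis only.

A synthetic meta-set generator with a planted linear risk signature
(exponential recurrence times, independent censoring, per-cohort batch
shifts, decoy and stably low-expressed genes) makes every stage testable
without downloading anything.

## Worked example

```r
library(progsig)

meta <- generate_meta_set(presets(seed = 7)$strong)
meta
#> meta_set: 62 genes (family of 10), cohorts:
#>   train [training]: 180 samples (58+, 39-)
#>   filter1 [filtration]: 80 samples (27+, 17-)
#>   filter2 [filtration]: 80 samples (25+, 19-)
#>   test [testing]: 160 samples (47+, 32-)

res <- run_search(meta, sizes = c(1, 2), include_full = TRUE)
res
#> search_result: 56 subsets evaluated, 20 passed filtration
#>                                                     gene_set auc_train
#>                                                  FAM01,FAM02 0.8965517
#>  FAM01,FAM02,FAM03,FAM04,FAM05,FAM06,FAM07,FAM08,FAM09,FAM10 0.9376658
#>                                                  FAM02,FAM09 0.7206012
#>                                                  FAM02,FAM03 0.7130858
#>                                                        FAM02 0.7170645
#>   auc_test         km_p
#>  0.8816489 2.792655e-08
#>  0.8151596 5.424774e-08
#>  0.7932181 3.375333e-03
#>  0.7912234 1.515624e-03
#>  0.7898936 4.969212e-03

permutation_test(c("FAM01", "FAM02"), meta, n = 999, seed = 7)
#> permutation_result: observed testing AUC = 0.8816 (n = 999 per strategy)
#>   train_only p = 0.044
#>   test_only  p = 0.001
#>   both       p = 0.001
#>   reported (most conservative) p = 0.044
```

Reading the output: the generator planted its risk signature on FAM01
(weight 1.0) and FAM02 (0.8), and the search recovers exactly that pair as
the top-ranked survivor — its testing AUC (0.88) beats the full 10-gene
family (0.82) because the eight unweighted genes only add noise. The
Kaplan–Meier split of the testing cohort separates strongly
(log-rank p ≈ 3e-08). The permutation test shows why the conservative
maximum matters: permuting the *testing* labels destroys the signal
completely (p = 0.001), but with only two genes a *retrained* classifier on
permuted training labels sometimes lands near ±(original direction) by
chance, so `train_only` is the binding strategy (p = 0.044) and is what gets
reported.

Run the same thing from a shell:

```sh
Rscript inst/cli/progsig generate --preset strong --seed 7 --out-dir data/
Rscript inst/cli/progsig search --dir data/ --sizes 1,2 --full --out-dir run/
```

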