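# tgrade — transcriptomic grading of breast tumours from RNA-seq counts

Histologic grade (HG) stratifies breast tumours 1–3 by differentiation and
is one of the strongest prognostic factors in the clinic, but roughly half
of all patients receive the intermediate grade 2, which carries little
information for treatment decisions. `tgrade` implements a transcriptomic
grade (TG): an expression-based dichotomisation of tumours into high and low
grade that is trained on the unambiguous HG1 and HG3 cases and then used to
split HG2 patients into groups with genuinely different recurrence risk.

The core model is an elastic-net penalised logistic regression on
variance-stabilised gene- or isoform-level counts,

&nbsp;&nbsp;&nbsp;&nbsp;min<sub>β₀,β</sub> −ℓ(β₀, β) + λ [ α‖β‖₁ + (1−α)‖β‖₂²/2 ],

evaluated under class-balanced nested Monte-Carlo cross-validation: an outer
loop of 90/10 splits stratified by grade (the same splits reused across
every model being compared) and an inner repeated 10-fold CV that tunes
(α, λ) over the grid α ∈ {0.001, …, 0.9} by misclassification error (or mean
binomial deviance for cross-cohort transfer). Held-out P(HG3) probabilities
are pooled into one ROC; the decision cutoff is the point closest to the
top-left corner, and an HG2 tumour is called HG2-High when its probability
is ≥ the cutoff. Around this sit the supporting analyses: subcomponent
(tubularity/nuclearity/mitotic-count) regression grading summed into a
composite score, a genomic-grade-index (GGI) comparator with train-anchored
[−1, 1] standardisation, voom-style moderated-t differential expression with
BH FDR and hypergeometric over-representation, Kaplan–Meier/log-rank and
Cox proportional-hazards recurrence-free-survival comparisons, and a
selection-frequency biomarker-panel derivation from the CV rounds.

Because the clinical cohorts such a model is built on are access-controlled,
the package ships a first-class synthetic cohort generator
(`simulate_cohort()`): negative-binomial counts with log-normal gene
baselines, grade acting through a latent dosage (HG1 = 0, HG2-low = 0.25,
HG2-high = 0.75, HG3 = 1) so that HG2 reclassification has a recoverable
truth, isoform structure with opposite-direction effects, subcomponent
scores with unequal molecular coupling, and grade-dependent recurrence
hazards. Every stage of the pipeline is tested against this generator's
ground truth.

## Worked example

```r
library(tgrade)

cfg    <- simulation_config(n_samples = 275, n_genes = 600, lfc_scale = 2, seed = 1)
cohort <- simulate_cohort(cfg)
cohort
#> tg_cohort: 275 samples, 600 genes, 1162 isoforms (grades 32/120/123)

x    <- t(vst_like_transform(cohort$genes)$values)
hg13 <- cohort$clinical$grade %in% c(1, 3)
y    <- as.integer(cohort$clinical$grade[hg13] == 3)

splits <- make_mc_splits(y, rounds = 10, test_frac = 0.1, seed = 1)
cv     <- nested_cv(x[hg13, ], y, elastic_net_spec(), splits,
                    inner_reps = 1, inner_folds = 5, seed = 1)
cv
#> nested MC CV: 10 rounds, pooled AUC = 1.000 (95% CI 1.000-1.000), threshold 0.675
```

The pooled AUC is the cross-validated accuracy of separating grade 1 from
grade 3; the threshold is the top-left ROC cutoff later applied to HG2
tumours. Reclassify the grade-2 samples and ask whether the two TG groups
differ in recurrence-free survival:

```r
tuned <- tune_alpha_lambda(x[hg13, ], y, elastic_net_spec(),
                           inner_reps = 1, inner_folds = 5, seed = 1)
model <- fit_elastic_net_logistic(x[hg13, ], y, tuned$alpha, tuned$lambda)
hg2   <- cohort$clinical$grade == 2
calls <- reclassify_hg2(model, cv$threshold, x[hg2, ])
table(calls$label)
#> HG2-High  HG2-Low
#>       58       62

rec <- rfs_records(cohort$clinical, calls = calls)
cox_fit(rec, stratify_dataset = FALSE)
#> HR = 3.68 (95% CI 1.42-9.53), Wald p = 0.00735
```

The hazard ratio compares HG2-High against HG2-Low: the transcriptomically
high-grade half of the intermediate tumours recurs substantially faster,
which is exactly the stratification TG is meant to provide. Against the
generator's latent subclasses the calls above are 100 % correct.

`run_pipeline(pipeline_config(...))` chains the same stages (preprocessing,
grading, reclassification, DE, survival) behind one configuration object,
reads/writes TSV/MTX counts and CSV clinical tables, and emits a manifest
whose hash is stable across reruns at a fixed seed.

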