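---
title: "Transcriptomic grading: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptomic grading: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`tgrade` turns bulk RNA-seq count matrices and a clinical table into a
dichotomous transcriptomic grade (TG) for breast tumours, with the explicit
goal of resolving the uninformative intermediate histologic grade (HG2).
This vignette is the package's own account of the statistics it implements:
the models and their assumptions, the conventions where several were
defensible, and what the bundled synthetic cohorts do and do not establish.

## The grading model

TG is an elastic-net penalised logistic regression of P(high grade) on
variance-stabilised expression, trained only on the unambiguous HG1 and HG3
tumours. The penalty is `lambda * (alpha * |b|_1 + (1 - alpha) * |b|_2^2 / 2)`
on internally standardised predictors, with coefficients reported on the
original scale; the solve is delegated to glmnet, whose parameterisation
matches this contract exactly. The logistic model assumes effects that are
additive on the log-odds scale after the variance-stabilising transform —
a deliberately simple model: with tens of thousands of correlated features
and ~150 labelled samples, the penalty, not the link function, does the
statistical work.

Performance is estimated by **class-balanced nested Monte-Carlo
cross-validation**. The outer loop repeatedly holds out
`round(0.1 * class size)` samples per class (at least one), so both classes
keep their prevalence on both sides of the split; the identical split list
is reused across every model being compared, which makes paired AUC
comparisons (DeLong) meaningful. The inner loop is repeated stratified
k-fold CV over a fixed alpha grid
(0.001, 0.005, 0.01, 0.05, 0.1, 0.2, 0.3, 0.5, 0.7, 0.9) and, per alpha, a
log-spaced 100-point lambda path from the data-driven maximum down to
`1e-4` of it. Within-cohort tuning minimises misclassification at
probability 0.5 (the inner cutoff is a package choice; nothing downstream
depends on it strongly), cross-cohort tuning minimises mean binomial
deviance. Ties are broken toward larger lambda, then larger alpha — i.e.
toward the sparser, more penalised model.

Three conventions in the CV harness deserve a note:

* **Pooling.** Held-out probabilities from all rounds are pooled into a
  single ROC rather than averaging per-round ROCs. Pooling uses every
  held-out prediction at its natural weight and yields one threshold; the
  alternative (vertical averaging) was rejected because the per-round test
  sets are tiny (a handful of samples) and their individual ROCs are
  degenerate step functions.
* **Threshold.** The decision cutoff minimises `(1 - TPR)^2 + FPR^2`
  (distance to the top-left ROC corner), evaluated at cutoffs midway
  between consecutive distinct scores. Exact ties go to the smaller cutoff,
  i.e. toward sensitivity — the clinically conservative direction for a
  high-risk call. A sample exactly at the cutoff is called high grade.
* **Reuse for HG2.** The final model is refit on all HG1/HG3 samples with
  freshly tuned (alpha, lambda), and HG2 tumours are dichotomised at the
  pooled-CV threshold. The threshold therefore reflects held-out, not
  resubstitution, operating characteristics.

For cross-dataset transfer both cohorts are reduced to their shared feature
space and **mean-centred per dataset** (each feature to mean zero within
each cohort). This removes global per-gene location offsets — the dominant
batch artefact between separately profiled cohorts — but deliberately not
scale or covariance differences; anything more aggressive would need
distributional assumptions the package does not want to impose silently.

## Preprocessing

Counts-per-million filtering keeps a feature when CPM ≥ 1 in at least 75 %
of samples. The boundary is **inclusive** (3 of 4 samples passes at 0.75);
the filter is idempotent and is applied to isoform matrices by default
(gene matrices can opt in), since isoform quantifications carry far more
near-zero features. TMM scaling factors are computed by edgeR's
implementation (log-ratio trim 30 %, abundance trim 5 %,
precision-weighted M-value mean, reference = library whose 75th-percentile
CPM is closest to the mean of those percentiles) and rescaled to geometric
mean 1; an independent brute-force trimmed-mean oracle cross-checks them in
the test suite. The prediction-side transform is the package's own
`vst_like_transform()`: median-of-ratios size factors over features with
all-positive counts, then `log2(count / sf + 1)`. A spline-based variance
stabilisation would differ in the exact variance profile, but the grading
model only needs a monotone, roughly variance-stabilising input, and the
median-of-ratios map is exact under pure library scaling; the convention is
recorded in the returned object's metadata. When no feature is positive in
every sample the transform falls back to library-size factors with a
warning rather than failing.

## Differential expression and enrichment

DE uses the package's own voom-style pipeline: log2-CPM with the 0.5/+1
pseudo-count convention on TMM-corrected effective library sizes, a lowess
(span 0.5) trend of sqrt residual SD against mean log-CPM, per-observation
weights as the inverse fourth power of the trend at each fitted value, then
per-feature weighted least squares with empirical-Bayes variance
moderation. The prior degrees of freedom `d0` and scale `s0^2` are
method-of-moments estimates on the log residual variances (the trigamma
inversion solved by Newton iteration); the moderated t has `d0 + d_resid`
degrees of freedom, and setting the prior off (`prior = "none"`) recovers
the ordinary pooled-variance t exactly — a limit the test suite asserts to
1e-9, alongside exact agreement with limma's `eBayes` on shared fixtures.
Significance everywhere is FDR < 0.05, strict. Fewer than 10 features is
too few to estimate a mean-variance trend; the weights fall back to unity
with a warning. Over-representation is the hypergeometric upper tail
`P(X >= overlap)` against a user-supplied universe, BH-adjusted across
sets; gene sets come from standard GMT files. The covariate-adjusted DE
variant (tumour size, nodal status) enters as extra columns of the
per-feature design; the default contrast is unadjusted.

## Survival

The endpoint is recurrence-free survival with a composite event (relapse,
metastasis, contralateral tumour, or death from any cause — a death without
documented relapse is treated as undetected metastasis), time measured in
years from diagnosis. Group comparisons use Kaplan–Meier estimates with the
log-rank test; hazard ratios come from Cox partial likelihood with
**Efron's tie handling** (the standard default; ties are common at yearly
resolution) and, when two cohorts are pooled, a stratified baseline hazard
per dataset. The adjusted model controls for age (continuous), tumour size
dichotomised at 20 mm, nodal status and ER status. The low-risk group is
always the reference level. Fits with fewer than five events per parameter
warn rather than fail. Both delegated computations (survfit, survdiff,
coxph) sit behind the package's record/estimate types so the covariate and
strata contract is fixed here, not at call sites.

## The genomic-grade-index comparator

The raw GGI score is the unweighted sum of expression over
grade-3-associated genes minus the sum over grade-1-associated genes. The
original microarray index carries probe weights and a cohort-specific scale
constant that are not reproducible from public material; the package
implements the unweighted contrast and records that choice in the score
metadata. Standardisation is the affine map sending the training minimum
and maximum to −1 and +1, applied unchanged to test samples (which may
therefore exceed the interval); it requires at least two distinct training
values and is invariant to any increasing affine transform of the raw
scores. The shipped signature file is an explicitly synthetic placeholder —
users supply the published gene list; tests plant a signature from the
generator's truth.

## Subcomponent grading

Each Nottingham subcomponent (tubularity T, nuclearity N, mitotic count M)
is modelled as a penalised **linear** regression on the numeric subscores
1/2/3 — ordinal alternatives were rejected in favour of the stated linear
treatment — with samples missing that subscore excluded from that
component's fit only. The composite score is exactly `T + N + M` with no
re-scaling, and is dichotomised by the same top-left ROC rule as TG (the
thresholding of the 3–9 composite is not otherwise pinned down; using one
rule across all five models keeps them comparable).

## The synthetic cohort generator

The generator is first-class, tested code, and its defaults are the study
conditions the rest of the package is validated under:

* **Cohort structure.** 275 samples with grade proportions
  (0.142, 0.440, 0.418); a second cohort of 487 is produced by simulating
  762 and splitting 274/488 by the nearest-integer rule, optionally with a
  global log2 batch offset on the second part.
* **Counts.** Negative binomial with common dispersion 0.1 and log-normal
  gene baselines (sd 1.2 on the log scale), expected library sizes uniform
  on 0.5–1.5 million over the simulated gene panel — chosen so that a
  600-gene desk-scale panel carries count depths per gene comparable to a
  20,000-gene transcriptome at 20–50 million reads. No generative model is
  published for the real cohorts; NB with a common dispersion is the
  standard bulk RNA-seq assumption.
* **Grade effects.** Grade acts through a latent dosage (HG1 = 0,
  HG2-low = 0.25, HG2-high = 0.75, HG3 = 1; HG2 subclasses drawn
  fairly), so reclassification has a recoverable truth and HG2 is, by
  construction, a mixture. A fraction `frac_de` (default 0.10) of genes
  carries a ±`lfc_scale` log2 effect per unit dosage with random sign.
* **Isoforms.** Each gene has `1 + Poisson(mean - 1)` isoforms with
  Dirichlet-distributed usage; gene counts are the sum of isoform counts
  ("sum" mode, the default, which makes the two levels exactly consistent).
  In a fraction of multi-isoform grade-associated genes the minor isoform
  carries the opposite-sign effect — flipping the minor isoform keeps the
  gene net grade-associated while creating the isoform-only signal the
  isoform-level analysis is meant to find.
* **Subcomponents.** Subscores are the latent dosage observed through
  component-specific Gaussian noise with sd `0.3 / signal`, discretised at
  1/3 and 2/3, with sporadic missingness. The signal vector defaults to
  (T, N, M) = (0.2, 0.4, 1.0): the mitotic score is the most faithful
  molecular readout and tubularity the least, which reproduces the
  qualitative ordering AUC(M) > AUC(N) > AUC(T) of the subcomponent
  classifiers. Coupling noise — rather than scaling the per-gene effect
  sizes by component — was chosen deliberately: it leaves the HG3-vs-HG1
  expression contrast of grade-associated genes at `lfc_scale` exactly,
  so the grade-level and subcomponent-level properties of the generator do
  not interfere.
* **Survival.** Event times are exponential with hazard
  `baseline_hazard * HR^dosage` (defaults 0.02/year and HR 2.62), censoring
  exponential at 0.18/year plus a 15-year administrative horizon — event
  counts and follow-up in the realistic sparse regime for an early
  breast-cancer cohort.
* **Determinism.** All randomness flows from one master seed through
  counter-based substreams, so any stage can be re-run independently and
  identical configurations are bit-identical.

What the generator does **not** emulate: gene–gene correlation structure
(features are conditionally independent given dosage), gene-specific
dispersions, GC/length biases, subtype mixture structure, or any read-level
artefacts. Passing tests on this generator therefore establish that the
pipeline's statistics behave as designed under their own assumptions — not
that the classifier would reach any particular AUC on a real cohort, where
correlated features make both the signal and the selection problem harder.

## Numerical choices and degenerate inputs

* Probabilities are clamped to `[1e-12, 1 - 1e-12]` inside deviance
  computations; tuning-grid ties use a 1e-12 slack before the
  larger-lambda/larger-alpha tie-break.
* The DeLong variance of paired identical score vectors is zero; the test
  returns z = 0, p = 1 rather than 0/0.
* Zero libraries, single-class labels, constant training GGI scores, zero
  observed events, and score values outside {1, 2, 3} are all hard errors
  naming the offender; all-trimmed TMM and trendless weight estimation
  degrade to unit factors/weights with a warning instead.
* An inner-CV repetition whose folds lose a class is redrawn (with a
  message), up to ten attempts.

## Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` run the full machinery at desk
scale, chosen once as the package's own validation conditions: 275-sample
cohorts over 600-gene panels with 25 outer Monte-Carlo rounds and a 2×5
inner CV for the grading checks; a 762-sample pair (274/488, batch offset
1 log2 unit) for cross-dataset transfer; five independent 100-sample
balanced null cohorts for the chance-level control, reported as their mean
AUC because a single pooled-CV AUC at that size has standard error near
0.08 and would say little about calibration; 100 replicates for Cox CI
coverage and 1000 for log-rank and DeLong test size; ten 1000-feature null
cohorts for moderated-t calibration; and a 500-sample cohort with ten
planted genes and 50 CV rounds for panel selection. These sizes are large
enough that each check's conclusion is statistically stable, and small
enough that the whole suite re-runs in minutes.

## Known limitations

* The elastic-net solver, survival fits and TMM factors are delegated
  (glmnet, survival, edgeR); the package pins their contracts and
  cross-checks them against independent oracles but does not reimplement
  them.
* The variance-stabilising transform is the median-of-ratios log transform
  described above, not a spline-calibrated one; the two differ for
  low-count features.
* `selection_frequency()` requires the per-round nonzero sets from this
  package's own CV result; panel evaluation needs a genuinely external
  cohort (a held-out split substitutes, flagged, when none exists).
* The GGI comparator is the unweighted contrast; results are not
  numerically comparable to the original microarray index.
* No competing-risks modelling, time-varying covariates, or
  proportional-hazards diagnostics beyond what the survival package offers.
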