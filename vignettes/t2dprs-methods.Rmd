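---
title: "Methods: multi-ancestry T2D PRS construction and characterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-ancestry T2D PRS construction and characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t2dprs)
```

## The problem

Polygenic risk scores summarize genome-wide susceptibility to a disease as
a single number per person: a weighted sum of effect-allele dosages with
per-variant log odds ratios as weights. For type 2 diabetes, the score's
predictive value and its clinical correlates must be characterized across
self-identified populations and across contexts (age, sex, adiposity,
comorbidity), because a score built largely from European-ancestry
discovery data does not transfer uniformly. This package implements that
characterization pipeline: harmonizing weight tables to genotype panels,
scoring and standardizing, combining population-specific scores, and
evaluating risk stratification, effect heterogeneity, trait associations,
a phenome-wide scan, and cross-study meta-analysis.

Because the motivating data (multi-cohort consortium and biobank data) are
access-controlled, the package is exercised end to end on synthetic
cohorts with known ground truth. The generator is first-class, tested
code, not a fixture.

## Scoring and standardization

`compute_prs()` forms the weighted sum of effect-allele dosages. The
effect-allele dosage is the panel's alt dosage when the weight table's
effect allele matches alt (`direct`, or `flip` after strand
complementation) and `2 − alt dosage` when it matches ref (`swap`,
`swap_flip`). Missing dosages are mean-imputed per variant, matching the
behaviour of the standard scoring tools.

`standardize_scores()` subtracts the control mean and divides by the
control sample SD (n − 1) within each group. **One z unit is one control
SD**; this is the estimand scale for every odds ratio the package reports.
The default grouping is population; the intermediate standardization used
before score combination groups by population × study, and both groupings
are parameters.

Percentile categories are cut at the 10/20/40/60/80/90th percentiles of
the *control* z distribution within each group (the natural companion of
control-anchored standardization; whether cut-points should instead use
all individuals is not settled, so the category assignment runs on
whatever grouping/score set it is given). Bins are half-open `[low,
high)`: a score exactly at a cut-point goes to the upper bin.

## Variant harmonization

Weight tables meet dosage panels on (chromosome, 1-based position).
Orientation is resolved by exact allele comparison before and after
Watson–Crick complementation. Palindromic pairs (A/T, C/G) cannot be
strand-resolved from alleles alone and are **excluded by default**;
`ambiguous_policy = "assume-plus-strand"` keeps them for users whose
pipelines guarantee consistent strand. Variants are dropped when INFO
< 0.4 or when the effective sample size `2·MAF·(1−MAF)·N·INFO` falls below
30; variants with missing metadata are flagged, never silently kept.
Coordinate/strand changes between genome builds are consumed as a
pre-computed mapping table (`apply_strand_mapping()`); computing liftover
from chain files is out of scope.

## Cross-validated non-negative combination

Population-specific scores are combined by a 3-fold cross-validation
within population × study cells. On the validation folds a logistic model
of case status on all population-specific scores (intercept plus scores;
no covariates, a covariate-adjusted variant can be fit by passing the
adjusted residual scores) is fitted; every predictor whose coefficient is
not strictly positive is removed and the model refitted until all
remaining coefficients are positive or none remain. A coefficient exactly
at 0 is treated as non-positive — the retention rule is a strict
inequality. All negative predictors are removed per iteration; a
one-at-a-time option exists. The retained coefficients weight the held-out
fold's combined score, so each individual is scored exactly once by a
model not fitted on them. Fold assignment is keyed by a stable hash of the
individual id plus the seed, making results independent of row order.
Perfect separation is detected by runaway coefficients (|β| > 15) and the
fold is reported as failed rather than silently imputed. If every
predictor is eliminated the fold's combined score is 0 for all test
individuals and the fit is flagged.

## Risk evaluation

The headline quantity is the OR per control SD from a logistic model
adjusting for age, sex, BMI, the first ten principal components, and study
(as categorical indicators; dropped automatically in single-study data).
Prediabetes individuals are excluded from case/control fits. AUC is the
rank-sum (Mann–Whitney) probability that a random case outranks a random
control, ties counting one half; confidence intervals use the DeLong
method via pROC. AUCs are in-sample, mirroring the usual PRS evaluation
practice, and are therefore mildly optimistic. Category ORs come from one
logistic model with category indicators against the 40–60% reference; with
no covariates this reproduces the 2×2 cross-product ratio exactly, which
the tests assert. Age at diagnosis is regressed on category indicators
among cases with the bottom decile as reference, so coefficients are mean
differences in years.

## Heterogeneity and interactions

Stratified per-SD effects are combined by Cochran's Q with inverse-variance
weights; τ² uses the DerSimonian–Laird moment estimator (the estimator is
not otherwise pinned down by convention) and I² = max(0, (Q − df)/Q)·100.
Heterogeneity is judged at an unadjusted p < 0.05. Interaction tests
compare covariate-adjusted logistic models with and without PRS×context
terms by a likelihood ratio test with one df per interaction term. Both
routes are computed and labelled distinctly since they answer subtly
different questions. Sex is never an adjustment covariate inside sex
strata. Trait associations use linear models (beta, R² increment) for
continuous traits — optionally log-transformed per trait — and logistic
models (OR, AUC) for binary traits, with a Bonferroni threshold of
0.05/20.

The fixed-effect inverse-variance meta-analysis pools per-study estimates
within populations, then pools the population estimates overall; the
two-stage pool equals the one-stage pool exactly (tested algebraically).
τ² and I² are reported descriptively alongside the fixed-effect pool.
Estimates with fewer than 100 cases or 100 controls are dropped with a
logged reason before pooling, including at stage 2; a single eligible
study passes through verbatim with a flag.

## PheWAS

ICD records are mapped to phecodes; a person is a phecode case with at
least 2 mapped records. Count-1 individuals are excluded from controls by
default — the convention of standard phecode tooling; the case rule is
the only one fixed by convention, so `count_one_as_control = TRUE` is
available. Exclusion ranges are honoured when the map provides them; the
bundled map (a small synthetic one covering all 17 disease categories,
clearly labelled synthetic) ships without ranges. Phecodes with fewer than
10 cases are skipped and listed, never emitted. Per-population Bonferroni
thresholds divide 0.05 by the number of phenotypes tested in that
population. Cross-population comparisons correlate log-ORs (a symmetric
scale) with Pearson's r.

## The synthetic cohort generator

`simulate_cohort()` draws, per population, variant MAFs uniformly in the
configured range (default 0.05–0.5, independently per population, so
populations differ in frequency) and genotypes binomially; there is no
linkage disequilibrium, admixture, relatedness or genotyping error — tests
passing here show the statistical machinery is correct, not that any given
real-data result will replicate. Disease status follows a logistic model

    logit(p) = alpha_pop + beta * z + sum(gamma_c * z * x_c) + covariate terms

with z the true score standardized within population. The disease model is
logistic rather than liability-threshold so that truth and analysis model
coincide and recovery tests are exact. Covariate effects (age 0.02/yr, sex
0.25, BMI 0.05/unit, all centered) are fixed, realistic magnitudes.

**The effect scale.** `true_beta_prs` (default log(1.78), a typical
headline T2D PRS effect) is defined per *control* SD — the scale every
fitted model reports. Because cases are preferentially removed from the
top of the score distribution, the control SD of a population-standardized
score is slightly below 1 (about 0.97 at 29% prevalence), which would
otherwise bias recovery tests by a few percent. The generator converts the
control-SD effect to the population-SD scale it simulates on with a
deterministic numeric fixed point (`calibrate_beta`), integrating the
logistic selection over the score and the approximately normal covariate
linear predictor. No data-driven tuning is involved.

Glycemic measurements are generated so that `classify_glycemic_status()`
— fasting glucose ≥ 126 mg/dl, random ≥ 200, HbA1c ≥ 6.5%, or physician
diagnosis for cases aged ≥ 25; fasting 100–125, HbA1c 5.7–6.4% or 2-h OGTT
140–199 for prediabetes aged ≥ 18; controls are unaffected adults ≥ 40 —
reproduces the drawn status exactly (a tested round-trip). The ADA-style
criteria are an OR-union, as written. Glucose is held in mg/dl internally
with a single constant (18.016 mg/dl per mmol/L) for conversion.

Age at diagnosis among cases is `52 + slope * z` plus Gaussian noise (SD 4
years), floored at 25. The default slope of −2.54 years/SD is chosen so
that the expected gap between extreme deciles (case z-gap ≈ 3.5 SD) is
about −8.9 years, a reported magnitude for T2D. Quantitative traits are
`delta * z + noise` (defaults: HbA1c-like 0.034/SD, fasting-glucose-like
0.030/SD, residual SD 0.5). The phenome mixes PRS-linked phecodes (T2D-like
OR 2.38, hypertension-like 1.34, hyperlipidemia-like 1.27) with null
codes; per-person ICD counts are Poisson (mean 2.5) for latent cases with
a 2% count-1 noise floor among non-cases, guaranteeing count-1 individuals
so the minimum-count rule is exercised. Emitted weight tables are noisy
copies of the true effects per source population (SD 0.5 × the weight SD),
with a fraction of rows allele-swapped (weight negated) or strand-flipped
to exercise harmonization; the meta table carries the true effects.

A fixed seed yields byte-identical output.

## Numerical choices and problem sizes

- Wald CIs use a 1.96 multiplier; two-sided p-values from the normal (or
  chi-square for Q and LRT).
- Sample SD (n − 1) throughout; ties at percentile cut-points go to the
  upper bin.
- Degenerate inputs fail loudly with the offending group/cell/field named:
  zero control variance, fewer than 2 controls per group, CV cells smaller
  than k, empty matched variant sets, single-class strata.
- The test suite runs its calibration studies at deliberately modest sizes
  chosen for tight Monte-Carlo control at reasonable cost: 200 replicates
  of n = 1,600 for null CI coverage; 100 replicates of n = 20,000 for
  effect recovery; 200 replicates for Q/LRT type-I rates (n = 2,000) and
  PheWAS family-wise error (100 null phecodes × n = 400); 20 replicates of
  n = 20,000 for interaction power.

## Known limitations

- No LD, admixture or relatedness in the generator; absolute effect-size
  transfer to real genotype data is untested by design.
- In-sample AUC overstates out-of-sample discrimination.
- The PheWAS fixture map is synthetic; real phecode maps drop in via
  `read_phecode_map()` but are never downloaded by tests.
- The non-negative combination fits intercept + scores only, as the
  method's defining regression is usually written; covariates enter
  the evaluation models instead.
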