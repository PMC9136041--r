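---
title: "Methods: serum metabolomics discrimination of concurrent TCM syndromes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serum metabolomics discrimination of concurrent TCM syndromes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Stable angina patients diagnosed with the traditional Chinese medicine
syndrome *intermingled phlegm and blood stasis* (IPBS) frequently carry a
concurrent syndrome on top of it — phlegm stasis with Qi deficiency (PQD),
Qi stagnation (PQS), or toxin (PST).  Telling the pure reference syndrome
apart from its concurrent variants by symptoms alone is unreliable, so the
workflow implemented here asks the serum metabolome two questions:

1. **What is shared?**  Which metabolites are both highly abundant in every
   group and *not* differential in any reference-vs-concurrent comparison —
   a candidate metabolic "essence" of the common syndrome — and which
   pathways are over-represented among them?
2. **What separates?**  Which metabolites discriminate IPBS from each
   concurrent syndrome, and how well does a small linear panel of them
   classify patients?

The pipeline operates on a wide-targeted LC-MS quantification table
(samples × metabolites, non-negative peak areas), a sample metadata table
with the syndrome label, a metabolite annotation table (compound classes
and pathway-compound keys), and a pathway map in GMT format.

## The analysis model

### Preprocessing: two fixed branches

Missing peak areas are imputed with **half the column minimum** of the
positive observed values, the conventional left-censoring assumption for
intensities below the detection limit.  After imputation the pipeline keeps
two parallel matrices and never mixes them:

* **unit-variance scaled** raw intensities (column mean 0, sample sd 1,
  n−1 denominator) feed unsupervised PCA;
* **log2-transformed, mean-centered** intensities feed OPLS-DA.

Both transforms refuse matrices containing missing values, which enforces
the impute → transform order by contract.  Zero-variance columns are set
to zero and flagged rather than producing NaNs.

### PCA and OPLS-DA

PCA is computed by singular value decomposition of the centered matrix;
scores, orthonormal loadings and per-component explained-variance
fractions are returned, and full-rank reconstruction is exact to numerical
precision.

The supervised model is two-class **OPLS-DA** with a single predictive
component and `n_ortho` orthogonal components (default 1, the common
choice for a two-class contrast).  For a univariate class vector the
NIPALS inner loop is closed-form, so each component is extracted exactly:
orthogonal components are identified and deflated from X first, then the
predictive weight is taken as the covariance direction between the
filtered X and the centered ±1 class vector.  The predictive score is
oriented so that the alphabetically later group has a positive mean,
making S-plot signs reproducible.

Per metabolite the model reports:

* **VIP**, computed over the predictive component only and normalized so
  that the mean squared VIP equals 1 — with a single predictive component
  this reduces to `sqrt(p) * |w_j|`;
* the **S-plot** coordinates: covariance `p1 = cov(x_j, t)` and
  correlation `pcorr = cor(x_j, t)` with the predictive score;
* **R²Y**, and **Q²** from stratified 7-fold cross-validation (fold count
  configurable, fold assignment seeded).  The orthogonal filter and
  centering are re-estimated inside each training fold.

Model validity is assessed by a **label-permutation test**: Q² is
recomputed under `n_perm` random relabelings and the empirical P-value is
`(1 + #{Q²perm ≥ Q²obs}) / (n_perm + 1)`, so it can never be 0.

### Screening thresholds

Fold change is the ratio of arithmetic group means on the **raw imputed
intensity scale** (the wide-targeted convention; the log2 matrix is used
only inside OPLS-DA).  With strict inequalities:

* **differential**: VIP > 1 and |log2 FC| > 1;
* **non-differential**: VIP < 1 and |log2 FC| < 1;
* everything else is **indeterminate** — the two definitions deliberately
  do not partition the plane, and boundary cases belong to neither set.

The non-differential fold-change band is symmetric by default (FC strictly
between 0.5 and 2).  A one-sided reading ("FC < 2" only) is available via
`symmetric = FALSE`, but it would classify strong down-regulation as
non-differential, which contradicts the purpose of a "no change" set —
hence the symmetric default.

Per group, the **top-k abundance set** (default k = 100) ranks metabolites
by within-group mean raw intensity, ties broken lexicographically by
metabolite id; the **top-k core** is the intersection across all four
groups.  The **essence set** is the intersection of the top-k core with
the three-way intersection of the per-comparison non-differential sets.

### Enrichment

Pathway over-representation uses the exact hypergeometric upper tail
`P(X ≥ k)`, accumulated from log binomial coefficients (log-sum-exp) so
large compound universes do not underflow.  The background is the set of
*detected* metabolites that carry a compound-key annotation — not the
whole pathway universe — which is the defensible choice when the assay
itself defines what could have been observed.  Unannotated metabolites are
dropped from query and background before counting; pathways with no
annotated background member are not tested.  The enrichment factor is
reported as k/n (the "gene ratio" convention; k/K available via config),
and Benjamini–Hochberg adjusted P-values are always reported alongside the
raw ones.

### Discriminant panels

Fitted panels are **weakly L2-penalized logistic regressions** on raw
candidate intensities (candidates default to the comparison's differential
metabolites).  The penalty (λ = 1e-3 on standardized coefficients,
intercept unpenalized) is there for conditioning, not shrinkage: it keeps
the fit defined under complete separation while leaving coefficients
essentially maximum-likelihood otherwise.  The reported model is
**intercept-free** — a plain weighted sum of intensities — with the
logistic intercept absorbed into the decision cutoff, which is placed at
the Youden-optimal point of the training ROC.  This matches the shape of
the three bundled fixed-coefficient reference panels (IPBS vs PST/PQS/PQD),
whose ~1e-7…1e-4 coefficient magnitudes imply raw peak-area inputs;
raw intensities are therefore the default scale throughout.

ROC curves use the distinct score values as thresholds; the trapezoidal
AUC equals the tie-aware pairwise probability
`P(score_pos > score_neg) + ½P(tie)`, an identity the test suite checks by
brute-force pair counting.  The positive class is the concurrent syndrome,
so sensitivity is the concurrent-syndrome detection rate.  Scores are
never auto-flipped: an AUC below 0.5 is reported as-is with a warning.
Out-of-sample performance is a stratified k-fold cross-validated AUC on
pooled held-out scores.

## The synthetic cohort generator

`generate_cohort()` emulates the study design the pipeline assumes:
164 samples (IPBS 64, PQD 64, PQS 26, PST 10), 800 metabolites in 17
primary and 43 nested secondary classes, and clinical covariates (age,
weight, sex, hypertension, diabetes, fasting glucose, TG, TC, LDL-C) drawn
around the per-group cohort summaries.  Intensities follow a two-level
log-normal model: each metabolite draws a baseline log2 mean once
(mean 17, sd 2.5 across metabolites — peak areas around 1e5, consistent
with the reference-panel coefficient magnitudes), then every sample adds
Gaussian log2 noise (sd 0.8, a typical serum assay CV on the log scale)
and the result is exponentiated.  Class occupancy is skewed so a few
primary classes dominate, as in real serum panels.

**Spikes** shift the log2 mean of one metabolite in one group only.  The
defaults plant one marker per concurrent syndrome — anserine up in PST,
cytidine 5'-diphosphocholine up in PQS, and 7,8-dihydro-L-biopterin *down*
in PQD (i.e. relatively higher in IPBS); the direction is carried by the
sign of `log2_effect`, so the opposite reading of the PQD marker is a
one-line config change.  A planted pathway (`SP_SPIKED`) containing
exactly the spiked markers gives enrichment a known positive, alongside
20 random pathways of 5–40 compounds.

Missing values, when requested, are injected completely at random
(`missing_rate`, default 0): nothing in the emulated workflow describes a
missingness mechanism, so the simplest one is used and documented.

What the generator deliberately does **not** emulate: chromatographic
drift, ion suppression, batch effects, correlated metabolite modules, or
covariate–metabolome dependence.  Passing tests on synthetic cohorts
therefore demonstrate that the *logic* of every stage behaves as specified
under a clean log-normal world — not that the pipeline's thresholds are
clinically tuned for real serum data.

## Numerical and design choices

* Sample (n−1) standard deviation everywhere scaling or covariance is
  involved.
* All identifier sorting uses byte-order (radix) collation, so results do
  not depend on the session locale.
* Seeded randomness is scoped: every stochastic function takes a seed,
  restores the caller's RNG state, and the pipeline derives per-stage
  seeds from the single run seed, so a run is a pure function of its
  config.
* Numbers are written to disk with 17 significant digits; a write/read
  round trip reproduces matrices exactly.
* Strict inequalities at the screening thresholds; values exactly at a
  threshold are indeterminate rather than silently assigned.
* ROC Youden ties are broken toward higher specificity, then toward the
  higher threshold.
* The hypergeometric tail, OPLS-DA/VIP, ROC/AUC and the screening algebra
  are validated against independent oracles in the test suite
  (exhaustive combinatorial sums for all population sizes ≤ 60, closed-form
  PLS1, eigen-decomposition PCA, brute-force pairwise AUC counting).

Problem sizes in the test and acceptance runs are chosen to exercise the
default study design (164 × 800) where fidelity matters, and compact
cohorts (tens of samples, ~100 metabolites) where only the stage logic is
under test.

## A worked run

```{r, eval = FALSE}
library(syndromet)

report <- run_full_analysis(run_config(
  simulate = cohort_config(seed = 1),
  n_perm = 99, seed = 1))
print(report)
```

On the default simulated design this reports the three comparisons
(IPBS vs PST/PQS/PQD), each with exactly one differential metabolite (the
planted marker), non-differential sets of several hundred metabolites, a
top-100 core of ~90 metabolites, an essence set of a few dozen, the
planted pathway as the top enrichment hit of every differential set, and
panel AUCs between roughly 0.88 and 0.98 depending on group size.

## Known limitations

* Only two-class OPLS-DA is provided; the workflow's star design never
  compares concurrent syndromes to each other.
* The single-predictive-component VIP is the standard formulation here;
  orthogonal components do not contribute to it.
* With 10 samples in the smallest group, cross-validated statistics for
  that comparison are noisy; the generator makes it easy to study the
  pipeline at larger group sizes.
* Fit statistics (R²Y, Q²) are validated by property and calibration
  tests, not against external reference values.
* The bundled reference panels are fixed coefficient vectors; their
  original fitting procedure and intensity calibration are not
  reconstructable, so they are provided for scoring, not re-evaluation.
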