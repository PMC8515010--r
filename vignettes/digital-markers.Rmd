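---
title: "Digital markers: transcriptome-screened KNN predictors of drug sensitivity"
author: "digitalMarker package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital markers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(digitalMarker)
```

## The problem

Choosing a chemotherapy agent for an individual tumor is still largely
empirical. Pharmacogenomic screens of cancer cell lines show that drug
sensitivity — summarized as the IC50, the concentration inhibiting 50% of
cell growth — co-varies with the transcriptome in a cancer-type-specific
way. A *digital marker* exploits this: a compact, ordered list of at most 30
genes whose expression, fed to a K-nearest-neighbour (KNN) model, predicts a
drug's IC50 Z-score (cell lines) or its probability of being ineffective
(patients/organoids). Because the panel is small, it can be quantified by
qRT-PCR in hours instead of the days an RNA-seq run takes, which is what
makes near point-of-care prediction plausible.

This package implements the full computational pipeline: gene screening,
cross-validated marker selection, prediction from TPM or qPCR input, and the
per-drug recommendation rule, together with synthetic-data generators that
make every stage testable without access to the large public pharmacogenomic
databases.

## Screening model

Screening is run per cancer type and drug. For **cell-line cohorts**
(continuous IC50):

1. *Expression filter.* Keep genes with mean `log10(1 + TPM) > 1` across all
   samples. The +1 pseudo-count keeps zero TPM finite; the cut removes
   unexpressed genes (on realistic backgrounds roughly two thirds of genes).
2. *Correlation filter.* Keep genes whose Pearson correlation between TPM
   and the cohort's IC50 Z-scores exceeds 0.25. By default the absolute
   value |r| is compared — sensitizing genes correlate negatively with IC50
   and resistance genes positively, and both are informative. The literal
   signed rule is available via `useAbs = FALSE`.
3. *Fisher discriminant score.* Rank survivors by the univariate two-group
   Fisher criterion |μ_high − μ_low| / sqrt(s²_high + s²_low) of
   `log10(1 + TPM)` between the cell lines in the lowest and highest 15% of
   IC50 Z-scores (tail size `max(2, floor(0.15 n))`; boundary ties broken by
   sample ID so results are deterministic). Both variances zero with equal
   means scores 0; with unequal means it scores +Inf and ranks first. The
   square-root form is used; squaring it would be rank-equivalent.

For **patient cohorts** (binary effective/ineffective labels) the filter is
mean `log10(TPM) > 0` without a pseudo-count — a gene with any zero TPM
fails it — and survivors are ranked by −log10 of the two-sided Mann–Whitney
U p-value between outcome groups (exact null when the smaller group has ≤ 8
samples and no ties, normal approximation with tie correction otherwise).
The p-values are used purely as a ranking score, so no multiple-testing
correction is applied. Equal p-values are broken by the absolute difference
of group medians, then gene ID.

All cuts are *strict* inequalities, matching the printed thresholds. When
two paired datasets are available, each is screened separately and per-gene
scores are *added* over the intersection of the surviving sets
(`synthesizeScores`); a rank-percentile mode is provided for cohorts whose
score scales are not commensurable. For wet-lab panel design,
`countStableGenes` keeps genes screened in more than 20 per-drug lists in
*both* datasets.

Log base: the sources write "log" unqualified; log10 is used throughout,
consistent with the magnitude of the fitted qPCR calibration intercept. It
is a package-wide convention, not a switch.

## Marker selection

`selectDigitalMarker` enumerates marker sizes m = 1..30 along the ranked
list and neighbour counts k = 1..30, scoring each (m, k) by mean AUC over
stratified 5-fold cross-validation. Features are `log10(1 + TPM)`,
standardized per gene with training-fold statistics; distances are
Euclidean; distance ties resolve by training-sample index. Regression tasks
rank held-out samples by −predicted Z and define the positive (sensitive)
class by true Z ≤ −1.0 (−0.6 is a common alternative); classification tasks
rank by predicted probability of effectiveness, and a tied vote
(p = 0.5) is called ineffective — the conservative direction for a
treatment recommendation. Equal AUCs prefer smaller m, then smaller k
(parsimony). The returned `DigitalMarker` freezes the gene list, k0, the
standardization statistics refit on the full cohort, the training data, and
the achieved CV AUC.

### Leakage and the nested mode

The original protocol ranks genes on the full cohort *before*
cross-validation, so the screening has seen the held-out folds; and it
reports the CV AUC of the (m, k) pair selected on those same folds. Both
effects inflate the reported AUC on null data — measurably: on signal-free
simulations the protocol-faithful report sits near 0.73 rather than 0.5,
almost entirely winner's curse over the 900-point (m, k) grid rather than
screening leakage. The package therefore exposes both designs:

- the default, protocol-faithful mode, and
- a nested mode: `selectDigitalMarker(nested = TRUE)` re-screens inside
  each training fold, and `nestedCvAuc` / `runCrossPrediction(evaluation =
  "nested")` evaluate untouched outer folds with both the screening and the
  (m, k) choice confined to the outer training portion.

The nested outer estimate is the one that calibrates to AUC ≈ 0.5 on
signal-free data, and it is what the package's null-calibration tests use.
The maximum of the selection grid is *not* a calibration statistic, even
under nested screening, because maxima of noisy surfaces are biased upward.

### Cross-prediction

`runCrossPrediction` compares three designs on a paired cohort: (1) rank by
the synthesized two-dataset scores, then CV within each dataset; (2) rank
and CV within the same dataset; (3) *cross-prediction* — rank on one
dataset, CV on the other. Method 3 is the generalization test: it transfers
well exactly when the two cohorts share sensitivity-associated genes.

## The qPCR path

qRT-PCR quantifies transcripts as quantification cycles; ΔCq = Cq_target −
Cq_reference (GAPDH by default) is linearly related to log abundance. The
calibration

\[ \log_{10}(\mathrm{TPM} + 1) = a\,\Delta Cq + b \]

is fitted by ordinary least squares (`fitConversion`); the package defaults
are the published SW620 coefficients a = −0.3995, b = 5.6974. One cycle
therefore corresponds to about 10^0.4 ≈ 2.5-fold less transcript, and ΔCq =
b/(−a) ≈ 14.26 maps to TPM = 0; back-converted values are floored at 0
because negative abundances are unphysical. `predictFromQpcr` converts a Cq
table and runs the frozen marker; with noiseless Cq constructed by the
inverse map the qPCR path reproduces the TPM path bit-for-bit (same
neighbours), which the tests pin down.

## Recommendation rule

For each drug, the predicted log IC50 is standardized against that cancer
type's cohort (population SD) to a *relative Z-score*: strictly below −1 is
"sensitive" (green), strictly above +1 "non-sensitive" (red), anything else
"neutral" (black) — exact ±1 lands on neutral. Classification outputs are
additionally banded into effective / intermediate / ineffective zones; the
published decision maps do not quantify the band edges, so the package cuts
the probability axis at thirds (1/3, 2/3), configurable, with boundary
values falling in the middle zone.

## Synthetic data: what it emulates and what it does not

`generateCellLinePair` draws a latent sensitivity z ~ N(0,1) per sample;
planted signal genes shift their `log10(1+TPM)` by `effectSize · z` with
alternating sign (so both directions of the correlation filter are
exercised), decoys are noise around log-normal baselines, and IC50 =
exp(σ z + ln median) so that standardizing log IC50 recovers z exactly.
Dataset B redraws samples and adds a constant log-scale batch shift, which
preserves cross-dataset rank structure — that is what makes method-3
cross-prediction a meaningful test. Defaults: 2000 genes, 10 signal genes,
60 + 60 samples, noise SD 0.3 on the log10 scale, effect size 1.5 × noise
SD, batch shift 0.2, median IC50 10 μM with ln-scale SD 1. Background
baselines N(0.8, 0.6) put roughly a third of decoys past the expression
filter; signal baselines N(2.0, 0.3) keep planted markers expressed — a
marker that fails its own expression filter would be unlearnable by
construction. `generatePatientCohort` assigns balanced binary outcomes
first, then shifts signal genes between classes; `generateQpcrReadout`
inverts the calibration with optional Gaussian cycle noise around a fixed
20-cycle reference.

The generators deliberately do **not** mimic real marginal TPM
distributions, gene–gene correlation structure, dropout, or batch
nonlinearity. Passing tests on them demonstrates that the pipeline's
machinery is correct and calibrated — not that real cohorts contain
learnable signal of this strength.

## Numerical choices and degenerate inputs

- IC50 Z-scores standardize natural-log IC50 with the population SD
  (log-scale because IC50 spans orders of magnitude; the scale is
  configurable). A single-sample cohort cannot be standardized and errors.
- Zero-variance genes: undefined correlations are dropped by the filter;
  zero training-fold SDs standardize with scale 1 (the gene then
  contributes nothing to distances).
- Duplicate gene rows mean-collapse with a warning (symbol-keyed matrices
  duplicate often); genes with missing values are dropped, not imputed.
- Folds are dealt per class (shuffle, then round-robin) from a single seed;
  every simulation, fold assignment and CLI run is reproducible from it.
- Problem sizes in the shipped tests and the summary script — 10–20
  simulation seeds, 2000-gene cohorts, 60-sample datasets — were chosen as
  the smallest sizes at which the planted-recovery and calibration
  properties are stable.

## Limitations

Cross-validation folds here cannot exceed what 5 folds of a 60-sample
cohort support; very unbalanced label splits can leave folds single-class
(such folds are skipped with the mean taken over valid folds). The
correlation filter's null pass rate is exact only because the simulated
Z-scores are Gaussian; heavy-tailed real responses shift it. The qPCR
calibration is assumed linear over the measured range and shared across
genes, as in the source data; per-gene amplification-efficiency differences
are not modelled.
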