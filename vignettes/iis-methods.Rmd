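---
title: "Constructing an immune infiltration score from paired tumour transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing an immune infiltration score from paired tumour transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Triple-negative breast tumours differ from the histologically normal tissue
around them in the composition of their immune microenvironment: some immune
cell populations are consistently enriched in the tumour, others depleted.
`iiscore` condenses those compositional shifts into a single per-sample
number, the immune infiltration score (IIS), built in five stages:

1. **Cell-content scoring.** Each sample's expression profile is reduced to
   one content score per cell type by a rank-based single-sample gene-set
   enrichment statistic over that type's signature genes.
2. **Paired differential testing.** With matched tumour (CA) and
   para-cancerous (CAP) samples, a paired t-test per cell type identifies
   the types whose content shifts, giving an *up* set and a *down* set.
3. **Reference z-normalisation.** Content scores are standardised per type
   with the mean and standard deviation of an external reference cohort,
   never of the analysed cohort, so the scale transfers across data sets.
4. **Indicators and the linear boundary.** `X1` is the per-sample sum of
   z-scores over the up set, `X2` the sum over the down set. A linear
   decision function `Y = a*X1 - b*X2 + c` is fitted to separate tumour from
   para-cancerous samples, by a soft-margin linear SVM (default) or by
   logistic regression. The built-in published model is
   `IIS = 1.706596 * X1 - X2 - 9.680123`.
5. **Stratification and validation.** Samples with IIS strictly above 0 are
   infiltration-positive. Strata are compared on survival (Kaplan-Meier,
   log-rank) and on checkpoint-marker expression (Wilcoxon rank-sum), with a
   Pearson chi-square for 2x2 categorical tables.

## The enrichment statistic

For a sample with `n` genes, expression values are converted to descending
ranks (`rank 1` = highest; ties get averaged ranks). Walking genes from best
to worst rank, an in-set gene increments a running sum by its normalised
rank weight `(n - rank + 1)^alpha / sum(in-set weights)`, an out-of-set gene
decrements it by `1/(n - m)` for set size `m`. The score is the mean of the
running sum over all `n` positions. Properties that matter downstream:

* it is computed **independently per sample**, so cohort composition cannot
  leak between samples;
* it depends on expression only through within-sample ranks, so any
  per-sample monotone normalisation (FPKM vs TPM, scaling) is irrelevant;
* `alpha` (default 0.25) softens the emphasis on extreme ranks; `alpha = 0`
  weights all in-set genes equally.

This scorer is deliberately transparent and fully testable: the test suite
checks it exhaustively against a literal per-position enumeration for every
gene subset at small `n`. It shares its contract (expression in, one content
score per cell type and sample out) with calibrated signature methods used
in tumour-microenvironment work, but performs no trained calibration and no
spillover compensation between correlated cell types; content scores are
also not floored at zero, because the downstream z-normalisation removes
location anyway.

## Direction calls

The paired t-test is applied to per-pair differences `CA - CAP` of the
content score, type by type, and two-sided `p < .05` (strict, uncorrected)
defines the up and down sets. No multiplicity correction is applied by
default because the construction treats the .05 rule as part of its
definition; `classify_directions(..., adjust = "BH")` provides
Benjamini-Hochberg as an opt-in. Types whose differences have zero variance
are flagged degenerate (`p = NA`) rather than dropped, so result tables stay
complete.

## Fitting and canonicalising the boundary

The published model reports the `X2` coefficient as exactly `-1`; a fitted
hyperplane `w1*X1 + w2*X2 + w0` is therefore canonicalised by dividing
through `|w2|` after orienting tumour samples to the positive side. Positive
rescaling never changes which side of the boundary a sample is on, so
classification is invariant under canonicalisation. If `|w2| < 1e-12` the
boundary does not use `X2` and canonicalisation fails with a diagnostic
rather than returning an unstable model. The SVM soft-margin cost defaults
to `C = 1` and is exposed. With well-separated classes the logistic fit sits
near complete separation; its coefficients are large but the canonicalised
ratios, and hence the scores, are stable, and the package asserts the two
methods' scores correlate rather than their raw coefficients.

A score of exactly 0 is classified **negative**: the cutoff describes
"scores higher than 0", so strictness is resolved against the positive
class and documented here.

## The synthetic cohort generator

Real paired tumour cohorts with raw expression cannot ship with a package,
so every downstream stage is exercised on synthetic cohorts whose
statistical structure mirrors the assumed study design. Defaults:

| parameter | default | meaning |
|---|---|---|
| `n_pairs` | 30 | tumour/para-cancerous pairs |
| `cell_types` | 4 up, 4 down, 4 null | planted direction tags |
| `effect_size` | 1.5 | tumour shift of tagged types, in reference sds of the true content |
| `genes_per_signature` | 25 | disjoint signature block per cell type |
| `n_background_genes` | 1500 | genes outside every signature |
| `noise_sd` | 0.3 | log-scale multiplicative expression noise |
| `hazard_ratio` | 3.0 | event hazard, score-positive vs negative |
| `censor_rate` | 0.3 | administrative censoring fraction |
| `marker_shift` | 1.0 | checkpoint-marker mean shift in positive stratum (sd units) |
| `n_reference` | 60 | internal unshifted reference cohort |

Design choices, made once and fixed:

* **Contents are log-normal** (median 1, log-sd 0.25, i.e. CV about 25%),
  keeping them positive and right-skewed like enrichment-derived abundances.
  A shared patient effect (log-sd 0.14) correlates the two samples of a
  pair, which is what makes the paired design informative.
* **Shifts are planted on the reference-sd scale** of the true content, so
  the z-scores the pipeline computes downstream have interpretable planted
  magnitudes. Shifted contents are floored at 0.01 to stay positive.
* **Expression is a signature-block mixture**: each signature gene's
  expression is its base abundance (log-normal across genes, log-sd 1)
  scaled by its type's content, times `exp(N(0, noise_sd))`; background
  genes omit the content factor.
* **Reference statistics live on the score scale.** Because z-normalisation
  consumes content *scores*, the generator scores an internal unshifted
  reference cohort with the same signatures and `alpha` and reports those
  per-type means and sds, standing in for an external reference cohort.
* **Outcomes**: exponential event times with baseline median 36 time units
  in the negative stratum, hazard multiplied by `hazard_ratio` in the
  positive stratum; censoring is uniform-administrative on `(0, tau)` with
  `tau` solved numerically so the negative-stratum censor fraction equals
  `censor_rate`; the marker value is `N(status * marker_shift, 1)`.
* **Seeding**: every stochastic operation takes an explicit seed and runs in
  a private RNG stream, restoring the caller's state; the same
  configuration is bit-reproducible.

One interaction deserves note. Rank-based scores are compositional: large
planted shifts move the ranks of *unshifted* genes too, and because a
down-shift of a given size is larger on the log scale than the matching
up-shift, null cell types inherit a small upward drift. Keeping the content
CV moderate and the signature genes a small fraction of the gene universe
(300 of 1800) keeps this drift well below the detection threshold — the test
suite verifies that null-type p-values are approximately uniform when
nothing is planted and that the per-type false-positive rate at the
defaults stays near the nominal 5% — but it is the reason a cohort can
occasionally call a ninth type significant at uncorrected .05, exactly as
real uncorrected screens do.

What the generator does **not** emulate: correlated or overlapping
signatures, spillover between related cell types, batch effects, tumour
purity gradients, library-size artefacts, or read-level noise. Tests passing
on these cohorts show the pipeline recovers the structure it assumes; they
do not certify performance on real tumour data.

## Problem sizes in the test suite

Unit tests run on reduced cohorts (8 pairs, 8-gene signatures, 200
background genes) where the planted structure is still comfortably
detectable; property-style checks use 100 default-scale cohorts (seeds
1-100) for direction-tag recovery and outcome contrasts, 250 reduced null
cohorts (1000 p-values) for type-I calibration, and 200 replicates for the
log-rank null rejection rate. Exhaustive oracle comparisons for the
enrichment statistic cover every gene subset at up to 10 genes.

## Known limitations

* The published coefficients cannot be re-derived without the original
  cohort's cell contents and its external reference statistics; the package
  ships them as constants and re-fits boundaries on whatever cohort it is
  given.
* Cell-type labels are opaque strings; mapping a signature collection's 64
  types onto the 8 reported populations is the user's responsibility.
* The survival stage implements two-group comparisons only — no Cox
  regression, competing risks or time-dependent covariates.
* With heavy censoring a Kaplan-Meier median can be undefined; `km_median()`
  returns `NA` and comparisons involving it must handle that case, as the
  stratum comparison helpers do.
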