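# iiscore

Immune infiltration scoring for paired tumour/para-cancerous bulk
transcriptomes.

Tumours reshape the immune composition of their microenvironment: in
triple-negative breast cancer, some immune populations (e.g. CD8+ central
memory T cells, Th1 cells, activated dendritic cells, macrophages) are
enriched in tumour tissue relative to the matched adjacent tissue, while
others (conventional dendritic cells, neutrophils, CD4+ central memory T
cells, mast cells) are depleted. `iiscore` condenses these paired
compositional shifts into a single prognostic number per sample, the
**immune infiltration score (IIS)**, and provides the statistics needed to
validate it.

The pipeline, for a gene × sample expression matrix with matched CA
(tumour) / CAP (para-cancerous) samples:

1. per-sample cell-type **content scores** via a rank-based single-sample
   gene-set enrichment statistic (weight exponent α = 0.25, average-tie
   ranks);
2. **paired t-tests** per cell type on CA − CAP differences; types with
   two-sided *p* < .05 form the up- and down-shifted sets;
3. **z-normalisation** of contents against reference-cohort means/sds
   (never the analysed cohort's own);
4. indicators **X1** (sum of z-scores over up types) and **X2** (sum over
   down types), and a linear boundary *Y* = a·X1 − b·X2 + c fitted by a
   soft-margin linear SVM or logistic regression, canonicalised so the X2
   coefficient is exactly −1. The built-in published model is

   ```
   IIS = 1.706596 × X1 − X2 − 9.680123
   ```

5. **stratification at cutoff 0** (IIS > 0 ⇒ infiltration-positive) and
   validation of the strata by Kaplan–Meier curves, log-rank, Wilcoxon
   rank-sum and chi-square tests.

Because raw patient cohorts cannot ship with a package, `iiscore` includes a
synthetic paired-cohort generator (`synthetic_config()` /
`generate_cohort()`) that plants the assumed structure — 30 pairs, 4 up + 4
down + 4 null cell types, shifts of 1.5 reference sd, threefold hazard in
score-positive samples — so the whole pipeline is testable offline.

## Worked example

```r
library(iiscore)

cohort   <- generate_cohort(synthetic_config(seed = 42))
analysis <- iis_analysis(cohort)        # score -> test -> normalise -> fit
analysis
#> IIS analysis of 60 samples, 12 cell types
#> Direction sets (p < 0.05 ):
#>   up:   CD8+ Tcm, Th1 cells, aDC, Macrophages
#>   down: cDC, Neutrophils, CD4+ Tcm, Mast cells
#> IIS model (max_margin): score = 1.134512 * X1 - 1 * X2 -8.278995
#>   mean IIS: tumour 6.077, para-cancerous -6.408
#>   31 of 60 samples infiltration-positive at cutoff 0

head(analysis$scores, 3)
#>   sample_id       X1         X2    score   status
#> 1    P01_CA 3.557304  -5.916098 1.672907 positive
#> 2    P02_CA 5.175781 -12.362885 9.955875 positive
#> 3    P03_CA 4.477957  -4.802258 1.603558 positive
```

The direction calls recover exactly the 4 planted up and 4 planted down
types; the fitted boundary puts tumour tissue on the positive side of
cutoff 0 (mean IIS +6.1 vs −6.4). Outcomes generated from the fitted strata
show the expected contrasts:

```r
status   <- setNames(analysis$scores$status, analysis$scores$sample_id)
outcomes <- generate_outcomes(status, cohort$config, seed = 43)
pos <- subset(outcomes, stratum == "positive")
neg <- subset(outcomes, stratum == "negative")

logrank_test(pos, neg)
#> Log-rank test: chi-square = 7.6888 (1 df), p = 0.0056
rank_sum_compare(pos$marker, neg$marker)$p   # checkpoint-marker contrast
#> [1] 0.002198
```

The packaged clinicopathological baseline table is summarised with exact
grouped counts:

```r
summarize_cohort(load_clinical_fixture())
#> Patients: 30
#> Grade:    II=13  III=17
#> Regional-node metastasis: No=15  Yes=15
#> Age: mean 50.83 (sd 11.80), median 49.00 [40.50, 59.75]
```

Scoring with the published coefficients needs only the indicators:

```r
score_iis(iis_published_model(), data.frame(X1 = 6, X2 = 0.5))
#>   sample_id X1  X2    score   status
#> 1      S001  6 0.5 0.059453 positive
```

A thin command-line wrapper covers the same stages
(`inst/scripts/iiscore.R` with subcommands `simulate`, `score-cells`,
`diff`, `iis-fit`, `iis-apply`, `survival`, `summarize`).

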