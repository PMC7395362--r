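# activeBreast

Histologically normal breast tissue is not transcriptionally uniform: bulk
RNA-seq of benign breast biopsies splits into two reproducible states, an
*Active* phenotype — enriched for adipocyte, inflammation and motility
programs and associated with elevated later breast-cancer risk — and an
*Inactive* phenotype. `activeBreast` implements the full analysis pipeline
for calling these phenotypes and characterising their adipocyte biology in a
two-batch cohort, for computational biologists working with normal-tissue
transcriptomes:

- **Signature scoring.** For a signature with upregulated gene set *U* and
  downregulated set *D*, each sample's score is the sign-corrected average

  $$S_s = \frac{\sum_{g \in U} \log_2(T_g + 1) - \sum_{g \in D} \log_2(T_g + 1)}{|U| + |D|}$$

  where $T_g$ is the gene's TPM and $|U|$, $|D|$ count the signature genes
  present in the data.
- **Phenotyping.** Per batch: log2 median-centred normalization, selection
  of variably expressed classifier genes (IQR > 0.8), unsupervised
  hierarchical clustering (1 − Pearson correlation, average linkage) cut
  into two groups, and labelling of the higher-scoring cluster as *Active*;
  plus per-gene Wilcoxon/Benjamini–Hochberg differential expression.
- **Batch integration.** Per-gene quantile normalization mapping one
  batch's expression distribution onto the other's, excluding zeros from
  both source and target and reattaching them after the mapping.
- **Hotspot variant filtering.** RNA-expressed cancer-gene hotspot calls
  filtered by likelihood score ≥ 5, allele frequency in [0.02, 0.40],
  variant allele depth ≥ 2, predicted non-silent amino-acid change, and
  presence in every supplied hotspot catalogue; per-sample mutation burden
  and burden–covariate Spearman association.
- **Gene-set post-processing.** Adipose-associated set selection by name
  rules (include "fat"/"adip"/"lip", exclude "sulfate"/"sulfation") and
  FDR-thresholded enrichment summaries of GSEA report tables.
- **Association statistics.** Wilcoxon/Welch/chi-square group comparisons,
  tissue-composition reports, and pairwise-complete correlation matrices
  with significance flags.
- **Synthetic cohorts.** A generator that emulates the full statistical
  structure of such a study (planted phenotypes, batch distortion,
  composition skew, covariate shifts, variant burden), so every stage is
  testable end-to-end without any external download.

## Worked example

```r
library(activeBreast)

cohort <- generateCohort(cohortSpec(seed = 42))   # 96 F + 55 P samples
ph <- phenotypeCohort(cohort$expression, cohort$classifier)
table(ph$assignment$batch, ph$assignment$label)
#>     Active Inactive
#>   F     47       49
#>   P     31       24
```

Per batch, roughly half the samples are called *Active* (the generator
plants 47/96 and 31/55). Against the generator's ground truth the labels
are fully recovered at the default effect size:

```r
truth <- setNames(cohort$truth$phenotype$phenotype,
                  cohort$truth$phenotype$sample)
mean(setNames(ph$assignment$label, ph$assignment$sample)[names(truth)] == truth)
#> [1] 1
```

*Active* samples are adipocyte-rich and stroma/epithelium-poor:

```r
compositionReport(cohort$covariates, ph$assignment)$table
#>      compartment mean_active mean_inactive fold_change            p
#> 1  pct_adipocyte   79.921795      47.69589   1.6756537 8.924126e-25
#> 2    pct_stromal   15.139744      29.62740   0.5110048 1.355803e-16
#> 3 pct_epithelial    4.932051      22.67260   0.2175335 5.089194e-24
```

and the filtered hotspot-mutation burden correlates positively with
adipocyte content:

```r
burden <- burdenPerSample(filterVariants(cohort$variants, cohort$hotspots),
                          cohort$covariates$sample)
burdenAssociation(burden, cohort$covariates, "pct_adipocyte")[c("rho", "p")]
#> $rho
#> [1] 0.3851007
#> $p
#> [1] 1.047379e-06
```

The whole pipeline (simulate → phenotype → integrate → hotspots →
associate) also runs from one configuration:

```r
runPipeline(list(out = "run1", seed = 1))
```

writing labels, the batch-corrected matrix, filtered variants, burden,
composition and correlation reports, plus a manifest with file hashes.

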