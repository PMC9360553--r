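# latgc

Latitude-stratified multi-omic analysis of gastric-cancer cohorts, packaged
as a tested, reusable R pipeline.

Tumor cohorts drawn from different geographic regions differ in clinical
outcome, mutation burden, immune infiltration and metabolic activity. This
package implements the analysis toolchain needed to compare two
latitude-defined patient groups (0–45° "low" vs 46–90° "high") across the
genome, transcriptome, immune microenvironment and survival — and to build
and validate an **immune-related prognostic model (IRPM)** from the immune
infiltration structure of the cohort. It is aimed at computational
oncologists who have a gene-by-sample expression matrix (counts + FPKM), a
somatic mutation table (MAF subset), and a clinical table with survival and
latitude, and who want the full comparison as one reproducible run.

## What it computes

- **Preprocessing** — zero-fraction gene filtering (genes with FPKM 0 in
  > 70 % of samples removed), K-nearest-neighbour imputation of the
  remaining zeros, log2 transform; Fisher's exact contingency tests of
  clinical factors against latitude groups.
- **ssGSEA activity scores** — for any gene-set collection (metabolic
  pathways, DNA-repair GO terms, immune-cell marker sets). For sample *j*
  and gene set *S*, genes are ranked by expression and the score is the
  integrated difference between the weighted in-set ECDF and the unweighted
  out-of-set ECDF:

  ES(S, j) = Σᵢ [ P_in(i) − P_out(i) ],  P_in(i) = Σ_{g∈S, r(g)≥r(i)} r(g)^α / Σ_{g∈S} r(g)^α

  with α = 0.25 by default; ESTIMATE-style stromal/immune/composite scores.
- **Mutation profiling** — TMB (nonsynonymous mutations per Mb), top mutated
  genes, pairwise co-occurrence/exclusivity (Fisher), subclone counts from
  1-D Gaussian-mixture fits to per-sample VAF distributions (BIC-selected),
  frequency-based driver-gene selection.
- **Differential expression** — TMM-normalized log2-CPM with per-gene
  rank-sum tests and BH correction; shared/specific overlap decomposition
  between the latitude groups.
- **Survival statistics** — Kaplan–Meier, log-rank, univariate Cox
  (Efron ties), median-split helper.
- **Driver regulation networks** — signed edges driver → pathway/immune cell
  where the activity score differs between mutated and wild-type samples
  (rank-sum p < 0.05), per latitude group.
- **IRPM** — three steps: (1) rank immune cells by univariate Cox
  significance and keep the top 5; (2) select the top 5 % of genes by mean
  Spearman correlation with the selected cells' infiltration, split by
  correlation sign; (3) score each sample with the Welch *t* statistic
  contrasting its positive-set vs negative-set expression, and dichotomize
  at the training-cohort median. The published 47-gene signature (35
  positive, 12 negative) ships with the package
  (`load_table1_signature()`).
- **Synthetic cohorts** — `generate_cohort()` draws a cohort with the full
  latent structure the analysis assumes (infiltration → marker genes and
  hazard, group-specific mutation frequencies, subclonal VAF mixtures) and
  stores its ground truth, so every stage can be tested by parameter
  recovery.

## Worked example

```r
library(latgc)

co <- generate_cohort(cohort_config(n_low = 60, n_high = 60, n_genes = 800,
                                    dropout_fraction = 0), seed = 7)
expr   <- log2_transform(co$expression_fpkm)
cells  <- grep("^cell_", names(co$genesets), value = TRUE)
infil  <- ssgsea_scores(expr, co$genesets[cells])
tumors <- co$clinical[co$clinical$sample_type == "tumor", ]

fit <- build_irpm(expr, infil, tumors)
fit$signature
#> IRPM signature (constructed): 28 positive, 12 negative genes
fit$cells[, c("cell", "hr", "p")]
#>      cell        hr            p
#> 1 cell_02 65.106590 1.086473e-05
#> 2 cell_05 13.276702 1.213343e-04
#> 3 cell_04 10.221670 2.831819e-03
#> 4 cell_03  5.313550 1.973978e-02
#> 5 cell_01  5.459415 2.241134e-02
signif(fit$validation$logrank$p, 3)
#> [1] 6.13e-10
```

All five simulated immune cells come out as risk factors (HR > 1), the
constructed signature recovers the genes built to track risk-cell
infiltration, and splitting samples at the median IRPM score separates
survival sharply (log-rank p ≈ 6e-10). Comparing infiltration between
latitude groups recovers the simulated shift:

```r
compare_groups(infil, assign_latitude_group(co$clinical))[, c("feature", "p", "direction")]
#>   feature            p      direction
#> 1 cell_01 9.180212e-04 higher_in_high
#> 2 cell_02 9.739182e-03 higher_in_high
#> 3 cell_03 4.481210e-03 higher_in_high
#> 4 cell_04 2.312647e-03 higher_in_high
#> 5 cell_05 1.717259e-06 higher_in_high
```

The whole analysis can also be driven from one config:

```r
run_pipeline(pipeline_config(seed = 1, outdir = "latgc_run"))
# writes ssgsea_scores.tsv, tmb.tsv, somatic_interactions.tsv, subclones.tsv,
# de_*_vs_normal.tsv, regulation_network.tsv, irpm_scores.tsv,
# clinical_contingency.tsv, latitude_logrank.tsv and run_manifest.json
```

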