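# cfScope

Genome-wide cell-free DNA (cfDNA) profiling for immune-mediated disease
signatures in shallow whole-genome sequencing (sWGS).

Non-invasive prenatal screening (NIPS) reads fetal trisomies out of
binned cfDNA counts from maternal plasma. A screen is *inconclusive* when
the fetal fraction (FF) is below 4% or the genome-wide quality score (QS)
is at or above 2 — and the high-QS failures are not noise: maternal
autoimmune disease (AID) and inflammatory bowel disease (IBD) distort the
plasma cfDNA pool genome-wide, so the "failed" profiles carry a disease
signature. cfScope is an R/Bioconductor-style package for the whole
analysis chain on binned cfDNA count matrices, for analysts working on
NIPS quality control or cfDNA liquid-biopsy signatures:

* **Screening statistics** — normalization (depth, per-sample GC fit,
  running-median smoothing), per-chromosome z-scores against a euploid
  reference set, `z_c = (r_c − µ_c)/σ_c`; the QS (sample SD of the 22
  autosomal z-scores after trimming the highest and lowest chromosome);
  and the conclusive/inconclusive call with its reason (`low-FF`,
  `high-QS`, `both`).
* **Unsupervised exploration** — centered PCA (top 50 PCs), kNN graph
  (k = 8) with Walktrap communities (walk length 2, modularity-optimal
  cut), tSNE layouts, Ward trees, and replicate concordance.
* **Supervised classification** — class-weighted SVM on PCA scores with
  grid search on a stratified 90/10 split, leave-one-out cross-validation
  with per-fold PCA refits, ROC/AUC, operating points at fixed
  specificity (default 95%), likelihood ratios
  `LR+ = sens/(1−spec)`, `LR− = (1−sens)/spec`.
* **Cohort statistics** — reporting-convention percentages,
  prevalence-based 2×2 odds ratios with Woolf intervals, one-vs-rest
  cluster enrichment (logistic LRT + Fisher cross-check), and
  covariate-adjusted logit models with separation detection.
* **Synthetic cohorts** — a negative-binomial generator (GC bias,
  fetal-fraction mixtures, trisomies, multiplicative disease signatures,
  replicates, batch effects) so that every stage is testable without any
  sequencing data.

The central container is a `RangedSummarizedExperiment`: bins as a
`GRanges` with GC annotation, samples in `colData`, counts as the assay.
See `vignettes/cfscope-methods.Rmd` for the models, parameter meanings and
design choices.

## A worked example

```r
library(cfScope)

bins <- makeBins(22, 100, seed = 1)              # 2,200-bin genome
sig <- randomSignature(bins, "AID-like", nBlocks = 10, blockWidth = 22,
                       effect = 1.3, seed = 5)   # ~10% of bins, 1.3x
design <- rbind(cohortArm("control", 100, pregnant = TRUE),
                cohortArm("AID-like", 20, pregnant = TRUE, signature = sig))
cohort <- simulateCohort(bins, design, simConfig(seed = 42))

md <- SummarizedExperiment::colData(cohort)
ref <- buildReference(normalizeCounts(cohort)[, md$disease_label == "control"],
                      bins)
calls <- nipsCalls(cohort, ref)
table(calls$call)
#>   conclusive inconclusive
#>          110           10

emb <- fitEmbedding(featureMatrix(cohort), 50)
cl <- clusterScores(emb$scores, k = 8, walkSteps = 2)
cl
#> ClusterResult: 3 communities over 120 samples; modularity 0.457 (k = 8, steps = 2)
table(cluster = clusterLabels(cl), label = md$disease_label)
#>        label
#> cluster AID-like control
#>       1       20       0
#>       2        0      48
#>       3        0      52
```

Ten samples are inconclusive (fetal fractions drawn below 4% plus
high-QS disease profiles), and the Walktrap partition isolates all 20
disease profiles in one community — the structural analogue of a
disease-enriched cluster in a screening cohort.

Cohort-level arithmetic works directly from published counts and
prevalences:

```r
orFromPrevalence(81611, 185, 13, 134.5)$or  # SLE vs inconclusive NIPS
#> 63.37...                                  # prints as 63.4
likelihoodRatios(0.71, 0.95)
#> $lrPlus 14.2   $lrMinus 0.3052632
```

A thin CLI over the same functions ships in `inst/scripts/cfscope`
(subcommands `simulate`, `gipseq`, `cluster`, `train`, `predict`,
`stats`, `run`).

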