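---
title: "cfScope: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cfScope: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfScope)
```

## The problem

Shallow whole-genome sequencing (sWGS) of plasma cell-free DNA (cfDNA) is
read out as counts over a fixed grid of genomic bins. In non-invasive
prenatal screening (NIPS), a sample's per-chromosome share of that signal
is compared against a euploid reference set to detect fetal trisomies. Two
situations make a screen *inconclusive*: too little placental DNA (fetal
fraction, FF, below 4%) or a genome-wide distortion of the count profile
(quality score, QS, at or above 2). The second situation is scientifically
interesting in its own right: maternal immune-mediated disease (systemic
autoimmune disease, inflammatory bowel disease) perturbs the cfDNA pool
genome-wide, so the "failed" profiles carry a disease signature that
unsupervised embedding and a supervised classifier can pick up.

cfScope implements the full chain — normalization, z-scores/QS/calling,
embedding and clustering, classification, cohort statistics — together
with a synthetic cohort generator so every stage is testable without
sequencing data.

## The screening statistics

For bins indexed by $b$ with counts $x_b$, the normalized profile is

1. depth normalization: $v_b = x_b / \sum_{b' \in \text{autosomes}} x_{b'}$;
2. GC correction (optional, default on): a robust local-linear fit
   (`lowess`, span 0.3) of $v_b$ against bin GC; $v_b$ is divided by the
   fit's prediction (rescaled to mean 1);
3. smoothing: a running median (default window 5 bins) within each
   chromosome;
4. renormalization so the autosomal values sum to 1.

The *chromosomal representation* $r_c$ is chromosome $c$'s share of the
autosomal signal. Against a reference set of $n \ge 10$ euploid controls
with per-chromosome mean $\mu_c$ and sample SD $\sigma_c$,

$$z_c = \frac{r_c - \mu_c}{\sigma_c},$$

and the quality score is the sample SD (denominator $n-1$) of the 22
autosomal z-scores after removing the single highest and the single lowest
scoring chromosome. A result is called inconclusive when FF $< 0.04$ or
QS $\ge 2$; the reason field records which rule fired (or `both`). Trisomy
flags for chromosomes 13/18/21 (z above a configurable cutoff, default 3)
are informational and only reported on conclusive calls.

Interpretation choices worth stating: "smoothed bin counts" is implemented
as the GC-corrected running median above (standard sWGS practice; both
steps are toggleable); the QS trim removes exactly one maximum and one
minimum value; fetal fraction is consumed from metadata, never estimated
from reads; and sex-chromosome bins, when present, are excluded from all
totals, z-scores and the QS.

## Unsupervised exploration

Profiles (samples $\times$ autosomal bins) are embedded by centered,
unscaled PCA keeping the top 50 components (bin values share a scale after
normalization; variance scaling would inflate noisy bins). A
k-nearest-neighbour graph ($k = 8$, Euclidean distance in PC space,
union-symmetrized, unweighted, distance ties broken toward the lower
sample index) feeds Walktrap community detection with walk length 2; the
partition is the modularity-maximizing cut of the merge tree. tSNE
(perplexity 30 clamped below $(n-1)/3$, fixed seed 42) provides the 2-D
layout, and Ward's linkage (`ward.D2` on Euclidean distances) the
hierarchical tree. Held-out samples are always *projected* onto the
training PCA basis, never refitted.

Replicate concordance calls a replicate group concordant when all members
share one Walktrap community or all pairs lie within 5% of each layout
dimension's range of each other.

## Supervised classification

The classifier couples the training-set PCA with a class-weighted SVM on
the PC scores. Hyperparameters are grid-searched by refitting each
candidate on a stratified 90% of the training set and scoring balanced
accuracy on the held-out 10%; ties resolve toward smaller cost, then the
linear kernel. The full grid spans linear and RBF kernels
($C \in 10^{-2..2}$, RBF width around the $1/p$ scale heuristic); a
reduced linear-only grid ($C \in \{0.1, 1, 10\}$) is the preset for
permutation studies and cross-validation sweeps. Class weights are
inversely proportional to class frequency, so duplicating the training
set leaves the decision rule unchanged.

Performance is estimated by leave-one-out cross-validation in which the
*entire* pipeline (PCA, grid search, SVM) is refitted without the held-out
sample — no leakage through the embedding. Operating points are set on the
out-of-fold scores as the smallest threshold reaching a target specificity
(default 95%), then frozen on the model and applied unchanged to
validation data. Likelihood ratios follow
$LR^+ = \text{sens}/(1-\text{spec})$, $LR^- = (1-\text{sens})/\text{spec}$.
AUC is trapezoidal with tie-averaging, identical to the Mann–Whitney rank
statistic; the test suite checks it against an independently coded rank
oracle.

## Cohort statistics

`proportionPct()` reproduces the reporting convention of clinical cohort
summaries: percentages are rounded half-up to **two significant figures**
and then presented half-up at the requested decimals. This is the
convention under which all of the screening cohort's published shares are
reproduced simultaneously (e.g. $5/143 = 3.4965\% \to 3.5 \to 4\%$ while
$25/143 = 17.48\% \to 17\%$); plain half-up of the exact ratio cannot
produce both. Set `sigDigits = NULL` for plain half-up.

Prevalence-based odds ratios build the 2×2 table from the cohort size, the
outcome count, the diseased-with-outcome count, and the expected disease
count `cohort × prevalence / 100,000` (rounded to the nearest integer by
default — the convention that reproduces the published estimates; an
unrounded variant differs by under 2% at cohort scale). Confidence
intervals are 95% Woolf; zero cells invoke the Haldane–Anscombe 0.5
correction, flagged in the method note.

Cluster enrichment is one-vs-rest logistic regression of the phenotype on
the in-cluster indicator (likelihood-ratio p-value), with Fisher's exact
test as a supplementary cross-check and a Bonferroni column for
transparency (raw p-values are the primary report). Clusters whose members
are all or none phenotype-positive separate the logistic model; they are
flagged and keep the exact test only. The covariate-adjusted logit model
(`logitPredictionModel`) is a maximum-likelihood IRLS fit reporting
adjusted odds ratios $e^{\hat\beta}$; complete separation or a constant
outcome is detected and routed to a lightly ridge-penalized IRLS
($\lambda = 10^{-3}$ on non-intercept terms), noted in the method note
rather than silently diverging.

## The synthetic cohort generator

No generative model is published for these data, so the generator encodes
the standard read-depth model the normalization must undo. The expected
fraction of reads in bin $b$ is

$$p_b \propto \text{baseline}_b \cdot
  e^{a\,(\text{gc}_b - 0.5)} \cdot s_b \cdot f_b,$$

with a softly varying baseline (smooth log-normal, part of the binning), a
multiplicative GC bias of amplitude $a$, a disease-signature factor $s_b$
(effect $e$ on affected bins, log-normal jitter across individuals of a
class) and a fetal factor $f_b$ that equals $(1-\mathrm{FF}) +
1.5\,\mathrm{FF}$ on the trisomic chromosome of a pregnant trisomic sample
and 1 elsewhere. The $p_b$ are renormalized to sum to 1 and counts are
drawn negative-binomially with mean $D\,p_b$ (depth $D$) and size
(dispersion) $\phi$: variance $\mu + \mu^2/\phi$.

Defaults — the frozen study conditions used by the tests and the
acceptance script:

| parameter | default | meaning |
|---|---|---|
| grid | 22 autosomes × 100 bins | scaled-down genome (full-scale 22 × 2614 ≈ 57.5k bins available) |
| `meanDepth` | 200,000 | ≈ 90 reads/bin; a scaled-down sWGS depth |
| `dispersion` | 50 | ≈ 2.8× Poisson variance at that depth |
| `gcBiasAmplitude` | 0.3 | moderate GC bias; 0.5 used in correction tests |
| FF | Beta, mean 0.10, SD 0.04, clipped to \[0, 0.5\] | typical first-trimester fetal fractions |
| `nBatches`/`batchEffectSd` | 2 / 0.05 | per-batch, per-bin log-normal multipliers |
| `replicateNoiseSd` | 0.02 | per-draw log-normal noise between repeats |

Disease signatures are multiplicative on configurable contiguous bin
blocks (default fixtures: 10 blocks × 22 bins ≈ 10% of the grid); the real
signal's genomic distribution (focal versus dispersed) is not
characterized in the literature, so the generator exposes both and claims
no biological fidelity. Trisomy is modelled only as the 1.5× fetal factor
on one chromosome — sufficient to exercise the z-score path, with no fetal
CNVs. Replicates share their individual's signature draw and fetal
fraction and differ by replicate noise, counting noise, and batch. All
randomness flows from the single config seed.

What the generator does *not* emulate: fragment-size (fragmentomics)
structure, methylation, read-level artefacts, mappability holes, CNVs, or
the correlated biological variation of real plasma. Passing tests
therefore demonstrate the pipeline's statistical machinery — calibration,
recovery, invariances — on data satisfying the model's assumptions, not
clinical performance. The published classifier headline numbers
(sensitivity at fixed specificity, AUC on the real cohort) depend on the
real data and are deliberately not reproduction targets; the synthetic
power curve and permutation nulls are.

## Numerical and design choices

* **Calibration of defaults.** The batch/dispersion defaults were
  calibrated once so that a null cohort scored against an independent
  reference has pooled z mean ≈ 0, SD ≈ 1, and ≥ 95% of QS values below
  2, then frozen. With only two batch draws per cohort, per-chromosome z
  means wobble by a few tenths of an SD (a two-level batch effect cannot
  average out); the pooled moments are the stable calibration readout,
  and the distributional unit tests therefore run with the batch effect
  disabled.
* **QS monotonicity.** Inflating a chromosome whose z lies at or above the
  trimmed-set mean can only increase the QS (the variance derivative is
  $2(z_j-\bar z) \ge 0$, and the hand-off when it becomes the trimmed
  maximum is continuous). Below the mean, a small inflation *reduces* the
  trimmed SD; the property test asserts the regime where monotonicity
  actually holds.
* **Parameter-recovery error bars.** A single $n = 500$ logistic replicate
  estimates the high-SLEDAI log-odds with SE ≈ 0.3, so recovery is
  reported as the mean over 20 seeded replicates (SE ≈ 0.07) — the same
  $n = 500$ design with Monte-Carlo noise suppressed.
* **Discrete p-values.** One-vs-rest enrichment p-values on 2×2 tables are
  discrete; their permutation-null calibration is checked through tail
  frequencies ($P(p < \alpha) \approx \alpha$) rather than a KS test,
  which rejects on ties alone.
* **Problem sizes.** Tests and the acceptance script use the 2,200-bin
  grid, cohorts of 130–600 samples, LOOCV at the reduced SVM grid, 20
  label permutations and 20 logit replicates — sizes chosen so the full
  pipeline remains interactive on one CPU while keeping every estimate's
  Monte-Carlo error well inside its acceptance band.
* **Determinism.** Every stochastic function takes or derives a seed and
  restores the caller's RNG state; rerunning a pipeline config reproduces
  numerically identical outputs, and the provenance stamp (package
  version, seed, config hash) is written into every output file.

## Limitations

The GC fit is per-sample and one-dimensional (no mappability covariate);
the reference set models chromosomal representation as independent
Gaussians (no cross-chromosome covariance); Walktrap's resolution
interacts with $k$ on very small cohorts; and the separation fallback's
ridge penalty, while flagged, is not a substitute for exact conditional
inference when events are very rare.

## A worked example

```{r example, eval = FALSE}
bins <- makeBins(22, 100, seed = 1)
sig <- randomSignature(bins, "AID-like", nBlocks = 10, blockWidth = 22,
                       effect = 1.3, seed = 5)
design <- rbind(cohortArm("control", 100, pregnant = TRUE),
                cohortArm("AID-like", 20, pregnant = TRUE, signature = sig))
cohort <- simulateCohort(bins, design, simConfig(seed = 42))

md <- SummarizedExperiment::colData(cohort)
ref <- buildReference(
  normalizeCounts(cohort)[, md$disease_label == "control"], bins)
calls <- nipsCalls(cohort, ref)
table(calls$call)

emb <- fitEmbedding(featureMatrix(cohort), 50)
cl <- clusterScores(emb$scores, k = 8, walkSteps = 2)
table(clusterLabels(cl),
      SummarizedExperiment::colData(cohort)$disease_label)
```
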