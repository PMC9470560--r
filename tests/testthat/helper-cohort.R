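# Shared fixtures, built in code and memoized per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# Default-scale genome: 22 autosomes x 100 bins.
testBins <- function() memo("bins22", makeBins(22L, 100L, seed = 1L))

# Small genome for cheap Monte-Carlo: 4 chromosomes x 30 bins.
smallBins <- function() memo("bins4", makeBins(4L, 30L, seed = 2L))

# 100 controls + 20 disease (effect 1.3 on ~10% of bins), the clustering
# separation cohort.
separationCohort <- function() memo("sepCohort", {
  bins <- testBins()
  sig <- randomSignature(bins, "AID-like", nBlocks = 10L, blockWidth = 22L,
                         effect = 1.3, seed = 5L)
  des <- rbind(cohortArm("control", 100L, pregnant = TRUE),
               cohortArm("AID-like", 20L, pregnant = TRUE, signature = sig))
  simulateCohort(bins, des, simConfig(seed = 42L))
})

cohortLabels <- function(cohort)
  SummarizedExperiment::colData(cohort)$disease_label

# Adjusted Rand Index, written directly from the pair-counting definition
# (independent of any clustering library).
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sumIJ <- sum(comb2(tab))
  sumI <- sum(comb2(rowSums(tab)))
  sumJ <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sumI * sumJ / n2
  (sumIJ - expected) / ((sumI + sumJ) / 2 - expected)
}

# Mann-Whitney formulation of the AUC: independent rank-statistic oracle.
aucRankOracle <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  r <- rank(c(pos, neg))
  u <- sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2
  u / (length(pos) * length(neg))
}

# Independent sort-trim-SD oracle for the quality score.
qsOracle <- function(z) {
  s <- sort(z)
  kept <- s[2:(length(s) - 1)]
  m <- sum(kept) / length(kept)
  sqrt(sum((kept - m)^2) / (length(kept) - 1))
}
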