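test_that("normalization is the identity on uniform counts and scale-free", {
  bins <- smallBins()
  n <- length(bins)
  uni <- rep(10, n)
  norm <- normalizeProfile(uni, bins, gcCorrect = FALSE, smoothWindow = 1L)
  expect_equal(norm, rep(1 / n, n), tolerance = 1e-12)

  counts <- simulateProfile(bins, simConfig(), seed = 3L)
  a <- normalizeProfile(as.numeric(counts), bins)
  b <- normalizeProfile(as.numeric(counts) * 2, bins)
  expect_equal(a, b, tolerance = 1e-12)
  expect_equal(sum(a), 1, tolerance = 1e-9)
})

test_that("all-zero profiles are rejected as degenerate", {
  bins <- smallBins()
  expect_error(normalizeProfile(rep(0, length(bins)), bins), "degenerate")
})

test_that("GC correction removes the simulated GC trend", {
  bins <- testBins()
  cfg <- simConfig(gcBiasAmplitude = 0.5, meanDepth = 5e5, seed = 12L)
  sim <- simulateCohort(bins, cohortArm("control", 3L, pregnant = TRUE), cfg)
  raw <- SummarizedExperiment::assay(sim, "counts")[, 1L]
  preR <- cor(raw / sum(raw), bins$gc)
  post <- cor(normalizeCounts(sim)[, 1L], bins$gc)
  expect_gt(abs(preR), 0.3)
  expect_lt(abs(post), 0.1)
})

test_that("chromosomal representation sums to 1 and tracks mass placement", {
  bins <- smallBins()
  n <- length(bins)
  uni <- normalizeProfile(rep(5, n), bins, gcCorrect = FALSE,
                          smoothWindow = 1L)
  rep4 <- chromosomalRepresentation(uni, bins)
  expect_equal(unname(rep4), rep(1 / 4, 4L), tolerance = 1e-12)

  chr1 <- as.numeric(as.character(GenomicRanges::seqnames(bins)) == "1")
  rep1 <- chromosomalRepresentation(chr1 / sum(chr1), bins)
  expect_equal(unname(rep1), c(1, 0, 0, 0), tolerance = 1e-12)
})

test_that("trisomy representation matches the mixture expectation", {
  bins <- smallBins()
  cfg <- simConfig(trisomyChrom = "3", batchEffectSd = 0, seed = 31L)
  simT <- simulateCohort(bins, cohortArm("T", 200L, pregnant = TRUE,
                                         trisomic = TRUE, ff = 0.10), cfg)
  simD <- simulateCohort(bins, cohortArm("D", 200L, pregnant = TRUE,
                                         trisomic = FALSE, ff = 0.10),
                         simConfig(batchEffectSd = 0, seed = 32L))
  # raw depth-normalized representation: on a 4-chromosome toy genome the
  # trisomic chromosome is a quarter of the features, so the GC fit would
  # partially absorb the inflation; correction is exercised elsewhere
  normT <- normalizeCounts(simT, gcCorrect = FALSE, smoothWindow = 1L)
  normD <- normalizeCounts(simD, gcCorrect = FALSE, smoothWindow = 1L)
  oddsT <- chromosomalRepresentation(normT, bins)["3", ]
  oddsT <- oddsT / (1 - oddsT)
  oddsD <- chromosomalRepresentation(normD, bins)["3", ]
  oddsD <- oddsD / (1 - oddsD)
  # odds form removes the renormalization of the other chromosomes
  ratio <- mean(oddsT) / mean(oddsD)
  se <- ratio * sqrt(var(oddsT) / mean(oddsT)^2 +
                       var(oddsD) / mean(oddsD)^2) / sqrt(200)
  expect_lt(abs(ratio - 1.05), 3 * se)
})

test_that("reference building enforces its preconditions", {
  bins <- smallBins()
  norm <- normalizeCounts(simulateCohort(
    bins, cohortArm("control", 12L), simConfig(seed = 13L)))
  expect_s4_class(buildReference(norm, bins), "ReferenceSet")
  expect_error(buildReference(norm[, 1:9], bins), "insufficient")
  identical20 <- norm[, rep(1L, 20L)]
  expect_error(buildReference(identical20, bins), "degenerate")
})

test_that("reference means are unbiased for the chromosome bin share", {
  bins <- smallBins()
  cfg <- simConfig(gcBiasAmplitude = 0, batchEffectSd = 0, seed = 14L)
  norm <- normalizeCounts(simulateCohort(bins, cohortArm("control", 100L),
                                         cfg),
                          gcCorrect = FALSE, smoothWindow = 1L)
  ref <- buildReference(norm, bins)
  base <- attr(simulateProfile(bins, cfg, seed = 1L), "expected")
  chr <- as.character(GenomicRanges::seqnames(bins))
  share <- tapply(base, factor(chr, unique(chr)), sum)
  se <- referenceSds(ref) / sqrt(100)
  expect_true(all(abs(referenceMeans(ref) - share) < 3 * se))
})

test_that("z-scores center the reference on itself and scale as defined", {
  bins <- smallBins()
  norm <- normalizeCounts(simulateCohort(bins, cohortArm("control", 30L),
                                         simConfig(seed = 15L)))
  ref <- buildReference(norm, bins)
  z <- zScores(norm, bins, ref)
  expect_true(all(abs(rowMeans(z)) < 1e-9))  # centering identity

  # a profile at the reference means scores zero everywhere
  chr <- as.character(GenomicRanges::seqnames(bins))
  atMean <- as.numeric(referenceMeans(ref)[chr] / table(chr)[chr])
  expect_equal(unname(zScores(atMean, bins, ref)), rep(0, 4L),
               tolerance = 1e-9)

  # representation mean + 2 sd on one chromosome scores exactly 2 there
  manual <- new("ReferenceSet",
                chromMean = setNames(rep(0.25, 4L), as.character(1:4)),
                chromSd = setNames(rep(0.01, 4L), as.character(1:4)),
                nReference = 10L)
  r <- c(0.25 + 0.02, 0.25 - 0.02, 0.25, 0.25)
  v <- as.numeric(r[as.integer(chr)] / table(chr)[chr])
  expect_equal(unname(zScores(v, bins, manual)), c(2, -2, 0, 0),
               tolerance = 1e-9)
})

test_that("null z-scores are calibrated against an independent reference", {
  bins <- testBins()
  cfg0 <- simConfig(batchEffectSd = 0, seed = 21L)
  ref <- buildReference(normalizeCounts(
    simulateCohort(bins, cohortArm("control", 100L, pregnant = TRUE),
                   cfg0)), bins)
  z <- zScores(normalizeCounts(
    simulateCohort(bins, cohortArm("control", 200L, pregnant = TRUE),
                   simConfig(batchEffectSd = 0, seed = 22L))), bins, ref)
  seMean <- sqrt(1 / 100 + 1 / 200)  # reference + sampling error
  expect_true(all(abs(rowMeans(z)) < 4 * seMean))
  expect_lt(abs(mean(z)), 3 * seMean / sqrt(22) * 2)
  expect_true(all(abs(apply(z, 1L, sd) - 1) < 4 * sqrt(1 / 200 + 1 / 200)))
})

test_that("quality score equals the sort-trim-SD oracle", {
  expect_equal(qualityScore(rep(0, 22)), 0)
  expect_equal(qualityScore(c(-5, rep(0, 20), 5)), 0)
  expect_error(qualityScore(c(0, 1, 2)), ">= 4")
  zs <- withr::with_seed(33, replicate(50, rnorm(22), simplify = FALSE))
  for (z in zs) expect_equal(qualityScore(z), qsOracle(z),
                             tolerance = 1e-12)
})

test_that("QS never decreases when inflating an above-mean chromosome", {
  # holds for chromosomes at or above the trimmed-set mean; below the mean a
  # small inflation provably shrinks the trimmed SD
  zs <- withr::with_seed(34, replicate(20, rnorm(22), simplify = FALSE))
  for (z in zs) {
    kept <- sort(z)[2:21]
    j <- which(z > min(z) & z < max(z) & z >= mean(kept))[1]
    path <- vapply(seq(0, 4, by = 0.2), function(t)
      qualityScore(replace(z, j, z[j] + t)), numeric(1))
    expect_true(all(diff(path) >= -1e-12))
  }
})

test_that("NIPS calls fire the documented rules", {
  z <- setNames(rep(0, 22), as.character(1:22))

  lowFF <- callNips(z, qs = 0.5, ff = 0.039)
  expect_equal(lowFF$call, "inconclusive")
  expect_equal(lowFF$reason, "low-FF")

  highQS <- callNips(z, qs = 2.0, ff = 0.10)
  expect_equal(highQS$call, "inconclusive")
  expect_equal(highQS$reason, "high-QS")

  z21 <- replace(z, "21", 5)
  ok <- callNips(z21, qs = 1.99, ff = 0.10)
  expect_equal(ok$call, "conclusive")
  expect_equal(ok$reason, "none")
  expect_true(ok$aneuploidyFlags[["21"]])
  expect_false(ok$aneuploidyFlags[["13"]])

  both <- callNips(z, qs = 2.5, ff = 0.01)
  expect_equal(both$reason, "both")

  noFF <- callNips(z, qs = 0.5)
  expect_equal(noFF$call, "conclusive")
})

test_that("the normalize -> z -> QS pipeline is bit-stable across runs", {
  bins <- smallBins()
  sim <- simulateCohort(bins, cohortArm("control", 15L),
                        simConfig(seed = 16L))
  run <- function() {
    norm <- normalizeCounts(sim)
    ref <- buildReference(norm, bins)
    qualityScore(zScores(norm, bins, ref))
  }
  expect_identical(run(), run())
})
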