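#' Create a simulation configuration
#'
#' Defaults describe the scaled-down study conditions used throughout the
#' package: 200,000 expected autosomal reads spread over the default
#' 2,200-bin grid (roughly 90 reads per bin), negative-binomial
#' overdispersion with size 50, a moderate multiplicative GC bias, fetal
#' fractions centred at 10% with SD 4%, two technical batches with a 5%
#' (log-scale) per-bin batch effect, and 2% replicate noise.
#'
#' @param meanDepth expected total autosomal read count per sample.
#' @param dispersion negative-binomial size; per-bin variance `mu + mu^2/size`.
#' @param gcBiasAmplitude amplitude of `exp(a * (gc - 0.5))` coverage bias.
#' @param ffMean,ffSd moments of the Beta fetal-fraction distribution for
#'   pregnant samples; draws clipped to \[0, 0.5\].
#' @param trisomyChrom chromosome name made trisomic in trisomic fetuses, or
#'   `NA` for none.
#' @param nBatches number of technical batches.
#' @param batchEffectSd log-scale SD of per-batch, per-bin multipliers.
#' @param replicateNoiseSd log-scale SD of per-replicate multipliers.
#' @param seed integer seed; all cohort randomness flows from it.
#' @return a [SimConfig-class] object.
#' @examples
#' simConfig(trisomyChrom = "21")
#' @export
simConfig <- function(meanDepth = 2e5, dispersion = 50,
                      gcBiasAmplitude = 0.3, ffMean = 0.10, ffSd = 0.04,
                      trisomyChrom = NA_character_, nBatches = 2L,
                      batchEffectSd = 0.05, replicateNoiseSd = 0.02,
                      seed = 1L) {
  new("SimConfig", meanDepth = meanDepth, dispersion = dispersion,
      gcBiasAmplitude = gcBiasAmplitude, ffMean = ffMean, ffSd = ffSd,
      trisomyChrom = as.character(trisomyChrom), nBatches = as.integer(nBatches),
      batchEffectSd = batchEffectSd, replicateNoiseSd = replicateNoiseSd,
      seed = as.integer(seed))
}

#' Define a multiplicative disease signature
#'
#' @param name class label, e.g. `"AID-like"`.
#' @param bins 1-based bin indices the signature perturbs; empty for the
#'   null signature.
#' @param effect multiplicative coverage factor (> 0) on affected bins.
#' @param withinClassSd log-scale SD of the per-individual effect jitter.
#' @return a [DiseaseSignature-class].
#' @examples
#' diseaseSignature("AID-like", 1:40, effect = 1.3)
#' @export
diseaseSignature <- function(name, bins = integer(), effect = 1,
                             withinClassSd = 0.05) {
  new("DiseaseSignature", name = name, bins = as.integer(bins),
      effect = effect, withinClassSd = withinClassSd)
}

#' @rdname diseaseSignature
#' @export
nullSignature <- function(name = "control") {
  diseaseSignature(name, integer(), effect = 1, withinClassSd = 0)
}

#' Draw a random block signature on a binning
#'
#' Places `nBlocks` contiguous blocks of `blockWidth` bins uniformly over the
#' grid (non-overlapping), mimicking dispersed region-level coverage
#' perturbations shared by a disease class.
#'
#' @param bins the binning `GRanges`.
#' @param nBlocks,blockWidth number and width (bins) of perturbed blocks.
#' @inheritParams diseaseSignature
#' @param seed integer seed for block placement.
#' @return a [DiseaseSignature-class].
#' @export
randomSignature <- function(bins, name = "disease-like", nBlocks = 10L,
                            blockWidth = 22L, effect = 1.3,
                            withinClassSd = 0.05, seed = 1L) {
  n <- length(bins)
  stopInvalid(nBlocks * blockWidth > n, "signature larger than the binning")
  withSeed(seed, {
    idx <- integer()
    starts <- integer()
    tries <- 0L
    while (length(starts) < nBlocks && tries < 10000L) {
      s <- sample.int(n - blockWidth + 1L, 1L)
      if (!any(abs(s - starts) < blockWidth)) starts <- c(starts, s)
      tries <- tries + 1L
    }
    stopInvalid(length(starts) < nBlocks, "could not place signature blocks")
    for (s in starts) idx <- c(idx, s:(s + blockWidth - 1L))
    diseaseSignature(name, sort(idx), effect, withinClassSd)
  })
}

# Plain-vector view of a binning + config, hoisted out of per-profile loops
# (S4 accessor dispatch is costly at cohort scale).
binContext <- function(bins, config) {
  gc <- bins$gc
  baseline <- if (is.null(bins$baseline)) rep(1, length(bins)) else bins$baseline
  trisomyBins <- if (!is.na(config@trisomyChrom)) {
    m <- binChroms(bins) == config@trisomyChrom
    stopInvalid(!any(m), "trisomyChrom not present in the binning")
    m
  } else rep(FALSE, length(bins))
  list(base = baseline * exp(config@gcBiasAmplitude * (gc - 0.5)),
       trisomyBins = trisomyBins)
}

# Expected per-bin fraction of reads for one sample: softly varying baseline
# x GC bias x disease effect x fetal factor, renormalized to sum to 1.
expectedBinFractions <- function(ctx, signatureFactor = NULL,
                                 pregnant = FALSE, ff = NA_real_,
                                 trisomic = FALSE, extraFactor = NULL) {
  w <- ctx$base
  if (!is.null(signatureFactor)) w <- w * signatureFactor
  if (pregnant && trisomic && any(ctx$trisomyBins))
    w[ctx$trisomyBins] <- w[ctx$trisomyBins] * ((1 - ff) + ff * 1.5)
  if (!is.null(extraFactor)) w <- w * extraFactor
  w / sum(w)
}

# Per-bin multiplicative factor of a signature for one individual (shared by
# that individual's replicates).
signatureFactor <- function(signature, nBins) {
  stopInvalid(length(signature@bins) > 0L && max(signature@bins) > nBins,
              "signature bin indices out of range")
  f <- rep(1, nBins)
  if (length(signature@bins)) {
    jitter <- if (signature@withinClassSd > 0)
      exp(rnorm(1L, 0, signature@withinClassSd)) else 1
    f[signature@bins] <- signature@effect * jitter
  }
  f
}

#' Simulate one cfDNA bin-count profile
#'
#' Draws negative-binomial bin counts around the expected fractions
#' `baseline x exp(gcBiasAmplitude (gc - 0.5)) x signature x fetal factor`,
#' renormalized to sum to 1 and scaled by `meanDepth`. For a pregnant
#' trisomic sample, bins on `trisomyChrom` are inflated by
#' `(1 - ff) + 1.5 ff`, the plasma mixture of a disomic maternal and a
#' trisomic placental compartment.
#'
#' @param bins binning `GRanges` from [makeBins()].
#' @param config a [SimConfig-class].
#' @param signature a [DiseaseSignature-class]; default none.
#' @param pregnant logical; `ff` is only honoured when `TRUE`.
#' @param ff fetal fraction in \[0, 0.5\].
#' @param trisomic logical; whether the fetus carries the configured trisomy.
#' @param seed optional seed; when `NULL` the current RNG state is used (as
#'   when called from [simulateCohort()]).
#' @return integer vector of bin counts (`length(bins)`), with the expected
#'   fractions in `attr(, "expected")`.
#' @examples
#' bins <- makeBins(4, 30, seed = 1)
#' counts <- simulateProfile(bins, simConfig(meanDepth = 5e4), seed = 7)
#' sum(counts)
#' @export
simulateProfile <- function(bins, config, signature = nullSignature(),
                            pregnant = FALSE, ff = NA_real_, trisomic = FALSE,
                            seed = NULL) {
  if (pregnant) stopInvalid(is.na(ff) || ff < 0 || ff > 0.5,
                            "pregnant samples need ff in [0, 0.5]")
  withSeed(seed, {
    ctx <- binContext(bins, config)
    f <- signatureFactor(signature, length(bins))
    p <- expectedBinFractions(ctx, f, pregnant, ff, trisomic)
    counts <- rnbinom(length(bins), mu = config@meanDepth * p,
                      size = config@dispersion)
    attr(counts, "expected") <- p
    counts
  })
}

#' Describe one arm of a simulated cohort
#'
#' @param label disease label (`"control"`, `"SLE-like"`, `"other-AID-like"`,
#'   `"IBD-like"`, `"blood-disorder-like"`, ...).
#' @param n number of individuals.
#' @param pregnant logical.
#' @param signature a [DiseaseSignature-class] shared by the arm.
#' @param nReplicates profiles drawn per individual (0/1 mean a single one).
#' @param trisomic logical; combined with the config's `trisomyChrom`.
#' @param ff fixed fetal fraction for the arm's pregnant individuals; `NA`
#'   draws per-individual from the configured Beta distribution.
#' @return a one-row design data.frame (rbind rows to build a design).
#' @export
cohortArm <- function(label, n, pregnant = FALSE,
                      signature = nullSignature(), nReplicates = 0L,
                      trisomic = FALSE, ff = NA_real_) {
  d <- data.frame(label = label, n = as.integer(n), pregnant = pregnant,
                  nReplicates = as.integer(nReplicates), trisomic = trisomic,
                  ff = ff, stringsAsFactors = FALSE)
  d$signature <- list(signature)
  d
}

#' Simulate a cfDNA cohort as a RangedSummarizedExperiment
#'
#' Generates every profile of a design (a row-bound set of [cohortArm()]s)
#' under a single seed. Replicates of an individual share its fetal fraction
#' and its per-individual disease-effect draw and differ by replicate noise,
#' fresh counting noise, and possibly batch. Batches cycle round-robin over
#' profiles; each batch carries its own per-bin log-normal effect.
#'
#' @param bins binning `GRanges`.
#' @param design data.frame from rbinding [cohortArm()] rows.
#' @param config a [SimConfig-class]; `config@seed` drives all draws.
#' @return a [SummarizedExperiment::RangedSummarizedExperiment]: assay
#'   `counts` (bins x samples), `rowRanges` the binning, `colData` the
#'   per-sample metadata and latent truth (ff, batch, individual effect,
#'   signature name, trisomy), and `metadata(x)$config`/`$batchFactors`.
#' @examples
#' bins <- makeBins(4, 30, seed = 1)
#' design <- rbind(cohortArm("control", 5), cohortArm("SLE-like", 2,
#'   signature = randomSignature(bins, "SLE-like", 3, 5, 1.4, seed = 2)))
#' sim <- simulateCohort(bins, design, simConfig(meanDepth = 5e4))
#' dim(sim)
#' @export
simulateCohort <- function(bins, design, config = simConfig()) {
  stopInvalid(nrow(design) == 0L, "design must be non-empty")
  nBins <- length(bins)
  ctx <- binContext(bins, config)
  withSeed(config@seed, {
    batchFactors <- matrix(
      exp(rnorm(nBins * config@nBatches, 0, config@batchEffectSd)),
      nrow = nBins)
    colnames(batchFactors) <- paste0("batch", seq_len(config@nBatches))

    counts <- list(); meta <- list()
    profileIdx <- 0L
    for (a in seq_len(nrow(design))) {
      arm <- design[a, ]
      sig <- arm$signature[[1L]]
      for (i in seq_len(arm$n)) {
        indivId <- sprintf("%s_%02d_%03d", arm$label, a, i)
        f <- signatureFactor(sig, nBins)
        ff <- if (!arm$pregnant) NA_real_
              else if (!is.na(arm$ff)) arm$ff
              else drawFetalFraction(config)
        sledai <- drawSledai(arm$label, arm$pregnant)
        nRep <- max(1L, arm$nReplicates)
        for (r in seq_len(nRep)) {
          profileIdx <- profileIdx + 1L
          batch <- ((profileIdx - 1L) %% config@nBatches) + 1L
          repNoise <- if (config@replicateNoiseSd > 0)
            exp(rnorm(nBins, 0, config@replicateNoiseSd)) else rep(1, nBins)
          p <- expectedBinFractions(ctx, f, arm$pregnant, ff, arm$trisomic,
                                    extraFactor = batchFactors[, batch] * repNoise)
          counts[[profileIdx]] <- rnbinom(nBins, mu = config@meanDepth * p,
                                          size = config@dispersion)
          meta[[profileIdx]] <- data.frame(
            sample_id = sprintf("%s_r%d", indivId, r),
            pregnant = arm$pregnant, ff = ff,
            disease_label = arm$label, replicate_group = indivId,
            batch = colnames(batchFactors)[batch],
            sledai_category = sledai, trisomic = arm$trisomic,
            signature = sig@name,
            indiv_effect = if (length(sig@bins)) f[sig@bins[1L]] else 1,
            stringsAsFactors = FALSE)
        }
      }
    }
    mat <- do.call(cbind, counts)
    cd <- do.call(rbind, meta)
    colnames(mat) <- cd$sample_id
    rownames(cd) <- cd$sample_id
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = mat), rowRanges = bins,
      colData = S4Vectors::DataFrame(cd))
    S4Vectors::metadata(se) <- list(config = config,
                                    batchFactors = batchFactors)
    se
  })
}

# Beta-distributed fetal fraction with the configured moments, clipped.
drawFetalFraction <- function(config) {
  if (config@ffSd <= 0) return(min(max(config@ffMean, 0), 0.5))
  m <- config@ffMean; v <- config@ffSd^2
  k <- m * (1 - m) / v - 1
  ff <- rbeta(1L, shape1 = m * k, shape2 = (1 - m) * k)
  min(max(ff, 0), 0.5)
}

# SLEDAI category: defined for non-pregnant SLE-like individuals only.
drawSledai <- function(label, pregnant) {
  if (identical(label, "SLE-like") && !pregnant) {
    sample(c("none", "mild", "high"), 1L, prob = c(0.3, 0.4, 0.3))
  } else "not-available"
}
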