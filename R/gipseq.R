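#' Normalize one bin-count profile
#'
#' Depth-normalizes raw bin counts (division by the autosomal total),
#' optionally removes the sample's GC bias by a robust local-linear fit of
#' count versus bin GC (the fit's prediction divides the counts), smooths
#' within each chromosome with a running median, and renormalizes so the
#' autosomal values sum to 1. Sex-chromosome bins, if present, are carried
#' through but excluded from all totals.
#'
#' @param counts non-negative integer/numeric vector, one value per bin.
#' @param bins binning `GRanges` matching `counts`.
#' @param gcCorrect logical; apply the GC fit.
#' @param smoothWindow odd integer running-median window (1 disables).
#' @param gcSpan smoother span of the GC fit.
#' @return numeric vector of normalized values (autosomal sum 1).
#' @examples
#' bins <- makeBins(3, 40, seed = 1)
#' norm <- normalizeProfile(simulateProfile(bins, simConfig(), seed = 1), bins)
#' sum(norm)
#' @export
normalizeProfile <- function(counts, bins, gcCorrect = TRUE,
                             smoothWindow = 5L, gcSpan = 0.3) {
  stopInvalid(length(counts) != length(bins),
              "counts length must match the binning")
  normalizeVec(counts, gc = bins$gc, chrom = binChroms(bins),
               auto = autosomeMask(bins), gcCorrect = gcCorrect,
               smoothWindow = smoothWindow, gcSpan = gcSpan)
}

# Plain-vector worker shared by normalizeProfile/normalizeCounts.
normalizeVec <- function(counts, gc, chrom, auto, gcCorrect, smoothWindow,
                         gcSpan) {
  stopInvalid(smoothWindow < 1L || smoothWindow %% 2L == 0L,
              "smoothWindow must be an odd positive integer")
  total <- sum(counts[auto])
  stopInvalid(total <= 0, "degenerate input: all-zero profile")
  v <- counts / total
  if (gcCorrect) {
    fit <- lowess(gc[auto], v[auto], f = gcSpan)
    pred <- stats::approx(fit$x, fit$y, xout = gc, rule = 2, ties = mean)$y
    pred <- pmax(pred, 1e-12)
    v <- v / (pred / mean(pred[auto]))
  }
  if (smoothWindow > 1L) {
    for (idx in split(seq_along(v), chrom)) {
      if (length(idx) >= smoothWindow)
        v[idx] <- runmed(v[idx], k = smoothWindow, endrule = "median")
    }
  }
  v / sum(v[auto])
}

#' Normalize every sample of a cohort
#'
#' @param x bins x samples count matrix, or a cohort
#'   `RangedSummarizedExperiment` from [simulateCohort()] (its `counts`
#'   assay and `rowRanges` are used).
#' @inheritParams normalizeProfile
#' @return bins x samples matrix of normalized values.
#' @export
normalizeCounts <- function(x, bins = NULL, gcCorrect = TRUE,
                            smoothWindow = 5L, gcSpan = 0.3) {
  if (is(x, "SummarizedExperiment")) {
    bins <- SummarizedExperiment::rowRanges(x)
    x <- SummarizedExperiment::assay(x, "counts")
  }
  stopInvalid(is.null(bins), "a binning is required for a plain matrix")
  gc <- bins$gc; chrom <- binChroms(bins); auto <- autosomeMask(bins)
  out <- apply(x, 2L, normalizeVec, gc = gc, chrom = chrom, auto = auto,
               gcCorrect = gcCorrect, smoothWindow = smoothWindow,
               gcSpan = gcSpan)
  dimnames(out) <- dimnames(x)
  out
}

#' Per-chromosome share of the autosomal cfDNA signal
#'
#' @param norm normalized value vector or bins x samples matrix from
#'   [normalizeCounts()].
#' @param bins binning `GRanges`.
#' @return chromosomal representation: fractions summing to 1 per sample
#'   (named vector, or chromosomes x samples matrix).
#' @export
chromosomalRepresentation <- function(norm, bins) {
  auto <- autosomeMask(bins)
  chr <- factor(binChroms(bins)[auto],
                levels = unique(binChroms(bins)[auto]))
  if (is.matrix(norm)) {
    rep <- rowsum(norm[auto, , drop = FALSE], chr)
    sweep(rep, 2L, colSums(rep), "/")
  } else {
    rep <- rowsum(norm[auto], chr)[, 1L]
    rep / sum(rep)
  }
}

#' Build a reference set from euploid control profiles
#'
#' Per-chromosome mean and sample SD of chromosomal representation across at
#' least 10 designated controls, the yardstick the z-scores are measured
#' against.
#'
#' @param controls bins x samples normalized matrix of control profiles.
#' @param bins binning `GRanges`.
#' @return a [ReferenceSet-class].
#' @export
buildReference <- function(controls, bins) {
  stopInvalid(!is.matrix(controls) || ncol(controls) < 10L,
              "insufficient reference: need >= 10 control profiles")
  rep <- chromosomalRepresentation(controls, bins)
  m <- rowMeans(rep)
  s <- apply(rep, 1L, sd)
  stopInvalid(any(s <= 0),
              "degenerate reference: zero SD on some chromosome")
  new("ReferenceSet", chromMean = m, chromSd = s,
      nReference = ncol(controls))
}

#' Chromosomal z-scores against a reference set
#'
#' `z_c = (representation_c - mean_c) / sd_c` for every autosome, measuring
#' the sample's differential cfDNA representation in reference SDs.
#'
#' @param norm normalized vector or bins x samples matrix.
#' @param bins binning `GRanges`.
#' @param ref a [ReferenceSet-class].
#' @return named z vector, or chromosomes x samples matrix.
#' @export
zScores <- function(norm, bins, ref) {
  rep <- chromosomalRepresentation(norm, bins)
  if (is.matrix(rep)) {
    stopInvalid(nrow(rep) != length(ref@chromMean),
                "reference does not match the binning")
    sweep(sweep(rep, 1L, ref@chromMean, "-"), 1L, ref@chromSd, "/")
  } else {
    stopInvalid(length(rep) != length(ref@chromMean),
                "reference does not match the binning")
    (rep - ref@chromMean) / ref@chromSd
  }
}

#' Genome-wide quality score
#'
#' The sample standard deviation (n-1 denominator) of the autosomal z-scores
#' after removing the single highest and single lowest scoring chromosome.
#' Large values flag profiles whose genome-wide representation deviates from
#' the reference beyond any single-chromosome event.
#'
#' @param z numeric z vector (>= 4 values), or a chromosomes x samples
#'   matrix (one QS per column).
#' @return numeric QS (scalar or per-sample vector).
#' @examples
#' qualityScore(c(-5, rep(0, 20), 5))  # extremes trimmed: 0
#' @export
qualityScore <- function(z) {
  if (is.matrix(z)) return(apply(z, 2L, qualityScore))
  stopInvalid(length(z) < 4L, "need >= 4 autosomal z-scores")
  ord <- order(z)
  sd(z[ord[c(-1L, -length(z))]])
}

#' Conclusive/inconclusive NIPS call for one sample
#'
#' A result is inconclusive when the fetal fraction is below `ffCutoff`
#' (default 4%) or the quality score is at or above `qsCutoff` (default 2);
#' the reason records which rule(s) fired. Trisomy flags for the target
#' chromosomes (13, 18, 21 when present in the binning) are informational
#' and only reported on conclusive calls. A missing fetal fraction (e.g. a
#' non-pregnant sample) disables the low-FF rule.
#'
#' @param z named autosomal z vector.
#' @param qs quality score (defaults to `qualityScore(z)`).
#' @param ff fetal fraction or `NA`.
#' @param ffCutoff,qsCutoff the call thresholds.
#' @param aneuploidyCutoff z cutoff for the informational trisomy flags.
#' @param targetChroms chromosomes screened for trisomy.
#' @return list with `call` (`"conclusive"`/`"inconclusive"`), `reason`
#'   (`"none"`, `"low-FF"`, `"high-QS"`, `"both"`), `qs`, `ff`, and
#'   `aneuploidyFlags` (named logical, `NA` on inconclusive calls).
#' @examples
#' z <- setNames(rep(0, 22), 1:22); z["21"] <- 5
#' callNips(z, ff = 0.1)
#' @export
callNips <- function(z, qs = qualityScore(z), ff = NA_real_,
                     ffCutoff = 0.04, qsCutoff = 2, aneuploidyCutoff = 3,
                     targetChroms = c("13", "18", "21")) {
  lowFF <- !is.na(ff) && ff < ffCutoff
  highQS <- qs >= qsCutoff
  reason <- if (lowFF && highQS) "both"
            else if (lowFF) "low-FF"
            else if (highQS) "high-QS"
            else "none"
  call <- if (reason == "none") "conclusive" else "inconclusive"
  targets <- intersect(targetChroms, names(z))
  flags <- setNames(rep(NA, length(targets)), targets)
  if (call == "conclusive")
    flags[] <- z[targets] >= aneuploidyCutoff
  list(call = call, reason = reason, qs = unname(qs), ff = unname(ff),
       aneuploidyFlags = flags)
}

#' Z-scores, QS and NIPS calls for a whole cohort
#'
#' Convenience wrapper running [normalizeCounts()], [zScores()],
#' [qualityScore()] and [callNips()] over every sample of a cohort against a
#' supplied reference.
#'
#' @param cohort cohort `RangedSummarizedExperiment` (needs `counts` assay,
#'   `rowRanges`, and an `ff` column in `colData` for pregnant samples).
#' @param ref a [ReferenceSet-class].
#' @inheritParams normalizeProfile
#' @inheritParams callNips
#' @return a `S4Vectors::DataFrame` with one row per sample: `qs`, `ff`,
#'   `call`, `reason`, per-target trisomy flags, and the z matrix in
#'   `metadata()$z`.
#' @export
nipsCalls <- function(cohort, ref, gcCorrect = TRUE, smoothWindow = 5L,
                      ffCutoff = 0.04, qsCutoff = 2, aneuploidyCutoff = 3) {
  bins <- SummarizedExperiment::rowRanges(cohort)
  norm <- normalizeCounts(cohort, gcCorrect = gcCorrect,
                          smoothWindow = smoothWindow)
  z <- zScores(norm, bins, ref)
  qs <- qualityScore(z)
  ff <- SummarizedExperiment::colData(cohort)$ff
  if (is.null(ff)) ff <- rep(NA_real_, ncol(cohort))
  calls <- lapply(seq_len(ncol(cohort)), function(i)
    callNips(z[, i], qs[i], ff[i], ffCutoff, qsCutoff, aneuploidyCutoff))
  flags <- do.call(rbind, lapply(calls, `[[`, "aneuploidyFlags"))
  out <- S4Vectors::DataFrame(
    sample_id = colnames(cohort),
    qs = qs, ff = ff,
    call = vapply(calls, `[[`, "", "call"),
    reason = vapply(calls, `[[`, "", "reason"))
  if (!is.null(flags) && ncol(flags))
    for (j in colnames(flags)) out[[paste0("t", j, "_flag")]] <- flags[, j]
  rownames(out) <- colnames(cohort)
  S4Vectors::metadata(out) <- list(z = z)
  out
}
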