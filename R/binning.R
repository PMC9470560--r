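#' Construct a synthetic genomic bin coordinate system
#'
#' Builds the fixed-width bin grid every cfDNA profile is indexed by, as a
#' [GenomicRanges::GRanges] with a `gc` metadata column (GC content drawn
#' smoothly along each chromosome, autocorrelated, in \[0.3, 0.7\]) and a
#' `baseline` column (softly varying relative mappability/coverage weight).
#' Coordinates are 0-based half-open internally (BED convention); the GRanges
#' stores `start + 1` per Bioconductor's 1-based closed convention and
#' round-trips through [writeBinAnnotation()] as 0-based half-open.
#'
#' The default grid (22 autosomes x 100 bins) is a scaled-down genome that
#' preserves chromosome-level behaviour; `makeBins(22, 2614)` gives a
#' full-scale grid of about 57.5k autosomal features.
#'
#' @param nChroms number of autosomes (chromosomes named `"1"`, `"2"`, ...).
#' @param nBinsPerChrom bins per chromosome; scalar or vector of length
#'   `nChroms`.
#' @param binSize bin width in bp.
#' @param seed integer seed; the GC and baseline tracks are deterministic
#'   given it.
#' @return a `GRanges` of bins with metadata columns `gc` and `baseline`.
#' @examples
#' bins <- makeBins(4, 50, seed = 1)
#' length(bins)
#' @export
makeBins <- function(nChroms = 22L, nBinsPerChrom = 100L, binSize = 50000L,
                     seed = 1L) {
  stopInvalid(nChroms < 2L, "nChroms must be >= 2")
  stopInvalid(any(nBinsPerChrom < 2L), "nBinsPerChrom must be >= 2")
  nb <- rep_len(as.integer(nBinsPerChrom), nChroms)
  withSeed(seed, {
    grl <- lapply(seq_len(nChroms), function(i) {
      n <- nb[i]
      gc <- 0.5 + 0.15 * smoothTrack(n, window = 11L)
      gc <- pmin(pmax(gc, 0.3), 0.7)
      baseline <- exp(0.10 * smoothTrack(n, window = 21L))
      GenomicRanges::GRanges(
        seqnames = as.character(i),
        ranges = IRanges::IRanges(
          start = seq.int(0L, by = binSize, length.out = n) + 1L,
          width = binSize),
        gc = gc, baseline = baseline)
    })
    bins <- suppressWarnings(do.call(c, grl))
    GenomeInfoDb::seqlevels(bins) <- as.character(seq_len(nChroms))
    validateBins(bins)
    bins
  })
}

# Smooth unit-variance track: moving-average of white noise, autocorrelated
# over ~`window` bins.
smoothTrack <- function(n, window = 11L) {
  e <- rnorm(n + window - 1L)
  s <- as.numeric(stats::filter(e, rep(1 / window, window), sides = 1L))
  s <- s[window:(n + window - 1L)]
  s * sqrt(window)  # restore unit variance
}

#' Validate a bin coordinate system
#'
#' Checks the invariants every cfScope binning must satisfy: per-chromosome
#' bins sorted and non-overlapping, positive widths, GC in \[0,1\], and at
#' least two bins on every chromosome.
#'
#' @param bins a `GRanges` with a numeric `gc` metadata column.
#' @return `bins`, invisibly; errors on violation.
#' @export
validateBins <- function(bins) {
  stopInvalid(!is(bins, "GRanges"), "bins must be a GRanges")
  stopInvalid(is.null(bins$gc), "bins must carry a 'gc' metadata column")
  stopInvalid(any(bins$gc < 0 | bins$gc > 1), "gc must be in [0, 1]")
  stopInvalid(any(GenomicRanges::width(bins) < 1L), "bins must have end > start")
  perChrom <- table(as.character(GenomicRanges::seqnames(bins)))
  stopInvalid(any(perChrom < 2L), "every chromosome needs >= 2 bins")
  bychr <- split(bins, as.character(GenomicRanges::seqnames(bins)))
  for (g in bychr) {
    s <- GenomicRanges::start(g); e <- GenomicRanges::end(g)
    stopInvalid(is.unsorted(s, strictly = TRUE),
                "bins within a chromosome must be sorted")
    if (length(s) > 1L)
      stopInvalid(any(s[-1] <= e[-length(e)]),
                  "bins within a chromosome must not overlap")
  }
  invisible(bins)
}

# Character chromosome vector of a binning.
binChroms <- function(bins) as.character(GenomicRanges::seqnames(bins))

# Logical mask of autosomal bins ("1".."22"; excludes "X"/"Y" etc).
autosomeMask <- function(bins) binChroms(bins) %in% as.character(1:22)
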