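#' Read a samples-by-bins count/value matrix from TSV
#'
#' First column `sample_id`, remaining columns one per bin. Ragged rows,
#' non-numeric cells, missing values and duplicate sample ids are rejected
#' with the offending line/sample named. Leading `#` comment lines (the
#' provenance stamp written by the pipeline) are skipped.
#'
#' @param path TSV path.
#' @return numeric matrix (samples x bins) with sample ids as rownames.
#' @export
readBinMatrix <- function(path) {
  stopInvalid(!file.exists(path), paste("no such file:", path))
  dt <- tryCatch(
    data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                      skip = countCommentLines(path)),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  stopInvalid(ncol(dt) < 2L || names(dt)[1L] != "sample_id",
              "bin matrix must start with a sample_id column")
  ids <- as.character(dt[[1L]])
  dup <- ids[duplicated(ids)]
  stopInvalid(length(dup) > 0L,
              paste("parse error: duplicate sample id", dup[1L]))
  m <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(dt[-1L], is.numeric, logical(1L)))[1L]
    stop("parse error: non-numeric cells in column '",
         names(dt)[-1L][bad], "'", call. = FALSE)
  }
  if (anyNA(m)) {
    bad <- which(rowSums(is.na(m)) > 0L)[1L]
    stop("parse error: missing values in sample '", ids[bad], "'",
         call. = FALSE)
  }
  rownames(m) <- ids
  message("read bin matrix: ", nrow(m), " samples x ", ncol(m), " bins")
  m
}

#' @rdname readBinMatrix
#' @param mat samples x bins matrix with sample ids as rownames.
#' @param path output TSV path.
#' @param stamp optional `# comment` provenance line written first.
#' @export
writeBinMatrix <- function(mat, path, stamp = NULL) {
  df <- data.frame(sample_id = rownames(mat), mat, check.names = FALSE)
  writeStamped(df, path, stamp)
  invisible(path)
}

#' Read a BED-like bin annotation into a binning
#'
#' Tab-separated columns `chrom`, `start`, `end`, `gc` (optionally
#' `baseline`), 0-based half-open coordinates. `end <= start` or GC outside
#' \[0, 1\] is a parse error; unsorted bins are accepted but re-sorted with
#' a warning.
#'
#' @param path TSV path.
#' @return binning `GRanges` (as from [makeBins()]).
#' @export
readBinAnnotation <- function(path) {
  stopInvalid(!file.exists(path), paste("no such file:", path))
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "gc")
  stopInvalid(!all(need %in% names(df)),
              "bin annotation needs columns chrom, start, end, gc")
  bad <- which(df$end <= df$start)
  stopInvalid(length(bad) > 0L,
              paste("parse error: end <= start at line", bad[1L] + 1L))
  bad <- which(df$gc < 0 | df$gc > 1)
  stopInvalid(length(bad) > 0L,
              paste("parse error: gc outside [0,1] at line", bad[1L] + 1L))
  if (is.null(df$baseline)) df$baseline <- 1
  o <- order(factor(df$chrom, levels = unique(df$chrom)), df$start)
  if (!identical(o, seq_len(nrow(df)))) {
    warning("bins were unsorted; re-sorting")
    df <- df[o, ]
  }
  bins <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    gc = df$gc, baseline = df$baseline)
  validateBins(bins)
  bins
}

#' @rdname readBinAnnotation
#' @param bins binning `GRanges`.
#' @inheritParams writeBinMatrix
#' @export
writeBinAnnotation <- function(bins, path, stamp = NULL) {
  df <- data.frame(chrom = binChroms(bins),
                   start = GenomicRanges::start(bins) - 1L,
                   end = GenomicRanges::end(bins),
                   gc = bins$gc,
                   baseline = if (is.null(bins$baseline)) 1 else bins$baseline)
  con <- file(path, "w")
  writeLines("# coordinates are 0-based half-open (BED convention)", con)
  if (!is.null(stamp)) writeLines(paste0("# ", stamp), con)
  close(con)
  suppressWarnings(
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                append = TRUE))
  invisible(path)
}

#' Write a simulated cohort to a directory of plain-text files
#'
#' Emits `matrix.tsv` (samples x bins counts), `bins.tsv` (BED-like
#' annotation), `metadata.tsv` (observable sample metadata) and `truth.tsv`
#' (the latent simulation truth: signature draws, batches, trisomy).
#'
#' @param cohort cohort `RangedSummarizedExperiment` from [simulateCohort()].
#' @param dir output directory (created if needed).
#' @param stamp optional provenance comment for every file.
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir, stamp = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeBinMatrix(t(SummarizedExperiment::assay(cohort, "counts")),
                 file.path(dir, "matrix.tsv"), stamp)
  writeBinAnnotation(SummarizedExperiment::rowRanges(cohort),
                     file.path(dir, "bins.tsv"), stamp)
  cd <- as.data.frame(SummarizedExperiment::colData(cohort))
  obs <- intersect(c("sample_id", "pregnant", "ff", "disease_label",
                     "replicate_group", "batch", "sledai_category"),
                   names(cd))
  writeStamped(cd[, obs], file.path(dir, "metadata.tsv"), stamp)
  writeStamped(cd, file.path(dir, "truth.tsv"), stamp)
  invisible(dir)
}

#' Read a cohort back from [writeCohort()] output
#'
#' @param dir directory holding `matrix.tsv`, `bins.tsv`, `metadata.tsv`.
#' @return cohort `RangedSummarizedExperiment`.
#' @export
readCohort <- function(dir) {
  mat <- readBinMatrix(file.path(dir, "matrix.tsv"))
  bins <- readBinAnnotation(file.path(dir, "bins.tsv"))
  stopInvalid(ncol(mat) != length(bins),
              "matrix and bin annotation disagree on bin count")
  md <- read.delim(file.path(dir, "metadata.tsv"), comment.char = "#",
                   stringsAsFactors = FALSE)
  stopInvalid(!identical(sort(md$sample_id), sort(rownames(mat))),
              "metadata and matrix disagree on sample ids")
  md <- md[match(rownames(mat), md$sample_id), ]
  rownames(md) <- md$sample_id
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = t(mat)), rowRanges = bins,
    colData = S4Vectors::DataFrame(md))
}

#' Plain-text classifier persistence
#'
#' Writes the full decision rule as documented text files — PCA center and
#' rotation (TSV), the SVM's support vectors and dual coefficients (TSV)
#' and a YAML of kernel, cost, gamma, rho, class weights, labels and the
#' frozen decision threshold — so predictions are reproducible without any
#' binary artifact. [readClassifier()] restores a classifier whose decision
#' values are computed directly from these primitives.
#'
#' @param classifier a [TrainedClassifier-class].
#' @param dir output directory.
#' @return `dir` (write) / a [TrainedClassifier-class] (read).
#' @export
writeClassifier <- function(classifier, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  emb <- classifier@embedding
  fit <- classifier@svmFit
  prim <- if (inherits(fit, "svm")) {
    dv1 <- colnames(attr(predict(fit, fit$SV[1, , drop = FALSE],
                                 decision.values = TRUE), "decision.values"))
    list(SV = fit$SV, coefs = as.numeric(fit$coefs), rho = as.numeric(fit$rho),
         gamma = fit$gamma, firstLabel = strsplit(dv1, "/")[[1L]][1L])
  } else fit
  utils::write.table(data.frame(center = emb@center),
                     file.path(dir, "embedding_center.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(emb@rotation),
                     file.path(dir, "embedding_rotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(prim$SV), file.path(dir, "svm_sv.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(coef = prim$coefs),
                     file.path(dir, "svm_coefs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(
    kernel = classifier@kernel, cost = classifier@cost,
    gamma = prim$gamma, rho = prim$rho, firstLabel = prim$firstLabel,
    classWeights = as.list(classifier@classWeights),
    decisionThreshold = classifier@decisionThreshold,
    positiveLabel = classifier@positiveLabel,
    levels = as.list(classifier@levels),
    explainedVariance = as.numeric(emb@explainedVariance),
    nPcs = emb@nPcs), file.path(dir, "model.yaml"))
  invisible(dir)
}

#' @rdname writeClassifier
#' @export
readClassifier <- function(dir) {
  spec <- yaml::read_yaml(file.path(dir, "model.yaml"))
  center <- read.delim(file.path(dir, "embedding_center.tsv"))$center
  rotation <- as.matrix(read.delim(file.path(dir, "embedding_rotation.tsv")))
  emb <- new("EmbeddingModel", center = center, rotation = rotation,
             explainedVariance = as.numeric(spec$explainedVariance),
             nPcs = as.integer(spec$nPcs), clamped = FALSE)
  prim <- list(
    SV = as.matrix(read.delim(file.path(dir, "svm_sv.tsv"))),
    coefs = read.delim(file.path(dir, "svm_coefs.tsv"))$coef,
    rho = spec$rho, gamma = spec$gamma, kernel = spec$kernel,
    firstLabel = spec$firstLabel)
  thr <- spec$decisionThreshold
  new("TrainedClassifier", embedding = emb, svmFit = prim,
      kernel = spec$kernel, cost = spec$cost, gamma = spec$gamma,
      classWeights = unlist(spec$classWeights),
      decisionThreshold = if (is.null(thr)) NA_real_ else thr,
      positiveLabel = spec$positiveLabel,
      levels = unlist(spec$levels), scoreSign = 1)
}

countCommentLines <- function(path) {
  n <- 0L
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    l <- readLines(con, n = 1L)
    if (!length(l) || !startsWith(l, "#")) break
    n <- n + 1L
  }
  n
}

writeStamped <- function(df, path, stamp = NULL) {
  con <- file(path, "w")
  if (!is.null(stamp)) writeLines(paste0("# ", stamp), con)
  close(con)
  suppressWarnings(
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                append = TRUE))
  invisible(path)
}
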