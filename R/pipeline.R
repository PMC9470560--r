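#' Assemble (or load) a pipeline configuration
#'
#' Collects the file paths and stage parameters of a full run. Defaults
#' encode the screening pipeline's fixed operating constants: QS cutoff 2,
#' FF cutoff 4%, 50 PCs, 8 neighbours, walk length 2, 95% target
#' specificity.
#'
#' @param binMatrix,binAnnotation,metadata input file paths (see
#'   [readBinMatrix()], [readBinAnnotation()]).
#' @param outputDir directory the result bundle is written to.
#' @param gcCorrect,smoothWindow normalization parameters.
#' @param nPcs,knnK,walkSteps embedding/clustering parameters.
#' @param tsnePerplexity,tsneSeed layout parameters.
#' @param qsThreshold,ffThreshold,aneuploidyCutoff calling parameters.
#' @param targetSpecificity classifier operating point.
#' @param reducedGrid logical; use the reduced SVM grid.
#' @param classify logical; run the supervised stage (needs a two-class
#'   `disease_label` column and defaults to on when one is present).
#' @param seed global seed; every stochastic stage derives from it.
#' @return a `cfscopeConfig` list.
#' @export
pipelineConfig <- function(binMatrix, binAnnotation, metadata,
                           outputDir = "cfscope_out",
                           gcCorrect = TRUE, smoothWindow = 5L,
                           nPcs = 50L, knnK = 8L, walkSteps = 2L,
                           tsnePerplexity = 30, tsneSeed = 42L,
                           qsThreshold = 2, ffThreshold = 0.04,
                           aneuploidyCutoff = 3,
                           targetSpecificity = 0.95,
                           reducedGrid = TRUE, classify = NA,
                           seed = 1L) {
  stopInvalid(qsThreshold <= 0 || ffThreshold <= 0,
              "thresholds must be positive")
  cfg <- list(binMatrix = binMatrix, binAnnotation = binAnnotation,
              metadata = metadata, outputDir = outputDir,
              gcCorrect = gcCorrect, smoothWindow = smoothWindow,
              nPcs = nPcs, knnK = knnK, walkSteps = walkSteps,
              tsnePerplexity = tsnePerplexity, tsneSeed = tsneSeed,
              qsThreshold = qsThreshold, ffThreshold = ffThreshold,
              aneuploidyCutoff = aneuploidyCutoff,
              targetSpecificity = targetSpecificity,
              reducedGrid = reducedGrid, classify = classify, seed = seed)
  class(cfg) <- "cfscopeConfig"
  cfg
}

#' @rdname pipelineConfig
#' @param path YAML file holding `pipelineConfig` fields.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  for (p in c("binMatrix", "binAnnotation", "metadata"))
    stopInvalid(is.null(y[[p]]) || !file.exists(y[[p]]),
                paste("config field", p, "must name an existing file"))
  do.call(pipelineConfig, y)
}

# Short provenance hash of a config (md5 of its canonical YAML).
configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  substr(unname(tools::md5sum(tmp)), 1L, 12L)
}

#' Run the full screening/exploration pipeline
#'
#' Orchestrates the stages in analysis order: read inputs, normalize,
#' reference + z-scores + QS + NIPS calls, PCA embedding, Walktrap
#' clustering, tSNE layout, optional supervised classification (LOOCV,
#' operating point at the target specificity) and cohort statistics
#' (cluster enrichment). Every output TSV carries a `#` provenance stamp
#' with the package version, seed and config hash; stage timings are
#' logged. Reference samples are the metadata rows with `is_reference =
#' TRUE` when that column exists, else all samples with `disease_label ==
#' "control"`.
#'
#' @param config a `cfscopeConfig` from [pipelineConfig()].
#' @return invisible list of written file paths plus the in-memory stage
#'   results.
#' @export
runPipeline <- function(config) {
  t0 <- Sys.time()
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  stamp <- paste0("cfScope ", as.character(utils::packageVersion("cfScope")),
                  " seed=", config$seed, " config=", configHash(config))
  stage <- function(name, expr) {
    tic <- Sys.time()
    r <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[%s] %.2fs", name,
                    as.numeric(difftime(Sys.time(), tic, units = "secs"))))
    r
  }

  inputs <- stage("read", {
    mat <- readBinMatrix(config$binMatrix)
    bins <- readBinAnnotation(config$binAnnotation)
    md <- read.delim(config$metadata, comment.char = "#",
                     stringsAsFactors = FALSE)
    md <- md[match(rownames(mat), md$sample_id), ]
    list(mat = mat, bins = bins, md = md)
  })
  mat <- inputs$mat; bins <- inputs$bins; md <- inputs$md

  norm <- stage("normalize",
    normalizeCounts(t(mat), bins, gcCorrect = config$gcCorrect,
                    smoothWindow = config$smoothWindow))

  calls <- stage("gipseq", {
    isRef <- if (!is.null(md$is_reference)) as.logical(md$is_reference)
             else md$disease_label == "control"
    stopInvalid(sum(isRef) < 10L, "need >= 10 reference samples")
    ref <- buildReference(norm[, isRef, drop = FALSE], bins)
    z <- zScores(norm, bins, ref)
    qs <- qualityScore(z)
    ff <- if (is.null(md$ff)) rep(NA_real_, nrow(md)) else md$ff
    rows <- lapply(seq_len(nrow(md)), function(i) {
      cl <- callNips(z[, i], qs[i], ff[i], config$ffThreshold,
                     config$qsThreshold, config$aneuploidyCutoff)
      data.frame(sample_id = md$sample_id[i], qs = cl$qs, ff = cl$ff,
                 call = cl$call, reason = cl$reason,
                 t(as.matrix(cl$aneuploidyFlags)))
    })
    out <- do.call(rbind, rows)
    writeStamped(out, file.path(config$outputDir, "gipseq_calls.tsv"), stamp)
    out
  })

  features <- t(norm[autosomeMask(bins), , drop = FALSE])
  embedded <- stage("embed", fitEmbedding(features, config$nPcs))

  clusters <- stage("cluster", {
    cl <- clusterScores(embedded$scores, k = config$knnK,
                        walkSteps = config$walkSteps)
    out <- data.frame(sample_id = rownames(features),
                      cluster = clusterLabels(cl))
    writeStamped(out, file.path(config$outputDir, "clusters.tsv"), stamp)
    cl
  })

  layout <- stage("tsne", {
    perp <- min(config$tsnePerplexity, (nrow(features) - 1) / 3 - 1e-9)
    ly <- tsneLayout(embedded$scores, perplexity = perp,
                     seed = config$tsneSeed)
    out <- data.frame(sample_id = rownames(features), tsneCoords(ly))
    names(out)[2:3] <- c("tsne1", "tsne2")
    writeStamped(out, file.path(config$outputDir, "tsne.tsv"), stamp)
    ly
  })

  classify <- config$classify
  hasLabels <- !is.null(md$disease_label) &&
    length(unique(md$disease_label)) == 2L
  if (is.na(classify)) classify <- hasLabels
  clfOut <- NULL
  if (isTRUE(classify)) {
    clfOut <- stage("classify", {
      stopInvalid(!hasLabels,
                  "classification needs a two-class disease_label column")
      grid <- svmGrid(reduced = config$reducedGrid, nFeatures = config$nPcs)
      oof <- loocvScores(features, md$disease_label, nPcs = config$nPcs,
                         grid = grid, seed = config$seed)
      op <- thresholdAtSpecificity(oof, md$disease_label,
                                   targetSpecificity = config$targetSpecificity)
      ev <- evalAtThreshold(oof, md$disease_label, op$threshold)
      pred <- data.frame(sample_id = md$sample_id, score = oof,
                         predicted = ifelse(oof >= op$threshold,
                                            "positive", "negative"),
                         label = md$disease_label)
      writeStamped(pred, file.path(config$outputDir, "predictions.tsv"),
                   stamp)
      yaml::write_yaml(list(stamp = stamp, auc = aucOf(ev),
                            sensitivity = ev@sensitivity,
                            specificity = ev@specificity,
                            lrPlus = ev@lrPlus, lrMinus = ev@lrMinus,
                            threshold = op$threshold),
                       file.path(config$outputDir, "classifier_eval.yaml"))
      list(scores = oof, op = op, eval = ev)
    })
  }

  statsOut <- stage("stats", {
    if (hasLabels && nCommunities(clusters) >= 2L) {
      phen <- md$disease_label != "control"
      enr <- clusterEnrichment(clusterLabels(clusters), phen)
      writeStamped(enr, file.path(config$outputDir, "stats_report.tsv"),
                   stamp)
      enr
    } else NULL
  })

  message(sprintf("[total] %.2fs",
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(list(calls = calls, embedding = embedded$model,
                 clusters = clusters, layout = layout,
                 classifier = clfOut, stats = statsOut,
                 outputDir = config$outputDir, stamp = stamp))
}
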