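#' @import methods
NULL

#' Simulation configuration for synthetic cfDNA cohorts
#'
#' Holds the generative parameters of the synthetic shallow-WGS cohort:
#' sequencing depth, negative-binomial overdispersion, GC bias amplitude,
#' the fetal-fraction distribution of pregnant samples, an optional trisomy
#' target chromosome, and the technical variance components (batch effects
#' and replicate noise). Construct with [simConfig()].
#'
#' @slot meanDepth expected total autosomal read count per sample.
#' @slot dispersion negative-binomial size parameter; per-bin variance is
#'   `mu + mu^2/dispersion`, so smaller values mean more overdispersion.
#' @slot gcBiasAmplitude amplitude `a` of the multiplicative GC bias
#'   `exp(a * (gc - 0.5))` on expected bin coverage.
#' @slot ffMean,ffSd mean and SD of the Beta-distributed fetal fraction drawn
#'   for pregnant samples; draws are clipped to \[0, 0.5\].
#' @slot trisomyChrom chromosome name carrying a fetal trisomy in trisomic
#'   samples, or `NA_character_`.
#' @slot nBatches number of technical batches samples are cycled through.
#' @slot batchEffectSd SD (log scale) of the per-batch, per-bin multiplicative
#'   effect shared by all samples of a batch.
#' @slot replicateNoiseSd SD (log scale) of the per-replicate multiplicative
#'   noise distinguishing repeats of the same individual.
#' @slot seed integer seed from which all cohort-level randomness flows.
#'
#' @export
setClass("SimConfig", representation(
  meanDepth = "numeric",
  dispersion = "numeric",
  gcBiasAmplitude = "numeric",
  ffMean = "numeric",
  ffSd = "numeric",
  trisomyChrom = "character",
  nBatches = "integer",
  batchEffectSd = "numeric",
  replicateNoiseSd = "numeric",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@meanDepth <= 0) msg <- c(msg, "meanDepth must be > 0")
  if (object@dispersion <= 0) msg <- c(msg, "dispersion must be > 0")
  if (object@ffMean < 0 || object@ffMean > 0.5)
    msg <- c(msg, "ffMean must be in [0, 0.5]")
  if (object@nBatches < 1L) msg <- c(msg, "nBatches must be >= 1")
  if (object@batchEffectSd < 0 || object@replicateNoiseSd < 0)
    msg <- c(msg, "noise SDs must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Multiplicative disease signature on a set of bins
#'
#' A disease class is modelled as a shared multiplicative perturbation of
#' expected cfDNA coverage on a set of bins, with log-normal jitter of the
#' effect across individuals of the class. An empty bin set is the null
#' signature. Construct with [diseaseSignature()] or [randomSignature()].
#'
#' @slot name label of the disease class (e.g. `"AID-like"`).
#' @slot bins integer bin indices (1-based) affected by the signature.
#' @slot effect multiplicative factor (> 0) applied to affected bins.
#' @slot withinClassSd log-scale SD of the per-individual effect jitter.
#'
#' @export
setClass("DiseaseSignature", representation(
  name = "character",
  bins = "integer",
  effect = "numeric",
  withinClassSd = "numeric"
))

setValidity("DiseaseSignature", function(object) {
  msg <- character()
  if (any(object@effect <= 0)) msg <- c(msg, "effect must be > 0")
  if (length(object@bins) && any(object@bins < 1L))
    msg <- c(msg, "bin indices must be >= 1")
  if (object@withinClassSd < 0) msg <- c(msg, "withinClassSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Per-chromosome reference statistics from euploid controls
#'
#' Mean and sample standard deviation of the chromosomal representation
#' (each autosome's share of the normalized autosomal signal) across a set of
#' designated control samples. Built with [buildReference()]; consumed by
#' [zScores()].
#'
#' @slot chromMean,chromSd named numeric vectors, one value per autosome.
#' @slot nReference number of control samples the statistics were built from.
#'
#' @export
setClass("ReferenceSet", representation(
  chromMean = "numeric",
  chromSd = "numeric",
  nReference = "integer"
))

setValidity("ReferenceSet", function(object) {
  msg <- character()
  if (length(object@chromMean) != length(object@chromSd))
    msg <- c(msg, "chromMean and chromSd lengths differ")
  if (any(object@chromSd <= 0)) msg <- c(msg, "all chromSd must be > 0")
  if (object@nReference < 10L) msg <- c(msg, "nReference must be >= 10")
  if (length(msg)) msg else TRUE
})

#' Fitted principal-component embedding
#'
#' A centered (unscaled) PCA basis fitted on a training feature matrix
#' (samples x bins). New samples are projected onto this fixed basis with
#' [projectScores()]; the basis is never refitted at projection time.
#'
#' @slot center per-feature mean used for centering.
#' @slot rotation features x nPcs orthonormal loading matrix.
#' @slot explainedVariance variance carried by each retained component.
#' @slot nPcs number of retained components (clamped to the matrix rank).
#' @slot clamped `TRUE` when the requested component count exceeded the rank.
#'
#' @export
setClass("EmbeddingModel", representation(
  center = "numeric",
  rotation = "matrix",
  explainedVariance = "numeric",
  nPcs = "integer",
  clamped = "logical"
))

setValidity("EmbeddingModel", function(object) {
  msg <- character()
  if (ncol(object@rotation) != object@nPcs)
    msg <- c(msg, "rotation must have nPcs columns")
  if (nrow(object@rotation) != length(object@center))
    msg <- c(msg, "rotation rows must match center length")
  g <- crossprod(object@rotation)
  if (max(abs(g - diag(ncol(g)))) > 1e-6)
    msg <- c(msg, "components must be orthonormal")
  if (length(msg)) msg else TRUE
})

#' Walktrap community assignment
#'
#' Cluster labels from Walktrap community detection on a k-nearest-neighbour
#' graph of PCA scores, cut at the modularity-maximizing merge level.
#'
#' @slot labels integer community id per sample (1-based).
#' @slot nCommunities number of communities.
#' @slot modularity modularity of the chosen partition.
#' @slot graphK neighbour count used to build the graph.
#' @slot walkSteps random-walk length of the Walktrap run.
#'
#' @export
setClass("ClusterResult", representation(
  labels = "integer",
  nCommunities = "integer",
  modularity = "numeric",
  graphK = "integer",
  walkSteps = "integer"
))

setValidity("ClusterResult", function(object) {
  msg <- character()
  if (length(object@labels) &&
      (min(object@labels) < 1L || max(object@labels) > object@nCommunities))
    msg <- c(msg, "labels must lie in [1, nCommunities]")
  if (object@modularity < -0.5 - 1e-9 || object@modularity > 1 + 1e-9)
    msg <- c(msg, "modularity must be in [-0.5, 1]")
  if (length(msg)) msg else TRUE
})

#' Two-dimensional tSNE layout
#'
#' @slot coords samples x 2 coordinate matrix.
#' @slot perplexity perplexity used.
#' @slot seed RNG seed the layout is deterministic under.
#'
#' @export
setClass("TsneLayout", representation(
  coords = "matrix",
  perplexity = "numeric",
  seed = "integer"
))

setValidity("TsneLayout", function(object) {
  msg <- character()
  if (ncol(object@coords) != 2L) msg <- c(msg, "coords must have 2 columns")
  if (any(!is.finite(object@coords))) msg <- c(msg, "coords must be finite")
  if (length(msg)) msg else TRUE
})

#' PCA-space class-weighted SVM classifier
#'
#' Couples the PCA embedding fitted on the training features with a support
#' vector machine fitted on the training scores, the grid-searched
#' hyperparameters, and a decision threshold. Prediction projects new
#' samples onto the frozen training PCA space and applies the SVM.
#'
#' @slot embedding the [EmbeddingModel-class] fitted on the training set.
#' @slot svmFit the fitted `e1071::svm` object.
#' @slot kernel,cost,gamma selected hyperparameters.
#' @slot classWeights per-class misclassification weights (inverse frequency).
#' @slot decisionThreshold score cutoff; samples scoring `>=` it are called
#'   positive. `NA` until set (e.g. by [thresholdAtSpecificity()]).
#' @slot positiveLabel label of the positive (disease) class.
#' @slot levels class labels in the order used internally.
#' @slot scoreSign +1/-1 factor normalising decision values so that larger
#'   means more positive-like.
#'
#' @export
setClass("TrainedClassifier", representation(
  embedding = "EmbeddingModel",
  svmFit = "ANY",
  kernel = "character",
  cost = "numeric",
  gamma = "numeric",
  classWeights = "numeric",
  decisionThreshold = "numeric",
  positiveLabel = "character",
  levels = "character",
  scoreSign = "numeric"
))

#' Classifier evaluation summary
#'
#' Operating-point characteristics and ranking performance of a score
#' vector against binary labels: sensitivity, specificity, predictive
#' values, likelihood ratios, trapezoidal AUC and the ROC curve points.
#'
#' @slot sensitivity,specificity,ppv,npv fractions at the operating point.
#' @slot auc area under the ROC curve.
#' @slot lrPlus,lrMinus positive and negative likelihood ratios.
#' @slot threshold the operating-point score cutoff.
#' @slot rocPoints data.frame with columns `fpr`, `tpr`.
#'
#' @export
setClass("ClassifierEval", representation(
  sensitivity = "numeric",
  specificity = "numeric",
  ppv = "numeric",
  npv = "numeric",
  auc = "numeric",
  lrPlus = "numeric",
  lrMinus = "numeric",
  threshold = "numeric",
  rocPoints = "data.frame"
))

setValidity("ClassifierEval", function(object) {
  if (is.finite(object@auc) && (object@auc < 0 || object@auc > 1))
    "auc must be in [0, 1]" else TRUE
})

## show methods ---------------------------------------------------------------

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: meanDepth", format(object@meanDepth, big.mark = ","),
      "| NB dispersion", object@dispersion,
      "| GC amplitude", object@gcBiasAmplitude, "\n")
  cat("  FF ~ Beta(mean", object@ffMean, ", sd", object@ffSd, ")",
      if (!is.na(object@trisomyChrom))
        paste0("| trisomy chr", object@trisomyChrom) else "", "\n")
  cat("  batches:", object@nBatches, "(sd", object@batchEffectSd, ")",
      "| replicate sd", object@replicateNoiseSd,
      "| seed", object@seed, "\n")
})

setMethod("show", "DiseaseSignature", function(object) {
  cat("DiseaseSignature '", object@name, "': ", length(object@bins),
      " bins, effect ", paste(unique(object@effect), collapse = "/"),
      " (within-class sd ", object@withinClassSd, ")\n", sep = "")
})

setMethod("show", "ReferenceSet", function(object) {
  cat("ReferenceSet over", length(object@chromMean), "autosomes from",
      object@nReference, "controls\n")
  cat("  representation SD range:",
      format(range(object@chromSd), digits = 3), "\n")
})

setMethod("show", "EmbeddingModel", function(object) {
  cat("EmbeddingModel:", object@nPcs, "PCs over",
      length(object@center), "features",
      if (object@clamped) "(clamped to rank)" else "", "\n")
})

setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult:", object@nCommunities, "communities over",
      length(object@labels), "samples; modularity",
      format(object@modularity, digits = 4),
      paste0("(k = ", object@graphK, ", steps = ", object@walkSteps, ")"),
      "\n")
})

setMethod("show", "TrainedClassifier", function(object) {
  cat("TrainedClassifier:", object@kernel, "SVM (C =", object@cost,
      if (object@kernel == "radial") paste(", gamma =", object@gamma) else "",
      ") on", object@embedding@nPcs, "PCs\n")
  cat("  positive class:", object@positiveLabel, "| threshold:",
      object@decisionThreshold, "\n")
})

setMethod("show", "ClassifierEval", function(object) {
  cat("ClassifierEval: AUC", format(object@auc, digits = 3),
      "| sens", format(object@sensitivity, digits = 3),
      "| spec", format(object@specificity, digits = 3),
      "| LR+", format(object@lrPlus, digits = 3),
      "| LR-", format(object@lrMinus, digits = 3), "\n")
})
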