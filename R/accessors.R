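#' Accessors for cfScope result objects
#'
#' Small read-only accessors so downstream code never touches slots directly.
#'
#' @param x a cfScope S4 object of the class each accessor documents.
#' @return the documented component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
clusterLabels <- function(x) {
  stopifnot(is(x, "ClusterResult"))
  x@labels
}

#' @rdname accessors
#' @export
nCommunities <- function(x) {
  stopifnot(is(x, "ClusterResult"))
  x@nCommunities
}

#' @rdname accessors
#' @export
clusterModularity <- function(x) {
  stopifnot(is(x, "ClusterResult"))
  x@modularity
}

#' @rdname accessors
#' @export
tsneCoords <- function(x) {
  stopifnot(is(x, "TsneLayout"))
  x@coords
}

#' @rdname accessors
#' @export
embeddingCenter <- function(x) {
  stopifnot(is(x, "EmbeddingModel"))
  x@center
}

#' @rdname accessors
#' @export
embeddingRotation <- function(x) {
  stopifnot(is(x, "EmbeddingModel"))
  x@rotation
}

#' @rdname accessors
#' @export
explainedVariance <- function(x) {
  stopifnot(is(x, "EmbeddingModel"))
  x@explainedVariance
}

#' @rdname accessors
#' @export
referenceMeans <- function(x) {
  stopifnot(is(x, "ReferenceSet"))
  x@chromMean
}

#' @rdname accessors
#' @export
referenceSds <- function(x) {
  stopifnot(is(x, "ReferenceSet"))
  x@chromSd
}

#' @rdname accessors
#' @export
decisionThreshold <- function(x) {
  stopifnot(is(x, "TrainedClassifier"))
  x@decisionThreshold
}

#' @rdname accessors
#' @export
aucOf <- function(x) {
  stopifnot(is(x, "ClassifierEval"))
  x@auc
}

#' @rdname accessors
#' @export
rocPoints <- function(x) {
  stopifnot(is(x, "ClassifierEval"))
  x@rocPoints
}
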