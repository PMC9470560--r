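#' Sample-by-feature matrix for embedding and classification
#'
#' Normalized, smoothed autosomal bin values per sample, transposed to the
#' samples x bins orientation the embedding and classifier operate on.
#'
#' @param cohort cohort `RangedSummarizedExperiment`.
#' @inheritParams normalizeProfile
#' @return samples x autosomal-bins numeric matrix.
#' @export
featureMatrix <- function(cohort, gcCorrect = TRUE, smoothWindow = 5L) {
  bins <- SummarizedExperiment::rowRanges(cohort)
  norm <- normalizeCounts(cohort, gcCorrect = gcCorrect,
                          smoothWindow = smoothWindow)
  t(norm[autosomeMask(bins), , drop = FALSE])
}

#' Fit a centered PCA embedding
#'
#' Centered, unscaled principal component analysis of a samples x features
#' matrix, keeping the top `nPcs` components (default 50). When `nPcs`
#' exceeds `min(n - 1, p)` it is clamped and the clamp recorded on the
#' model.
#'
#' @param x samples x features numeric matrix.
#' @param nPcs number of components to retain.
#' @return list with `model` (an [EmbeddingModel-class]) and `scores`
#'   (samples x nPcs).
#' @examples
#' fit <- fitEmbedding(matrix(rnorm(40), 8), nPcs = 3)
#' fit$model
#' @export
fitEmbedding <- function(x, nPcs = 50L) {
  stopInvalid(nrow(x) < 2L, "need >= 2 samples")
  stopInvalid(all(apply(x, 2L, function(col) diff(range(col))) == 0),
              "degenerate input: constant feature matrix")
  maxPcs <- min(nrow(x) - 1L, ncol(x))
  clamped <- nPcs > maxPcs
  if (clamped) {
    message("nPcs clamped from ", nPcs, " to the rank bound ", maxPcs)
    nPcs <- maxPcs
  }
  pr <- prcomp(x, center = TRUE, scale. = FALSE, rank. = nPcs)
  model <- new("EmbeddingModel", center = pr$center,
               rotation = pr$rotation[, seq_len(nPcs), drop = FALSE],
               explainedVariance = pr$sdev[seq_len(nPcs)]^2,
               nPcs = as.integer(nPcs), clamped = clamped)
  list(model = model, scores = pr$x[, seq_len(nPcs), drop = FALSE])
}

#' Project samples onto a fitted PCA space
#'
#' `(x - center) %*% rotation`, with no refitting — held-out or validation
#' samples are always mapped through the training basis.
#'
#' @param model an [EmbeddingModel-class].
#' @param x samples x features matrix (or a single feature vector).
#' @return samples x nPcs score matrix.
#' @export
projectScores <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  stopInvalid(ncol(x) != length(model@center),
              "feature dimension does not match the embedding")
  sweep(x, 2L, model@center, "-") %*% model@rotation
}

#' k-nearest-neighbour graph of embedding scores
#'
#' Undirected, unweighted graph with an edge between i and j whenever j is
#' among i's k nearest Euclidean neighbours or vice versa (union
#' symmetrization). Distance ties are broken toward the lower sample index.
#'
#' @param scores samples x dims score matrix.
#' @param k neighbour count (default 8).
#' @return an `igraph` graph with `length(nrow(scores))` vertices.
#' @export
knnGraph <- function(scores, k = 8L) {
  n <- nrow(scores)
  stopInvalid(n <= k, "need more samples than k")
  d <- as.matrix(dist(scores))
  edges <- matrix(0L, nrow = n * k, ncol = 2L)
  for (i in seq_len(n)) {
    o <- order(d[i, -i], seq_len(n - 1L))[seq_len(k)]
    nb <- setdiff(seq_len(n), i)[o]
    edges[((i - 1L) * k + 1L):(i * k), ] <- cbind(i, nb)
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  if (igraph::vcount(g) < n)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  g
}

#' Walktrap communities at the modularity-optimal cut
#'
#' Runs Walktrap (short random walks, default length 2) on the kNN graph
#' and takes the merge-tree cut maximizing modularity. An edgeless graph
#' degenerates to one community per node with modularity 0; disconnected
#' components always end up in different communities.
#'
#' @param graph an `igraph` graph (e.g. from [knnGraph()]).
#' @param walkSteps random-walk length.
#' @param graphK neighbour count recorded on the result (informational).
#' @return a [ClusterResult-class].
#' @export
walktrapClusters <- function(graph, walkSteps = 2L, graphK = NA_integer_) {
  n <- igraph::vcount(graph)
  stopInvalid(n == 0L, "graph must be non-empty")
  n <- as.integer(n)
  if (igraph::ecount(graph) == 0L) {
    return(new("ClusterResult", labels = seq_len(n), nCommunities = n,
               modularity = 0, graphK = as.integer(graphK),
               walkSteps = as.integer(walkSteps)))
  }
  wt <- igraph::cluster_walktrap(graph, steps = walkSteps)
  labels <- as.integer(igraph::membership(wt))
  new("ClusterResult", labels = labels,
      nCommunities = length(unique(labels)),
      modularity = igraph::modularity(graph, labels),
      graphK = as.integer(graphK), walkSteps = as.integer(walkSteps))
}

#' Cluster embedding scores end to end
#'
#' [knnGraph()] followed by [walktrapClusters()] — the default unsupervised
#' route for a cohort's PCA scores.
#'
#' @inheritParams knnGraph
#' @inheritParams walktrapClusters
#' @return a [ClusterResult-class].
#' @export
clusterScores <- function(scores, k = 8L, walkSteps = 2L) {
  walktrapClusters(knnGraph(scores, k), walkSteps, graphK = k)
}

#' Two-dimensional tSNE layout of embedding scores
#'
#' @param scores samples x dims score matrix.
#' @param perplexity tSNE perplexity; must satisfy
#'   `perplexity < (n - 1) / 3`.
#' @param seed RNG seed; the layout is identical across runs for a fixed
#'   seed and input.
#' @param maxIter gradient-descent iterations.
#' @return a [TsneLayout-class].
#' @export
tsneLayout <- function(scores, perplexity = 30, seed = 42L, maxIter = 1000L) {
  n <- nrow(scores)
  stopInvalid(perplexity >= (n - 1) / 3,
              "perplexity too large: need perplexity < (n - 1) / 3")
  coords <- withSeed(seed, Rtsne::Rtsne(scores, dims = 2L,
                                        perplexity = perplexity,
                                        pca = FALSE, theta = 0.5,
                                        max_iter = maxIter,
                                        check_duplicates = FALSE)$Y)
  rownames(coords) <- rownames(scores)
  new("TsneLayout", coords = coords, perplexity = perplexity,
      seed = as.integer(seed))
}

#' Ward hierarchical tree of embedding scores
#'
#' Agglomerative clustering of Euclidean distances under Ward's criterion
#' (`hclust` method `"ward.D2"`, which operates on the distances themselves).
#'
#' @param scores samples x dims score matrix.
#' @return an `hclust` dendrogram.
#' @export
wardTree <- function(scores) {
  stopInvalid(nrow(scores) < 2L, "need >= 2 samples")
  hclust(dist(scores), method = "ward.D2")
}

#' Replicate concordance in cluster and layout space
#'
#' A replicate group is concordant when all its members fall in one Walktrap
#' cluster, or when every pair of members is geometrically close on the tSNE
#' layout — differing by less than `closenessFraction` of each embedding
#' dimension's coordinate range (default 5%).
#'
#' @param labels cluster id per sample.
#' @param layout a [TsneLayout-class] for the same samples.
#' @param groups replicate-group id per sample.
#' @param closenessFraction closeness limit as a fraction of each
#'   dimension's range, in (0, 1).
#' @return list with `fraction` (concordant groups / groups with >= 2
#'   members) and `perGroup` (named logical).
#' @export
replicateConcordance <- function(labels, layout, groups,
                                 closenessFraction = 0.05) {
  stopInvalid(closenessFraction <= 0 || closenessFraction >= 1,
              "closenessFraction must be in (0, 1)")
  coords <- tsneCoords(layout)
  stopInvalid(length(labels) != nrow(coords) ||
                length(groups) != nrow(coords),
              "labels, layout and groups must cover the same samples")
  lim <- apply(coords, 2L, function(c) diff(range(c))) * closenessFraction
  multi <- names(which(table(groups) >= 2L))
  stopInvalid(length(multi) == 0L,
              "undefined metric: no replicate group with >= 2 members")
  perGroup <- vapply(multi, function(g) {
    idx <- which(groups == g)
    if (length(unique(labels[idx])) == 1L) return(TRUE)
    for (a in seq_along(idx)[-length(idx)]) for (b in (a + 1L):length(idx)) {
      if (any(abs(coords[idx[a], ] - coords[idx[b], ]) >= lim)) return(FALSE)
    }
    TRUE
  }, logical(1L))
  list(fraction = mean(perGroup), perGroup = perGroup)
}
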