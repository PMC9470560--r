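test_that("PCA embedding is centered, orthonormal and rank-aware", {
  x <- withr::with_seed(1, matrix(rnorm(60 * 100), 60))
  fit <- fitEmbedding(x, nPcs = 10L)
  expect_equal(fit$model@nPcs, 10L)
  g <- crossprod(embeddingRotation(fit$model))
  expect_equal(g, diag(10L), tolerance = 1e-8, ignore_attr = TRUE)

  # three collinear points in 2D carry all variance on one component
  pts <- cbind(c(0, 1, 2), c(0, 2, 4))
  colin <- suppressMessages(fitEmbedding(pts, nPcs = 2L))
  ev <- explainedVariance(colin$model)
  expect_gt(ev[1], 0)
  expect_lt(ev[2] / ev[1], 1e-12)

  expect_error(fitEmbedding(matrix(1, 5, 4), nPcs = 2L), "degenerate")
  clamped <- suppressMessages(fitEmbedding(x[1:5, ], nPcs = 50L))
  expect_equal(clamped$model@nPcs, 4L)
  expect_true(clamped$model@clamped)
})

test_that("full-rank reconstruction recovers the centered data", {
  x <- withr::with_seed(2, matrix(rnorm(20 * 8), 20))
  fit <- suppressMessages(fitEmbedding(x, nPcs = 8L))
  rec <- fit$scores %*% t(embeddingRotation(fit$model))
  centered <- sweep(x, 2L, embeddingCenter(fit$model), "-")
  expect_equal(rec, centered, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("explained variances match an independent eigendecomposition", {
  x <- withr::with_seed(3, matrix(rnorm(80 * 40), 80) %*%
                          diag(sqrt(seq(4, 0.1, length.out = 40))))
  fit <- fitEmbedding(x, nPcs = 20L)
  eig <- eigen(cov(x), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(explainedVariance(fit$model)), sum(eig[1:20]),
               tolerance = 1e-6)
})

test_that("projection reproduces training scores and maps the center to 0", {
  x <- withr::with_seed(4, matrix(rnorm(30 * 50), 30))
  fit <- fitEmbedding(x, nPcs = 5L)
  expect_equal(projectScores(fit$model, x), fit$scores, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(as.numeric(projectScores(fit$model,
                                        embeddingCenter(fit$model))),
               rep(0, 5L), tolerance = 1e-12)
  expect_error(projectScores(fit$model, x[, 1:10]), "dimension")
})

test_that("held-out disease profiles project near the disease centroid", {
  cohort <- separationCohort()
  feats <- featureMatrix(cohort)
  labs <- cohortLabels(cohort)
  dis <- which(labs != "control")
  hold <- dis[1:10]
  fit <- fitEmbedding(feats[-hold, ], nPcs = 20L)
  trainLab <- labs[-hold]
  cen <- list(
    control = colMeans(fit$scores[trainLab == "control", ]),
    disease = colMeans(fit$scores[trainLab != "control", ]))
  proj <- projectScores(fit$model, feats[hold, ])
  nearer <- apply(proj, 1L, function(p)
    sqrt(sum((p - cen$disease)^2)) < sqrt(sum((p - cen$control)^2)))
  expect_gte(mean(nearer), 0.9)
})

test_that("kNN graph equals brute-force neighbours and respects geometry", {
  scores <- withr::with_seed(5, matrix(rnorm(50 * 3), 50))
  g <- knnGraph(scores, k = 4L)
  d <- as.matrix(dist(scores))
  adj <- matrix(FALSE, 50, 50)
  for (i in 1:50) {
    nb <- setdiff(order(d[i, ]), i)[1:4]
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)  # union symmetrization
  gAdj <- as.matrix(igraph::as_adjacency_matrix(g)) > 0
  expect_equal(unname(gAdj), adj)

  blobs <- rbind(matrix(rnorm(40, 0, 0.1), 20),
                 matrix(rnorm(40, 50, 0.1), 20))
  gb <- knnGraph(blobs, k = 8L)
  cross <- as.matrix(igraph::as_adjacency_matrix(gb))[1:20, 21:40]
  expect_equal(sum(cross), 0)

  expect_error(knnGraph(scores[1:4, ], k = 4L), "more samples than k")
})

test_that("Walktrap recovers planted partitions and degenerate graphs", {
  cl10 <- igraph::make_full_graph(10L)
  two <- igraph::disjoint_union(cl10, cl10)
  res <- walktrapClusters(two, walkSteps = 2L)
  expect_equal(nCommunities(res), 2L)
  expect_equal(clusterLabels(res)[1:10], rep(clusterLabels(res)[1], 10L))
  expect_equal(adjustedRand(clusterLabels(res), rep(1:2, each = 10L)), 1)

  one <- walktrapClusters(cl10)
  expect_equal(nCommunities(one), 1L)

  empty <- igraph::make_empty_graph(6L, directed = FALSE)
  lone <- walktrapClusters(empty)
  expect_equal(nCommunities(lone), 6L)
  expect_equal(clusterModularity(lone), 0)
})

test_that("Walktrap resolves a stochastic block model at high ARI", {
  p <- matrix(0.05, 3, 3); diag(p) <- 0.8
  g <- withr::with_seed(7, igraph::sample_sbm(45L, p, c(15L, 15L, 15L)))
  res <- walktrapClusters(g, walkSteps = 2L)
  expect_gte(adjustedRand(clusterLabels(res), rep(1:3, each = 15L)), 0.9)
})

test_that("clustering is invariant to sample order", {
  scores <- withr::with_seed(8, rbind(matrix(rnorm(60, 0), 20),
                                      matrix(rnorm(60, 6), 20),
                                      matrix(rnorm(60, -6), 20)))
  res <- clusterScores(scores, k = 8L)
  perm <- withr::with_seed(9, sample(nrow(scores)))
  resP <- clusterScores(scores[perm, ], k = 8L)
  expect_equal(adjustedRand(clusterLabels(res)[perm],
                            clusterLabels(resP)), 1)
})

test_that("tSNE layouts are deterministic and separate blobs", {
  scores <- withr::with_seed(10, rbind(matrix(rnorm(200, 0), 50),
                                       matrix(rnorm(200, 10), 50)))
  ly1 <- tsneLayout(scores, perplexity = 15, seed = 42L)
  ly2 <- tsneLayout(scores, perplexity = 15, seed = 42L)
  expect_identical(tsneCoords(ly1), tsneCoords(ly2))

  sil <- cluster::silhouette(rep(1:2, each = 50L),
                             dist(tsneCoords(ly1)))
  expect_gt(mean(sil[, "sil_width"]), 0.5)

  expect_error(tsneLayout(scores[1:10, ], perplexity = 5),
               "perplexity")
})

test_that("Ward tree merges are ordered and start at the closest pair", {
  two <- matrix(c(0, 0, 3, 4), 2, byrow = TRUE)
  h2 <- wardTree(two)
  expect_equal(h2$height, 5)  # single merge at the Euclidean distance

  pts <- withr::with_seed(11, matrix(rnorm(20 * 2), 20))
  h <- wardTree(pts)
  expect_true(all(diff(h$height) >= -1e-12))
  d <- as.matrix(dist(pts)); diag(d) <- Inf
  closest <- sort(which(d == min(d), arr.ind = TRUE)[1L, ])
  expect_equal(sort(-h$merge[1L, ]), as.numeric(closest))
})

test_that("embedding route does not distort within-set distances", {
  a <- withr::with_seed(12, matrix(rnorm(15 * 6), 15))
  b <- withr::with_seed(13, matrix(rnorm(10 * 6), 10))
  fitA <- suppressMessages(fitEmbedding(a, nPcs = 6L))
  fitAB <- suppressMessages(fitEmbedding(rbind(a, b), nPcs = 6L))
  dA1 <- dist(projectScores(fitA$model, a))
  dA2 <- dist(projectScores(fitAB$model, a))
  expect_equal(as.numeric(dA1), as.numeric(dA2), tolerance = 1e-8)
})

test_that("replicate concordance scores groups by cluster or closeness", {
  coords <- rbind(c(0, 0), c(0.1, 0.1), c(100, 100), c(-100, 50))
  layout <- new("TsneLayout", coords = coords, perplexity = 5, seed = 1L)
  groups <- c("g1", "g1", "g2", "g3")

  same <- replicateConcordance(c(1L, 1L, 2L, 3L), layout, groups)
  expect_equal(same$fraction, 1)

  apart <- replicateConcordance(c(1L, 2L, 3L, 4L),
                                new("TsneLayout",
                                    coords = rbind(c(0, 0), c(100, 100),
                                                   c(50, -50), c(-100, 50)),
                                    perplexity = 5, seed = 1L),
                                groups)
  expect_equal(apart$fraction, 0)

  close <- replicateConcordance(c(1L, 2L, 3L, 4L), layout, groups)
  expect_equal(close$fraction, 1)  # different clusters but within 5% range

  expect_error(replicateConcordance(1:4, layout, c("a", "b", "c", "d")),
               "undefined")
})

test_that("replicates are concordant when noise is below the signature", {
  bins <- testBins()
  sig <- randomSignature(bins, "AID-like", 10L, 22L, 1.3,
                         withinClassSd = 0.05, seed = 3L)
  des <- rbind(cohortArm("control", 60L, pregnant = TRUE),
               cohortArm("AID-like", 15L, pregnant = TRUE,
                         signature = sig, nReplicates = 2L))
  sim <- simulateCohort(bins, des, simConfig(seed = 9L))
  emb <- fitEmbedding(featureMatrix(sim), 50L)
  cl <- clusterScores(emb$scores)
  ly <- tsneLayout(emb$scores, perplexity = 20, seed = 42L)
  rc <- replicateConcordance(
    clusterLabels(cl), ly,
    SummarizedExperiment::colData(sim)$replicate_group)
  expect_gte(rc$fraction, 0.9)
})
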