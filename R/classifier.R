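#' Hyperparameter grid for the SVM
#'
#' The full grid spans linear and RBF kernels, costs `10^(-2..2)` and, for
#' RBF, widths `(1/p) * 10^(-2..2)` around the scale heuristic. The reduced
#' grid (linear kernel, three costs) is the preset for permutation studies
#' and large cross-validation sweeps.
#'
#' @param reduced logical; use the small linear-only grid.
#' @param nFeatures feature count the RBF scale heuristic is based on.
#' @return data.frame with columns `kernel`, `cost`, `gamma`, ordered so
#'   that grid-search ties resolve toward smaller cost, then linear kernel.
#' @export
svmGrid <- function(reduced = FALSE, nFeatures = 50L) {
  if (reduced) {
    g <- data.frame(kernel = "linear", cost = c(0.1, 1, 10), gamma = 0)
  } else {
    lin <- data.frame(kernel = "linear", cost = 10^(-2:2), gamma = 0)
    rbf <- expand.grid(kernel = "radial", cost = 10^(-2:2),
                       gamma = (1 / nFeatures) * 10^(-2:2),
                       stringsAsFactors = FALSE)
    g <- rbind(lin, rbf[, c("kernel", "cost", "gamma")])
  }
  g <- g[order(g$cost, g$kernel != "linear", g$gamma), ]
  rownames(g) <- NULL
  g
}

# Inverse-frequency class weights (sklearn's "balanced" convention).
balancedWeights <- function(labels) {
  tab <- table(labels)
  w <- length(labels) / (length(tab) * as.numeric(tab))
  setNames(w, names(tab))
}

# Stratified index split: ~frac of each class for training the grid fold.
stratifiedSplit <- function(labels, frac) {
  idx <- unlist(lapply(split(seq_along(labels), labels), function(ix) {
    nTrain <- max(1L, floor(length(ix) * frac))
    if (nTrain >= length(ix)) nTrain <- length(ix) - 1L
    sample(ix, nTrain)
  }))
  sort(unname(idx))
}

fitSvm <- function(scores, labels, kernel, cost, gamma, weights) {
  e1071::svm(x = scores, y = labels, kernel = kernel, cost = cost,
             gamma = if (kernel == "radial") gamma else 1 / ncol(scores),
             class.weights = weights, scale = FALSE, probability = FALSE)
}

# Decision values oriented so that larger = more positive-class-like.
# Works both for fresh e1071 fits and for classifiers restored from the
# plain-text serialization (kernel primitives: SV, dual coefs, rho).
svmDecision <- function(fit, scores, positiveLabel) {
  if (inherits(fit, "svm")) {
    pr <- predict(fit, scores, decision.values = TRUE)
    dv <- unname(attr(pr, "decision.values")[, 1L])
    firstLabel <- strsplit(colnames(attr(pr, "decision.values")), "/")[[1L]][1L]
    if (firstLabel == positiveLabel) dv else -dv
  } else {
    K <- if (fit$kernel == "linear") {
      scores %*% t(fit$SV)
    } else {
      d2 <- outer(rowSums(scores^2), rowSums(fit$SV^2), "+") -
        2 * scores %*% t(fit$SV)
      exp(-fit$gamma * pmax(d2, 0))
    }
    dv <- as.numeric(K %*% fit$coefs - fit$rho)
    if (fit$firstLabel == positiveLabel) dv else -dv
  }
}

#' Train the PCA + class-weighted SVM classifier
#'
#' Fits the centered PCA on the training features, grid-searches SVM
#' hyperparameters by refitting each candidate on a stratified 90% of the
#' training samples and scoring balanced accuracy on the held-out 10%, then
#' refits the winning combination on all training data with
#' inverse-frequency class weights. Ties resolve toward smaller cost, then
#' the linear kernel.
#'
#' @param features samples x bins matrix (e.g. [featureMatrix()]).
#' @param labels two-class factor/character vector.
#' @param nPcs PCA components (clamped to the rank).
#' @param grid hyperparameter grid from [svmGrid()].
#' @param gridFraction fraction of training data each grid candidate is
#'   fitted on.
#' @param positiveLabel positive (disease) class; default the rarer class.
#' @param seed RNG seed for the stratified grid split.
#' @return a [TrainedClassifier-class] (decision threshold unset).
#' @export
trainClassifier <- function(features, labels, nPcs = 50L, grid = svmGrid(),
                            gridFraction = 0.9, positiveLabel = NULL,
                            seed = 1L) {
  stopInvalid(nrow(features) < 10L, "need >= 10 training samples")
  trainCore(features, labels, nPcs, grid, gridFraction, positiveLabel, seed)
}

# Training body, shared with cross-validation folds (which hold one sample
# out of an already-size-checked set).
trainCore <- function(features, labels, nPcs, grid, gridFraction,
                      positiveLabel, seed) {
  labels <- as.character(labels)
  tab <- table(labels)
  stopInvalid(length(tab) != 2L, "need exactly two classes in the labels")
  if (is.null(positiveLabel)) positiveLabel <- names(which.min(tab))
  lev <- c(setdiff(names(tab), positiveLabel), positiveLabel)
  y <- factor(labels, levels = lev)
  emb <- fitEmbedding(features, nPcs)
  scores <- emb$scores
  weights <- balancedWeights(y)
  best <- withSeed(seed, {
    trainIdx <- stratifiedSplit(y, gridFraction)
    holdIdx <- setdiff(seq_along(y), trainIdx)
    acc <- vapply(seq_len(nrow(grid)), function(i) {
      fit <- fitSvm(scores[trainIdx, , drop = FALSE], y[trainIdx],
                    grid$kernel[i], grid$cost[i], grid$gamma[i], weights)
      pred <- predict(fit, scores[holdIdx, , drop = FALSE])
      balancedAccuracy(pred, y[holdIdx])
    }, numeric(1L))
    grid[which.max(acc), ]  # grid pre-ordered: first max is the tie winner
  })
  fit <- fitSvm(scores, y, best$kernel, best$cost, best$gamma, weights)
  new("TrainedClassifier", embedding = emb$model, svmFit = fit,
      kernel = best$kernel, cost = best$cost, gamma = best$gamma,
      classWeights = weights, decisionThreshold = NA_real_,
      positiveLabel = positiveLabel, levels = lev, scoreSign = 1)
}

balancedAccuracy <- function(pred, truth) {
  mean(vapply(split(pred == truth, truth), mean, numeric(1L)), na.rm = TRUE)
}

#' Decision scores of a trained classifier on new samples
#'
#' Projects features onto the frozen training PCA space and evaluates the
#' SVM decision function, oriented so larger scores mean more disease-like.
#'
#' @param classifier a [TrainedClassifier-class].
#' @param features samples x bins matrix on the training feature grid.
#' @return numeric score per sample.
#' @export
classifierScores <- function(classifier, features) {
  stopInvalid(length(features) == 0L, "empty feature set")
  scores <- projectScores(classifier@embedding, features)
  svmDecision(classifier@svmFit, scores, classifier@positiveLabel)
}

#' Predict labels and scores for new samples
#'
#' @param object a [TrainedClassifier-class].
#' @param newdata samples x bins feature matrix.
#' @param ... ignored.
#' @return list with `scores` and `labels` (positive where score >=
#'   `decisionThreshold`; an unset threshold falls back to the SVM's 0
#'   margin).
#' @export
setMethod("predict", "TrainedClassifier", function(object, newdata, ...) {
  sc <- classifierScores(object, newdata)
  thr <- if (is.na(object@decisionThreshold)) 0 else object@decisionThreshold
  neg <- setdiff(object@levels, object@positiveLabel)
  list(scores = sc,
       labels = ifelse(sc >= thr, object@positiveLabel, neg))
})

#' Leave-one-out cross-validated decision scores
#'
#' For each sample the entire pipeline — PCA, grid search, SVM — is refitted
#' without it and the held-out sample's decision value recorded. Fold seeds
#' derive deterministically from `seed`.
#'
#' @inheritParams trainClassifier
#' @return numeric out-of-fold score per sample (named by rownames).
#' @export
loocvScores <- function(features, labels, nPcs = 50L, grid = svmGrid(),
                        gridFraction = 0.9, positiveLabel = NULL,
                        seed = 1L) {
  labels <- as.character(labels)
  stopInvalid(nrow(features) < 10L, "need >= 10 samples for LOOCV")
  if (is.null(positiveLabel))
    positiveLabel <- names(which.min(table(labels)))
  out <- vapply(seq_len(nrow(features)), function(i) {
    clf <- trainCore(features[-i, , drop = FALSE], labels[-i],
                     nPcs = nPcs, grid = grid,
                     gridFraction = gridFraction,
                     positiveLabel = positiveLabel,
                     seed = seed + i)
    classifierScores(clf, features[i, , drop = FALSE])
  }, numeric(1L))
  names(out) <- rownames(features)
  out
}

#' ROC curve and trapezoidal AUC
#'
#' Area under the ROC curve over all score thresholds, with tied scores
#' handled by averaging — numerically identical to the Mann-Whitney
#' rank statistic `U / (n1 n0)`.
#'
#' @param scores numeric decision scores (larger = more positive-like).
#' @param labels two-class labels.
#' @param positiveLabel the positive class (default the rarer one).
#' @return a [ClassifierEval-class] with `auc` and `rocPoints` filled in
#'   (operating-point fields `NA`; see [evalAtThreshold()]).
#' @export
rocAuc <- function(scores, labels, positiveLabel = NULL) {
  labels <- as.character(labels)
  tab <- table(labels)
  stopInvalid(length(tab) != 2L, "need both classes to compute a ROC curve")
  if (is.null(positiveLabel)) positiveLabel <- names(which.min(tab))
  r <- pROC::roc(response = labels == positiveLabel, predictor = scores,
                 direction = "<", quiet = TRUE)
  pts <- data.frame(fpr = rev(1 - r$specificities),
                    tpr = rev(r$sensitivities))
  new("ClassifierEval", sensitivity = NA_real_, specificity = NA_real_,
      ppv = NA_real_, npv = NA_real_, auc = as.numeric(pROC::auc(r)),
      lrPlus = NA_real_, lrMinus = NA_real_, threshold = NA_real_,
      rocPoints = pts)
}

#' Operating threshold at a target specificity
#'
#' The smallest score cutoff whose empirical specificity (fraction of
#' negatives scoring below it) reaches the target; sensitivity is reported
#' at that cutoff. Fewer than 20 negatives triggers a warning, the target
#' quantile being unstable there.
#'
#' @inheritParams rocAuc
#' @param targetSpecificity required specificity (default 0.95).
#' @return list with `threshold`, `sensitivity`, `specificity`.
#' @export
thresholdAtSpecificity <- function(scores, labels, positiveLabel = NULL,
                                   targetSpecificity = 0.95) {
  labels <- as.character(labels)
  if (is.null(positiveLabel))
    positiveLabel <- names(which.min(table(labels)))
  pos <- scores[labels == positiveLabel]
  neg <- scores[labels != positiveLabel]
  if (length(neg) < 20L)
    warning("fewer than 20 negatives: the specificity quantile is unstable")
  cand <- sort(unique(scores))
  specs <- vapply(cand, function(t) mean(neg < t), numeric(1L))
  ok <- which(specs >= targetSpecificity)
  if (!length(ok)) {
    warning("no finite threshold reaches the target specificity")
    return(list(threshold = Inf, sensitivity = 0, specificity = 1))
  }
  thr <- cand[ok[1L]]
  list(threshold = thr, sensitivity = mean(pos >= thr),
       specificity = mean(neg < thr))
}

#' Positive and negative likelihood ratios
#'
#' `LR+ = sens / (1 - spec)` and `LR- = (1 - sens) / spec`; a perfect
#' specificity yields an infinite LR+, a zero specificity an infinite LR-.
#'
#' @param sensitivity,specificity fractions in \[0, 1\].
#' @return list with `lrPlus`, `lrMinus`.
#' @examples
#' likelihoodRatios(0.71, 0.95)
#' @export
likelihoodRatios <- function(sensitivity, specificity) {
  stopInvalid(sensitivity < 0 || sensitivity > 1 ||
                specificity < 0 || specificity > 1,
              "sensitivity and specificity must be in [0, 1]")
  list(lrPlus = if (specificity == 1) Inf else
         sensitivity / (1 - specificity),
       lrMinus = if (specificity == 0) Inf else
         (1 - sensitivity) / specificity)
}

#' Full evaluation at a fixed operating threshold
#'
#' Sensitivity, specificity, predictive values, likelihood ratios, AUC and
#' the ROC points of a score vector at a given cutoff (positive when
#' `score >= threshold`).
#'
#' @inheritParams rocAuc
#' @param threshold operating-point cutoff.
#' @return a [ClassifierEval-class].
#' @export
evalAtThreshold <- function(scores, labels, threshold,
                            positiveLabel = NULL) {
  labels <- as.character(labels)
  if (is.null(positiveLabel))
    positiveLabel <- names(which.min(table(labels)))
  base <- rocAuc(scores, labels, positiveLabel)
  pos <- labels == positiveLabel
  called <- scores >= threshold
  sens <- mean(called[pos]); spec <- mean(!called[!pos])
  ppv <- if (any(called)) mean(pos[called]) else NA_real_
  npv <- if (any(!called)) mean(!pos[!called]) else NA_real_
  lr <- likelihoodRatios(sens, spec)
  new("ClassifierEval", sensitivity = sens, specificity = spec,
      ppv = ppv, npv = npv, auc = base@auc, lrPlus = lr$lrPlus,
      lrMinus = lr$lrMinus, threshold = threshold,
      rocPoints = rocPoints(base))
}

#' Freeze a decision threshold on a classifier
#'
#' Typically the LOOCV out-of-fold threshold at 95% specificity, then
#' applied unchanged to validation sets.
#'
#' @param classifier a [TrainedClassifier-class].
#' @param threshold the score cutoff to freeze.
#' @return the updated classifier.
#' @export
setDecisionThreshold <- function(classifier, threshold) {
  classifier@decisionThreshold <- threshold
  validObject(classifier)
  classifier
}
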