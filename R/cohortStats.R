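#' Cohort percentage with the reporting rounding convention
#'
#' `100 * numerator / denominator`, rounded half-up. By default the value is
#' first rounded half-up to `sigDigits` significant figures (the two
#' significant figures clinical cohort summaries report) and then presented
#' half-up at `decimals` — e.g. 5/143 = 3.4965% -> 3.5 -> 4, while
#' 25/143 = 17.48% -> 17. Set `sigDigits = NULL` for plain half-up rounding
#' of the exact ratio.
#'
#' @param numerator,denominator non-negative counts, `numerator <=
#'   denominator`, `denominator > 0`.
#' @param decimals decimal places of the reported percentage.
#' @param sigDigits significant figures of the pre-rounding step, or `NULL`
#'   to disable.
#' @return the percentage as a plain number.
#' @examples
#' proportionPct(185, 81611, 2)  # 0.23
#' proportionPct(143, 185)       # 77
#' @export
proportionPct <- function(numerator, denominator, decimals = 0L,
                          sigDigits = 2L) {
  stopInvalid(denominator <= 0, "denominator must be > 0")
  stopInvalid(numerator < 0 || numerator > denominator,
              "need 0 <= numerator <= denominator")
  pct <- 100 * numerator / denominator
  if (!is.null(sigDigits)) pct <- signifHalfUp(pct, sigDigits)
  roundHalfUp(pct, decimals)
}

#' Expected disease cases from a population prevalence
#'
#' @param cohortN cohort size.
#' @param casesPer100k population prevalence in cases per 100,000.
#' @param rounding `"nearest"` (half-up to an integer) or `"none"`.
#' @return expected case count.
#' @examples
#' expectedCases(81611, 134.5)  # 110
#' @export
expectedCases <- function(cohortN, casesPer100k,
                          rounding = c("nearest", "none")) {
  stopInvalid(cohortN <= 0, "cohortN must be > 0")
  stopInvalid(casesPer100k <= 0 || casesPer100k >= 1e5,
              "casesPer100k must be in (0, 100000)")
  rounding <- match.arg(rounding)
  e <- cohortN * casesPer100k / 1e5
  if (rounding == "nearest") roundHalfUp(e) else e
}

#' Odds ratio of a 2x2 contingency table
#'
#' Cross-product odds ratio `a d / (b c)` with the 95% Woolf interval
#' `exp(log OR +- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. Any zero cell invokes
#' the Haldane-Anscombe 0.5 correction on all four cells, flagged in the
#' method note. Cells may be non-integer when derived from prevalence
#' expectations.
#'
#' @param a,b,c,d cell counts: a = exposed with outcome, b = exposed
#'   without, c = unexposed with outcome, d = unexposed without.
#' @return list with `or`, `ciLow`, `ciHigh`, `method`, `table`.
#' @examples
#' or2x2(20, 10, 5, 40)$or  # 16
#' @export
or2x2 <- function(a, b, c, d) {
  stopInvalid(any(c(a, b, c, d) < 0), "cell counts must be >= 0")
  stopInvalid(a + b + c + d <= 0, "table total must be > 0")
  method <- "Woolf 95% CI"
  if (any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
    method <- "Haldane-Anscombe 0.5 correction; Woolf 95% CI"
  }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = or,
       ciLow = exp(log(or) - 1.96 * se),
       ciHigh = exp(log(or) + 1.96 * se),
       method = method,
       table = c(a = a, b = b, c = c, d = d))
}

#' Prevalence-based odds ratio for an outcome-enriched disease
#'
#' Builds the 2x2 table comparing disease odds among samples with the
#' outcome (e.g. an inconclusive NIPS result) against the rest of the
#' cohort, with the cohort's disease count estimated from the population
#' prevalence: `a` = diseased with outcome, `b` = expected diseased without
#' (`expected - a`), `c` = outcome without disease, `d` = the remainder.
#'
#' @param cohortN total cohort size.
#' @param nOutcome samples with the outcome.
#' @param nDiseaseOutcome diseased samples among the outcome group.
#' @param casesPer100k population prevalence of the disease.
#' @inheritParams expectedCases
#' @return list as in [or2x2()], plus `expectedCases`.
#' @examples
#' orFromPrevalence(81611, 185, 13, 134.5)$or  # ~63.4
#' @export
orFromPrevalence <- function(cohortN, nOutcome, nDiseaseOutcome,
                             casesPer100k,
                             rounding = c("nearest", "none")) {
  stopInvalid(nDiseaseOutcome > nOutcome || nOutcome > cohortN,
              "need nDiseaseOutcome <= nOutcome <= cohortN")
  expected <- expectedCases(cohortN, casesPer100k, rounding)
  stopInvalid(expected < nDiseaseOutcome,
              "expected disease cases fall below the observed count")
  a <- nDiseaseOutcome
  b <- expected - a
  cc <- nOutcome - a
  d <- cohortN - nOutcome - b
  res <- or2x2(a, b, cc, d)
  res$expectedCases <- expected
  res
}

#' Cluster enrichment of a binary phenotype
#'
#' For every cluster, a one-vs-rest logistic regression of the phenotype on
#' the in-cluster indicator (p-value from the likelihood-ratio test), with
#' Fisher's exact test as a supplementary cross-check and a Bonferroni
#' column for transparency (raw p-values are the primary report). Clusters
#' whose members are all or none phenotype-positive separate the logistic
#' model; they get the exact test only and a flag.
#'
#' @param clusters cluster id per sample.
#' @param phenotype logical (or two-level) phenotype per sample.
#' @param alpha significance level for the `enriched` flag.
#' @return data.frame, one row per cluster: sizes, case counts, `pLogit`,
#'   `pFisher`, `pBonferroni`, `oddsRatio`, `degenerate`, `enriched`.
#' @export
clusterEnrichment <- function(clusters, phenotype, alpha = 0.05) {
  if (!is.logical(phenotype)) {
    lv <- unique(phenotype)
    stopInvalid(length(lv) != 2L, "phenotype must be binary")
    phenotype <- phenotype == names(which.min(table(phenotype)))
  }
  stopInvalid(length(unique(clusters)) < 2L, "need >= 2 clusters")
  stopInvalid(!any(phenotype) || all(phenotype),
              "phenotype must have both values")
  rows <- lapply(sort(unique(clusters)), function(cl) {
    inCl <- clusters == cl
    tab <- matrix(c(sum(inCl & phenotype), sum(inCl & !phenotype),
                    sum(!inCl & phenotype), sum(!inCl & !phenotype)), 2L)
    fish <- fisher.test(tab)
    degenerate <- all(phenotype[inCl]) || !any(phenotype[inCl])
    pLogit <- if (degenerate) NA_real_ else {
      fit <- glm(phenotype ~ inCl, family = binomial())
      as.numeric(anova(fit, test = "Chisq")[2L, "Pr(>Chi)"])
    }
    orr <- or2x2(tab[1, 1], tab[2, 1], tab[1, 2], tab[2, 2])
    data.frame(cluster = cl, n = sum(inCl), nCases = sum(inCl & phenotype),
               pLogit = pLogit, pFisher = fish$p.value,
               oddsRatio = orr$or, degenerate = degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  pPrimary <- ifelse(is.na(out$pLogit), out$pFisher, out$pLogit)
  out$pBonferroni <- pmin(1, pPrimary * nrow(out))
  out$enriched <- out$oddsRatio > 1 & pPrimary < alpha
  out
}

#' Covariate-adjusted logit model of a prediction outcome
#'
#' Maximum-likelihood logistic regression of a correct-prediction flag on
#' patient covariates (age, SLEDAI category, disease activity, comorbidity,
#' ...), reporting per-covariate coefficients, standard errors, adjusted
#' odds ratios (`exp(coef)`) and Wald p-values. Complete separation (or a
#' constant outcome) is detected and reported; the fit then falls back to a
#' lightly ridge-penalized IRLS (penalty `lambda` on non-intercept
#' coefficients), noted in the method note rather than silently diverging.
#'
#' @param outcome logical (or 0/1) outcome per patient.
#' @param covariates data.frame of covariates; factors are expanded to
#'   treatment contrasts.
#' @param lambda ridge penalty of the separation fallback.
#' @return list with `coefficients` (data.frame: term, estimate, se,
#'   adjustedOR, p), `separation` flag and `method` note.
#' @export
logitPredictionModel <- function(outcome, covariates, lambda = 1e-3) {
  outcome <- as.logical(outcome)
  stopInvalid(nrow(covariates) != length(outcome),
              "outcome and covariates must align")
  X <- stats::model.matrix(~ ., data = covariates)
  stopInvalid(length(outcome) < ncol(X) + 5L,
              "need n >= number of parameters + 5")
  degenerate <- all(outcome) || !any(outcome)
  separation <- degenerate
  fit <- NULL
  if (!degenerate) {
    fit <- suppressWarnings(
      glm(outcome ~ ., data = covariates, family = binomial()))
    eta <- stats::predict(fit, type = "link")
    separation <- !fit$converged || max(abs(coef(fit)), na.rm = TRUE) > 15 ||
      max(abs(eta)) > 20
  }
  if (separation) {
    co <- ridgeLogit(X, outcome, lambda)
    method <- paste("complete separation or degenerate outcome detected;",
                    "ridge-penalized IRLS fallback (lambda =", lambda, ")")
  } else {
    s <- summary(fit)$coefficients
    co <- data.frame(term = rownames(s), estimate = s[, 1L], se = s[, 2L],
                     p = s[, 4L], stringsAsFactors = FALSE)
    method <- "maximum-likelihood logistic regression (IRLS)"
  }
  co$adjustedOR <- exp(co$estimate)
  rownames(co) <- NULL
  list(coefficients = co[, c("term", "estimate", "se", "adjustedOR", "p")],
       separation = separation, method = method)
}

# Ridge-penalized logistic IRLS: penalty lambda * I on non-intercept terms.
# Used only as the flagged separation fallback of logitPredictionModel.
ridgeLogit <- function(X, y, lambda, tol = 1e-8, maxIter = 200L) {
  P <- diag(c(0, rep(lambda, ncol(X) - 1L)), ncol(X))
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxIter)) {
    eta <- pmin(pmax(as.numeric(X %*% beta), -30), 30)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    H <- crossprod(X, X * W) + P
    g <- crossprod(X, y - mu) - P %*% beta
    step <- solve(H, g)
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < tol) break
  }
  se <- sqrt(diag(solve(H)))
  z <- beta / se
  data.frame(term = colnames(X), estimate = beta, se = se,
             p = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE)
}
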