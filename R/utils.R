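#' @importFrom stats rnbinom rnorm runif rbeta sd quantile dist hclust cutree
#' @importFrom stats prcomp lowess runmed fisher.test glm binomial predict
#' @importFrom stats coef pnorm anova as.dendrogram complete.cases setNames
#' @importFrom utils read.delim write.table head tail
NULL

# Evaluate `expr` under a fixed RNG state, restoring the caller's state after.
# All stochastic code in the package funnels through this so that no function
# perturbs (or depends on) global random state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Round half away from zero at `digits` decimals (base round() is half-even).
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Round half-up to `sig` significant figures.
signifHalfUp <- function(x, sig = 2) {
  out <- x
  nz <- is.finite(x) & x != 0
  e <- floor(log10(abs(x[nz])))
  out[nz] <- roundHalfUp(x[nz], sig - 1 - e)
  out
}

stopInvalid <- function(cond, msg) {
  if (cond) stop(msg, call. = FALSE)
}
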