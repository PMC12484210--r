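#' Fit an IG-GSCA model by alternating least squares
#'
#' Estimates component weights, indicator loadings and ridge-regularized
#' structural path coefficients jointly, by alternating exact least-squares
#' sub-steps until the global criterion (sum of squared residuals of all
#' indicator and structural equations plus \code{lambda} times the sum of
#' squared structural coefficients) stabilizes. Indicators are standardized
#' internally with the population (divide-by-n) convention, so component
#' scores have exactly unit variance and loadings equal the sample
#' correlation between each indicator and its component. Interaction
#' components are standardized products of their parent scores, recomputed
#' after every weight update; they carry no free parameters.
#'
#' @param data an \linkS4class{IGDataset}, or a samples x indicators matrix
#'   or data.frame whose column names cover the model's indicators
#'   (standardized internally either way).
#' @param model a \linkS4class{PathModel}.
#' @param lambda non-negative ridge penalty on the structural coefficients
#'   (loadings and weights are never penalized).
#' @param maxIterations,tolerance stopping rule: stop when the relative
#'   criterion change falls below \code{tolerance} (default 1e-6) or after
#'   \code{maxIterations} (default 500, with a warning).
#' @param init \code{"equal"} (default, deterministic: equal weights
#'   1/sqrt(k) per composite) or \code{"random"} (seeded normal weights, for
#'   basin checks).
#' @param seed optional seed for random initialization.
#' @param warmStart optional \linkS4class{IGFit} whose weights initialize
#'   the iterations (used by the bootstrap and the cross-validation grid).
#' @return an \linkS4class{IGFit}.
#' @examples
#' sim <- simulateDataset(nSamples = 120, seed = 1,
#'                        roiSubset = c("ACgG", "CO"))
#' m <- buildStudyModel(roiSubset = c("ACgG", "CO"))
#' fit <- igFit(sim$dataset, m, lambda = 10)
#' head(pathCoefficients(fit))
#' @export
igFit <- function(data, model, lambda = 0, maxIterations = 500L,
                  tolerance = 1e-6, init = c("equal", "random"),
                  seed = NULL, warmStart = NULL) {
  init <- match.arg(init)
  stopifnot(is.numeric(lambda), length(lambda) == 1L, lambda >= 0)
  cm <- .compileModel(model)
  X <- .assembleIndicators(data, model)
  if (nrow(X) < 2L) stop("need at least two samples")
  Z <- standardizeColumns(X)
  W0 <- NULL
  if (!is.null(warmStart)) {
    stopifnot(methods::is(warmStart, "IGFit"))
    W0 <- lapply(cm$name, function(nm) warmStart@weights[[nm]])
  } else if (init == "random") {
    if (!is.null(seed)) set.seed(seed)
    W0 <- lapply(seq_len(cm$C), function(j)
      if (cm$multi[j]) rnorm(length(cm$indIdx[[j]])) else NULL)
  }
  st <- .fitEngine(Z, cm, lambda = lambda, tolerance = tolerance,
                   maxIterations = maxIterations, W0 = W0)
  if (!st$converged)
    warning("ALS did not converge in ", maxIterations,
            " iterations (last relative change ",
            signif(abs(diff(utils::tail(st$trace, 2))) /
                     utils::tail(st$trace, 1), 3), ")", call. = FALSE)
  weights <- st$W
  names(weights) <- cm$name
  weights <- weights[cm$composite]
  loadings <- data.frame(construct = cm$name[cm$indCon],
                         indicator = cm$indicator,
                         loading = st$Load,
                         stringsAsFactors = FALSE)
  paths <- data.frame(from = cm$name[cm$eFrom], to = cm$name[cm$eTo],
                      estimate = st$B[cbind(cm$eFrom, cm$eTo)],
                      stringsAsFactors = FALSE)
  scores <- st$Gamma
  colnames(scores) <- cm$name
  methods::new("IGFit",
    model = model, lambda = lambda, weights = weights,
    loadings = loadings, paths = paths, scores = scores, r2 = st$r2,
    criterionTrace = st$trace, converged = st$converged,
    details = list(Z = Z, cm = cm, B = st$B, Load = st$Load,
                   center = attr(Z, "center"), scale = attr(Z, "scale"),
                   interCenter = st$interCenter,
                   interScale = st$interScale,
                   iterations = st$iterations,
                   config = list(maxIterations = maxIterations,
                                 tolerance = tolerance, init = init,
                                 seed = seed)))
}

#' Component scores from given weights
#'
#' Computes composite scores as weighted sums of each construct's own
#' (standardized) indicators, optionally rescaled to unit variance, and
#' interaction scores as standardized element-wise products of the two
#' parent scores. Exposed mainly for diagnostics and testing; [igFit()]
#' maintains scores internally.
#'
#' @param Z standardized samples x indicators matrix (model indicator
#'   columns present by name).
#' @param weights named list of weight vectors, one per construct with
#'   indicators.
#' @param model a \linkS4class{PathModel}.
#' @param normalize rescale each composite score to unit (population)
#'   variance (default TRUE). With \code{FALSE} the raw weighted sums are
#'   returned (interaction scores are standardized regardless).
#' @return samples x constructs score matrix.
#' @export
computeComponents <- function(Z, weights, model, normalize = TRUE) {
  cm <- .compileModel(model)
  Z <- as.matrix(Z)
  n <- nrow(Z)
  Gamma <- matrix(0, n, cm$C, dimnames = list(NULL, cm$name))
  for (j in which(cm$composite)) {
    idx <- cm$indIdx[[j]]
    w <- weights[[cm$name[j]]]
    if (is.null(w)) w <- rep(1 / sqrt(length(idx)), length(idx))
    g <- Z[, cm$indicator[idx], drop = FALSE] %*% w
    if (normalize) {
      s <- sqrt(sum((g - mean(g))^2) / n)
      if (s < 1e-12) .degenerate_stop(cm$name[j])
      g <- (g - mean(g)) / s
    }
    Gamma[, j] <- g
  }
  .interactionScores(Gamma, cm)
}

#' Accessors for fitted IG-GSCA models
#'
#' \code{componentScores()}: samples x constructs unit-variance score
#' matrix. \code{componentWeights()}: named list of weight vectors.
#' \code{indicatorLoadings()}: data.frame of loadings (equal to
#' indicator-component correlations). \code{pathCoefficients()}: data.frame
#' of structural coefficients. \code{rSquared()}: named explained-variance
#' fraction per endogenous construct. \code{criterionTrace()}: criterion
#' value per iteration.
#'
#' @param object an \linkS4class{IGFit}.
#' @name igFit-accessors
NULL

#' @rdname igFit-accessors
setMethod("componentScores", "IGFit", function(object) object@scores)

#' @rdname igFit-accessors
setMethod("componentWeights", "IGFit", function(object) object@weights)

#' @rdname igFit-accessors
setMethod("indicatorLoadings", "IGFit", function(object) object@loadings)

#' @rdname igFit-accessors
setMethod("pathCoefficients", "IGFit", function(object) object@paths)

#' @rdname igFit-accessors
setMethod("rSquared", "IGFit", function(object) object@r2)

#' @rdname igFit-accessors
setMethod("criterionTrace", "IGFit", function(object) object@criterionTrace)

setMethod("show", "IGFit", function(object) {
  cat("IGFit:", nrow(object@scores), "samples,",
      nrow(object@model@constructs), "constructs,",
      nrow(object@paths), "structural paths\n")
  cat("  lambda =", object@lambda, "|",
      object@details$iterations, "iterations,",
      if (object@converged) "converged" else "NOT converged", "\n")
  cat("  mean R2 of endogenous constructs:",
      round(mean(object@r2), 3), "\n")
})
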