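#' Default candidate grid for the ridge penalty
#'
#' Zero plus 40 log-spaced values from 1 to 1000. A dense integer grid over
#' the same range can be supplied instead when fine resolution of the
#' selected penalty matters.
#'
#' @return sorted numeric vector of 41 candidate penalties.
#' @export
defaultLambdaGrid <- function() c(0, 10^seq(0, 3, length.out = 40))

#' Select the ridge penalty by repeated k-fold cross-validation
#'
#' For each repeat the samples are partitioned into \code{nFolds} folds
#' (seeded). For each candidate penalty the model is fitted on the training
#' folds, with standardization parameters learned on the training data only;
#' held-out component scores are then formed with the training weights (and
#' training interaction scaling), and the out-of-fold error is the sum of
#' squared structural-equation residuals on the held-out samples. The
#' selected penalty minimizes the mean error over folds and repeats, with
#' ties broken towards the larger penalty. The loss covers structural
#' residuals only, because the ridge penalty applies only to structural
#' paths.
#'
#' @param data an \linkS4class{IGDataset} or samples x indicators matrix.
#' @param model a \linkS4class{PathModel}.
#' @param lambdaGrid sorted non-negative candidate penalties.
#' @param nFolds folds per repeat (default 5).
#' @param nRepeats independent repetitions (default 10).
#' @param seed integer seed controlling the fold partitions.
#' @param tolerance,maxIterations passed to the inner fits.
#' @return an \linkS4class{IGLambdaCV}.
#' @export
selectLambda <- function(data, model, lambdaGrid = defaultLambdaGrid(),
                         nFolds = 5L, nRepeats = 10L, seed = 1L,
                         tolerance = 1e-6, maxIterations = 500L) {
  stopifnot(length(lambdaGrid) >= 1L, all(lambdaGrid >= 0),
            !is.unsorted(lambdaGrid), nFolds >= 2L, nRepeats >= 1L)
  cm <- .compileModel(model)
  X <- .assembleIndicators(data, model)
  n <- nrow(X)
  if (n < 2L * nFolds)
    stop("need at least 2 x nFolds samples")
  set.seed(seed)
  errs <- matrix(NA_real_, nRepeats, length(lambdaGrid))  # per-repeat means
  for (r in seq_len(nRepeats)) {
    folds <- NULL
    for (attempt in seq_len(20L)) {
      cand <- sample(rep(seq_len(nFolds), length.out = n))
      ok <- all(vapply(seq_len(nFolds), function(f) {
        Xt <- X[cand != f, , drop = FALSE]
        all(.colSds(Xt) > 1e-12)
      }, logical(1)))
      if (ok) { folds <- cand; break }
      warning("fold with a constant indicator column; partition redrawn",
              call. = FALSE)
    }
    if (is.null(folds))
      stop("could not draw folds without constant training columns")
    fold_err <- matrix(0, nFolds, length(lambdaGrid))
    for (f in seq_len(nFolds)) {
      train <- folds != f
      Ztr <- standardizeColumns(X[train, , drop = FALSE])
      Zte <- standardizeColumns(X[!train, , drop = FALSE],
                                center = attr(Ztr, "center"),
                                scale = attr(Ztr, "scale"))
      W0 <- NULL
      for (li in seq_along(lambdaGrid)) {
        st <- .fitEngine(Ztr, cm, lambda = lambdaGrid[li],
                         tolerance = tolerance,
                         maxIterations = maxIterations, W0 = W0)
        W0 <- st$W  # warm start along the grid
        fold_err[f, li] <- .oofError(Zte, cm, st)
      }
    }
    errs[r, ] <- colMeans(fold_err)
  }
  meanErr <- colMeans(errs)
  sdErr <- if (nRepeats > 1) apply(errs, 2, sd) else rep(NA_real_,
                                                         ncol(errs))
  best <- max(lambdaGrid[meanErr == min(meanErr)])
  methods::new("IGLambdaCV", grid = as.numeric(lambdaGrid),
               meanError = meanErr, sdError = sdErr, selected = best,
               config = list(nFolds = nFolds, nRepeats = nRepeats,
                             seed = seed))
}

# column SDs without extra dependencies
.colSds <- function(x) {
  m <- colMeans(x)
  sqrt(colMeans(sweep(x, 2L, m)^2))
}

# Out-of-fold structural residual error: held-out scores from training
# weights, residuals of every structural equation summed over held-out
# samples.
.oofError <- function(Zte, cm, st) {
  n <- nrow(Zte)
  Gamma <- matrix(0, n, cm$C)
  for (j in which(cm$composite))
    Gamma[, j] <- Zte[, cm$indIdx[[j]], drop = FALSE] %*% st$W[[j]]
  if (length(cm$inter)) {
    stats <- list(center = st$interCenter, scale = st$interScale)
    Gamma <- .interactionScores(Gamma, cm, stats, apply = TRUE)
  }
  pred <- Gamma %*% st$B
  sum((Gamma[, cm$endo, drop = FALSE] - pred[, cm$endo, drop = FALSE])^2)
}

#' CV curve as a data frame
#'
#' @param object an \linkS4class{IGLambdaCV}.
#' @return data.frame with \code{lambda}, \code{meanError}, \code{sdError}.
#' @export
cvTable <- function(object) {
  stopifnot(methods::is(object, "IGLambdaCV"))
  data.frame(lambda = object@grid, meanError = object@meanError,
             sdError = object@sdError)
}

setMethod("show", "IGLambdaCV", function(object) {
  cat("IGLambdaCV:", length(object@grid), "candidate penalties,",
      object@config$nRepeats, "x", object@config$nFolds,
      "fold cross-validation\n")
  cat("  selected lambda =", object@selected, "\n")
})
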