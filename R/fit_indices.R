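#' FIT: explained fraction of total variance
#'
#' FIT = 1 - (sum of squared residuals of all indicator equations and all
#' structural equations) / (total sum of squares of all indicators and all
#' endogenous components). The ridge penalty term is excluded from the
#' numerator: FIT measures explained variance at the estimated parameters,
#' not the penalized criterion.
#'
#' @param object an \linkS4class{IGFit}.
#' @return fraction in [0, 1].
#' @export
fitIndex <- function(object) {
  stopifnot(methods::is(object, "IGFit"))
  d <- object@details
  cm <- d$cm
  Z <- d$Z
  n <- nrow(Z)
  Gamma <- object@scores
  Zhat <- Gamma[, cm$indCon, drop = FALSE] * rep(d$Load, each = n)
  pred <- Gamma %*% d$B
  sse <- sum((Z - Zhat)^2) +
    sum((Gamma[, cm$endo, drop = FALSE] - pred[, cm$endo, drop = FALSE])^2)
  sst <- n * (cm$p + length(cm$endo))
  1 - sse / sst
}

#' @describeIn reproducedCovariance reconstruction from the fitted
#'   parameters.
#' @export
setMethod("reproducedCovariance", "IGFit", function(object) {
  d <- object@details
  cm <- d$cm
  Z <- d$Z
  n <- nrow(Z)
  ## model-implied scores: exogenous constructs keep their actual scores;
  ## endogenous ones are replaced by their structural predictions in
  ## topological order; interaction scores are recomputed from the implied
  ## parents.
  implied <- object@scores
  is_endo <- seq_len(cm$C) %in% cm$endo
  for (j in cm$topo) {
    if (is_endo[j]) {
      pa <- cm$parents[[j]]
      implied[, j] <- implied[, pa, drop = FALSE] %*%
        d$B[pa, j, drop = FALSE]
    }
  }
  if (length(cm$inter))
    implied <- .interactionScores(implied, cm)
  Zhat <- implied[, cm$indCon, drop = FALSE] * rep(d$Load, each = n)
  Zhat <- sweep(Zhat, 2L, colMeans(Zhat))
  Sig <- crossprod(Zhat) / n
  dimnames(Sig) <- list(cm$indicator, cm$indicator)
  single <- which(cm$kind[cm$indCon] %in% c("observed", "outcome") &
                    !is_endo[cm$indCon])
  ## exogenous single-indicator constructs are observed without error:
  ## keep their unit variance on the diagonal
  diag(Sig)[single] <- 1
  Sig
})

#' GFI and SRMR from a pair of covariance matrices
#'
#' GFI = 1 - trace((S - Sigma)^2) / trace(S^2). SRMR is the root mean
#' square of the standardized residual covariances over the lower triangle
#' including the diagonal: residual r_ij = (s_ij - sigma_ij) /
#' sqrt(s_ii s_jj).
#'
#' @param sampleCov sample covariance matrix S.
#' @param reproducedCov model-reproduced covariance matrix Sigma.
#' @return list with \code{gfi} and \code{srmr}.
#' @examples
#' gfiSrmr(diag(4), matrix(0, 4, 4))  # gfi 0, srmr sqrt(4/10)
#' @export
gfiSrmr <- function(sampleCov, reproducedCov) {
  S <- as.matrix(sampleCov)
  Sg <- as.matrix(reproducedCov)
  if (!all(dim(S) == dim(Sg)))
    stop("covariance matrices must have the same dimension")
  D <- S - Sg
  gfi <- 1 - sum(D * D) / sum(S * S)
  sdv <- sqrt(diag(S))
  R <- D / outer(sdv, sdv)
  lower <- R[lower.tri(R, diag = TRUE)]
  list(gfi = gfi, srmr = sqrt(mean(lower^2)))
}

#' @describeIn fitIndices FIT, GFI and SRMR for a fitted model, with
#'   pass/fail flags against the conventional cutoffs (GFI > 0.93,
#'   SRMR < 0.08).
#' @export
setMethod("fitIndices", "IGFit", function(object) {
  d <- object@details
  S <- crossprod(d$Z) / nrow(d$Z)
  dimnames(S) <- list(d$cm$indicator, d$cm$indicator)
  gs <- gfiSrmr(S, reproducedCovariance(object))
  list(fit = fitIndex(object), gfi = gs$gfi, srmr = gs$srmr,
       gfiPass = gs$gfi > 0.93, srmrPass = gs$srmr < 0.08)
})
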