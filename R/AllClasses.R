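#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData
#'   colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats cor quantile rnorm runif rbinom rbeta sd var
#'   pt qnorm setNames complete.cases
#' @importFrom utils read.csv read.delim write.table packageVersion
NULL

.CONSTRUCT_KINDS <- c("composite", "interaction", "observed", "outcome")

#' Directed component path model
#'
#' A \code{PathModel} holds the construct definitions (composites with
#' indicators, single-indicator observed variables, an outcome, and
#' indicator-free interaction constructs defined as products of two parent
#' components) together with the directed structural edges between them.
#'
#' @slot constructs data.frame with columns \code{name} and \code{kind}
#'   (one of composite, interaction, observed, outcome).
#' @slot indicators data.frame with columns \code{indicator} and
#'   \code{construct}; each indicator belongs to exactly one construct.
#' @slot interactions data.frame with columns \code{construct},
#'   \code{parent1}, \code{parent2} for interaction constructs.
#' @slot edges data.frame with columns \code{from} and \code{to}, the
#'   directed structural paths (predictor to outcome construct).
#'
#' @seealso [buildStudyModel()], [validateModel()], [countFreePaths()]
#' @export
setClass("PathModel",
  representation(
    constructs   = "data.frame",
    indicators   = "data.frame",
    interactions = "data.frame",
    edges        = "data.frame"
  )
)

setValidity("PathModel", function(object) {
  v <- validateModel(object)
  if (length(v)) paste(v, collapse = "; ") else TRUE
})

#' Aligned imaging-genetics dataset
#'
#' An \code{IGDataset} is a \linkS4class{SummarizedExperiment} whose single
#' assay \code{"indicators"} stores SNP minor-allele dosages and relative ROI
#' volumes (rows = indicators, columns = samples), with phenotype and
#' covariate columns (\code{pte}, \code{severity}, \code{gender}, \code{age},
#' \code{audit}) in \code{colData}. It is complete by construction: samples
#' with any missing value are removed listwise when the object is assembled
#' (see [listwiseExclude()]).
#'
#' @seealso [listwiseExclude()], [genotypes()], [roiVolumes()],
#'   [phenotypes()]
#' @export
setClass("IGDataset", contains = "SummarizedExperiment")

.PHENO_COLS <- c("pte", "severity", "gender", "age", "audit")

setValidity("IGDataset", function(object) {
  msg <- character(0)
  a <- SummarizedExperiment::assay(object, "indicators")
  if (anyNA(a)) msg <- c(msg, "missing values in indicator assay")
  cd <- SummarizedExperiment::colData(object)
  miss <- setdiff(.PHENO_COLS, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste("missing phenotype columns:",
                        paste(miss, collapse = ", ")))
  else {
    ph <- as.data.frame(cd[, .PHENO_COLS])
    if (anyNA(ph)) msg <- c(msg, "missing values in phenotypes")
    else {
      if (any(ph$pte < 0 | ph$pte > 17))
        msg <- c(msg, "pte outside 0-17")
      if (any(ph$audit < 0 | ph$audit > 40))
        msg <- c(msg, "audit outside 0-40")
      if (any(ph$severity < 0))
        msg <- c(msg, "negative severity")
    }
  }
  rd <- SummarizedExperiment::rowData(object)
  if (!"type" %in% colnames(rd))
    msg <- c(msg, "rowData must have a 'type' column")
  else if (!anyNA(a)) {
    snp <- rd$type == "snp"
    if (any(snp) && !all(a[snp, ] %in% 0:2))
      msg <- c(msg, "SNP dosages must be 0, 1 or 2")
    roi <- rd$type == "roi"
    if (any(roi) && any(a[roi, ] <= 0 | a[roi, ] > 1))
      msg <- c(msg, "relative ROI volumes must lie in (0, 1]")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Fitted IG-GSCA model
#'
#' Holds the alternating-least-squares estimates: component weights,
#' indicator loadings, ridge-regularized structural path coefficients,
#' unit-variance component scores, per-endogenous-construct R-squared, and
#' the per-iteration criterion trace.
#'
#' @slot model the \linkS4class{PathModel} that was fitted.
#' @slot lambda ridge penalty applied to the structural coefficients.
#' @slot weights named list of component weight vectors (composites only).
#' @slot loadings data.frame \code{construct}, \code{indicator},
#'   \code{loading}.
#' @slot paths data.frame \code{from}, \code{to}, \code{estimate}.
#' @slot scores samples x constructs matrix of unit-variance component
#'   scores.
#' @slot r2 named numeric, explained-variance fraction per endogenous
#'   construct.
#' @slot criterionTrace numeric, least-squares criterion per iteration.
#' @slot converged logical.
#' @slot details list of internal state (standardized data, compiled model,
#'   standardization parameters, interaction scaling) reused by the fit-index
#'   and bootstrap machinery.
#' @export
setClass("IGFit",
  representation(
    model          = "PathModel",
    lambda         = "numeric",
    weights        = "list",
    loadings       = "data.frame",
    paths          = "data.frame",
    scores         = "matrix",
    r2             = "numeric",
    criterionTrace = "numeric",
    converged      = "logical",
    details        = "list"
  )
)

#' Bootstrap inference for an IG-GSCA fit
#'
#' Stores per-resample path and loading draws (after sign alignment against
#' the full-sample components), with standard errors (standard deviation
#' across resamples) and percentile 95\% confidence intervals.
#'
#' @slot fit the full-sample \linkS4class{IGFit} used as alignment reference.
#' @slot pathDraws resamples x paths matrix of aligned coefficients.
#' @slot loadingDraws resamples x indicators matrix of aligned loadings.
#' @slot pathTable data.frame \code{from}, \code{to}, \code{estimate},
#'   \code{se}, \code{lower}, \code{upper}.
#' @slot loadingTable same layout for loadings.
#' @slot nResamples number of retained resamples.
#' @slot nDiscarded resamples discarded for degenerate components and
#'   redrawn.
#' @slot seed integer seed used for resampling.
#' @export
setClass("IGBoot",
  representation(
    fit          = "IGFit",
    pathDraws    = "matrix",
    loadingDraws = "matrix",
    pathTable    = "data.frame",
    loadingTable = "data.frame",
    nResamples   = "numeric",
    nDiscarded   = "numeric",
    seed         = "numeric"
  )
)

#' Cross-validation curve for the ridge tuning parameter
#'
#' @slot grid candidate ridge penalties.
#' @slot meanError mean out-of-fold structural residual error per penalty.
#' @slot sdError dispersion of the per-repeat mean errors.
#' @slot selected the selected penalty (minimum mean error, ties towards the
#'   larger penalty).
#' @slot config list with folds, repeats and seed.
#' @export
setClass("IGLambdaCV",
  representation(
    grid      = "numeric",
    meanError = "numeric",
    sdError   = "numeric",
    selected  = "numeric",
    config    = "list"
  )
)

#' Ground truth of a simulated dataset
#'
#' Emitted by [simulateDataset()] alongside the data so parameter-recovery
#' tests can compare estimates against the planted generative parameters.
#'
#' @slot plantedPaths data.frame \code{from}, \code{to}, \code{estimate} of
#'   the planted structural coefficients (edges not listed are zero).
#' @slot indicatorLoading target construct-indicator correlation used to
#'   generate ROI indicators.
#' @slot config list of generator settings (sample size, seed, LD, PTE
#'   moments).
#' @export
setClass("SyntheticTruth",
  representation(
    plantedPaths     = "data.frame",
    indicatorLoading = "numeric",
    config           = "list"
  )
)
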