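#' Number of free structural paths in a model
#'
#' @param model a \linkS4class{PathModel}.
#' @return integer, the number of directed structural edges.
#' @examples
#' countFreePaths(buildStudyModel())
#' @export
setGeneric("countFreePaths", function(model) standardGeneric("countFreePaths"))

#' Validate a path model
#'
#' Checks acyclicity, disjoint indicator membership, interaction parents
#' (exactly two, existing, non-interaction), and per-kind indicator counts.
#' Violations are returned, not raised.
#'
#' @param model a \linkS4class{PathModel}.
#' @return character vector of violations; empty if the model is valid.
#' @export
setGeneric("validateModel", function(model) standardGeneric("validateModel"))

#' @rdname genotypes
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname genotypes
#' @export
setGeneric("roiVolumes", function(x) standardGeneric("roiVolumes"))

#' @rdname genotypes
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @rdname igFit-accessors
#' @export
setGeneric("componentScores", function(object) standardGeneric("componentScores"))

#' @rdname igFit-accessors
#' @export
setGeneric("componentWeights", function(object) standardGeneric("componentWeights"))

#' @rdname igFit-accessors
#' @export
setGeneric("indicatorLoadings", function(object) standardGeneric("indicatorLoadings"))

#' @rdname igFit-accessors
#' @export
setGeneric("pathCoefficients", function(object) standardGeneric("pathCoefficients"))

#' @rdname igFit-accessors
#' @export
setGeneric("rSquared", function(object) standardGeneric("rSquared"))

#' @rdname igFit-accessors
#' @export
setGeneric("criterionTrace", function(object) standardGeneric("criterionTrace"))

#' Structural paths whose bootstrap 95\% CI excludes zero
#'
#' Significance is strict exclusion of zero by the unrounded percentile
#' interval; no multiplicity correction is applied, because all paths are
#' estimated jointly within one multivariate model.
#'
#' @param object an \linkS4class{IGBoot}.
#' @return data.frame of significant paths with estimates, SEs and CIs.
#' @export
setGeneric("significantPaths", function(object) standardGeneric("significantPaths"))

#' Indirect (mediation) effect along a chain of paths
#'
#' The point estimate is the exact product of the full-sample path
#' coefficients along the chain; the SE and percentile CI come from the
#' per-resample products of the aligned bootstrap draws.
#'
#' @param object an \linkS4class{IGBoot}.
#' @param chain character vector of construct names forming a directed path
#'   in the model, e.g. \code{c("HTR3A", "ACgG", "PTSD")}.
#' @return data.frame with one row: chain, estimate, se, lower, upper.
#' @export
setGeneric("indirectEffect", function(object, chain) standardGeneric("indirectEffect"))

#' Overall goodness-of-fit indices
#'
#' Computes FIT (explained fraction of the total variance of all indicators
#' and endogenous components), GFI and SRMR (both from the discrepancy
#' between the sample and model-reproduced indicator covariance matrices),
#' with the conventional cutoffs GFI > 0.93 and SRMR < 0.08.
#'
#' @param object an \linkS4class{IGFit}.
#' @return list with \code{fit}, \code{gfi}, \code{srmr}, \code{gfiPass},
#'   \code{srmrPass}.
#' @export
setGeneric("fitIndices", function(object) standardGeneric("fitIndices"))

#' Model-reproduced indicator covariance matrix
#'
#' Reconstructs each indicator as its loading applied to the model-implied
#' component score (endogenous components replaced by their structural
#' predictions, recursively from the exogenous components) and returns the
#' covariance of the reconstruction, with unit diagonal for indicators of
#' single-indicator observed constructs.
#'
#' @param object an \linkS4class{IGFit}.
#' @return covariance matrix over the model's indicators.
#' @export
setGeneric("reproducedCovariance", function(object) standardGeneric("reproducedCovariance"))
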