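#' Bootstrap standard errors and percentile confidence intervals
#'
#' Resamples rows with replacement and refits the model at the fixed ridge
#' penalty for each resample (warm-started from the full-sample weights).
#' Because component scores are only identified up to sign, every
#' component of each refit is aligned so that its score correlates
#' positively with the full-sample component score on the resampled rows;
#' loadings, weights and paths flip with it. Standard errors are the
#' standard deviation of the aligned draws; confidence intervals are the
#' 2.5/97.5 percentiles. Resamples in which a component degenerates (e.g. a
#' constant indicator column after resampling) are discarded and redrawn,
#' with a warning when more than 1\% of draws were discarded.
#'
#' @param data an \linkS4class{IGDataset} or samples x indicators matrix.
#' @param model a \linkS4class{PathModel}.
#' @param lambda ridge penalty, held fixed across refits (typically the
#'   cross-validated value; re-tuning inside the bootstrap is not done).
#' @param nResamples number of bootstrap resamples (default 5000).
#' @param seed integer seed for the resampling.
#' @param tolerance,maxIterations passed to the refits.
#' @return an \linkS4class{IGBoot}.
#' @export
igBootstrap <- function(data, model, lambda = 0, nResamples = 5000L,
                        seed = 1L, tolerance = 1e-6,
                        maxIterations = 500L) {
  stopifnot(nResamples >= 2L)
  cm <- .compileModel(model)
  X <- .assembleIndicators(data, model)
  n <- nrow(X)
  fit <- igFit(X, model, lambda = lambda, tolerance = tolerance,
               maxIterations = maxIterations)
  fullW <- lapply(cm$name, function(nm)
    if (cm$composite[match(nm, cm$name)]) fit@weights[[nm]] else NULL)
  fullScores <- fit@scores

  edge_names <- paste(cm$name[cm$eFrom], cm$name[cm$eTo], sep = " -> ")
  pathDraws <- matrix(NA_real_, nResamples, cm$nEdges,
                      dimnames = list(NULL, edge_names))
  loadDraws <- matrix(NA_real_, nResamples, cm$p,
                      dimnames = list(NULL, cm$indicator))
  set.seed(seed)
  discarded <- 0L
  b <- 1L
  while (b <= nResamples) {
    idx <- sample.int(n, n, replace = TRUE)
    st <- tryCatch({
      Zb <- standardizeColumns(X[idx, , drop = FALSE])
      .fitEngine(Zb, cm, lambda = lambda, tolerance = tolerance,
                 maxIterations = maxIterations, W0 = fullW)
    }, igscaDegenerateError = function(e) NULL,
       error = function(e) {
         if (grepl("constant column", conditionMessage(e))) NULL
         else stop(e)
       })
    if (is.null(st)) {
      discarded <- discarded + 1L
      if (discarded > 100L + 10L * nResamples)
        stop("too many degenerate bootstrap resamples")
      next
    }
    ## sign alignment against the full-sample scores on the same rows
    s <- rep(1, cm$C)
    ref <- fullScores[idx, , drop = FALSE]
    for (j in seq_len(cm$C)) {
      if (!cm$multi[j] && !(j %in% cm$inter)) next  # fixed-sign constructs
      cc <- sum(st$Gamma[, j] * ref[, j])
      if (is.finite(cc) && cc < 0) s[j] <- -1
    }
    B <- st$B * outer(s, s)
    Load <- st$Load
    for (j in which(s < 0 & cm$composite))
      Load[cm$indIdx[[j]]] <- -Load[cm$indIdx[[j]]]
    pathDraws[b, ] <- B[cbind(cm$eFrom, cm$eTo)]
    loadDraws[b, ] <- Load
    b <- b + 1L
  }
  if (discarded > 0.01 * nResamples)
    warning(discarded, " degenerate resample(s) discarded and redrawn (> 1%)",
            call. = FALSE)

  summarize <- function(draws, est) {
    qs <- apply(draws, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
    data.frame(estimate = est,
               se = apply(draws, 2, sd),
               lower = qs[1, ], upper = qs[2, ],
               row.names = NULL)
  }
  pathTable <- cbind(fit@paths[, c("from", "to")],
                     summarize(pathDraws, fit@paths$estimate))
  loadingTable <- cbind(fit@loadings[, c("construct", "indicator")],
                        summarize(loadDraws, fit@loadings$loading))
  methods::new("IGBoot", fit = fit, pathDraws = pathDraws,
               loadingDraws = loadDraws, pathTable = pathTable,
               loadingTable = loadingTable,
               nResamples = as.numeric(nResamples),
               nDiscarded = as.numeric(discarded),
               seed = as.numeric(seed))
}

#' Bootstrap result tables
#'
#' \code{pathTable()} returns the structural coefficients with SEs and
#' percentile 95\% CIs; \code{loadingTable()} the same for loadings.
#'
#' @param object an \linkS4class{IGBoot}.
#' @return data.frame.
#' @name igBoot-accessors
#' @export
pathTable <- function(object) {
  stopifnot(methods::is(object, "IGBoot"))
  object@pathTable
}

#' @rdname igBoot-accessors
#' @export
loadingTable <- function(object) {
  stopifnot(methods::is(object, "IGBoot"))
  object@loadingTable
}

#' @describeIn significantPaths strict zero-exclusion on the unrounded
#'   percentile bounds.
#' @export
setMethod("significantPaths", "IGBoot", function(object) {
  tab <- object@pathTable
  tab[tab$lower > 0 | tab$upper < 0, , drop = FALSE]
})

#' @describeIn indirectEffect per-resample products of the aligned draws.
#' @export
setMethod("indirectEffect", signature("IGBoot", "character"),
          function(object, chain) {
  if (length(chain) < 2L)
    stop("chain needs at least two constructs")
  fit <- object@fit
  legs <- paste(chain[-length(chain)], chain[-1], sep = " -> ")
  missing <- setdiff(legs, colnames(object@pathDraws))
  if (length(missing))
    stop("chain is not a directed path in the model: ",
         paste(missing, collapse = ", "))
  key <- paste(fit@paths$from, fit@paths$to, sep = " -> ")
  est <- prod(fit@paths$estimate[match(legs, key)])
  draws <- apply(object@pathDraws[, legs, drop = FALSE], 1, prod)
  data.frame(chain = paste(chain, collapse = " -> "),
             estimate = est,
             se = sd(draws),
             lower = quantile(draws, 0.025, names = FALSE),
             upper = quantile(draws, 0.975, names = FALSE),
             row.names = NULL)
})

setMethod("show", "IGBoot", function(object) {
  cat("IGBoot:", object@nResamples, "resamples (",
      object@nDiscarded, "discarded ), lambda =", object@fit@lambda, "\n")
  cat("  significant paths (95% CI excludes 0):",
      nrow(significantPaths(object)), "of", nrow(object@pathTable), "\n")
})
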