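#' Run the full study analysis pipeline
#'
#' Orchestrates the end-to-end analysis on an assembled dataset: build (or
#' accept) the path model, select the ridge penalty by repeated k-fold
#' cross-validation (or use a fixed penalty), fit, bootstrap all parameters,
#' screen significant paths, compute the requested indirect effects, and
#' compute overall fit indices. All result tables are written as TSV to
#' \code{outDir} together with a machine-readable JSON manifest of seeds
#' and settings; the bundle is a deterministic function of the manifest.
#'
#' @param dataset an \linkS4class{IGDataset}.
#' @param model a \linkS4class{PathModel} or \code{"study"} for the packaged
#'   study model.
#' @param lambda fixed ridge penalty; \code{NULL} selects it by
#'   cross-validation. Exactly one of \code{lambda} / CV is active.
#' @param lambdaGrid,nFolds,nRepeats cross-validation settings (used only
#'   when \code{lambda} is NULL).
#' @param nResamples bootstrap resamples (default 500 for desk-scale runs;
#'   set 5000 for full-precision intervals).
#' @param seed integer seed governing CV partitions and bootstrap draws.
#' @param chains list of character vectors naming mediation chains to
#'   report; \code{NULL} auto-enumerates every gene -> ROI -> outcome chain
#'   whose two legs are both significant, always adding the
#'   HTR3A -> ACgG -> PTSD and NR3C1 -> CO -> PTSD chains when present in
#'   the model.
#' @param outDir output directory for the report bundle (created); NULL
#'   skips writing.
#' @return invisibly, a list with the fit, bootstrap, CV result (if any),
#'   fit indices, significant paths, mediation table and manifest.
#' @export
runStudyPipeline <- function(dataset, model = "study", lambda = NULL,
                             lambdaGrid = defaultLambdaGrid(),
                             nFolds = 5L, nRepeats = 10L,
                             nResamples = 500L, seed = 1L,
                             chains = NULL, outDir = NULL) {
  if (identical(model, "study")) model <- buildStudyModel()
  stopifnot(methods::is(model, "PathModel"))
  cv <- NULL
  if (is.null(lambda)) {
    cv <- selectLambda(dataset, model, lambdaGrid = lambdaGrid,
                       nFolds = nFolds, nRepeats = nRepeats, seed = seed)
    lambda <- cv@selected
  }
  boot <- igBootstrap(dataset, model, lambda = lambda,
                      nResamples = nResamples, seed = seed)
  fit <- boot@fit
  indices <- fitIndices(fit)
  sig <- significantPaths(boot)

  if (is.null(chains)) {
    chains <- .enumerateChains(model, sig)
  }
  mediation <- if (length(chains))
    do.call(rbind, lapply(chains, function(ch) indirectEffect(boot, ch)))
  else data.frame()

  r2tab <- data.frame(construct = names(rSquared(fit)),
                      r2 = unname(rSquared(fit)))
  r2tab <- rbind(r2tab, data.frame(construct = "Average",
                                   r2 = mean(rSquared(fit))))
  manifest <- list(package = as.character(packageVersion("igsca")),
                   seed = seed, lambda = lambda,
                   lambdaSelectedByCV = !is.null(cv),
                   nResamples = nResamples,
                   nFolds = if (is.null(cv)) NULL else nFolds,
                   nRepeats = if (is.null(cv)) NULL else nRepeats,
                   nSamples = ncol(dataset),
                   nPaths = countFreePaths(model),
                   converged = fit@converged,
                   iterations = fit@details$iterations,
                   criterionTrace = fit@criterionTrace,
                   fitIndices = indices[c("fit", "gfi", "srmr")])
  out <- list(fit = fit, bootstrap = boot, cv = cv, fitIndices = indices,
              loadings = loadingTable(boot), paths = pathTable(boot),
              r2 = r2tab, significant = sig, mediation = mediation,
              manifest = manifest)
  if (!is.null(outDir)) .writeBundle(out, outDir)
  invisible(out)
}

.enumerateChains <- function(model, sig) {
  cons <- model@constructs
  outcome <- cons$name[cons$kind == "outcome"]
  genes <- cons$name[cons$kind == "composite" &
                       cons$name %in% unique(geneMap()$gene)]
  rois <- setdiff(cons$name[cons$kind == "composite"], genes)
  sig_key <- paste(sig$from, sig$to)
  chains <- list()
  for (g in genes) for (m in rois) {
    if (paste(g, m) %in% sig_key && paste(m, outcome) %in% sig_key)
      chains[[length(chains) + 1L]] <- c(g, m, outcome)
  }
  # always report the two focal chains when the constructs are in the model
  for (focal in list(c("HTR3A", "ACgG", "PTSD"), c("NR3C1", "CO", "PTSD")))
    if (all(focal %in% cons$name) &&
        !any(vapply(chains, identical, logical(1), y = focal)))
      chains[[length(chains) + 1L]] <- focal
  chains
}

.writeBundle <- function(out, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f)
    utils::write.table(x, file.path(outDir, f), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  wt(out$loadings, "loadings.tsv")
  wt(out$paths, "paths.tsv")
  wt(out$r2, "r2.tsv")
  wt(out$significant, "significant_paths.tsv")
  if (nrow(out$mediation)) wt(out$mediation, "indirect_effects.tsv")
  if (!is.null(out$cv)) wt(cvTable(out$cv), "cv_curve.tsv")
  jsonlite::write_json(out$manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outDir)
}
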