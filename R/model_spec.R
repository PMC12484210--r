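#' Construct a path model
#'
#' Low-level constructor; most users want [buildStudyModel()]. Interaction
#' constructs carry no indicators and are defined as the standardized product
#' of their two parent component scores.
#'
#' @param constructs data.frame with \code{name}, \code{kind}.
#' @param indicators data.frame with \code{indicator}, \code{construct}.
#' @param edges data.frame with \code{from}, \code{to}.
#' @param interactions data.frame with \code{construct}, \code{parent1},
#'   \code{parent2} (may be empty).
#' @return a validated \linkS4class{PathModel}.
#' @export
PathModel <- function(constructs, indicators, edges,
                      interactions = data.frame(construct = character(0),
                                                parent1 = character(0),
                                                parent2 = character(0))) {
  methods::new("PathModel",
               constructs = as.data.frame(constructs),
               indicators = as.data.frame(indicators),
               interactions = as.data.frame(interactions),
               edges = as.data.frame(edges))
}

.is_acyclic <- function(nodes, edges) {
  # Kahn's algorithm; returns topological order or NULL if cyclic
  order <- character(0)
  edges <- edges[, c("from", "to")]
  remaining <- nodes
  repeat {
    indeg <- table(factor(edges$to, levels = remaining))
    src <- remaining[indeg[remaining] == 0]
    if (!length(src)) break
    order <- c(order, src)
    remaining <- setdiff(remaining, src)
    edges <- edges[!(edges$from %in% src), , drop = FALSE]
    if (!length(remaining)) return(order)
  }
  if (length(remaining)) NULL else order
}

#' @describeIn validateModel returns violations of the structural rules.
#' @export
setMethod("validateModel", "PathModel", function(model) {
  v <- character(0)
  cons <- model@constructs
  if (!all(c("name", "kind") %in% colnames(cons)))
    return("constructs must have 'name' and 'kind' columns")
  if (anyDuplicated(cons$name))
    v <- c(v, "duplicated construct names")
  bad_kind <- setdiff(unique(cons$kind), .CONSTRUCT_KINDS)
  if (length(bad_kind))
    v <- c(v, paste("unknown construct kind:", paste(bad_kind, collapse = ", ")))
  ind <- model@indicators
  if (anyDuplicated(ind$indicator))
    v <- c(v, "indicator assigned to more than one construct")
  if (length(setdiff(ind$construct, cons$name)))
    v <- c(v, "indicator assigned to undefined construct")
  n_ind <- table(factor(ind$construct, levels = cons$name))
  comp <- cons$kind == "composite"
  if (any(n_ind[cons$name[comp]] < 1))
    v <- c(v, "composite construct without indicators")
  single <- cons$kind %in% c("observed", "outcome")
  if (any(n_ind[cons$name[single]] != 1))
    v <- c(v, "observed/outcome constructs need exactly one indicator")
  inter <- cons$name[cons$kind == "interaction"]
  if (any(n_ind[inter] != 0))
    v <- c(v, "interaction constructs must not have indicators")
  it <- model@interactions
  if (!setequal(it$construct, inter))
    v <- c(v, "interaction table does not match interaction constructs")
  for (i in seq_len(nrow(it))) {
    pp <- c(it$parent1[i], it$parent2[i])
    if (!all(pp %in% cons$name))
      v <- c(v, paste0("interaction ", it$construct[i], ": undefined parent"))
    else if (any(cons$kind[match(pp, cons$name)] == "interaction"))
      v <- c(v, paste0("interaction ", it$construct[i],
                       ": parent is itself an interaction"))
  }
  ed <- model@edges
  if (nrow(ed)) {
    if (length(setdiff(c(ed$from, ed$to), cons$name)))
      v <- c(v, "edge endpoint is not a defined construct")
    if (anyDuplicated(ed[, c("from", "to")]))
      v <- c(v, "duplicated edges")
    if (any(ed$to %in% inter))
      v <- c(v, "interaction constructs cannot receive structural paths")
    if (is.null(.is_acyclic(cons$name, ed)))
      v <- c(v, "structural edge graph contains a cycle")
  }
  v
})

#' @describeIn countFreePaths number of structural edges of the model.
#' @export
setMethod("countFreePaths", "PathModel", function(model) nrow(model@edges))

setMethod("show", "PathModel", function(object) {
  k <- table(factor(object@constructs$kind, levels = .CONSTRUCT_KINDS))
  cat("PathModel:", nrow(object@constructs), "constructs (",
      k[["composite"]], "composite,", k[["interaction"]], "interaction,",
      k[["observed"]], "observed,", k[["outcome"]], "outcome ),",
      nrow(object@indicators), "indicators,",
      nrow(object@edges), "structural paths\n")
})

#' Build the study path model
#'
#' Constructs the full hypothesized model: gene composites from their SNP
#' dosages, ROI composites from their part volumes, single-indicator
#' constructs for PTE, the outcome severity, and the covariates (gender,
#' age, AUDIT), plus one gene-by-PTE interaction construct per gene. Edges:
#' every gene, PTE, every interaction and every covariate predicts every
#' ROI; every ROI, PTE and every covariate predicts the outcome. There are
#' no direct gene-to-outcome or interaction-to-outcome paths. With the
#' packaged maps this yields 22 predictors for each of 60 ROIs plus 64
#' predictors of severity: 1,384 structural paths.
#'
#' @param genes gene map (see [geneMap()]).
#' @param rois ROI map (see [roiMap()]).
#' @param roiSubset optional character vector of ROI construct names to
#'   restrict the mediators to a submodel.
#' @return a \linkS4class{PathModel}.
#' @examples
#' m <- buildStudyModel()
#' countFreePaths(m)  # 1384
#' @export
buildStudyModel <- function(genes = geneMap(), rois = roiMap(),
                            roiSubset = NULL) {
  gene_names <- unique(genes$gene)
  if (!is.null(roiSubset)) {
    missing <- setdiff(roiSubset, rois$construct)
    if (length(missing))
      stop("unknown ROI construct(s): ", paste(missing, collapse = ", "))
    rois <- rois[rois$construct %in% roiSubset, , drop = FALSE]
  }
  roi_names <- unique(rois$construct)
  if (!length(gene_names) || !length(roi_names))
    stop("gene and ROI maps must be non-empty")
  inter_names <- paste0(gene_names, "xPTE")
  covs <- c("gender", "age", "AUDIT")

  constructs <- data.frame(
    name = c(gene_names, "PTE", inter_names, covs, roi_names, "PTSD"),
    kind = c(rep("composite", length(gene_names)), "observed",
             rep("interaction", length(inter_names)),
             rep("observed", length(covs)),
             rep("composite", length(roi_names)), "outcome"),
    stringsAsFactors = FALSE)

  indicators <- rbind(
    data.frame(indicator = genes$rs_id, construct = genes$gene),
    data.frame(indicator = "pte", construct = "PTE"),
    data.frame(indicator = c("gender", "age", "audit"), construct = covs),
    data.frame(indicator = rois$indicator, construct = rois$construct),
    data.frame(indicator = "severity", construct = "PTSD"))

  interactions <- data.frame(construct = inter_names,
                             parent1 = gene_names, parent2 = "PTE",
                             stringsAsFactors = FALSE)

  roi_pred <- c(gene_names, "PTE", inter_names, covs)
  edges <- rbind(
    expand.grid(from = roi_pred, to = roi_names,
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE),
    data.frame(from = c(roi_names, "PTE", covs), to = "PTSD",
               stringsAsFactors = FALSE))

  PathModel(constructs, indicators, edges, interactions)
}

#' Read/write a path model as JSON
#'
#' The declarative on-disk format lists constructs (name, kind, indicators
#' or interaction parents) and edges, so alternative models can be specified
#' without code changes. Serialization round-trips losslessly.
#'
#' @param model a \linkS4class{PathModel}.
#' @param path file path.
#' @return \code{writePathModel} returns \code{path} invisibly;
#'   \code{readPathModel} returns a \linkS4class{PathModel}.
#' @name modelIO
#' @export
writePathModel <- function(model, path) {
  obj <- list(constructs = model@constructs,
              indicators = model@indicators,
              interactions = model@interactions,
              edges = model@edges)
  jsonlite::write_json(obj, path, dataframe = "rows", digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname modelIO
#' @export
readPathModel <- function(path) {
  obj <- jsonlite::fromJSON(path)
  inter <- obj$interactions
  if (is.null(inter) || !length(inter))
    inter <- data.frame(construct = character(0), parent1 = character(0),
                        parent2 = character(0))
  PathModel(obj$constructs, obj$indicators, obj$edges, inter)
}
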