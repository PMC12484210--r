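#' Packaged gene-to-SNP map
#'
#' The nine candidate genes and their 18 SNP indicators, with wild-type
#' genotype, minor allele, and observed genotype class counts in the study
#' sample (N = 231). The mutant count for rs4713916 is the renormalized
#' remainder of the sample after the wild and heterozygous classes, because
#' the printed class percentages for that SNP are internally inconsistent.
#'
#' @return data.frame with columns \code{gene}, \code{rs_id},
#'   \code{wild_genotype}, \code{minor_allele}, \code{n_wild},
#'   \code{n_hetero}, \code{n_mutant}.
#' @examples
#' head(geneMap())
#' @export
geneMap <- function() {
  path <- system.file("extdata", "gene_map.json", package = "igsca",
                      mustWork = TRUE)
  jsonlite::fromJSON(path)
}

#' Packaged ROI construct map
#'
#' The 60 brain region-of-interest constructs and their volume indicators
#' (left/right parts; six parts for the inferior frontal gyrus, a single
#' right part for the inferior lateral ventricles), with per-indicator volume
#' means and standard deviations in cm^3 used by the synthetic-data
#' generator.
#'
#' @return data.frame with columns \code{construct}, \code{label},
#'   \code{indicator}, \code{mean}, \code{sd}.
#' @examples
#' nrow(roiMap())         # 123 indicators
#' length(unique(roiMap()$construct))  # 60 constructs
#' @export
roiMap <- function() {
  path <- system.file("extdata", "roi_map.json", package = "igsca",
                      mustWork = TRUE)
  jsonlite::fromJSON(path)
}

#' Genotype class frequencies
#'
#' Per-SNP proportions of the wild, heterozygous and mutant genotype classes
#' (dosage 0, 1, 2), derived from the packaged counts.
#'
#' @param map gene map, as returned by [geneMap()].
#' @return data.frame with columns \code{rs_id}, \code{p0}, \code{p1},
#'   \code{p2} summing to one per SNP.
#' @export
genotypeFrequencies <- function(map = geneMap()) {
  tot <- map$n_wild + map$n_hetero + map$n_mutant
  data.frame(rs_id = map$rs_id,
             p0 = map$n_wild / tot,
             p1 = map$n_hetero / tot,
             p2 = map$n_mutant / tot)
}

#' Default planted structural effects for the synthetic-data generator
#'
#' The six structural coefficients forming the reported mediation structure:
#' two gene-to-ROI effects (HTR3A to the anterior cingulate gyrus, NR3C1 to
#' the central operculum), three ROI-to-severity effects, and the direct
#' PTE-to-severity effect. All structural edges not listed are planted at
#' zero.
#'
#' @return data.frame with columns \code{from}, \code{to}, \code{estimate}.
#' @export
plantedPathDefaults <- function() {
  data.frame(
    from = c("HTR3A", "NR3C1", "CO", "OFuG", "ACgG", "PTE"),
    to   = c("ACgG", "CO", "PTSD", "PTSD", "PTSD", "PTSD"),
    estimate = c(-0.11, 0.09, -0.11, -0.13, -0.10, 0.35),
    stringsAsFactors = FALSE
  )
}
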