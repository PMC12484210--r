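#' Count minor alleles in a genotype call
#'
#' Converts two-letter genotype strings (order-insensitive) into minor-allele
#' dosages: 0 for the wild type, 1 for heterozygotes, 2 for mutant
#' homozygotes.
#'
#' @param genotype character vector of two-letter genotypes, e.g. "AG".
#' @param snp a one-row data.frame or list with \code{rs_id},
#'   \code{wild_genotype} and \code{minor_allele} (a row of [geneMap()]).
#' @return integer vector of dosages in 0..2.
#' @examples
#' snp <- geneMap()[geneMap()$rs_id == "rs25531", ]
#' codeMinorAlleles(c("AA", "AG", "GG"), snp)
#' @export
codeMinorAlleles <- function(genotype, snp) {
  minor <- as.character(snp$minor_allele)
  major <- setdiff(strsplit(as.character(snp$wild_genotype), "")[[1]], minor)
  if (length(major) == 0)  # wild genotype is homozygous major
    major <- substr(as.character(snp$wild_genotype), 1, 1)
  alleles <- strsplit(toupper(genotype), "")
  vapply(seq_along(alleles), function(i) {
    a <- alleles[[i]]
    if (length(a) != 2L || !all(a %in% c(major, minor)))
      stop("invalid genotype '", genotype[i], "' for ", snp$rs_id,
           " (alleles ", major, "/", minor, ")", call. = FALSE)
    sum(a == minor)
  }, integer(1))
}

#' Convert a table of genotype strings to dosages
#'
#' @param x data.frame with a \code{sample_id} column and one two-letter
#'   genotype column per SNP (named by rs id).
#' @param map gene map, see [geneMap()].
#' @return data.frame of sample_id plus integer dosage columns.
#' @export
codeGenotypeTable <- function(x, map = geneMap()) {
  stopifnot("sample_id" %in% colnames(x))
  rs <- intersect(map$rs_id, colnames(x))
  if (!length(rs)) stop("no SNP columns from the gene map found")
  out <- x[, "sample_id", drop = FALSE]
  for (id in rs) {
    snp <- map[map$rs_id == id, ]
    g <- x[[id]]
    d <- rep(NA_integer_, length(g))
    ok <- !is.na(g)
    d[ok] <- codeMinorAlleles(g[ok], snp)
    out[[id]] <- d
  }
  out
}

#' Relative ROI volumes
#'
#' Divides every part volume by the subject's total brain volume, turning
#' absolute cm^3 volumes into dimensionless relative sizes that adjust for
#' individual differences in overall brain volume.
#'
#' @param volumes data.frame with \code{sample_id}, one column per ROI part
#'   (cm^3), and \code{total_brain_volume} (cm^3).
#' @return the same table with part volumes replaced by ratios in (0, 1];
#'   the \code{total_brain_volume} column is dropped.
#' @export
relativeVolumes <- function(volumes) {
  stopifnot(all(c("sample_id", "total_brain_volume") %in% colnames(volumes)))
  tot <- volumes$total_brain_volume
  bad <- !is.na(tot) & tot <= 0
  if (any(bad))
    stop("non-positive total brain volume for sample(s) ",
         paste(volumes$sample_id[bad], collapse = ", "))
  parts <- setdiff(colnames(volumes), c("sample_id", "total_brain_volume"))
  out <- volumes[, c("sample_id", parts)]
  out[parts] <- volumes[parts] / tot
  out
}

#' Assemble a complete dataset by listwise exclusion
#'
#' Joins the genotype, relative ROI volume and phenotype tables on
#' \code{sample_id} and keeps only samples present and complete in all
#' three; any sample with a missing value anywhere is dropped entirely.
#' The number of excluded samples is reported with a message.
#'
#' @param genotypes data.frame: \code{sample_id} plus dosage columns (0/1/2).
#' @param volumes data.frame of relative volumes (see [relativeVolumes()]).
#' @param phenotypes data.frame: \code{sample_id}, \code{pte},
#'   \code{severity}, \code{gender}, \code{age}, \code{audit}.
#' @return an \linkS4class{IGDataset}.
#' @export
listwiseExclude <- function(genotypes, volumes, phenotypes) {
  for (tab in list(genotypes, volumes, phenotypes))
    if (!"sample_id" %in% colnames(tab))
      stop("all tables need a sample_id column")
  complete_ids <- function(tab)
    tab$sample_id[complete.cases(tab)]
  keep <- Reduce(intersect, list(complete_ids(genotypes),
                                 complete_ids(volumes),
                                 complete_ids(phenotypes)))
  all_ids <- unique(c(genotypes$sample_id, volumes$sample_id,
                      phenotypes$sample_id))
  if (!length(keep))
    stop("no samples remain after listwise exclusion")
  n_excluded <- length(all_ids) - length(keep)
  message(n_excluded, " sample(s) excluded listwise; ", length(keep),
          " retained")
  g <- genotypes[match(keep, genotypes$sample_id), , drop = FALSE]
  v <- volumes[match(keep, volumes$sample_id), , drop = FALSE]
  p <- phenotypes[match(keep, phenotypes$sample_id), , drop = FALSE]

  snp_cols <- setdiff(colnames(g), "sample_id")
  roi_cols <- setdiff(colnames(v), c("sample_id", "total_brain_volume"))
  assay <- t(cbind(as.matrix(g[snp_cols]), as.matrix(v[roi_cols])))
  colnames(assay) <- keep
  rowdat <- S4Vectors::DataFrame(
    type = rep(c("snp", "roi"), c(length(snp_cols), length(roi_cols))),
    row.names = rownames(assay))
  coldat <- S4Vectors::DataFrame(p[setdiff(colnames(p), "sample_id")],
                                 row.names = keep)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(indicators = assay), rowData = rowdat, colData = coldat)
  methods::new("IGDataset", se)
}

#' Dataset part accessors
#'
#' \code{genotypes()} returns the samples x SNPs dosage matrix,
#' \code{roiVolumes()} the samples x parts relative-volume matrix, and
#' \code{phenotypes()} the phenotype/covariate data.frame.
#'
#' @param x an \linkS4class{IGDataset}.
#' @return matrix or data.frame with samples as rows.
#' @name genotypes
#' @aliases genotypes,IGDataset-method roiVolumes,IGDataset-method
#'   phenotypes,IGDataset-method
NULL

#' @rdname genotypes
setMethod("genotypes", "IGDataset", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  t(SummarizedExperiment::assay(x, "indicators")[rd$type == "snp", ,
                                                 drop = FALSE])
})

#' @rdname genotypes
setMethod("roiVolumes", "IGDataset", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  t(SummarizedExperiment::assay(x, "indicators")[rd$type == "roi", ,
                                                 drop = FALSE])
})

#' @rdname genotypes
setMethod("phenotypes", "IGDataset", function(x) {
  as.data.frame(SummarizedExperiment::colData(x))[, .PHENO_COLS]
})

setMethod("show", "IGDataset", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  cat("IGDataset:", ncol(object), "samples;",
      sum(rd$type == "snp"), "SNP dosages,",
      sum(rd$type == "roi"), "relative ROI volumes,",
      length(.PHENO_COLS), "phenotype columns\n")
})

#' Column standardization (population convention)
#'
#' Centres each column to mean zero and scales it to unit variance using the
#' population (divide-by-n) variance, so that component unit-variance
#' constraints and the loading-equals-correlation identity hold exactly.
#'
#' @param x numeric matrix (samples x variables).
#' @param center,scale optional vectors of precomputed centres/scales (used
#'   to standardize held-out folds with training-fold parameters).
#' @return standardized matrix with attributes \code{center} and
#'   \code{scale}.
#' @export
standardizeColumns <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- sqrt(colMeans(sweep(x, 2L, center)^2))
    zero <- scale < 1e-12
    if (any(zero))
      stop("constant column(s): ",
           paste(colnames(x)[zero], collapse = ", "), call. = FALSE)
  }
  z <- sweep(sweep(x, 2L, center), 2L, scale, "/")
  attr(z, "center") <- center
  attr(z, "scale") <- scale
  z
}

.read_table <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = FALSE,
                         fileEncoding = "UTF-8")
  if (colnames(x)[1] != "sample_id")
    colnames(x)[1] <- "sample_id"
  x$sample_id <- as.character(x$sample_id)
  x
}

#' Read the delimited input tables
#'
#' CSV or TSV (by extension), UTF-8, first column \code{sample_id}.
#' \code{readGenotypeTable()} accepts either precoded dosages or two-letter
#' genotype strings (normalized to dosages through the gene map).
#'
#' @param path file path.
#' @param map gene map used to code genotype strings.
#' @return data.frame.
#' @name readers
#' @export
readGenotypeTable <- function(path, map = geneMap()) {
  x <- .read_table(path)
  rs <- setdiff(colnames(x), "sample_id")
  is_string <- vapply(rs, function(cc) is.character(x[[cc]]), logical(1))
  if (any(is_string)) x <- codeGenotypeTable(x, map)
  x
}

#' @rdname readers
#' @export
readRoiVolumeTable <- function(path) {
  x <- .read_table(path)
  parts <- setdiff(colnames(x), c("sample_id", "total_brain_volume"))
  vals <- as.matrix(x[parts])
  if (any(vals <= 0, na.rm = TRUE))
    stop("non-positive ROI volumes in ", path)
  if ("total_brain_volume" %in% colnames(x)) {
    over <- vals > x$total_brain_volume
    if (any(over, na.rm = TRUE))
      stop("part volume exceeds total brain volume in ", path)
  }
  x
}

#' @rdname readers
#' @export
readPhenotypeTable <- function(path) {
  x <- .read_table(path)
  need <- setdiff(.PHENO_COLS, colnames(x))
  if (length(need))
    stop("phenotype table missing column(s): ", paste(need, collapse = ", "))
  x
}

#' Write the three dataset tables as CSV
#'
#' @param dataset an \linkS4class{IGDataset}.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
writeDatasetTables <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- list(
    genotypes = data.frame(sample_id = colnames(dataset),
                           genotypes(dataset), check.names = FALSE),
    roi_volumes = data.frame(sample_id = colnames(dataset),
                             roiVolumes(dataset), check.names = FALSE),
    phenotypes = data.frame(sample_id = colnames(dataset),
                            phenotypes(dataset), check.names = FALSE))
  paths <- character(0)
  for (nm in names(tabs)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tabs[[nm]], p, row.names = FALSE, fileEncoding = "UTF-8")
    paths <- c(paths, p)
  }
  invisible(paths)
}
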