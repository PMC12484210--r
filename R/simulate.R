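#' Simulate SNP genotype dosages
#'
#' Draws minor-allele dosages whose marginal genotype class frequencies
#' match the packaged per-SNP proportions in expectation. SNPs within the
#' same gene are correlated through a latent Gaussian threshold (copula)
#' scheme with equicorrelation \code{withinGeneLd} on the latent scale;
#' SNPs in different genes are independent. An infeasible equicorrelation
#' for a gene's SNP count is reduced to the feasible bound with a warning.
#'
#' @param n number of samples.
#' @param seed optional integer seed.
#' @param withinGeneLd latent within-gene correlation (default 0.8).
#' @param map gene map with genotype counts, see [geneMap()].
#' @return data.frame: \code{sample_id} plus one integer dosage column per
#'   SNP.
#' @export
simulateGenotypes <- function(n, seed = NULL, withinGeneLd = 0.8,
                              map = geneMap()) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(withinGeneLd > -1, withinGeneLd < 1)
  freqs <- genotypeFrequencies(map)
  out <- data.frame(sample_id = sprintf("S%04d", seq_len(n)))
  for (gene in unique(map$gene)) {
    rs <- map$rs_id[map$gene == gene]
    m <- length(rs)
    rho <- withinGeneLd
    lo <- -1 / (m - 1) + 1e-9
    if (m > 1 && rho <= -1 / (m - 1)) {
      rho <- lo
      warning("within-gene correlation infeasible for ", gene,
              "; reduced to ", signif(rho, 3), call. = FALSE)
    }
    ## latent equicorrelated normals: shared factor + unique part
    if (m == 1) {
      L <- matrix(rnorm(n), n, 1)
    } else {
      shared <- rnorm(n)
      L <- sqrt(rho) * matrix(shared, n, m) +
        sqrt(1 - rho) * matrix(rnorm(n * m), n, m)
    }
    for (i in seq_len(m)) {
      p <- freqs[freqs$rs_id == rs[i], ]
      t1 <- qnorm(p$p0)
      t2 <- qnorm(p$p0 + p$p1)
      out[[rs[i]]] <- as.integer(L[, i] >= t1) + as.integer(L[, i] >= t2)
    }
  }
  out
}

# Beta-binomial count over `size` items targeting a mean and SD; falls back
# to a plain binomial when the target is not over-dispersed.
.rcount <- function(n, size, mean, sd) {
  p <- mean / size
  stopifnot(p > 0, p < 1)
  npq <- size * p * (1 - p)
  if (sd^2 <= npq) return(rbinom(n, size, p))
  rho <- (sd^2 / npq - 1) / (size - 1)   # intraclass correlation
  rho <- min(rho, 0.999)
  ab <- 1 / rho - 1
  rbinom(n, size, rbeta(n, p * ab, (1 - p) * ab))
}

#' Simulate a complete imaging-genetics dataset with known truth
#'
#' Generates a dataset with the statistical structure the analysis assumes:
#' genotype dosages at the packaged class frequencies with within-gene LD;
#' a potentially-traumatic-events count (beta-binomial over 17 items, mean
#' 3.72, SD 2.47); gender, age and AUDIT covariates at the observed sample
#' moments; ROI construct scores driven by the planted structural effects
#' (all unlisted effects are zero) with Gaussian residuals scaled to unit
#' score variance; ROI part volumes generated from their construct scores
#' so the fitted indicator-component correlation targets
#' \code{indicatorLoading}, then mapped affinely to the packaged per-part
#' volume means/SDs (cm^3) and divided out again through a simulated total
#' brain volume; and an outcome severity built from the planted ROI, PTE
#' and covariate effects, mapped to the clinical scale (28.20 +/- 20.33,
#' truncated at 0).
#'
#' @param nSamples number of samples (default 231).
#' @param seed optional integer seed; the same configuration and seed
#'   reproduce the dataset exactly.
#' @param withinGeneLd latent within-gene SNP correlation (default 0.8).
#' @param indicatorLoading target correlation between ROI indicators and
#'   their fitted component (default 0.9).
#' @param plantedPaths data.frame \code{from}, \code{to}, \code{estimate}
#'   of planted structural coefficients (default [plantedPathDefaults()]).
#' @param pteMean,pteSd target moments of the PTE count (defaults 3.72,
#'   2.47).
#' @param roiSubset optional ROI construct subset (see
#'   [buildStudyModel()]).
#' @param genes,rois resource maps.
#' @return list with \code{dataset} (an \linkS4class{IGDataset}) and
#'   \code{truth} (a \linkS4class{SyntheticTruth}).
#' @export
simulateDataset <- function(nSamples = 231L, seed = NULL,
                            withinGeneLd = 0.8, indicatorLoading = 0.9,
                            plantedPaths = plantedPathDefaults(),
                            pteMean = 3.72, pteSd = 2.47,
                            roiSubset = NULL, genes = geneMap(),
                            rois = roiMap()) {
  stopifnot(nSamples >= 10L, indicatorLoading > 0, indicatorLoading < 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nSamples
  model <- buildStudyModel(genes, rois, roiSubset = roiSubset)
  cm <- .compileModel(model)
  if (!is.null(roiSubset))
    rois <- rois[rois$construct %in% roiSubset, , drop = FALSE]
  plantedPaths <- plantedPaths[plantedPaths$from %in% cm$name &
                                 plantedPaths$to %in% cm$name, ,
                               drop = FALSE]

  geno <- simulateGenotypes(n, seed = NULL, withinGeneLd = withinGeneLd,
                            map = genes)
  pte <- .rcount(n, 17L, pteMean, pteSd)
  gender <- rbinom(n, 1L, 0.325)            # 1 = male, observed proportion
  age <- rnorm(n, 46.10, 13.49)
  audit <- pmin(.rcount(n, 40L, 3.04, 3.61), 40L)

  ## exogenous construct scores: standardized equal-weight composites
  std <- function(x) {
    s <- sqrt(mean((x - mean(x))^2))
    if (s < 1e-12) stop("degenerate simulated variable")
    (x - mean(x)) / s
  }
  scores <- matrix(0, n, cm$C, dimnames = list(NULL, cm$name))
  for (gene in unique(genes$gene)) {
    D <- as.matrix(geno[, genes$rs_id[genes$gene == gene], drop = FALSE])
    scores[, gene] <- std(rowMeans(apply(D, 2, std)))
  }
  scores[, "PTE"] <- std(pte)
  scores[, "gender"] <- std(gender)
  scores[, "age"] <- std(age)
  scores[, "AUDIT"] <- std(audit)
  scores <- .interactionScores(scores, cm)

  ## endogenous construct scores in topological order
  B <- matrix(0, cm$C, cm$C)
  pf <- match(plantedPaths$from, cm$name)
  pt_ <- match(plantedPaths$to, cm$name)
  B[cbind(pf, pt_)] <- plantedPaths$estimate
  for (j in cm$topo) {
    if (!length(cm$parents[[j]])) next
    s <- scores %*% B[, j]
    vs <- mean((s - mean(s))^2)
    if (vs >= 1) {
      stop("planted paths imply score variance >= 1 for construct ",
           cm$name[j])
    }
    scores[, j] <- std(s + rnorm(n, sd = sqrt(1 - vs)))
  }

  ## ROI part volumes: indicators from construct scores at the target
  ## fitted loading, mapped to the packaged cm^3 means/SDs
  vol <- data.frame(sample_id = geno$sample_id)
  for (rc in unique(rois$construct)) {
    ri <- rois[rois$construct == rc, , drop = FALSE]
    k <- nrow(ri)
    if (k == 1L) {
      a <- 1
    } else {
      a2 <- (k * indicatorLoading^2 - 1) / (k - 1)
      if (a2 <= 0)
        stop("indicatorLoading ", indicatorLoading,
             " infeasible for ", rc, " with ", k, " indicators")
      a <- sqrt(a2)
    }
    for (i in seq_len(k)) {
      x <- a * scores[, rc] +
        if (k == 1L) 0 else sqrt(1 - a^2) * rnorm(n)
      v <- ri$mean[i] + ri$sd[i] * x
      vol[[ri$indicator[i]]] <- pmax(v, ri$mean[i] * 0.05)
    }
  }
  vol$total_brain_volume <- rnorm(n, 1450, 20)

  severity <- pmax(28.20 + 20.33 * scores[, "PTSD"], 0)
  pheno <- data.frame(sample_id = geno$sample_id, pte = pte,
                      severity = severity, gender = gender,
                      age = age, audit = audit)

  dataset <- suppressMessages(
    listwiseExclude(geno, relativeVolumes(vol), pheno))
  truth <- methods::new("SyntheticTruth",
    plantedPaths = plantedPaths,
    indicatorLoading = indicatorLoading,
    config = list(nSamples = nSamples, seed = seed,
                  withinGeneLd = withinGeneLd, pteMean = pteMean,
                  pteSd = pteSd, roiSubset = roiSubset))
  list(dataset = dataset, truth = truth)
}

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", nrow(object@plantedPaths),
      "planted structural paths; target indicator loading",
      object@indicatorLoading, "\n")
})
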