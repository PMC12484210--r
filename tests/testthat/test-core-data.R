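test_that("minor-allele coding counts minor alleles, order-insensitively", {
  map <- geneMap()
  snp <- map[map$rs_id == "rs25531", ]
  expect_identical(codeMinorAlleles(c("AA", "AG", "GA", "GG"), snp),
                   c(0L, 1L, 1L, 2L))
  expect_error(codeMinorAlleles("AT", snp), "rs25531")
  # bijection between genotype classes and dosage for every packaged SNP
  for (i in seq_len(nrow(map))) {
    s <- map[i, ]
    major <- substr(s$wild_genotype, 1, 1)
    g <- c(s$wild_genotype,
           paste0(major, s$minor_allele),
           paste0(s$minor_allele, s$minor_allele))
    expect_identical(codeMinorAlleles(g, s), 0:2, label = s$rs_id)
  }
})

test_that("genotype string tables normalize to dosages", {
  x <- data.frame(sample_id = c("a", "b"),
                  rs25531 = c("AG", "GG"),
                  rs6265 = c("CC", NA),
                  stringsAsFactors = FALSE)
  d <- codeGenotypeTable(x)
  expect_identical(d$rs25531, c(1L, 2L))
  expect_identical(d$rs6265, c(0L, NA))
})

test_that("relative volumes divide by total brain volume", {
  v <- data.frame(sample_id = c("a", "b"),
                  p1 = c(3.0, 2.0), p2 = c(150, 700), p3 = c(0.6, 1.4),
                  total_brain_volume = c(1500, 1400))
  r <- relativeVolumes(v)
  # element-wise hand division
  expect_equal(r$p1, c(3.0 / 1500, 2.0 / 1400))
  expect_equal(r$p2, c(150 / 1500, 700 / 1400))
  expect_equal(r$p3, c(0.6 / 1500, 1.4 / 1400))
  expect_equal(r$p1[1], 0.002)
  # boundary: part equal to total gives exactly 1
  v1 <- data.frame(sample_id = "a", p1 = 10, total_brain_volume = 10)
  expect_equal(relativeVolumes(v1)$p1, 1.0)
  v$total_brain_volume[2] <- 0
  expect_error(relativeVolumes(v), "non-positive total")
})

test_that("listwise exclusion keeps exactly the complete samples", {
  set.seed(42)
  sim <- simulateDataset(nSamples = 30, seed = 5, roiSubset = ROIS5)
  g <- data.frame(sample_id = colnames(sim$dataset),
                  genotypes(sim$dataset), check.names = FALSE)
  v <- data.frame(sample_id = colnames(sim$dataset),
                  roiVolumes(sim$dataset), check.names = FALSE)
  p <- data.frame(sample_id = colnames(sim$dataset),
                  phenotypes(sim$dataset), check.names = FALSE)
  # no missing: identity
  d0 <- suppressMessages(listwiseExclude(g, v, p))
  expect_identical(colnames(d0), g$sample_id)
  # one missing SNP drops the whole sample; one sample absent from a table
  # drops it too
  g2 <- g; g2$rs25531[3] <- NA
  v2 <- v[-7, ]
  p2 <- p; p2$age[12] <- NA
  expect_message(d <- listwiseExclude(g2, v2, p2), "3 sample\\(s\\) excluded")
  # brute-force set intersection oracle
  keep <- Reduce(intersect, list(
    g2$sample_id[complete.cases(g2)],
    v2$sample_id[complete.cases(v2)],
    p2$sample_id[complete.cases(p2)]))
  expect_identical(colnames(d), keep)
  expect_equal(ncol(d), 27)
  # nothing left
  g3 <- g; g3$rs25531 <- NA
  expect_error(suppressMessages(listwiseExclude(g3, v, p)), "no samples")
})

test_that("standardization uses the population convention", {
  set.seed(1)
  x <- matrix(rnorm(40, 5, 3), 10, 4,
              dimnames = list(NULL, paste0("c", 1:4)))
  z <- standardizeColumns(x)
  # brute-force column moments
  for (j in 1:4) {
    expect_equal(mean(z[, j]), 0, tolerance = 1e-12)
    expect_equal(mean(z[, j]^2), 1, tolerance = 1e-12)
    expect_equal(unname(attr(z, "center")[j]), mean(x[, j]))
  }
  expect_equal(mean(standardizeColumns(matrix(1:3, 3, 1))[, 1]^2), 1)
  # idempotence
  z2 <- standardizeColumns(z)
  expect_equal(unclass(z2)[, ], unclass(z)[, ], tolerance = 1e-12)
  x[, 2] <- 7
  expect_error(standardizeColumns(x), "c2")
})

test_that("standardized relative volumes are invariant to per-sample global rescaling", {
  set.seed(8)
  v <- data.frame(sample_id = letters[1:8],
                  p1 = runif(8, 1, 5), p2 = runif(8, 1, 5),
                  total_brain_volume = runif(8, 1300, 1600))
  fac <- runif(8, 0.5, 2)
  v2 <- v
  v2[, c("p1", "p2", "total_brain_volume")] <-
    v[, c("p1", "p2", "total_brain_volume")] * fac
  z1 <- standardizeColumns(as.matrix(relativeVolumes(v)[, c("p1", "p2")]))
  z2 <- standardizeColumns(as.matrix(relativeVolumes(v2)[, c("p1", "p2")]))
  expect_equal(unclass(z1)[, ], unclass(z2)[, ], tolerance = 1e-12)
})

test_that("dataset tables round-trip through CSV", {
  sim <- simulateDataset(nSamples = 20, seed = 2, roiSubset = c("ACgG", "CO"))
  dir <- tempfile()
  writeDatasetTables(sim$dataset, dir)
  g <- readGenotypeTable(file.path(dir, "genotypes.csv"))
  v <- readRoiVolumeTable(file.path(dir, "roi_volumes.csv"))
  p <- readPhenotypeTable(file.path(dir, "phenotypes.csv"))
  d <- suppressMessages(listwiseExclude(g, v, p))
  expect_equal(genotypes(d), genotypes(sim$dataset), tolerance = 1e-12)
  expect_equal(roiVolumes(d), roiVolumes(sim$dataset), tolerance = 1e-12)
  expect_equal(phenotypes(d), phenotypes(sim$dataset), tolerance = 1e-12)
})

test_that("packaged resources have the study cardinalities", {
  gm <- geneMap()
  expect_equal(length(unique(gm$gene)), 9)
  expect_equal(nrow(gm), 18)
  expect_true(all(gm$n_wild + gm$n_hetero + gm$n_mutant == 231))
  fr <- genotypeFrequencies()
  expect_equal(fr$p0 + fr$p1 + fr$p2, rep(1, 18))
  rm_ <- roiMap()
  expect_equal(length(unique(rm_$construct)), 60)
  expect_equal(nrow(rm_), 123)
  expect_equal(sum(rm_$construct == "IFG"), 6)
  expect_equal(sum(rm_$construct == "ILV"), 1)
})
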