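test_that("ALS paths at lambda = 0 equal closed-form standardized regression", {
  # X -> M -> Y chain: slopes are correlations
  d <- chainData(300, 0.6, 0.4, seed = 3)
  m <- singleIndicatorModel(data.frame(from = c("X", "M"), to = c("M", "Y")))
  fit <- igFit(d, m, lambda = 0)
  pc <- pathCoefficients(fit)
  expect_equal(pc$estimate[pc$from == "X"], cor(d[, "x"], d[, "m"]),
               tolerance = 1e-8)
  expect_equal(pc$estimate[pc$from == "M"], cor(d[, "m"], d[, "y"]),
               tolerance = 1e-8)

  # two correlated predictors: b = Rxx^{-1} rxy
  set.seed(9)
  R <- matrix(c(1, .5, .3, .5, 1, .2, .3, .2, 1), 3)
  d2 <- rmvn(400, R, c("a", "b", "y"))
  m2 <- singleIndicatorModel(data.frame(from = c("A", "B"), to = c("Y", "Y")))
  fit2 <- igFit(d2, m2, lambda = 0)
  S <- cor(d2)
  oracle <- solve(S[c("a", "b"), c("a", "b")], S[c("a", "b"), "y"])
  pc2 <- pathCoefficients(fit2)
  expect_equal(pc2$estimate[match(c("A", "B"), pc2$from)], unname(oracle),
               tolerance = 1e-8)
})

test_that("single-indicator constructs have weight = loading = 1 and score = z", {
  d <- chainData(50, 0.5, 0.5, seed = 1)
  m <- singleIndicatorModel(data.frame(from = c("X", "M"), to = c("M", "Y")))
  fit <- igFit(d, m)
  expect_equal(indicatorLoadings(fit)$loading, rep(1, 3), tolerance = 1e-12)
  expect_equal(unname(unlist(componentWeights(fit))), rep(1, 3))
  z <- standardizeColumns(d)
  expect_equal(componentScores(fit)[, "X"], unname(z[, "x"]),
               tolerance = 1e-12)
})

test_that("an overwhelming ridge penalty zeroes paths but not loadings", {
  set.seed(4)
  Z <- cbind(rmvn(200, matrix(c(1, .7, .7, 1), 2), c("x1", "x2")),
             rmvn(200, matrix(c(1, .6, .6, 1), 2), c("y1", "y2")))
  m <- twoCompositeModel()
  m@indicators <- m@indicators[m@indicators$indicator %in% colnames(Z), ]
  fit0 <- igFit(Z, m, lambda = 0)
  fitBig <- igFit(Z, m, lambda = 1e9)
  expect_lt(max(abs(pathCoefficients(fitBig)$estimate)), 1e-5)
  expect_equal(indicatorLoadings(fitBig)$loading,
               indicatorLoadings(fit0)$loading, tolerance = 0.05)
  expect_gt(min(abs(indicatorLoadings(fitBig)$loading)), 0.5)
})

test_that("criterion is monotone non-increasing without interactions", {
  set.seed(11)
  for (seed in 1:4) {
    R <- diag(6)
    R[1:3, 1:3] <- 0.6; R[4:6, 4:6] <- 0.5; diag(R) <- 1
    R[1:3, 4:6] <- 0.25; R[4:6, 1:3] <- 0.25
    Z <- rmvn(120, R, c(paste0("x", 1:3), paste0("y", 1:3)))
    fit <- igFit(Z, twoCompositeModel(), lambda = 2, init = "random",
                 seed = seed)
    tr <- criterionTrace(fit)
    expect_true(all(diff(tr) <= 1e-10 * max(1, tr[1])))
  }
})

test_that("criterion trace converges with interaction constructs present", {
  sim <- simulateDataset(nSamples = 150, seed = 21,
                         roiSubset = c("ACgG", "CO"))
  m <- buildStudyModel(roiSubset = c("ACgG", "CO"))
  fit <- igFit(sim$dataset, m, lambda = 5, tolerance = 1e-6)
  expect_true(fit@converged)
  tr <- criterionTrace(fit)
  n_tr <- length(tr)
  expect_lt(abs(tr[n_tr] - tr[n_tr - 1]) / tr[n_tr - 1], 1e-6)
})

test_that("loadings equal indicator-component correlations", {
  sim <- simulateDataset(nSamples = 200, seed = 13, roiSubset = ROIS5)
  m <- buildStudyModel(roiSubset = ROIS5)
  fit <- igFit(sim$dataset, m, lambda = 10)
  Z <- fit@details$Z
  sc <- componentScores(fit)
  lo <- indicatorLoadings(fit)
  direct <- vapply(seq_len(nrow(lo)), function(i)
    cor(Z[, lo$indicator[i]], sc[, lo$construct[i]]), numeric(1))
  expect_equal(lo$loading, direct, tolerance = 1e-8)
  # sign convention: per-composite loading sums are positive
  sums <- tapply(lo$loading, lo$construct, sum)
  expect_true(all(sums > 0))
})

test_that("lambda = 0 estimates are invariant to indicator sign flips", {
  set.seed(17)
  R <- diag(6)
  R[1:3, 1:3] <- 0.6; R[4:6, 4:6] <- 0.5; diag(R) <- 1
  R[1:3, 4:6] <- 0.3; R[4:6, 1:3] <- 0.3
  Z <- rmvn(150, R, c(paste0("x", 1:3), paste0("y", 1:3)))
  m <- twoCompositeModel()
  fit1 <- igFit(Z, m, lambda = 0, tolerance = 1e-13, maxIterations = 2000)
  Zf <- Z; Zf[, "x2"] <- -Zf[, "x2"]
  fit2 <- igFit(Zf, m, lambda = 0, tolerance = 1e-13, maxIterations = 2000)
  expect_equal(pathCoefficients(fit2)$estimate,
               pathCoefficients(fit1)$estimate, tolerance = 1e-6)
  l1 <- indicatorLoadings(fit1)$loading
  l2 <- indicatorLoadings(fit2)$loading
  expect_equal(abs(l2), abs(l1), tolerance = 1e-6)
  expect_equal(l2[2], -l1[2], tolerance = 1e-6)
})

test_that("ridge shrinkage of the structural coefficients is monotone in lambda", {
  sim <- simulateDataset(nSamples = 231, seed = 19,
                         roiSubset = c("ACgG", "CO", "OFuG"))
  m <- buildStudyModel(roiSubset = c("ACgG", "CO", "OFuG"))
  ssq <- vapply(c(0, 5, 50, 500, 5000), function(l)
    sum(pathCoefficients(igFit(sim$dataset, m, lambda = l))$estimate^2),
    numeric(1))
  expect_true(all(diff(ssq) < 1e-10))
})

test_that("component scores: products, unit variance, closed-form composite variance", {
  set.seed(23)
  # interaction score of two uncorrelated standard-normal parents is
  # standardized exactly
  n <- 1e5
  Z <- cbind(a = rnorm(n), b = rnorm(n), y = rnorm(n))
  Z <- standardizeColumns(Z)
  m <- PathModel(
    constructs = data.frame(name = c("A", "B", "AxB", "Y"),
                            kind = c("observed", "observed", "interaction",
                                     "outcome")),
    indicators = data.frame(indicator = c("a", "b", "y"),
                            construct = c("A", "B", "Y")),
    edges = data.frame(from = c("A", "B", "AxB"), to = "Y"),
    interactions = data.frame(construct = "AxB", parent1 = "A",
                              parent2 = "B"))
  sc <- computeComponents(Z, list(), m)
  expect_equal(mean(sc[, "AxB"]), 0, tolerance = 1e-12)
  expect_equal(mean(sc[, "AxB"]^2), 1, tolerance = 1e-12)
  # raw product of independent standard normals has variance near 1 before
  # standardization (Monte-Carlo check)
  raw <- sc[, "A"] * sc[, "B"]
  expect_equal(var(raw), 1, tolerance = 0.05)

  # equal weights 1/2 on two indicators with correlation r:
  # pre-normalization variance (1 + r)/2
  r <- 0.42
  Z2 <- rmvn(2e4, matrix(c(1, r, r, 1), 2), c("x1", "x2"))
  Z2 <- standardizeColumns(Z2)
  m2 <- PathModel(
    constructs = data.frame(name = c("X", "Y"),
                            kind = c("composite", "outcome")),
    indicators = data.frame(indicator = c("x1", "x2", "y"),
                            construct = c("X", "X", "Y")),
    edges = data.frame(from = "X", to = "Y"))
  Z2 <- cbind(Z2, y = standardizeColumns(matrix(rnorm(2e4)))[, 1])
  sc2 <- computeComponents(Z2, list(X = c(0.5, 0.5)), m2, normalize = FALSE)
  robs <- cor(Z2[, "x1"], Z2[, "x2"])
  expect_equal(mean(sc2[, "X"]^2), (1 + robs) / 2, tolerance = 1e-10)
})

test_that("R-squared matches the closed-form multiple correlation", {
  set.seed(29)
  R <- matrix(c(1, .4, .5, .4, 1, .45, .5, .45, 1), 3)
  d <- rmvn(500, R, c("a", "b", "y"))
  m <- singleIndicatorModel(data.frame(from = c("A", "B"), to = c("Y", "Y")))
  fit <- igFit(d, m, lambda = 0)
  S <- cor(d)
  oracle <- drop(S["y", c("a", "b")] %*%
                   solve(S[c("a", "b"), c("a", "b")], S[c("a", "b"), "y"]))
  expect_equal(unname(rSquared(fit)["Y"]), oracle, tolerance = 1e-8)
  # trivial limits
  dx <- cbind(x = rnorm(100))
  d1 <- cbind(dx, y = dx[, "x"])
  m1 <- singleIndicatorModel(data.frame(from = "X", to = "Y"))
  expect_equal(unname(rSquared(igFit(d1, m1, lambda = 0))["Y"]), 1,
               tolerance = 1e-10)
  d0 <- cbind(x = rnorm(2000), y = rnorm(2000))
  expect_lt(unname(rSquared(igFit(d0, m1, lambda = 1e12))["Y"]), 1e-6)
})

test_that("degenerate components raise informative errors", {
  d <- cbind(x = rnorm(50), y = rnorm(50))
  m1 <- singleIndicatorModel(data.frame(from = "X", to = "Y"))
  d[, "x"] <- 3
  expect_error(igFit(d, m1), "constant column")
  expect_error(computeComponents(matrix(0, 10, 1,
                                        dimnames = list(NULL, "x1")),
                                 list(), PathModel(
    constructs = data.frame(name = "X", kind = "composite"),
    indicators = data.frame(indicator = "x1", construct = "X"),
    edges = data.frame(from = character(0), to = character(0)))),
    class = "igscaDegenerateError")
})
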