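test_that("FIT is 1 for a zero-residual model and 0 when all parameters vanish", {
  set.seed(31)
  x <- rnorm(100)
  d <- cbind(x = x, m = x, y = x)   # perfect chain
  m <- singleIndicatorModel(data.frame(from = c("X", "M"), to = c("M", "Y")))
  fit <- igFit(d, m, lambda = 0)
  expect_equal(fitIndex(fit), 1, tolerance = 1e-12)

  # forcing every loading and path to zero leaves nothing explained
  d2 <- chainData(100, 0.5, 0.5, seed = 1)
  fit2 <- igFit(d2, m, lambda = 0)
  fit2@details$Load <- fit2@details$Load * 0
  fit2@details$B <- fit2@details$B * 0
  expect_equal(fitIndex(fit2), 0, tolerance = 1e-12)
})

test_that("FIT matches a brute-force residual accounting on a toy model", {
  set.seed(33)
  R <- diag(6)
  R[1:3, 1:3] <- 0.6; R[4:6, 4:6] <- 0.5; diag(R) <- 1
  R[1:3, 4:6] <- 0.3; R[4:6, 1:3] <- 0.3
  Z <- rmvn(150, R, c(paste0("x", 1:3), paste0("y", 1:3)))
  fit <- igFit(Z, twoCompositeModel(), lambda = 0)
  Zs <- fit@details$Z
  sc <- componentScores(fit)
  lo <- indicatorLoadings(fit)
  pc <- pathCoefficients(fit)
  n <- nrow(Zs)
  sse <- 0
  for (i in seq_len(nrow(lo)))
    sse <- sse + sum((Zs[, lo$indicator[i]] -
                        sc[, lo$construct[i]] * lo$loading[i])^2)
  sse <- sse + sum((sc[, "Y"] - pc$estimate * sc[, "X"])^2)
  expect_equal(fitIndex(fit), 1 - sse / (n * (6 + 1)), tolerance = 1e-12)
  # zeroing an estimated coefficient cannot raise FIT
  fit0 <- fit
  fit0@details$B <- fit0@details$B * 0
  expect_lte(fitIndex(fit0), fitIndex(fit))
})

test_that("GFI and SRMR follow their element-wise definitions", {
  # identical matrices
  S <- diag(3)
  gs <- gfiSrmr(S, S)
  expect_equal(gs$gfi, 1)
  expect_equal(gs$srmr, 0)
  # reproduced zero, sample identity, p = 4
  gs2 <- gfiSrmr(diag(4), matrix(0, 4, 4))
  expect_equal(gs2$gfi, 0)
  expect_equal(gs2$srmr, sqrt(4 / 10))
  # random symmetric case against the brute-force formulas
  set.seed(35)
  A <- crossprod(matrix(rnorm(50), 10, 5)) / 10
  Bm <- crossprod(matrix(rnorm(50), 10, 5)) / 10
  gs3 <- gfiSrmr(A, Bm)
  D <- A - Bm
  expect_equal(gs3$gfi, 1 - sum(diag(D %*% D)) / sum(diag(A %*% A)),
               tolerance = 1e-12)
  resid <- D / sqrt(outer(diag(A), diag(A)))
  cells <- resid[lower.tri(resid, diag = TRUE)]
  expect_equal(gs3$srmr, sqrt(mean(cells^2)), tolerance = 1e-12)
  expect_error(gfiSrmr(diag(3), diag(4)), "dimension")
})

test_that("reproduced covariance reconstructs indicators sample-by-sample", {
  # saturated single-indicator chain with perfect fit
  x <- rnorm(80)
  d <- cbind(x = x, m = x, y = x)
  m <- singleIndicatorModel(data.frame(from = c("X", "M"), to = c("M", "Y")))
  fit <- igFit(d, m, lambda = 0)
  S <- crossprod(fit@details$Z) / nrow(d)
  expect_equal(unname(reproducedCovariance(fit)), unname(S),
               tolerance = 1e-10)

  # brute-force reconstruction oracle on a 4-indicator toy
  set.seed(37)
  R <- diag(4)
  R[1:2, 1:2] <- 0.7; R[3:4, 3:4] <- 0.6; diag(R) <- 1
  R[1:2, 3:4] <- 0.35; R[3:4, 1:2] <- 0.35
  Z <- rmvn(200, R, c("x1", "x2", "y1", "y2"))
  m2 <- PathModel(
    constructs = data.frame(name = c("X", "Y"), kind = "composite"),
    indicators = data.frame(indicator = c("x1", "x2", "y1", "y2"),
                            construct = c("X", "X", "Y", "Y")),
    edges = data.frame(from = "X", to = "Y"))
  fit2 <- igFit(Z, m2, lambda = 0)
  sc <- componentScores(fit2)
  lo <- indicatorLoadings(fit2)
  b <- pathCoefficients(fit2)$estimate
  implied_y <- b * sc[, "X"]            # endogenous score replaced
  Zhat <- cbind(sc[, "X"] * lo$loading[1], sc[, "X"] * lo$loading[2],
                implied_y * lo$loading[3], implied_y * lo$loading[4])
  Zhat <- sweep(Zhat, 2, colMeans(Zhat))
  oracle <- crossprod(Zhat) / nrow(Zhat)
  expect_equal(unname(reproducedCovariance(fit2)), unname(oracle),
               tolerance = 1e-10)

  # null structural model: cross-construct blocks vanish
  fit3 <- igFit(Z, m2, lambda = 1e12)
  Sig <- reproducedCovariance(fit3)
  expect_lt(max(abs(Sig[c("x1", "x2"), c("y1", "y2")])), 1e-6)
})

test_that("GFI improves and SRMR falls as the reproduced matrix approaches the sample", {
  set.seed(39)
  S <- crossprod(matrix(rnorm(60), 12, 5)) / 12
  Sig0 <- diag(diag(S))
  steps <- seq(0, 1, by = 0.25)
  gfis <- numeric(0); srmrs <- numeric(0)
  for (t in steps) {
    gs <- gfiSrmr(S, Sig0 + t * (S - Sig0))
    gfis <- c(gfis, gs$gfi); srmrs <- c(srmrs, gs$srmr)
  }
  expect_true(all(diff(gfis) > 0))
  expect_true(all(diff(srmrs) < 0))
})

test_that("fit indices report the conventional cutoff flags", {
  x <- rnorm(60)
  d <- cbind(x = x, m = x, y = x)
  m <- singleIndicatorModel(data.frame(from = c("X", "M"), to = c("M", "Y")))
  fi <- fitIndices(igFit(d, m, lambda = 0))
  expect_equal(fi$fit, 1, tolerance = 1e-10)
  expect_equal(fi$gfi, 1, tolerance = 1e-10)
  expect_equal(fi$srmr, 0, tolerance = 1e-10)
  expect_true(fi$gfiPass)   # > 0.93
  expect_true(fi$srmrPass)  # < 0.08
})
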