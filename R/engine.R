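# Internal estimation engine: compiled model representation and the
# alternating-least-squares loop. All public entry points live in fit.R.

.degenerate_stop <- function(what) {
  stop(errorCondition(paste0("degenerate component: ", what,
                             " has (near) zero variance"),
                      class = c("igscaDegenerateError", "error",
                                "condition")))
}

# Integer-indexed model representation used by the fitting loop.
.compileModel <- function(model) {
  v <- validateModel(model)
  if (length(v)) stop("invalid model: ", paste(v, collapse = "; "))
  cons <- model@constructs
  C <- nrow(cons)
  name <- cons$name
  cidx <- setNames(seq_len(C), name)
  ind <- model@indicators
  indCon <- unname(cidx[ind$construct])
  indIdx <- lapply(seq_len(C), function(j) which(indCon == j))
  edges <- model@edges
  eFrom <- unname(cidx[edges$from])
  eTo <- unname(cidx[edges$to])
  parents <- lapply(seq_len(C), function(j) eFrom[eTo == j])
  children <- lapply(seq_len(C), function(j) eTo[eFrom == j])
  it <- model@interactions
  list(C = C, p = nrow(ind), name = name, kind = cons$kind,
       indicator = ind$indicator, indCon = indCon, indIdx = indIdx,
       eFrom = eFrom, eTo = eTo, nEdges = nrow(edges),
       parents = parents, children = children,
       endo = which(lengths(parents) > 0),
       inter = unname(cidx[it$construct]),
       interParents = cbind(unname(cidx[it$parent1]),
                            unname(cidx[it$parent2])),
       composite = lengths(indIdx) > 0,
       multi = lengths(indIdx) > 1,
       topo = unname(cidx[.is_acyclic(name, edges)]))
}

# Raw indicator matrix (samples x indicators) in model order.
.assembleIndicators <- function(data, model) {
  want <- model@indicators$indicator
  if (methods::is(data, "IGDataset")) {
    x <- cbind(as.data.frame(t(SummarizedExperiment::assay(
      data, "indicators"))), phenotypes(data))
  } else {
    x <- as.data.frame(data)
  }
  missing <- setdiff(want, colnames(x))
  if (length(missing))
    stop("data lacks model indicator(s): ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) ", ...")
  as.matrix(x[, want, drop = FALSE])
}

# Standardized product scores for the interaction constructs. Returns the
# updated score matrix; records the raw-product centring/scaling in `stats`
# (an environment) when provided, so held-out samples can be scored with
# training-fold parameters.
.interactionScores <- function(Gamma, cm, stats = NULL, apply = FALSE) {
  if (!length(cm$inter)) return(Gamma)
  for (r in seq_along(cm$inter)) {
    j <- cm$inter[r]
    pdt <- Gamma[, cm$interParents[r, 1]] * Gamma[, cm$interParents[r, 2]]
    if (apply) {
      m <- stats$center[r]; s <- stats$scale[r]
    } else {
      m <- mean(pdt)
      s <- sqrt(mean((pdt - m)^2))
      if (s < 1e-12) .degenerate_stop(cm$name[j])
      if (!is.null(stats)) { stats$center[r] <- m; stats$scale[r] <- s }
    }
    Gamma[, j] <- (pdt - m) / s
  }
  Gamma
}

# Alternating least squares on standardized indicators Z.
#
# Criterion: sum of squared residuals of all indicator equations
# (Z_j ~ gamma_j loadings_j') and all structural equations
# (gamma_k ~ Gamma_parents b_k), plus lambda * sum(b^2). The ridge penalty
# applies to structural coefficients only, never to loadings or weights.
#
# A-step: loadings by per-construct least squares; incoming paths by ridge
# regression of each endogenous score on its predictors' scores.
# W-step: each multi-indicator composite's weights solve the global
# criterion exactly under the unit-variance constraint (the quadratic term
# is constant on the constraint set, so the unconstrained least-squares
# direction followed by rescaling is the exact constrained minimizer);
# interaction scores are recomputed afterwards as standardized products.
.fitEngine <- function(Z, cm, lambda = 0, tolerance = 1e-6,
                       maxIterations = 500L, W0 = NULL) {
  n <- nrow(Z)
  C <- cm$C
  W <- vector("list", C)
  Gamma <- matrix(0, n, C)
  for (j in seq_len(C)) {
    if (!cm$composite[j]) next
    idx <- cm$indIdx[[j]]
    if (length(idx) == 1L) {          # fixed unit weight
      W[[j]] <- 1
      Gamma[, j] <- Z[, idx]
      next
    }
    w <- if (!is.null(W0) && !is.null(W0[[j]])) W0[[j]] else
      rep(1 / sqrt(length(idx)), length(idx))
    g <- Z[, idx, drop = FALSE] %*% w
    s <- sqrt(sum(g * g) / n)
    if (s < 1e-12) .degenerate_stop(cm$name[j])
    W[[j]] <- w / s
    Gamma[, j] <- g / s
  }
  interStats <- new.env(parent = emptyenv())
  interStats$center <- numeric(length(cm$inter))
  interStats$scale <- numeric(length(cm$inter))
  Gamma <- .interactionScores(Gamma, cm, interStats)

  B <- matrix(0, C, C)
  Load <- numeric(cm$p)
  trace <- numeric(0)
  fprev <- Inf
  converged <- FALSE
  minnorm_warned <- FALSE

  astep <- function() {
    for (j in which(cm$composite))
      Load[cm$indIdx[[j]]] <<- crossprod(Z[, cm$indIdx[[j]], drop = FALSE],
                                         Gamma[, j]) / n
    for (k in cm$endo) {
      pa <- cm$parents[[k]]
      P <- Gamma[, pa, drop = FALSE]
      G <- crossprod(P)
      rhs <- crossprod(P, Gamma[, k])
      b <- if (lambda > 0) {
        solve(G + diag(lambda, length(pa)), rhs)
      } else {
        tryCatch(solve(G, rhs), error = function(e) {
          if (!minnorm_warned) {
            warning("rank-deficient predictor block for '", cm$name[k],
                    "' at lambda = 0; using the minimum-norm solution",
                    call. = FALSE)
            minnorm_warned <<- TRUE
          }
          MASS::ginv(G) %*% rhs
        })
      }
      B[pa, k] <<- b
    }
  }

  for (it in seq_len(maxIterations)) {
    astep()
    pred <- Gamma %*% B
    for (j in which(cm$multi)) {
      idx <- cm$indIdx[[j]]
      Zj <- Z[, idx, drop = FALSE]
      tj <- Zj %*% Load[idx]
      if (length(cm$parents[[j]])) tj <- tj + pred[, j]
      ch <- cm$children[[j]]
      for (k in ch)
        tj <- tj + B[j, k] * (Gamma[, k] - (pred[, k] - B[j, k] * Gamma[, j]))
      G <- crossprod(Zj)
      rhs <- crossprod(Zj, tj)
      w <- tryCatch(solve(G, rhs),
                    error = function(e) MASS::ginv(G) %*% rhs)
      g <- Zj %*% w
      s <- sqrt(sum(g * g) / n)
      if (s < 1e-12) .degenerate_stop(cm$name[j])
      w <- w / s
      g <- g / s
      if (length(ch))
        pred[, ch] <- pred[, ch] + (g - Gamma[, j]) %*% B[j, ch,
                                                          drop = FALSE]
      Gamma[, j] <- g
      W[[j]] <- as.numeric(w)
    }
    Gamma <- .interactionScores(Gamma, cm, interStats)
    pred <- Gamma %*% B
    Zhat <- Gamma[, cm$indCon, drop = FALSE] * rep(Load, each = n)
    f <- sum((Z - Zhat)^2) +
      sum((Gamma[, cm$endo, drop = FALSE] -
             pred[, cm$endo, drop = FALSE])^2) +
      lambda * sum(B^2)
    trace <- c(trace, f)
    if (it > 1L && abs(fprev - f) <= tolerance * max(abs(fprev), 1e-12)) {
      converged <- TRUE
      break
    }
    fprev <- f
  }
  astep()  # sync loadings and paths with the final scores

  ## Sign convention: orient each composite so the sum of its loadings is
  ## positive; interaction scores flip with the product of their parents.
  s <- rep(1, C)
  for (j in which(cm$multi))
    if (sum(Load[cm$indIdx[[j]]]) < 0) s[j] <- -1
  if (length(cm$inter))
    s[cm$inter] <- s[cm$interParents[, 1]] * s[cm$interParents[, 2]]
  if (any(s < 0)) {
    for (j in which(s < 0 & cm$composite)) {
      W[[j]] <- -W[[j]]
      Load[cm$indIdx[[j]]] <- -Load[cm$indIdx[[j]]]
    }
    Gamma <- sweep(Gamma, 2L, s, "*")
    B <- B * outer(s, s)
    Gamma <- .interactionScores(Gamma, cm, interStats)
  }

  pred <- Gamma %*% B
  r2 <- 1 - colSums((Gamma[, cm$endo, drop = FALSE] -
                       pred[, cm$endo, drop = FALSE])^2) / n
  names(r2) <- cm$name[cm$endo]

  list(W = W, Gamma = Gamma, B = B, Load = Load, r2 = r2, trace = trace,
       converged = converged, iterations = length(trace),
       interCenter = interStats$center, interScale = interStats$scale)
}
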