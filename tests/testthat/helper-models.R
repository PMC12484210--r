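# Toy model builders and data generators shared across tests.

# Model where every construct has a single indicator named tolower(name).
singleIndicatorModel <- function(edges, outcome = NULL) {
  nodes <- unique(c(edges$from, edges$to))
  if (is.null(outcome)) outcome <- nodes[length(nodes)]
  constructs <- data.frame(
    name = nodes,
    kind = ifelse(nodes == outcome, "outcome", "observed"))
  indicators <- data.frame(indicator = tolower(nodes), construct = nodes)
  PathModel(constructs, indicators, edges)
}

# Two 3-indicator composites X -> Y (no interactions), indicators x1..x3,
# y1..y3.
twoCompositeModel <- function() {
  PathModel(
    constructs = data.frame(name = c("X", "Y"),
                            kind = c("composite", "composite")),
    indicators = data.frame(indicator = c(paste0("x", 1:3), paste0("y", 1:3)),
                            construct = rep(c("X", "Y"), each = 3)),
    edges = data.frame(from = "X", to = "Y"))
}

# Correlated standard-normal columns with population correlation matrix R.
rmvn <- function(n, R, names) {
  L <- chol(R)
  Z <- matrix(rnorm(n * ncol(R)), n) %*% L
  colnames(Z) <- names
  Z
}

# Data for the X -> M -> Y chain with standardized true slopes b1, b2.
chainData <- function(n, b1, b2, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  m <- b1 * x + sqrt(1 - b1^2) * rnorm(n)
  y <- b2 * m + sqrt(1 - b2^2) * rnorm(n)
  cbind(x = x, m = m, y = y)
}

# Minimal gene/ROI resource maps with g genes (2 SNPs each) and r ROIs
# (2 indicators each), for cardinality properties.
tinyMaps <- function(g, r) {
  genes <- data.frame(
    gene = rep(paste0("G", seq_len(g)), each = 2),
    rs_id = paste0("rs", seq_len(2 * g)),
    wild_genotype = "AA", minor_allele = "G",
    n_wild = 100, n_hetero = 80, n_mutant = 51)
  rois <- data.frame(
    construct = rep(paste0("R", seq_len(r)), each = 2),
    label = rep(paste0("R", seq_len(r)), each = 2),
    indicator = paste0("v", seq_len(2 * r)),
    mean = 3, sd = 0.5)
  list(genes = genes, rois = rois)
}

ROIS5 <- c("ACgG", "CO", "OFuG", "Hippocampus", "Amygdala")

# Null planted-path set (all structural effects zero).
noPlanted <- function() plantedPathDefaults()[0, ]
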