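#' Welch two-sample t test from group summaries
#'
#' Unequal-variance (Welch) t statistic computed from per-group n, mean and
#' sample SD, with the Welch-Satterthwaite degrees of freedom and a
#' two-sided p value. Group order matters: t is computed as
#' (mean1 - mean2) / SE, so swapping the groups negates the statistic.
#'
#' @param n1,mean1,sd1 first group: size, mean, sample SD.
#' @param n2,mean2,sd2 second group.
#' @return list with \code{t}, \code{df}, \code{p}.
#' @examples
#' # severity in healthy vs PTSD participants, from the group summaries
#' welchTestSummaries(137, 16.87, 13.81, 94, 44.71, 16.68)$t  # about -13.35
#' @export
welchTestSummaries <- function(n1, mean1, sd1, n2, mean2, sd2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  if (v1 + v2 == 0) {
    if (mean1 == mean2)
      stop("undefined statistic: both variances zero and equal means")
    return(list(t = sign(mean1 - mean2) * Inf, df = NA_real_, p = 0))
  }
  tstat <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df))
}

#' Welch t test from raw data
#'
#' Convenience wrapper computing the group summaries and delegating to
#' [welchTestSummaries()]; identical to the unequal-variance t test on the
#' raw values.
#'
#' @param x,y numeric vectors for the two groups.
#' @return list with \code{t}, \code{df}, \code{p}.
#' @export
welchTest <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  welchTestSummaries(length(x), mean(x), sd(x), length(y), mean(y), sd(y))
}

#' Distribution screening by skewness and kurtosis
#'
#' Sample skewness (m3 / m2^1.5) and plain (non-excess) kurtosis
#' (m4 / m2^2, so a normal distribution scores 3), with a pass flag for the
#' conventional approximate-normality screen |skewness| < 2 and
#' kurtosis < 7.
#'
#' @param x numeric vector, n >= 4.
#' @param skewLimit,kurtLimit screening thresholds (defaults 2 and 7).
#' @return list with \code{skewness}, \code{kurtosis}, \code{pass}.
#' @export
momentsScreen <- function(x, skewLimit = 2, kurtLimit = 7) {
  x <- x[!is.na(x)]
  if (length(x) < 4L) stop("need at least 4 observations")
  if (var(x) < 1e-24) stop("undefined moments: zero variance")
  sk <- e1071::skewness(x, type = 1)
  ku <- e1071::kurtosis(x, type = 1) + 3
  list(skewness = sk, kurtosis = ku,
       pass = abs(sk) < skewLimit && ku < kurtLimit)
}

#' Group comparison table
#'
#' Summarizes the phenotype variables per group (mean and sample SD, counts
#' for the binary gender code) and reports Welch t statistics and p values
#' for the pairwise group comparisons.
#'
#' @param dataset an \linkS4class{IGDataset}.
#' @param group logical or two-level vector along the samples (e.g. case
#'   status); the first level/\code{FALSE} is taken as group 1.
#' @return data.frame with one row per variable.
#' @export
describeGroups <- function(dataset, group) {
  ph <- phenotypes(dataset)
  if (length(group) != nrow(ph))
    stop("group must have one entry per sample")
  g <- as.factor(group)
  if (nlevels(g) != 2L) stop("group must have exactly two levels")
  vars <- c("age", "audit", "pte", "severity")
  rows <- lapply(vars, function(v) {
    x <- ph[[v]][g == levels(g)[1]]
    y <- ph[[v]][g == levels(g)[2]]
    wt <- welchTest(x, y)
    data.frame(variable = v,
               mean1 = mean(x), sd1 = sd(x),
               mean2 = mean(y), sd2 = sd(y),
               t = wt$t, df = wt$df, p = wt$p)
  })
  out <- do.call(rbind, rows)
  attr(out, "n") <- table(g)
  out
}
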