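---
title: "Methods: component-based path modelling for imaging genetics"
author: "igsca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: component-based path modelling for imaging genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igsca)
```

## The model

`igsca` implements generalized structured component analysis for imaging
genetics (IG-GSCA): a component-based structural equation model in which
every construct is a *component* — an exactly computed, unit-variance
weighted composite of its observed indicators — rather than a latent
factor. In the packaged study design:

* each of nine candidate genes (SLC6A4, FKBP5, ADCYAP1R1, BDNF, COMT,
  HTR3A, DRD2, NR3C1, OXTR) is a composite of its SNP minor-allele dosages
  (18 SNPs in total; dosages coded 0/1/2);
* each of 60 brain regions of interest (ROIs) is a composite of its part
  volumes (usually left/right; six parts for the inferior frontal gyrus,
  one for the inferior lateral ventricles), measured as volumes relative
  to total brain volume;
* the potentially-traumatic-event count (PTE, 0–17 experienced items),
  the outcome (clinician-rated PTSD symptom severity), and the covariates
  gender, age and AUDIT are single-indicator constructs with fixed unit
  weight and loading;
* one gene-by-environment interaction construct per gene, named
  `<gene>xPTE`, is the standardized element-wise product of the gene and
  PTE component scores. Interaction constructs carry no indicators and no
  free measurement parameters.

The structural pattern routes every gene, PTE, every interaction and
every covariate to every ROI, and every ROI, PTE and every covariate to
severity — ROIs mediate; there are no direct gene-to-outcome paths. With
9 genes and 60 ROIs this gives $(9+1+9+3)\times 60 + (60+1+3) = 1{,}384$
structural paths, against which `countFreePaths()` is checked.

## Estimation

Let $Z$ be the column-standardized indicator matrix. Standardization uses
the population (divide-by-$n$) convention throughout, so the unit-variance
constraint on scores is exact and a loading equals the sample correlation
between an indicator and its component. Writing $\gamma_j = Z_j w_j$ for
the component scores, $c_j$ for loadings and $b$ for structural
coefficients, the estimation criterion is

$$
f \;=\; \sum_j \lVert Z_j - \gamma_j c_j^\top \rVert^2
\;+\; \sum_k \lVert \gamma_k - \Gamma_{\mathrm{pa}(k)} b_k \rVert^2
\;+\; \lambda \sum b^2 ,
$$

the sum of squared residuals of all indicator equations and all
structural equations plus a ridge penalty on the structural coefficients
*only* — loadings and weights are never penalized. Minimization alternates
two exact sub-steps:

* **A-step** — given scores, loadings solve per-construct least squares
  ($c_j = Z_j^\top\gamma_j / n$) and each endogenous construct's incoming
  paths solve the ridge system
  $b_k = (\Gamma^\top\Gamma + \lambda I)^{-1}\Gamma^\top \gamma_k$.
* **W-step** — each multi-indicator composite's weights minimize the
  global criterion under the unit-variance constraint. Because every
  appearance of $\gamma_j$ in the criterion is linear and the quadratic
  term is constant on the constraint set, the unconstrained least-squares
  direction followed by rescaling is the *exact* constrained minimizer,
  which makes the criterion provably non-increasing across iterations
  when no interaction constructs are present (a property the test suite
  asserts to within 1e-10). Interaction scores are deterministic
  functions of their parents; they are recomputed as standardized
  products after every W-step and treated as fixed within it, so with
  interactions present the trace is only required to converge.

Iteration stops when the relative criterion change falls below
`tolerance` (default 1e-6; 500 iterations maximum, with a warning rather
than silent failure on non-convergence). Initialization is deterministic
equal weights $1/\sqrt{k}$ by default; seeded random initialization is
available for basin checks. At $\lambda = 0$ a rank-deficient predictor
block is resolved by the minimum-norm (pseudoinverse) solution with a
logged warning. Sign indeterminacy of composites is fixed by orienting
each weight vector so the sum of its loadings is positive.

$R^2$ of an endogenous construct is $1 - \lVert\gamma_k -
\Gamma b_k\rVert^2 / n$, legitimate because scores have unit variance.

## Choosing the ridge penalty

`selectLambda()` runs repeated $k$-fold cross-validation (default
$10\times 5$, read as ten independent repetitions of 5-fold CV; both
knobs are configurable). Standardization parameters and all model
parameters are learned on the training folds only; held-out component
scores are formed with the training weights (and the training
product-scaling for interactions), and the out-of-fold loss is the sum of
squared structural residuals on held-out samples. The loss deliberately
covers structural residuals only — the penalty being tuned applies only
to structural paths, so measurement residuals are constant in what the
penalty controls. The selected penalty minimizes the mean loss, ties
broken towards the larger (more stable) penalty. The default grid is 0
plus 40 log-spaced points up to 1000; a dense integer grid over the same
range can be supplied when the resolution of the selected value matters.

On weak-signal data the CV curve is often flat and large penalties win;
this is expected behaviour, not a defect — most true structural effects
in a high-dimensional path pattern are near zero.

## Bootstrap inference and mediation

`igBootstrap()` resamples rows with replacement and refits everything
(weights, loadings, paths) at the fixed selected penalty, warm-starting
from the full-sample weights. Component sign indeterminacy would inflate
standard errors spuriously, so each refit component is aligned to
correlate positively with the full-sample component scores on the
resampled rows before draws are recorded. Standard errors are standard
deviations across draws; intervals are plain 2.5/97.5 percentiles (not
BCa). Resamples with a degenerate component (for instance a constant
dosage column after resampling a rare allele) are discarded and redrawn,
with a warning past 1% discards. Significance screening is strict zero
exclusion by the unrounded interval; no multiplicity correction is
layered on top, because all paths are estimated jointly within one
multivariate model.

An indirect (mediation) effect along a chain such as gene → ROI →
severity is the product of the chain's path coefficients — exactly, for
the point estimate — with its interval taken from the per-resample
products of aligned draws.

## Goodness of fit

* **FIT** $= 1 - \mathrm{SSE}/\mathrm{SST}$ where SSE adds the indicator
  and structural residuals (without the penalty term) and SST is the
  total sum of squares of all indicators and endogenous components.
* **GFI** $= 1 - \mathrm{tr}\{(S-\hat\Sigma)^2\}/\mathrm{tr}(S^2)$ and
  **SRMR** is the root mean square of standardized residual covariances
  over the lower triangle *including* the diagonal (stated explicitly so
  the value is reproducible), with conventional cutoffs 0.93 and 0.08.

The reproduced covariance $\hat\Sigma$ for a component model is not
uniquely defined in the literature; this package fixes a reconstruction
contract: each indicator is reconstructed as its loading applied to the
model-implied component score, where endogenous components are replaced
by their structural predictions recursively from the exogenous
components, and indicators of exogenous single-indicator constructs keep
unit variance. Under this definition the diagonal blocks of endogenous
composites are attenuated by their structural $R^2$, so GFI/SRMR values
are conservative relative to conventions that add back residual
variances; the exact-fit identities (GFI = 1, SRMR = 0 at
$\hat\Sigma = S$) are unaffected and are what the test suite pins down.

## Descriptive conventions

Group comparisons use the unequal-variance (Welch) $t$ with
Welch–Satterthwaite degrees of freedom: it reproduces the study's printed
severity statistic from the printed group summaries far better than the
pooled form does. Distribution screening reports moment-based skewness
($m_3/m_2^{3/2}$) and *plain* kurtosis ($m_4/m_2^2$, normal $=$ 3),
consistent with the screening thresholds $|\text{skew}| < 2$ and
kurtosis $< 7$.

## The synthetic-data generator

Because the original clinical dataset is confidential, `simulateDataset()`
emulates the design so every stage is testable end to end:

* **Genotypes** — dosages drawn by a latent Gaussian threshold (copula)
  scheme whose thresholds reproduce the packaged per-SNP genotype class
  frequencies in expectation; SNPs within a gene share a latent
  equicorrelation (default 0.8, which lands the multi-SNP gene loadings
  in the observed 0.83–0.92 band), SNPs across genes are independent.
  One packaged frequency row is internally inconsistent as printed; the
  resource keeps the wild and heterozygous counts and assigns the mutant
  class the remainder of the sample.
* **PTE** — beta-binomial over the 17 checklist items matching the
  observed mean 3.72 and SD 2.47 (over-dispersed relative to a binomial);
  AUDIT likewise as an over-dispersed count, gender as Bernoulli(0.325),
  age as Normal(46.1, 13.5²).
* **Structure** — planted structural coefficients (defaults: the six
  reported mediation-structure paths, all other edges zero) drive each
  endogenous score, with Gaussian residuals scaled so scores have unit
  variance; a planted set implying variance above one is rejected with
  the offending construct named.
* **ROI volumes** — indicators are generated from their construct score
  with the cross-indicator mixing chosen so the *fitted* composite
  loading converges to the configured target (default 0.9): for $k$
  indicators the score coefficient is $a=\sqrt{(kL^2-1)/(k-1)}$. Values
  are mapped affinely to the packaged per-part cm³ means/SDs and divided
  by a simulated total brain volume so the relative-volume step of the
  pipeline is exercised.
* **Severity** — mapped to the clinical scale (28.20 ± 20.33) and
  truncated at zero; the truncation is a mild departure from Gaussian
  residuals that the recovery tolerances absorb.

What the generator does *not* emulate: real LD structure and
gene–environment dependence (unknowable from summary tables), spatial
correlation between neighbouring ROIs beyond what shared prediction
induces, measurement floor/ceiling effects, and case–control sampling
structure. Passing recovery tests therefore demonstrate that the
estimator recovers the data-generating process it assumes — not that the
clinical estimates themselves are correct.

## Problem sizes and tolerances used by the checks

The test suite verifies closed-form equivalence of ALS at $\lambda=0$ to
1e-8 on single-indicator models; parameter recovery on the full
1,384-path model at $n=2000$ over 20 seeds, requiring each planted
coefficient's mean estimate within ±0.05 and the mean ROI loading within
±0.02 of the 0.9 target (the mean over seeds is the recovery criterion —
a per-draw criterion would conflate Monte-Carlo noise with bias; the
residual bias is the known, small attenuation from reconstructing a
generated score by a finite composite); and type-I calibration on a
5-ROI submodel at $n=231$ with 20 seeds × 500 resamples, requiring the
per-path significance rate within 0.05 ± 0.02. Bootstrap defaults are
5000 resamples for analysis but 500 in the pipeline's example
configuration, which is ample for rate calibration while keeping
desk-scale runtime.

## Known limitations

* The reproduced-covariance contract above makes GFI/SRMR conservative
  for endogenous composites (see *Goodness of fit*).
* $\lambda$ is held fixed across bootstrap refits; re-tuning within each
  resample is out of scope.
* Listwise deletion is the only missing-data policy; no imputation.
* Only recursive (acyclic) structural models are supported; no latent
  factors, no multi-group models, and only gene × PTE interactions are
  generated for the study model (no gene–gene epistasis terms).
* Interaction constructs make the criterion non-monotone in principle;
  convergence of the trace is monitored instead.

## A compact end-to-end run

```{r example, eval = FALSE}
rois <- c("ACgG", "CO", "OFuG")
sim <- simulateDataset(nSamples = 231, seed = 42, roiSubset = rois)
model <- buildStudyModel(roiSubset = rois)
cv <- selectLambda(sim$dataset, model, lambdaGrid = c(0, 10, 62, 250, 1000),
                   nFolds = 5, nRepeats = 2, seed = 42)
res <- runStudyPipeline(sim$dataset, model = model, lambda = cv@selected,
                        nResamples = 500, seed = 42, outDir = "report")
significantPaths(res$bootstrap)
```
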