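---
title: "Methods: twin-based genetic parcellation and endophenotype association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: twin-based genetic parcellation and endophenotype association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endotwin)
```

This vignette is the package's own account of the models it implements,
the choices made where the methodology was genuinely open, and what the
synthetic cohorts used in the test suite do and do not establish about
real data.

## 1. The AE twin model

For a family of $m \le 3$ members with expected additive relatedness
matrix $R$ (1 between MZ co-twins, 0.5 between DZ twins and full
siblings — the package deliberately treats DZ twins and siblings as
exchangeable), one trait is modelled as

$$ y \sim \mathcal{N}(\mu \mathbf{1},\; a^2 R + e^2 I), $$

with $a^2$ the additive-genetic and $e^2$ the unique-environment
variance, $h^2 = a^2/(a^2+e^2)$. The likelihood is full-information:
missing family members are marginalised, so a pair with one absent
member contributes a singleton density. Shared-environment (C) and
dominance (D) components are omitted; when a C component truly exists,
the AE fit will absorb part of it into $a^2$, slightly overestimating
heritability — the classical caveat of the AE restriction.

**Estimation.** For fixed $h^2$ the profile over $(\mu, \sigma^2 =
a^2+e^2)$ has closed-form maximisers (a GLS mean and a normalised
quadratic form), so `fit_ae()` reduces the problem to an exact 1-d
search of $h^2 \in [0,1)$ with `optimize()`. This is boundary-safe by
construction — no constrained multi-start optimisation can land on a
spurious local mode in one dimension — and makes profile confidence
intervals (inverting the 1-df LRT at $\chi^2_{0.95,1}/2 = 1.92$) cheap.
A sample containing only one relatedness level (e.g. MZ pairs only)
cannot separate additive-genetic from familial variance; the fit is
returned but flagged `identified = FALSE`.

The bivariate model stacks two traits per individual; the family
covariance is $R \otimes A + I \otimes E$ with 2×2 blocks $A, E$
parameterised by their Cholesky factors, so positive semi-definiteness
is structural and boundary values $|r_G| = 1$ are attainable (flagged,
not errored). The 8-parameter likelihood is maximised by BFGS from
three deterministic starts — moment-based (cross-relative cross-trait
covariances), near-null, and mid-range — best log-likelihood wins, ties
to the first; relative tolerance $10^{-10}$. Power runs use the
moment start alone, which the null-calibration test shows is accurate
at these problem sizes.

**Power for $r_G$.** `power_detect_rg()` simulates complete-data
cohorts directly from the per-family-type multivariate normal and
counts rejections of the 1-df LRT ($r_G$ free vs $r_G = 0$). The
environmental correlation is a free parameter defaulting to 0: for the
small $r_G$ values this analysis targets, the rejection rate is
insensitive to it, and no published value pins it down.

## 2. Genetic parcellation

Vertex measures are first residualised (`residualize()`) on global and
acquisition covariates by exact least squares — residuals are orthogonal
to the design, and rank-deficient designs are rejected naming the
aliased columns, rather than silently dropping them.

**Genetic correlations.** The reference estimator fits the bivariate AE
model to every vertex pair. Because that is quadratic in V, the default
for large matrices is a moment estimator: under the AE model the
cross-relative covariance at relatedness $r$ is $rA_{12}$ for every
relative class, so the genetic covariance matrix is the pair-count
weighted least-squares solution
$\hat A = \sum_r n_r r C_r / \sum_r n_r r^2$, computed in one vectorised
pass over all $V^2$ pairs. This uses the same no-shared-environment
assumption as the FIML model; the alternative Falconer-style difference
$2(C_{MZ} - C_{DZ})$ is robust to a C component but pays roughly a
three-fold variance penalty, which at desk-scale cohort sizes swamps the
estimand. The test suite verifies the two estimators agree within ±0.1
on over 95% of pairs of a 30-vertex benchmark. Vertices whose estimated
genetic variance is non-positive have no identified $r_G$; their entries
are `NA` and flagged, and are imputed with row-median dissimilarities
(reported via an attribute) only at the clustering step, which needs a
complete matrix.

**Dissimilarity.** $d = 1 - r_G$, the simplest monotone transform onto
$[0,2]$. Nothing in the methodology forces this over, say,
$\sqrt{2(1-r_G)}$; it is a configuration point by design (pass any
matrix to `fanny_cluster()`).

**FANNY.** `fanny_cluster()` minimises the Kaufman–Rousseeuw objective
$\sum_v \left(\sum_{ij} u_{iv}^r u_{jv}^r d_{ij}\right) / \left(2\sum_j
u_{jv}^r\right)$ with membership exponent $r = 2$ (the standard default;
configurable). Memberships are initialised from a deterministic
PAM-style BUILD medoid selection, smoothed one-hot (0.75 own cluster,
0.25 spread), then updated by the Lagrangian fixed-point rule
$u_{iv} \propto (1/g_{iv})^{1/(r-1)}$ on the objective's partial
derivatives; when a derivative is non-positive the point snaps to that
cluster. A step-halving safeguard accepts an update only if the
objective does not increase, so the objective trace is monotone by
construction; convergence is a relative change below $10^{-9}$ (at most
500 iterations). Determinism was preferred over the randomised
initialisation of older implementations: the same matrix always yields
the same memberships, which matters for pipeline reproducibility. The
test suite cross-checks the converged objective against the classical
`cluster::fanny` implementation and against an exhaustive membership
grid on a 5-point instance.

**Silhouette and choosing k.** Silhouette widths
$s(i) = (b_i - a_i)/\max(a_i, b_i)$ are computed on the crisp argmax
labels (ties to the smallest cluster index), with $s = 0$ for singleton
clusters; fuzzy silhouette variants are deliberately out of scope since
a single coefficient per k is what the selection rule needs.
`select_k()` reports the full curve and recommends the *smallest* k
within 2% (configurable) of the curve maximum — a plateau-onset rule
that prefers parsimonious parcellations when the curve flattens, and
flags the recommendation low-confidence when even the best silhouette is
below 0.1. The choice remains a judgment call on real data; the user
override is the `k` configuration field.

## 3. Spline association under kinship

**Winsorisation.** Symptom sum scores have heavy right tails; values
above mean + 4 SD (computed on the input) are capped at that cutoff,
upper tail only by default.

**Orthogonal spline orders.** The three effect columns live in the
natural cubic spline space with boundary knots at the observed range and
interior knots at the terciles of the winsorised score (the knot rule is
configurable; terciles give equal-information segments). Within that
space the columns are defined as the projections of $x, x^2, x^3$,
Gram–Schmidt-orthonormalised in that order against the intercept. This
gives the columns stable semantics — linear trend, then the
quadratic-like and cubic-like curvature directions the space admits —
keeps them exactly orthogonal (no polynomial collinearity), and keeps
every column linear beyond the boundary knots, so extreme scores cannot
drag diverging tails. The B-spline columns of a standard natural-spline
basis have no such ordering, which is why the package defines its own
canonical ordering rather than testing raw basis columns.

**Mixed model.** `fit_kinship_lmm()` fits
$y = X\beta + g + \varepsilon$, $g \sim \mathcal{N}(0, \sigma^2_g\,2K)$,
by REML. $2K$ (twice kinship = expected additive relationship, the
animal-model convention; using $\varphi$ itself would halve the genetic
variance scale) is eigendecomposed once; since kinship is block-diagonal
by family the decomposition is done per block in linear time when blocks
are small, falling back to a dense decomposition otherwise. In the
rotated basis the covariance is diagonal in the variance ratio
$\gamma = \sigma^2_g / \sigma^2_e$, which is profiled on the log scale
over $[e^{-14}, e^{14}]$ with an explicit $\gamma = 0$ (OLS) candidate.
The extended quasi-likelihood fitters used elsewhere for this model
coincide with Gaussian REML for a Gaussian response with one random
effect; REML was chosen as the transparent, exactly reproducible form.
Tests are Student t with $df = N - \mathrm{rank}(X)$ — the simplest
defensible convention; Satterthwaite-type corrections are out of scope —
and each effect is also reported as the correlation-scale effect size
$r = \mathrm{sign}(\beta)\,|t|/\sqrt{t^2 + df}$.

**Multiple testing.** The Li–Ji effective number of phenotypes is
computed from the eigenvalues of the correlation matrix of
covariate-residualised phenotypes (residualising first matters:
shared covariate effects inflate correlations and deflate Meff).
Eigenvalues are clipped at zero and integer-rounded at $10^{-9}$ before
the floor operation — otherwise a mathematically integer eigenvalue
computed as $1.999\ldots$ contributes a spurious unit. Meff is rounded
to the nearest integer before multiplying by the 3 spline orders,
matching the convention of quoting an integer number of effective
phenotypes; the raw value is kept in the output. Šidák
($1-(1-\mathrm{FWER})^{1/m}$) is the primary conversion because it is
exact for independent tests, which is what Meff counts; Bonferroni is
reported alongside since published thresholds are sometimes computed
either way.

## 4. The synthetic cohort generator

`simulate_cohort()` is the package's study-conditions generator, not a
test fixture: family structures are counts of MZ/DZ/sibling pairs,
twin+sibling trios and singletons (families never exceed three members);
`discovery_family_structure()` encodes the 833-individual discovery
composition used by the power analysis. The generative model is exactly
the AE model the estimators assume:

* per-individual genetic factors drawn jointly within families with
  cross-relative correlation equal to expected relatedness (the MZ-pair
  relatedness matrix is singular; factor draws use a symmetric
  eigenvalue square root);
* vertices organised in blocks: within-block genetic correlation
  `within_block_rg` (default 0.8), between-block `between_block_rg`
  (default 0), per-block heritabilities (defaults in the 0.3–0.7 range
  typical of cortical measures; 0.55 in the demo config);
* a score with heritability `h2_score` (default 0.28, the lower end of
  published anxiety-depression estimates), genetic correlation
  `rg_score_target` with one target block's shared factor, and a heavy
  right tail produced by exponentially tilting values above the 90th
  percentile with rate `score_tail` (default 0.8, which yields a few
  beyond-4-SD observations per ~800 individuals — enough to exercise
  winsorisation). No published tail shape exists to calibrate against,
  so the parameter is qualitative by design;
* an optional spline-shaped phenotypic effect on the target block's
  vertices, specified as correlations per orthogonal spline order and
  injected as $r/\sqrt{1-r^2}$ times the unit-variance basis column
  (the demo plants a cubic-only $r = -0.10$);
* covariates (sex, two ages, wave, acquisition) with configurable linear
  effects, default zero, so residualisation is exercised rather than
  assumed.

What this emulates well: relatedness structure, block-structured genetic
covariance, small genetic correlations, nonlinear phenotypic effects,
skewed scores, covariate nuisance. What it does not: spatial smoothness
and boundary ambiguity of real cortical maps, shared-environment or
dominance variance, measurement error correlated across vertices,
selection and attrition. Passing tests therefore demonstrate that the
estimators recover the truth *under their own model class at these
sample sizes* — they cannot certify robustness to C/D misspecification
or to spatially structured noise.

## 5. Problem sizes and numerical tolerances

The test suite runs at sizes chosen to keep Monte-Carlo error well below
each tolerance: heritability recovery at 1000 MZ + 1000 DZ pairs
(estimator SD ≈ 0.02–0.03 against a ±0.05 band, averaged over five
replicate cohorts), bivariate $r_G$ recovery at the same scale against
±0.1, the moment-vs-FIML agreement benchmark at 30 vertices × 1500
pairs, null calibration of the 48-phenotype scan over 200 replicate
cohorts of 320 individuals, planted-effect detection at N = 5000, and
the power computation over 500 replicates of the 833-individual
structure. Determinism invariants (same seed, same bytes) are asserted
at every stage; the pipeline derives per-stage substreams from the one
user seed so changing association options never perturbs the simulated
cohort.

Key tolerances: FIML convergence $10^{-10}$ relative (BFGS), FANNY
$10^{-9}$ relative objective change, membership row sums within
$10^{-9}$, LRT negative-statistic tolerance $10^{-4}$ before a refit
warning, spline Gram matrix within $10^{-8}$ of identity.

## 6. Known limitations

* AE only in the fitted models; an ACE/ADE extension would need a second
  relatedness contrast and is not implemented.
* No extended pedigrees: families are truncated at three members, as in
  the designs this package targets.
* The LMM profiles a single variance ratio; multiple random effects
  (e.g. dominance or household) are out of scope.
* Silhouette-based k selection is a heuristic; on weak structure it is
  explicitly flagged rather than trusted.
* The moment $r_G$ estimator shares the AE assumption of the FIML model;
  neither is robust to shared-environment covariance between relatives.
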