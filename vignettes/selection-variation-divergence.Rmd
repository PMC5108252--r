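---
title: "Linking nonlinear selection, trait covariance, and divergence"
author: "selscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking nonlinear selection, trait covariance, and divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selscape)
```

## The question the package addresses

Two observations recur in comparative data: lineages often show long
periods of restrained divergence, and the covariance of trait means among
related species (the divergence matrix **D**) often resembles the
phenotypic covariance within a species (**P**). Both are commonly read as
signatures of standing genetic constraint. An alternative is that both are
shaped by the same feature of the adaptive landscape — stabilizing
(nonlinear) selection, summarised by the quadratic gradient matrix
**γ**. If selection is convex along some direction, variance within a
population and divergence among species should both be depleted along that
direction, whether or not genetic constraints persist.

`selscape` implements the full chain needed to test this "triple
alignment" with three traits measured in ambush bugs (*Phymata*): pronotum
width (PN, mm) and two melanism scores (MD, ML, mean pixel darkness on a
0–255 scale), but nothing is specific to those traits or to p = 3.

## The model pieces

**Selection gradients.** With relative fitness
$w_\mathrm{rel} = w/\bar w$ and variance-standardized traits $z$, the
Lande–Arnold regressions are

$$w_\mathrm{rel} = \alpha + \beta'z + \varepsilon
  \qquad\text{and}\qquad
  w_\mathrm{rel} = \alpha + b'z + \tfrac12 z'\gamma z + \varepsilon .$$

`selection_gradients()` fits both by OLS, reports $\beta$ from the
linear-only model (the convention behind published gradient tables), and
doubles the fitted squared-term coefficients so that
$\gamma_{ii} = \partial^2 w/\partial z_i^2$ (`double_quadratic = FALSE`
recovers the raw coefficients; published matrices are taken as printed).

**Canonical analysis.** `canonical_analysis()` diagonalizes γ. The axes
$m_i$ (unit eigenvectors) carry eigenvalues $\lambda_i$ (curvature) and
directional gradients $\theta_i = m_i\cdot\beta$. The axis with the most
negative $\lambda$, `m_max`, is the direction of strongest stabilizing
selection. Because an eigenvector's sign is arbitrary, loadings are
reported with the first nonzero loading positive — the convention the
published tables of this system use, which differs from "largest loading
positive" whenever the dominant loading is negative.

**Curvature significance.** `eigenvalue_permutation_test()` shuffles
fitness across individuals (the phenotype distribution is conditioned on),
re-estimates and re-diagonalizes γ, sorts each null spectrum, and compares
rank with rank. The test is one-tailed in the observed sign direction by
default; p-values use the add-one estimator $(1+b)/(n_\mathrm{perm}+1)$,
so the smallest attainable p at 10,000 permutations is about $10^{-4}$.
Rank-matching of sorted eigenvalues is our resolution of the
correspondence problem (which null eigenvalue "is" the observed one); it is
exchangeable under the null, so the test is exact up to permutation noise.

**Projection pursuit.** Because sampling error in γ tends to pull its
canonical axes toward directions of low phenotypic variance,
`projection_pursuit()` offers a γ-free estimate of the dominant surface
direction: random unit directions $a$ (uniform on the sphere), a cubic
smoothing spline of $w_\mathrm{rel}$ on $Za$ at each value of a log-scale
smoothing-parameter grid (default $-10$ to $10$ in steps of 2, applied as
`exp(grid)` to `stats::smooth.spline`), scored by leave-one-out
cross-validated explained deviance, and a Nelder–Mead polish of the best
start on the sphere. The per-grid best directions are returned so the user
can verify the direction is stable across smoothing choices; heavy
smoothing (large positive grid values) flattens the spline toward a line
and the direction becomes uninformative, which the stability table makes
visible.

**P and D.** `p_matrix()` is the sample covariance (n − 1 everywhere in
this package); with `pool_by = "year"` traits are first mean-standardized
within year, which removes between-year differences in multivariate means
that would otherwise inflate variance along the direction separating the
yearly means. Element-wise standard errors come from a delete-one
jackknife. `d_matrix()` divides each taxon's mean vector by the reference
means (the *P. a. americana* museum row, by default) and takes the
covariance across taxa, each taxon weighted equally; the n − 1 denominator
and equal weighting are validated by reproducing the published divergence
variances from the packaged 37-taxon table. A moment-based MANOVA
estimator (`d_matrix_moments()`) is provided for individual-level data:
$\hat D = (MS_b - MS_w)/n_0$, eigenvalue-truncated at zero when sampling
noise makes it indefinite. It is a method-of-moments companion to the REML
mixed-model formulation, which is out of scope here.

**Alignment.** `vector_correlation()` is $|a\cdot b|/(\|a\|\|b\|)$.
`alignment_test()` holds the reference direction fixed (treated as
error-free), shuffles each trait column independently — destroying
covariance while preserving the margins — and recomputes the designated
eigenvector each time. An important consequence of this null: marginal
variances are preserved, so if the low-variance direction coincides with a
single trait axis, much of the "alignment" is inside the null and the test
is conservative. Power comes from oblique, correlation-driven structure.
For divergence, `taxon_alignment_test()` shuffles the mean-standardized
taxon-mean rows themselves; with 37 rows this null is noticeably more
dispersed than one built by reshuffling hundreds of underlying specimens
and re-forming means, so its p-values are conservative relative to
specimen-level resampling (which requires data not packaged here).

**Directional variance.** $e(m) = m'Am$ for $A \in \{P, D\}$ measures the
variance available along a stated direction; over random directions its
expectation is $\mathrm{tr}(A)/p$, which `random_direction_average()`
approaches as draws grow.

**Flury hierarchy.** `flury_hierarchy()` compares two covariance matrices
through the nested models equality ⊃ proportionality ⊃ common principal
components ⊃ one shared component ⊃ unrelated, with effective sample sizes
$n_i = N_i - 1$. The equality statistic is
$\sum_i n_i \ln(\det\bar S/\det S_i)$; proportionality is fit by the
standard fixed-point iteration; the CPC rotation by the Flury–Gautschi
pairwise algorithm; the shared CPC(1) component by direct likelihood
optimization on the unit sphere, started from every full-CPC axis (the
starts make the optimum reliable for p = 3; the polish is strictly
likelihood-increasing). AIC is the jump-up χ² plus twice the parameters
freed relative to equality, which reproduces the published AIC column
arithmetic. `best_model()` implements both selection rules; note that
"jump-up" (highest model not rejected against unrelated) applied to the
published table selects CPC.

**Dimorphism.** `mahalanobis_dimorphism()` is
$\sqrt{(\mu_m-\mu_f)'S^{-1}(\mu_m-\mu_f)}$ on mean-standardized traits.
The source covariance for the metric is genuinely ambiguous in this
literature, so `dimorphism_table()` exposes both options: the pooled
within-taxon, both-sex covariance (default) or a user-supplied reference
matrix. The index is symmetric in the sexes and scales as $\sqrt c$ if the
metric is divided by $c$.

## What the synthetic generator emulates — and what it does not

`sim_config()` defaults encode the study conditions the analyses assume: a
field sample of 44 males scored for mating success; two common-garden
cohorts of 50 and 58 males for **P**; 37 taxa (median ≈ 7, range 4–20
specimens each here) for **D**. Phenotypes are multivariate normal on the
raw measurement scale, with covariance implied by the published
mean-standardized **P** and the reference trait means
(`cov_ij = P_ij m_i m_j`), and taxon means scatter with covariance equal
to the published **D** similarly rescaled. Mating success defaults to a
Bernoulli draw under a Gaussian fitness surface (optimum at the
standardized mean, width 2 on each standardized axis, peak mating
probability 0.7 — a moderate surface a field study of this size could
plausibly detect); a `quadratic_exact` surface and Poisson counts are
available. Under the quadratic surface, negative expected fitness is
truncated at zero with a logged count: quadratic surfaces are unbounded
below, so a *strong* planted γ is not exactly recoverable from truncated
fitness — recovery properties are therefore tested with surfaces that stay
positive over the sample, where the estimator is exact up to the
relative-fitness normalization $\bar w$.

What the generator deliberately omits: measurement error specific to
museum photographs, phylogenetic covariance among taxon means (taxa are
drawn independently — a "star" phylogeny), unequal and correlated
measurement protocols between datasets, and any skew or kurtosis in
phenotypes. Passing recovery tests therefore show the estimators are
correct for the assumed data-generating process, not that real data meet
those assumptions.

## Numerical choices

* Covariance denominators are n − 1 throughout; effective sizes in
  likelihoods are N − 1.
* Eigen-decompositions symmetrize their input (`(A + t(A))/2`) before
  calling `eigen(symmetric = TRUE)`; near-degenerate extreme eigenvalues
  (gap below `1e-8 * trace`) trigger a warning because the corresponding
  direction is ill-determined.
* FG convergence: sweeps stop when the sign-aligned rotation update falls
  below `1e-10`; non-convergence at 1,000 sweeps is an error, not a silent
  result.
* Permutation p-values never return 0: $(1+b)/(n_\mathrm{perm}+1)$.
* All stochastic functions take an explicit `seed`; the pipeline threads a
  single seed through every stage.

Problem sizes used in the shipped tests were chosen to make the
statistical claims sharp at desk scale: 500 replicate null datasets for
type-I calibration of the eigenvalue test, 100,000 random directions for
the trace identity, n = 50,000 for quadratic-surface recovery, 5,000 per
year for **P** recovery, and 500 taxa for **D** recovery.

## A worked fixture analysis

```{r fixture}
ca <- canonical_analysis(phymata_gamma(), phymata_beta())
tidy(ca)

D <- d_matrix(phymata_taxa(), reference = phymata_reference_means())
round(D$matrix * 10, 3)

mmax <- phymata_m_vectors()[, "m_max"]
c(rho_P = vector_correlation(mmax, min_eigenvector(phymata_P())),
  rho_D = vector_correlation(mmax, min_eigenvector(D)))

flury_hierarchy(phymata_P(), 108, phymata_D(), 37)
```

## Known limitations

* The divergence alignment test operates on taxon means (the only data
  published at that level); its permutation null is conservative compared
  with specimen-level reshuffling.
* The REML mixed-model divergence matrix is not implemented; the moment
  estimator stands in for individual-level data.
* Phylogenetic non-independence among taxa is not modelled anywhere.
* `flury_hierarchy()` is written and tested for two groups; the underlying
  FG code accepts more but k > 2 is untested.
* Projection pursuit assumes a single dominant surface direction; a
  genuinely multi-ridge surface will be summarised by whichever projection
  cross-validates best.
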