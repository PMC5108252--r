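# selscape

Tools for asking whether the shape of a nonlinear (sexual) selection
surface predicts both standing phenotypic variation within a species and
macroevolutionary divergence among species — the "triple alignment" of
**γ** (quadratic selection gradients), **P** (phenotypic covariance), and
**D** (covariance of taxon means). The package grew around a three-trait
ambush-bug (*Phymata*) system — pronotum width and two melanism scores —
and ships the published trait tables of that system as fixtures, but every
function is generic in the traits.

## What it computes

* **Selection analysis** — Lande–Arnold gradients from individual fitness
  data (`selection_gradients()`: β from a linear model, γ from the full
  quadratic model with the squared-coefficient doubling convention),
  canonical rotation of γ (`canonical_analysis()`: axes `m_i`, eigenvalues
  `λ_i`, `θ_i = m_i·β`, and `m_max`, the direction of strongest
  stabilizing selection), permutation tests of curvature per axis
  (`eigenvalue_permutation_test()`), and a spline-based projection-pursuit
  estimate of the dominant surface direction (`projection_pursuit()`).
* **Matrix estimation** — `p_matrix()` (two-sample pooling with
  within-year mean standardization, delete-one jackknife SEs),
  `d_matrix()` (covariance of mean-standardized taxon means), and a
  moment-based MANOVA estimator `d_matrix_moments()`.
* **Alignment** — vector correlations `|a·b|` between `m_max` and the
  minimum-variance directions `p_min` / `d_min`, with within-trait
  permutation nulls (`alignment_test()`, `taxon_alignment_test()`);
  directional variances `e(m) = m'Am` and random-direction averages.
* **Matrix comparison** — the Flury common-principal-components hierarchy
  (`flury_hierarchy()`: equality, proportionality, CPC, one shared
  component, unrelated; FG algorithm, AIC model building and jump-up
  tests).
* **Dimorphism** — per-taxon Mahalanobis distance between male and female
  mean phenotypes (`mahalanobis_dimorphism()`, `dimorphism_table()`).
* **Synthetic data** — `sim_config()` plus generators for a selection
  sample, a two-year common-garden sample, and taxon-mean tables, so the
  whole pipeline is testable end to end without field data.

Results follow tidyverse conventions: data frames in, tibbles out,
`tidy()`/`glance()` on fitted objects, `autoplot()` on result types.

## A worked example

Canonical analysis of the packaged variance-standardized γ, and the
alignment of the mean-standardized `m_max` with the least-variance
directions of **P** and **D**:

```r
library(selscape)

tidy(canonical_analysis(phymata_gamma(), phymata_beta()))
#> # A tibble: 3 × 6
#>   axis    theta  lambda    PN     MD     ML
#>   <chr>   <dbl>   <dbl> <dbl>  <dbl>  <dbl>
#> 1 m1    0.00375  0.181  0.926 -0.130 -0.354
#> 2 m2    0.00133 -0.0936 0.360  0.582  0.729
#> 3 m3    0.0365  -0.522  0.111 -0.803  0.586

mmax <- phymata_m_vectors()[, "m_max"]
vector_correlation(mmax, min_eigenvector(phymata_P()))
#> [1] 0.7833212
vector_correlation(mmax, min_eigenvector(phymata_D()))
#> [1] 0.8208667
```

The third canonical axis carries strong negative curvature (λ = −0.52):
an axis contrasting dorsal melanism against the other two traits is under
stabilizing sexual selection, and both phenotypic variance (ρ = 0.78) and
among-taxon divergence (ρ = 0.82) are most depleted along nearly the same
direction. The Flury comparison of **P** and **D** tells the same story at
the whole-matrix level:

```r
flury_hierarchy(phymata_P(), 108, phymata_D(), 37)
#> # A tibble: 5 × 7
#>   model           chi2_step df_step chi2_jumpup df_jumpup  p_jumpup    aic
#>   <chr>               <dbl>   <dbl>       <dbl>     <dbl>     <dbl>  <dbl>
#> 1 equality         105.           1    151.             6  5.15e-30 151.
#> 2 proportionality   45.1          2     45.8            5  9.91e- 9  47.8
#> 3 cpc                0.648        1      0.739          3  8.64e- 1   6.74
#> 4 cpc1               0.0912       2      0.0912         2  9.55e- 1   8.09
#> 5 unrelated         NA           NA      0              0 NA         12
```

The matrices are neither equal nor proportional, but share their
eigenvectors: the common-principal-components model minimizes AIC.

The full chain (gradients → canonical axes → **P** → **D** → alignment →
directional variances → CPC) is orchestrated by `run_full_pipeline()`,
which accepts raw rows or ready-made matrices at each stage and returns a
single report object.

See `vignettes/selection-variation-divergence.Rmd` for the model details,
the permutation-null design (and why the taxon-level null is
conservative), and the synthetic-data assumptions.

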