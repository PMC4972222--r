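---
title: "Marker-based quantitative genetics in clonal plant populations: models and design choices"
author: "markerQG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-based quantitative genetics in clonal plant populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markerQG)
```

## The problem

Estimating evolutionary potential in a wild, long-lived, clonal plant
population requires three things that are all awkward in the field: knowing
which sampled shoots (*ramets*, here "patches") belong to the same genetic
individual (*genet*); knowing how related the distinct genets are to one
another without a pedigree; and partitioning the phenotypic variance of
each trait into an additive genetic part and a residual part given that
relatedness. markerQG implements this workflow for codominant SSR
(microsatellite) genotypes, plus the two satellite analyses that make the
heritabilities interpretable: derivation of snowmelt-phenology traits from
soil-temperature logger series, and standardized-trait performance
regressions contrasting early-snowmelt (ridge) and late-snowmelt (snowbed)
microhabitats.

## Clone identification

Two patches are treated as the same genet when their Lynch band-sharing
distance falls strictly below 0.05. Per locus the similarity between
diploid calls is $s = 2|A \cap B| / (|A| + |B|)$ on the sets of *distinct*
alleles (a heterozygote contributes two alleles, a homozygote one), and
the distance is $1 - \bar{s}$ averaged over loci typed in both patches.
Grouping is single linkage (transitive closure): clonal fragments of one
genet can be linked through intermediates. One representative patch per
genet is drawn uniformly at random; the seed is stored in the
`CloneAssignment` object so the choice is reproducible. Pairs with no
shared typed locus cannot be merged and are counted, not guessed.

Why strict single linkage at 0.05 and not model-based genotype matching:
error-free clonal copies have distance exactly 0, and with seven loci the
smallest nonzero distance between non-identical genotypes is 1/21 (one
shared-allele step at one locus), so the threshold separates the two cases
with a margin. The multilocus probability of identity,
$PI = \prod_l \left(\sum_i p_i^4 + \sum_{i<j}(2 p_i p_j)^2\right)$,
quantifies how unlikely a chance multilocus match is; `piProfile()`
reports it for every panel size.

## Pairwise relatedness

Four published moment estimators are implemented from their original
formulas: Queller–Goodnight, Li, Lynch–Ritland, and Wang. All consume the
same inputs — the two diploid genotypes and the population allele
frequencies — and differ in how they weight allele sharing. Multilocus
combination follows each original publication: ratio of summed numerators
and denominators for Queller–Goodnight and Li, inverse-variance locus
weights for Lynch–Ritland, and, for Wang, the per-locus
genotype-similarity category probabilities (identical; three alleles with
a homozygote–heterozygote share; heterozygotes sharing one allele) entered
into the exact moment system for the IBD-sharing coefficients
$(\varphi, \Delta)$ with $r = \Delta + \varphi/2$, locus-weighted by
$1/(2 a_2 - a_3)$ and solved by least squares. The Wang small-sample
frequency correction is omitted: frequencies here come from the full
clone-filtered sample (hundreds of genets), where the correction is
negligible. A flag `equalLocusWeights` switches every estimator to a plain
per-locus average for sensitivity analysis.

The asymmetric estimators (Queller–Goodnight, Lynch–Ritland) are
symmetrized as the mean of the two reference-individual directions.
Zero-denominator locus-directions (e.g. a reference individual homozygous
for an allele at frequency one, or a Queller–Goodnight heterozygous
reference at a two-allele locus) are skipped and counted. Allele
frequencies are taken from the clone-filtered sample itself — using all
patches would overweight the alleles of large clones.

For mixed-model use the matrix gets a unit diagonal (`setDiagonalUnity`)
and is projected to the nearest positive semi-definite matrix with unit
diagonal by Higham's alternating projections (`Matrix::nearPD(corr =
TRUE)`, up to 300 iterations, convergence tolerance 1e-7). Unusable pairs
are filled with 0 first — the expectation of every estimator for a random
pair. A matrix already positive semi-definite (all eigenvalues at least
`eps = 1e-8`) is passed through unchanged, which also makes the projection
idempotent.

## The animal model

For each trait the model is
$$y = X\beta + a + e, \qquad
  \mathrm{Var}(a) = \sigma^2_a M, \quad \mathrm{Var}(e) = \sigma^2_e I,$$
with $M$ the marker-inferred relatedness matrix and $X$ the treatment-coded
design for transect (3 levels), elevation (2), microhabitat (2) and the
microhabitat × elevation and microhabitat × transect interactions — eight
columns in the balanced 12-site layout. Aliased columns (degenerate
layouts) are dropped with a warning. Elevation enters as a two-level
factor (lower/upper part of the range), not as metres.

Estimation is restricted maximum likelihood. A single spectral
decomposition $M = U D U^\top$ turns the covariance into a diagonal form,
so the profile over the variance ratio $\lambda = \sigma^2_a / \sigma^2_e$
costs one weighted regression per candidate $\lambda$. The profile is
scanned on a 61-point log grid over $[10^{-6}, 10^{6}]$ plus the
$\lambda = 0$ boundary, then refined by Brent's method (tolerance 1e-10 on
$\log \lambda$); the boundary is re-checked afterwards because a flat
profile can favour $\sigma^2_a = 0$. Variance components are therefore
non-negative by construction. Standard errors come from the inverse
*expected* information in $(\sigma^2_a, \sigma^2_e)$, which is well defined
on the boundary.

Narrow-sense heritability is $h^2 = \sigma^2_a/(\sigma^2_a + \sigma^2_e)$,
with a delta-method standard error propagated from the full
$(\sigma^2_a, \sigma^2_e)$ sampling covariance. Confidence bounds are
deliberately *not* truncated: a weakly supported heritability can print a
negative lower bound, which is informative. Significance of
$\sigma^2_a$ uses a one-sided Z-test (variances cannot be negative; at the
boundary the convention is $p = 0.5$, and the boundary makes the test
conservative). Fixed terms get incremental Wald F statistics at the
estimated covariance, with residual-method denominator degrees of freedom
$n - \mathrm{rank}(X)$; at $\lambda = 0$ these reduce exactly to classical
ANOVA F ratios.

Two failure modes are detected rather than silently absorbed: a
relatedness matrix containing off-diagonal values of 1 (clonal replicates
retained) is rejected with a pointer to clone filtering, and $M \approx I$
sets a non-identifiability flag because additive and residual variance are
then confounded.

### Genetic covariances

The paper-scale analysis wants a full G matrix across six traits. A joint
six-trait REML fit against a dense marker relatedness matrix is numerically
fragile, so the G matrix is assembled from univariate fits (diagonal) and
pairwise bivariate fits (off-diagonal). The bivariate likelihood uses
$\mathrm{Var}(a) = G_0 \otimes M$, $\mathrm{Var}(e) = R_0 \otimes I$ with
$G_0, R_0$ parameterized through Cholesky factors (log-scale diagonals) so
they stay positive semi-definite; optimization is Nelder–Mead from the
univariate solutions followed by a BFGS polish. A relative ridge of
$10^{-8}$ on $R_0$ keeps the restricted likelihood bounded when the two
traits are nearly collinear; for *exactly* collinear inputs the model is
singular and the additive covariance is returned as the (scaled)
univariate additive variance, which is its defined value. Covariance
Z-tests are two-sided (covariances may take either sign), from a numerical
Hessian in the direct $(V_{a1}, V_{a2}, \mathrm{cov}_a, \ldots)$
parameterization. Pairwise and joint multivariate fits can differ; the
pairwise construction guarantees symmetry but not joint positive
semi-definiteness of the assembled G, which is reported as-is.

## Phenology traits from soil temperature

Soil at 5 cm depth under snow sits within about half a degree of 0 °C; at
melt-out it warms sharply. `detectSnowmeltDay()` operationalizes this as:
the first day whose daily mean exceeds 1.5 °C after at least five
consecutive days with daily means inside ±0.5 °C. All three parameters are
exposed because the exact change-point rule is a judgment call; the
defaults are conservative enough that ±0.1 °C noise on the flat period
almost never produces a false melt day, and a gradual ramp is dated at the
threshold crossing. With several loggers per site the site value is the
median of per-logger days.

Growing-degree days accumulate $\max(0, \bar{T}_d - 5\,°\mathrm{C})$ over
an inclusive day window from the snowmelt day to the phenophase day; daily
means are taken over the twelve 2-hourly readings, and a day missing more
than a quarter of its readings is excluded and reported. The 5 °C base is
the threshold that tracks growth of alpine and arctic plants. Whether GDD
should accumulate sub-daily is not settled; daily means are the default
and `subDaily = TRUE` switches to per-reading truncation.

Leaf size is the ellipse area $\pi \cdot \tfrac{L}{2} \cdot \tfrac{W}{2}$.
Clonal performance is the stem-number ratio 2012/2011 (undefined, hence
missing, when the 2011 count is zero); sexual performance is the
proportion of flowering stems in 2012. A phenophase observed before the
site's snowmelt day indicates a record error; the trait is set missing and
the row flagged, never silently used. Missingness is per-trait, not
per-patch.

## Performance regressions

Each performance measure is regressed on the four standardized traits
(leaf size, snowmelt-to-leaf-expansion interval, GDD to leaf expansion,
GDD to flowering), microhabitat, and the four trait × microhabitat
interactions, in a Gaussian linear mixed model (REML) with random
intercepts for transect and site-within-transect. Standardization makes
slopes comparable across traits in the manner of a selection-gradient
analysis, though the responses are performance proxies, not fitness, and
no formal gradient interpretation is claimed. The proportion response is
modeled as Gaussian, not binomial — a documented simplification that keeps
the slopes on the standardized-trait scale. Per-term marginal Wald F tests
use nlme's containment denominator degrees of freedom; no multiplicity
correction is applied, and an interaction with $p < 0.05$ gates a separate
per-microhabitat refit from which habitat-specific slope signs are read.
Elevation is excluded from this model.

## What the synthetic generator emulates — and what it does not

`simulateGenotypes()` draws founder alleles from a symmetric
Dirichlet(0.5) spectrum over 23 alleles per locus at 7 loci, giving a few
common plus many rare alleles (expected heterozygosity ≈ 0.88, about 8
effective alleles) — the signature of a highly variable SSR panel.
Descendant cohorts arise by Mendelian inheritance from random parent
pairs; clonal patches are exact genotype copies at a declared rate;
the pedigree relationship matrix A, the clone map and the true
frequencies are recorded as ground truth. `simulateTraits()` is the
forward direction of the animal model: breeding values drawn with
covariance $\sigma^2_a A$ through a PSD factorization, i.i.d. residuals,
declared microhabitat/elevation/transect effects, optional multi-trait
generation with a declared genetic correlation. `simulateTemperature()`
plants a known melt day under a seasonal curve with a diurnal cycle;
`simulateDyads()` produces unrelated and parent–offspring pairs with
known generating frequencies for estimator calibration.

The paper-scale preset (`paperLikePreset()`) uses 939 genets sampled as
1061 patches across 12 sites, with the six declared heritabilities and
total variances. Its population descends from a small founding cohort (51
founders, two cohorts of 444 descendants), i.e. a locally founded stand
with substantial half- and full-sib structure. This choice matters: with
only seven loci, pairwise relatedness estimates carry a per-pair noise
standard deviation around 0.1, and in a shallow, mostly unrelated
population the marker matrix is almost pure noise. Family structure is
what gives the panel usable signal — and even then the marker-based
heritabilities are attenuated several-fold relative to the generating
values, reproducing the downward bias of marker-based estimates reported
in the literature. Passing recovery tests against the *pedigree* matrix
therefore shows the REML machinery is correct; passing the marker-based
ranking test shows the pipeline preserves relative ordering, not absolute
calibration. Real SSR data additionally contain genotyping error, null
alleles and frequency mis-specification, none of which the generator
emulates (an error flag is reserved but off).

Simulation sizes used by the test suite were chosen to exercise each
property at meaningful power: estimator calibration on 1000 dyads
(Monte-Carlo standard error of the mean ≈ 0.003), heritability recovery
at $n = 900$ with 20 replicate stands per level, clone recovery at 1000
patches, brute-force REML oracle checks at $n = 50$ where dense
likelihood evaluation is cheap, and scaled-down counterparts in the unit
tests.

## Numerical choices, in one place

* REML profile: $\lambda \in [10^{-6}, 10^{6}]$ log-grid (61 points) plus
  the 0 boundary, Brent refinement, boundary re-check; log-likelihood
  reported with the $\tfrac{n-p}{2}\log 2\pi$ constant.
* Standard errors: inverse expected information; delta method for $h^2$;
  CIs not truncated.
* Eigenvalues of $M$ clipped at 0 if above $-10^{-6}$; anything lower is
  an error directing to `nearPositiveDefinite()`.
* nearPD: `corr = TRUE` (unit diagonal restored each iteration),
  `eig.tol = 1e-6`, `conv.tol = 1e-7`, maxit 300, final eigen check at
  $-10^{-8}$.
* Bivariate REML: Cholesky parameterization, Nelder–Mead (reltol 1e-12,
  up to 2000 iterations) + BFGS polish, $10^{-8}$ relative ridge on $R_0$.
* Lynch-distance threshold 0.05 strict; representative choice from a
  dedicated seeded stream that never disturbs the session RNG.
* GDD: inclusive day windows; days with >25 % missing readings excluded.
* Standardization: $n-1$ denominator, computed over non-missing entries.

## Known limitations

Marker-based $h^2$ with a 7-locus panel is attenuated and should be read
as a lower bound; the package reports what the data support rather than
correcting the attenuation. The G matrix from pairwise fits need not be
jointly positive semi-definite. The proportion-flowering response is
treated as Gaussian. Wald F denominator degrees of freedom use simple
containment/residual rules rather than Satterthwaite or Kenward–Roger.
The snowmelt detector assumes the series spans the transition; seasons
with no closed snow cover are reported as errors, by design.
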