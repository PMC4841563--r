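---
title: "Functional regression tests of epistasis for multiple quantitative traits: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional regression tests of epistasis for multiple quantitative traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfrg)
```

## The problem and the model

Classical epistasis scans test one SNP pair at a time. For rare variants
this is hopeless: each pair carries almost no information and the multiple
testing burden explodes. `mfrg` instead takes the *gene* (genomic region) as
the unit of analysis and tests the cumulative interaction between all
variants of two regions against one or several correlated quantitative
traits at once.

The key device is to treat each individual's dosage vector across a region
as a *genotype function* $x_i(t)$ of genomic position $t$. For two regions
$[a_1, b_1]$ and $[a_2, b_2]$ and traits $y_{ik}$, $k = 1, \dots, K$, the
functional interaction model is

$$
y_{ik} = \alpha_{0k} + \sum_d \nu_{id}\tau_{kd}
       + \int_T \alpha_k(t)\,x_i(t)\,dt
       + \int_S \beta_k(s)\,x_i(s)\,ds
       + \int_T\!\!\int_S \gamma_k(t,s)\,x_i(t)\,x_i(s)\,dt\,ds
       + \varepsilon_{ik},
$$

with i.i.d. Gaussian errors $\varepsilon_i \sim N(0, \Sigma)$ across
individuals. Expanding the centered genotype functions in the orthonormal
eigenfunctions of their empirical covariance function,
$x_i(t) = \sum_j \xi_{ij}\phi_j(t)$ and
$x_i(s) = \sum_l \eta_{il}\psi_l(s)$, and truncating at $J$ and $L$
components turns this into an ordinary multivariate regression

$$
Y = e\,\alpha_0 + \nu\tau + \xi\alpha + \eta\beta + \Gamma\gamma + \varepsilon
  = W B + \varepsilon,
$$

where $\Gamma$ holds the $J \cdot L$ elementwise products
$\xi_{ij}\eta_{il}$. The least-squares solution is
$\hat B = (W'W)^{-1}W'Y$ with maximum-likelihood residual covariance
$\hat\Sigma = (Y - W\hat B)'(Y - W\hat B)/n$ (divisor $n$, not $n - p$: the
likelihood-ratio statistic below assumes the MLE form). Writing $A$ for the
last $J L$ rows of $(W'W)^{-1}W'$, the interaction block is
$\hat\gamma = A Y$ with covariance
$\Lambda = \hat\Sigma \otimes (A A')$ for the trait-major stacking
$\mathrm{vec}(\hat\gamma)$ (columns of the $JL \times K$ block stacked
trait by trait — the ordering the Kronecker form forces; it is asserted
against a brute-force $(I \otimes A)(\hat\Sigma \otimes I)(I \otimes A')$
construction in the tests so an ordering bug cannot slip through).

Two statistics test $H_0: \gamma = 0$:

* Wald: $T_I = \mathrm{vec}(\hat\gamma)'\,\Lambda^{-1}\,\mathrm{vec}(\hat\gamma)$,
* likelihood ratio: $T_{I\Lambda} = -n \log\left(|\hat\Sigma| / |\hat\Sigma_1|\right)$,

where $\hat\Sigma_1$ comes from the reduced model that keeps covariates and
both main-effect score blocks but drops $\Gamma$. Both are asymptotically
central $\chi^2$ with $K \cdot J \cdot L$ degrees of freedom under the
null. They agree asymptotically; the Wald form is the default because it
needs a single fit and its small-sample behavior on the simulated designs
is indistinguishable.

Covariates (sex, age, ancestry PCs from `ancestry_pcs()`) enter the design
directly rather than being residualized out beforehand, which keeps the
test exact under the stated model. Traits can be passed through the
rank-based inverse normal transform (`inverse_normal_transform()`, Blom
offset 3/8) to enforce marginal normality; in the scan driver this happens
after sample intersection and before fitting.

## Tunable parameters and their defaults

* **`variance_threshold = 0.8`** — retained components $J$ (and $L$) are
  the smallest number explaining 80% of the (quadrature-weighted) profile
  variance. 80% mirrors the conventional retention rule used for the
  ordinary-PC comparator; the realized $J, L$ always feed the degrees of
  freedom, so the choice trades power against df rather than validity.
* **`max_components = 10`** — a hard cap; rarely binding under the default
  smoothing.
* **`smoothing = "fourier"`, `n_smoothing_basis = 7`** — profiles are
  projected onto a constant plus three harmonic pairs before the
  eigen-expansion. The functional viewpoint presumes the genotype signal
  lives in a few smooth components; pre-smoothing enforces that, and it is
  what keeps $K \cdot J \cdot L$ modest (hence the $\chi^2$ approximation
  accurate) for regions with many variants — most visibly for rare-variant
  regions, whose raw covariance is near-diagonal and would otherwise
  require many components to reach any variance threshold.
  `smoothing = "none"` recovers the raw discrete expansion; with uniform
  quadrature weights that path coincides exactly with ordinary PCA of the
  centered dosage matrix, which is how it is cross-checked.
* **`quadrature = "trapezoid"`** — the simplest consistent discretization
  of the expansion integrals on irregular variant grids. Positions are
  affinely rescaled to $[0, 1]$; duplicate base-pair positions are jittered
  by one grid step, deterministically.
* **Allele orientation** — dosages count the *minor* allele by default
  (`orient = "alt"` in `read_region()` keeps the VCF ALT coding). The
  0/1/2 genotype coding does not by itself fix which allele is counted;
  counting the minor allele makes rare-variant semantics unambiguous.
  "Rare" defaults to MAF < 0.01 and "common" to MAF ≥ 0.05 in
  `filter_variants()` arms, both configurable.
* **Missing data** — missing genotypes are mean-imputed (to $2 \cdot$MAF)
  by default, which keeps the least-squares machinery dense; missing
  phenotypes/covariates drop the sample listwise.

## Numerical choices and degenerate inputs

* Regions need at least 4 variants: with 3 or fewer the eigenfunction
  expansion of the profiles is not meaningful, and such genes are skipped
  (and logged) in scans.
* Rank deficiency of $W$ — common for rare-variant $\Gamma$ columns, whose
  products are supported on a handful of double carriers — is handled by a
  pivoted QR on *column-equilibrated* $W$: exactly collinear or all-zero
  columns are dropped (with a classed warning) and the interaction df
  shrink to the realized block size. Equilibration matters: small-norm but
  independent product columns must survive.
* $\Lambda$ is inverted through its symmetric eigendecomposition; if the
  condition number exceeds `cond_max = 1e12` the pseudo-inverse is used and
  the df become the numerical rank, with a warning.
* Eigenfunction signs are fixed so each function's largest-magnitude grid
  value is positive; the statistics are invariant to sign flips and to
  rotations within tied eigenvalue blocks (both asserted in the tests).
* $T_{I\Lambda}$ is clipped at zero against roundoff; the determinant
  ordering $|\hat\Sigma| \le |\hat\Sigma_1|$ guarantees non-negativity in
  exact arithmetic.

## The synthetic generator

Reference data for the simulations in the original study of this design
were resampled exome haplotypes; the package replaces them with a
parametric stand-in, `haplotype_pool()`:

* **MAF spectra** — common: Uniform(0.05, 0.5); rare: Beta(0.5, 3) scaled
  to (1/n_hap, 0.01), a right-skewed spectrum in which a minority of
  near-1% variants dominates the region's variance, as in sequence data.
* **Linkage** — common-variant pools are built as segment mosaics of a
  small founder set (default 6 founders, per-variant switch rate 0.01).
  A real gene carries only a handful of common haplotypes, and it is this
  bounded haplotype diversity that makes genotype profiles genuinely
  low-dimensional; an LD-free pool (`ld = "none"`, available for
  comparison) is not a realistic model of resampled exomes. Rare variants
  are placed i.i.d. Bernoulli(MAF): recent mutations carry little LD.
* **Traits** — exchangeable correlation 0.5 with unit variances. Null
  scenarios: pure noise, marginal additive effects at one gene, or at both
  genes, with per-trait effects $\alpha_k = (r_k - 1) f_0$, risk parameters
  $r_k \sim U(1.1, 1.6)$ redrawn each replicate, $f_0 = 1$, and genotypes
  entering through the frequency-centered coding
  $\{2(1-P),\, 1-2P,\, -2P\}$ (mean zero under Hardy–Weinberg).
* **Interaction (power) models** — four two-locus penetrance tables
  (Dominant OR/AND Dominant, Recessive OR Recessive, Threshold; the
  threshold table is applied symmetrically in the two loci) assign a
  genotypic mean of 0 or $r$; 20% of each gene's variants are causal, and
  the i-th causal variant of gene 1 is paired with the i-th of gene 2
  (recycling the shorter list; an all-pairs mode exists). Each trait
  receives the genotypic sum scaled by an independent random sign
  (`trait_effects = "signed"`): the epistatic effect has magnitude $r$ in
  every trait but its direction varies across traits, the pleiotropic
  pattern that makes joint testing profitable. This matters more than it
  may look: if instead every trait carries the *identical* genetic sum
  (`trait_effects = "shared"`), the signal lies entirely along the
  equicorrelated direction of trait space, where exchangeable noise is
  largest — the noncentrality then scales as $K / (0.5K + 0.5)$, saturating
  at 2, while the degrees of freedom grow linearly in $K$, so multi-trait
  power *declines* with $K$. With sign heterogeneity the noncentrality
  scales as $\mathrm{tr}(\Sigma^{-1}) \propto K$ and the power of the joint
  test grows with the number of correlated traits, as it should for
  genuinely complementary phenotypes.

What the generator does *not* emulate: coalescent-realistic LD decay,
population stratification, cohort heterogeneity, genotyping error, and
binary traits. Passing type-I and power checks on these pools therefore
demonstrates the statistics' calibration and ranking under controlled,
realistic-scale conditions — not performance on any particular cohort.

## Design decisions that were genuinely open

* **Component selection.** No selection rule for $J, L$ is forced by the
  model; the 80%-of-variance rule with a small smoothing basis was chosen
  once, on the grounds that the method's premise is "a few" informative
  components and that df inflation visibly erodes the $\chi^2$ calibration
  when dozens of components are retained at these sample sizes.
* **Permutation scheme** for the pairwise comparator: phenotype rows are
  permuted jointly across traits (preserving their correlation), in a
  covariate-free model; the per-pair statistic is the squared Wald $t$ of
  the product coefficient. Pairs with degenerate product columns (no
  double carriers) are skipped rather than emitting NaNs.
* **Thresholding** in scans is Bonferroni on the realized number of tested
  pairs — the package computes the threshold from the scan itself rather
  than hard-coding any published constant; FDR control is deliberately out
  of scope.
* **Risk parameters** $r_k$ for the marginal-null scenarios are redrawn
  per replicate, matching the averaging-over-gene-pairs character of the
  reference tables.

## Problem sizes used in the checks

The packaged acceptance checks run 2,000 Monte-Carlo replicates per type-I
condition (common variants at $n$ = 1,000 and 5,000 with marginal effects
at both genes; rare variants at $n$ = 5,000 and 1,000 under the pure null,
$K = 5$ throughout), and 200 replicates per point of a five-point risk
grid for the power ordering (Dominant OR Dominant, $n$ = 2,000, 15 common
variants per gene, 20% causal, $K \in \{1, 2, 5, 10\}$; 200 permutations
for the pairwise comparator). These sizes put the Monte-Carlo standard
error near 0.005 on a rejection proportion of 0.05, comfortably inside the
tolerances being checked, while keeping a full run on one CPU in the
minutes range.

## Known limitations

* Binary traits, mixed-model relatedness adjustment, X-chromosome dosage
  compensation, phasing and imputation to reference panels are out of
  scope.
* The continuous interaction surface $\gamma(t, s)$ is tested, not
  estimated or visualized.
* The $\chi^2(KJL)$ reference is asymptotic; at $n$ = 1,000 a mild global
  inflation of the Wald statistic is visible (a consequence of the MLE
  residual covariance, divisor $n$), most clearly for rare-variant genes —
  it fades by $n$ = 5,000. For small $n$ or very large $K \cdot J \cdot L$,
  interpret marginal p-values cautiously.
* Power of the smoothed functional test is not uniformly superior: on short
  common-variant genes whose raw principal components already span the
  causal dosages, the ordinary-PC comparator can match or exceed it. The
  functional representation's advantage is concentrated where dimension
  reduction is decisive — regions with many variants and rare alleles.
* All-pairs genome scans stream pairs but are $O(G^2)$ tests; biobank-scale
  exhaustive scans are not a target.
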