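---
title: "Power of multivariate association tests for a single QTL: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Power of multivariate association tests for a single QTL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`mvqtlsim` is a simulation laboratory for comparing multivariate
genome-wide association tests on a single bi-allelic quantitative trait
locus (QTL). It has three layers: a generative model for genotypes and
correlated quantitative traits, native implementations of ten association
procedures, and a permutation engine that fixes every method's
false-positive rate empirically before comparing power. This vignette
documents the models, the tunable parameters, the numerical choices, and
what the simulation does and does not establish about real data.

## The generative model

Genotypes count copies of the minor allele at frequency $q$: each
individual's genotype is the sum of two independent Bernoulli($q$)
alleles, so genotype frequencies follow the Hardy–Weinberg proportions
$(p^2,\,2pq,\,q^2)$ with $p = 1 - q$. The minor allele is the effect
allele throughout.

Each of $k$ traits is an additive QTL contribution plus a residual,
$$Y_j = a_j G + e_j,\qquad
  a_j = \pm\sqrt{\frac{h^2_j}{2pq}},$$
where $h^2_j$ is the fraction of trait variance the QTL explains: with
residual variance $1 - h^2_j$, the genotype term contributes
$a_j^2 \cdot 2pq = h^2_j$, so the trait has unit variance and the QTL
explains exactly $h^2_j$ of it. The residual rows are multivariate normal
with variances $1 - h^2_j$ and common pairwise *correlation* `rE`
(off-diagonal covariance $r_E\sqrt{(1-h^2_j)(1-h^2_l)}$, so `rE` is
invariant to the heritabilities). After assembly every trait column is
centered and scaled to sample mean 0 and variance 1, mirroring how such
data are analyzed in practice; standardization uses the replicate's own
sample moments, not population values.

The sign of $a_j$ is a per-trait switch. Before scaling, the QTL induces
a cross-trait covariance $a_j a_l \cdot 2pq$, so opposite signs create a
*negative* genetic correlation on top of the (positive) residual one —
the regime in which direct multivariate tests gain the most power.

### The scenario grid

`scenario_grid()` enumerates the 30 default conditions: one, two or all
three of three traits associated (each associated trait with
$h^2 = 0.1\%$), the two signs of the induced genetic correlation where
two or more traits are associated, residual correlations
$r_E \in \{0, 0.3, 0.7\}$, and minor allele frequencies
$q \in \{0.01, 0.4\}$, at $N = 1000$ individuals, 1,000 replicates and 10
permutations per replicate. These defaults *are* the study conditions;
they are parameters of `scenario_spec()` only so that reduced-scale runs
(used in the analysis drivers) and the supplementary designs
(intermediate allele frequencies; the unequal-heritability grid
$h^2 = (0.001, 0.002, 0.0005)$ via `scenario_grid_unequal_h2()`) remain
expressible.

Reproducibility contract: a scenario's master seed spawns per-replicate
child seeds deterministically (`child_seed()`), and each replicate's
permutation stream is seeded from the same lineage. Identical
specification + seed gives bit-identical datasets, tables and figures,
and replicates can be regenerated in any order.

## The association tests

```{r}
library(mvqtlsim)
d <- simulate_dataset(scenario_spec(maf = 0.4, h2 = c(0.001, 0, 0),
                                    residual_corr = 0.7, seed = 1))
cca_test(d$genotype, d$traits)
bayes_mv_bf(d$genotype, d$traits)
```

**Canonical correlation (`cca_test`).** With a single variant the first
canonical correlation $r$ between genotype and traits satisfies
$r^2 = R^2$ of the regression of $G$ on $Y$, and
$F = \frac{n-1-k}{k}\frac{r^2}{1-r^2}$ is exact on $(k, n-1-k)$ degrees
of freedom (Rao's F for Wilks' $\Lambda$ with one variate). The test is
invariant under invertible affine recombinations of the traits.

**Conjugate Bayesian multivariate regression (`bayes_mv_bf`).** The
model $Y = 1\mu' + G\beta' + E$ with rows of $E$ iid $N(0,\Sigma)$,
$\beta \mid \Sigma \sim N(0, v_b\Sigma)$ and
$\Sigma \sim \mathrm{IW}(Q I_k,\, c)$ has matrix-variate-t marginal
likelihoods, so the $\log_{10}$ Bayes factor against $\beta = 0$ is a
ratio of determinant powers — no sampling. Defaults $v_b = 0.02$,
$Q = 6$, $c = 4$. Published front-ends differ in their inverse-Wishart
conventions, so both scalars are exposed verbatim; the convention used
here is scale matrix $Q I_k$ with degrees of freedom $c$, and the flat
prior on the mean is removed by centering, giving posterior degrees of
freedom $c + n - 1$. Under this convention the empirical 5% thresholds
on the null log10 Bayes factor stay in a narrow band around 0 across the
whole scenario grid (about $-0.03$ at common alleles to $0.27$ at
$q = 0.01$), which the acceptance checks pin down. $v_b = 0$ returns
exactly 0.
Genotypes enter as supplied, so expected imputation dosages are valid
input for this test.

**Reverse proportional-odds regression (`ordinal_reverse_lrt`).** The
genotype category ($0 < 1 < 2$) is regressed on all traits jointly and
the trait coefficients are tested with a likelihood-ratio statistic
against the intercepts-only model ($\chi^2_k$). The fitter is a direct
Newton–Raphson on the proportional-odds likelihood with analytic gradient
and Hessian (step-halving keeps the cutpoints ordered), which matches the
standard `polr` fit to optimizer tolerance but is an order of magnitude
faster — essential at permutation scale. Known failure mode of this model
family at low minor allele frequency: when the rarest genotype category
has fewer than 5 observations it is merged with its neighbour, and with
two categories the model is an ordinary logistic regression;
non-convergence raises a typed condition carrying diagnostics.

**Partition-averaged Bayes factor (`bimbam_partition_bf`).** Every
assignment of traits to unaffected (U), directly affected (D) and
indirectly affected (I) classes with at least one D is an alternative
model. Its Bayes factor factorizes: D traits are regressed on genotype
with the U traits as covariates under a conjugate normal effect prior
(prior effect SD averaged with equal weight over the grid
$\sigma_a \in \{0.1, 0.2\}$, on the standardized-trait scale); I traits
depend only on D traits and U traits are independent of the genotype, so
those factors cancel against the null. The overall Bayes factor averages
the partitions with equal weight, and per-trait class posteriors are
reported. The conditional priors (flat on covariate coefficients,
Jeffreys on the error variance) follow the standard conjugate framework;
they are the one place where detailed prior choices were genuinely open,
and they are confined to this function.

**Principal component of heritability (`pch_test`).** Training subsets
(150 individuals, drawn without replacement) estimate the trait
combination maximizing the heritable variance share — weights
$\propto \hat\Sigma_e^{-1}\hat a$, normalized, averaged over bootstrap
bags — and the held-out individuals' combined score is regressed on
genotype. Per-split t statistics are averaged (200 splits for the
observed statistic, 50 per permutation replicate, 50 bags, 1,000
permutations by default). The final p-value refers the pooled statistic
to a scaled-t whose standard deviation and degrees of freedom are
moment-matched to the permutation distribution (degrees of freedom from
the excess kurtosis, $\nu = 6/\hat\kappa + 4$, clamped to $[5, 1000]$).
The subset-sampling scheme, pooling rule and df estimation were
under-specified in the original description; the choices above are
exposed in `pch_settings()` and the method is therefore held only to
qualitative calibration checks.

**Univariate-based procedures.** Per-trait OLS slope t-tests
(`uv_linear_tests`); their minimum p (`uv_min_p`), the family-wise
statistic whose permutation null sets the adjusted univariate threshold;
the first principal component tested univariately (`uv_pca_test`);
the sample-size-weighted signed-Z meta-analysis (`meta_samplesize`,
$Z = \sum w_j Z_j / \sqrt{\sum w_j^2}$, $w_j = \sqrt{n_j}$), which loses
power when effect signs oppose; Fisher's method (`fisher_combine`),
sign-free by construction; and the extended-Simes combination `tates`.

**Extended Simes (`tates`).** Sorted p-values $p_{(1)} \le \dots \le
p_{(k)}$ are combined as $\min_j m_e \, p_{(j)} / m_e(j)$, where
$m_e(j)$ is the Li–Ji effective number of tests among the top $j$
traits: $\sum_i [\,\mathbb{1}(\lambda_i \ge 1) + (\lambda_i -
\lfloor\lambda_i\rfloor)\,]$ over the eigenvalues of the (absolute)
p-value correlation matrix. The bridge from trait correlations to
p-value correlations is estimated by Monte Carlo once per session — on a
grid of underlying correlations, two-sided p-values of bivariate-normal
z-scores are correlated empirically (50,000 draws, fixed internal
stream, interpolated thereafter) — because the original polynomial
coefficients are not public; a `polynomial` mode accepts user-supplied
coefficients. Two numerical points deserve note: eigenvalues within
$10^{-8}$ of an integer are snapped before the floor (the Li–Ji rule is
discontinuous at integers, and exactly collinear traits otherwise flip
between 1 and 2 effective tests on floating-point noise), and the raw
vs absolute correlation choice is a documented switch (`use_abs`,
default absolute).

## Calibration and power

Thresholds are empirical, never nominal. For each scenario, every
dataset's trait matrix is row-permuted against its fixed genotype 10
times (preserving the trait correlation structure exactly), each method
is run on all $M = 10{,}000$ permuted replicates, and the threshold is
the mean of the $\lfloor \alpha M \rfloor$-th and next order statistics
in the significance direction — the mean of the 500th and 501st values at
the study scale, generalized so reduced-$M$ runs stay well defined.
Strict inequality defines significance (p below, Bayes factor above),
and by construction each method's own null is rejected at exactly 5%.
Ties straddling the cut leave the threshold defined and emit a warning
with the achieved rate. Power is the percentage of 1,000 replicates
passing the threshold, with a Wilson 95% interval (chosen over the Wald
interval because it behaves well at the tail rejection rates involved).

Monomorphic genotype draws (realistic only at $q = 0.01$, probability
$\approx (1-q)^{2N}$) are *not* silently redrawn: the affected method
raises a typed error, the engine counts it, and a scenario-method cell
fails only above a configurable error-rate cap. Silent redraws would
bias the null distributions.

## What the tests and drivers compute

The `analysis/` drivers are reduced-scale narratives (200–300 replicates
per scenario, a subset of scenarios) chosen so each script runs in about
a minute while preserving every qualitative contrast; the package's test
suite and `scripts/acceptance.R` run the headline quantities at the full
$M = 10{,}000$ / 1,000-replicate scale. The heritability-component test
runs at reduced split/permutation settings everywhere outside its
defaults because its nested resampling dominates runtime; its defaults
remain the study configuration.

## What passing does and does not show

The simulator emulates a single additive bi-allelic QTL in
Hardy–Weinberg equilibrium with equicorrelated Gaussian residuals and
complete data. It deliberately omits linkage disequilibrium, multiple
causal variants, covariates, family and population structure, genotype
uncertainty, non-additive effects, binary traits, missingness and trait
outliers. Power rankings established here therefore speak to the
correlation-structure mechanics of the methods — how each converts
cross-trait correlation and effect-sign patterns into evidence — not to
robustness against the failure modes of real cohorts (the
canonical-correlation test, for instance, is known to inflate under
trait outliers at low allele frequencies, which this design cannot
exhibit).
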