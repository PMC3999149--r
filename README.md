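# mvqtlsim

Simulation-based power comparison of multivariate GWAS tests for a
single quantitative trait locus (QTL).

When several correlated quantitative traits are measured on the same
cohort, a variant can be tested against all of them jointly instead of
one trait at a time. Joint tests exploit the cross-trait covariance and
avoid the multiple-testing penalty, but their relative power depends
sharply on how the QTL-induced (genetic) correlation lines up with the
residual correlation between traits. `mvqtlsim` is for methodologists
and analysts who want to quantify those trade-offs under controlled
conditions: it simulates the canonical single-QTL multi-trait design and
compares ten association procedures at an *empirically fixed*
false-positive rate.

## What is implemented

**Generative model.** Genotypes $G \in \{0,1,2\}$ count minor alleles at
frequency $q$, drawn as two independent Bernoulli($q$) alleles (exact
Hardy–Weinberg). Traits are $Y_j = a_j G + e_j$ with
$a_j = \pm\sqrt{h^2_j / (2pq)}$, so the QTL explains exactly the chosen
heritability $h^2_j$ of each unit-variance trait; residuals are
multivariate normal with pairwise correlation $r_E$; columns are
standardized. Signs of $a_j$ set the sign of the genetic correlation.
`scenario_grid()` enumerates the 30 default conditions (1/2/3 associated
traits × rG sign × $r_E \in \{0, 0.3, 0.7\}$ × $q \in \{0.01, 0.4\}$,
$N = 1000$, $h^2 = 0.1\%$ per associated trait).

**Association tests** (uniform interface, genotype vector + trait
matrix): canonical correlation / MANOVA exact F (`cca_test`); conjugate
Bayesian multivariate-regression log10 Bayes factor with matrix-normal
effect and inverse-Wishart error priors (`bayes_mv_bf`); reverse
proportional-odds regression joint LRT (`ordinal_reverse_lrt`);
partition-averaged Bayes factor over unaffected / directly / indirectly
affected trait groups (`bimbam_partition_bf`); principal component of
heritability with training/test splits, bagging and an internal
permutation null (`pch_test`); extended-Simes trait-based combination
(`tates`); and the univariate family — per-trait OLS (`uv_linear_tests`),
minimum p (`uv_min_p`), first principal component (`uv_pca_test`),
sample-size-weighted signed-Z meta-analysis (`meta_samplesize`),
Fisher's method (`fisher_combine`).

**Evaluation engine.** `run_study()` simulates each scenario's
replicates, builds the permutation null (trait rows permuted against the
fixed genotype, 10 permutations per replicate), derives each method's
empirical 5% threshold as the mean of the bracketing null order
statistics (500th/501st of 10,000 at full scale), and reports power over
the replicates with Wilson 95% intervals. Everything is deterministic
given the scenario seeds.

## Worked example

```r
library(mvqtlsim)

sp <- scenario_spec(maf = 0.4, h2 = c(0.001, 0, 0), residual_corr = 0.7,
                    n_replicates = 200, n_permutations = 10, seed = 2024)
st <- run_study(sp, methods = c("uv", "cca", "bayes", "tates"))
st$thresholds[, c("method", "measure_kind", "threshold")]
#>  method measure_kind   threshold
#>      uv      p_value 0.020161560
#>     cca      p_value 0.047631364
#>   bayes     log10_bf 0.003751812
#>   tates      p_value 0.054583070
st$power[, c("method", "power", "ci_lower", "ci_upper")]
#>  method power  ci_lower ci_upper
#>      uv   9.0  5.768745 13.77657
#>     cca  19.5 14.605521 25.54404
#>   bayes  19.5 14.605521 25.54404
#>   tates   9.0  5.768745 13.77657
```

One trait of three carries a 0.1% QTL effect and the traits share a 0.7
residual correlation. The univariate family-wise threshold tightens to
about 2% (three correlated tests), while the multivariate p-value
methods calibrate near the nominal 5% and the Bayes-factor threshold
sits near 0. At matched 5% type-I error the joint tests roughly double
the power of the univariate analysis (19.5% vs 9% here at 200
replicates) — the high residual correlation sharpens the contrast between
the single affected trait and its correlated neighbours, which the
per-trait and extended-Simes analyses cannot exploit.

The `analysis/` directory holds numbered reduced-scale drivers:
`01_simulate.R` (scenario grid and generative checks), `02_thresholds.R`
(threshold structure across residual correlations), `03_power.R` (power
contrasts including the negative-genetic-correlation regime) and
`04_report.R` (grouped summary and bar chart). Each writes its tables
under `results/`.

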