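test_that("genotypes follow Hardy-Weinberg proportions", {
  set.seed(41)
  g <- simulate_genotypes(1e6, 0.4)
  freq <- tabulate(g + 1L, 3L) / 1e6
  expect_equal(freq, c(0.36, 0.48, 0.16), tolerance = 0.01)
  expect_equal(mean(g), 0.8, tolerance = 0.01)
  chisq <- sum((tabulate(g + 1L, 3L) - 1e6 * c(0.36, 0.48, 0.16))^2 /
                 (1e6 * c(0.36, 0.48, 0.16)))
  expect_lt(chisq, qchisq(0.999, df = 2))

  # rare-allele expectation: mean minor-allele count over seeded draws
  set.seed(42)
  counts <- replicate(1000, sum(simulate_genotypes(1000, 0.01)))
  se <- sd(counts) / sqrt(1000)
  expect_lt(abs(mean(counts) - 20), 3 * se)

  expect_true(all(simulate_genotypes(1000, 0) == 0))
  expect_true(all(simulate_genotypes(500, 0.25) %in% 0:2))
  expect_error(simulate_genotypes(10, 0.6), "minor allele frequency")
})

test_that("QTL effect size makes the locus explain exactly h2", {
  expect_identical(qtl_effect_size(0, 0.4), 0)
  expect_equal(qtl_effect_size(0.001, 0.4), sqrt(0.001 / (2 * 0.6 * 0.4)))
  # rarer allele, larger effect at fixed heritability
  expect_gt(qtl_effect_size(0.001, 0.01), qtl_effect_size(0.001, 0.4))
  expect_error(qtl_effect_size(0.001, 0), "monomorphic")

  # empirical explained-variance recovery at large n
  set.seed(7)
  n <- 1e6
  q <- 0.4
  h2 <- 0.001
  g <- simulate_genotypes(n, q)
  a <- qtl_effect_size(h2, q)
  y <- a * g + rnorm(n, sd = sqrt(1 - h2))
  r2 <- summary(lm(y ~ g))$r.squared
  expect_equal(r2, h2, tolerance = 0.15)  # Monte-Carlo error at h2 = 1e-3
})

test_that("residuals have the generating covariance structure", {
  set.seed(11)
  h2 <- c(0.001, 0.001, 0.001)
  e <- simulate_residuals(1e6, h2, 0.7)
  cors <- cor(e)[upper.tri(diag(3))]
  expect_equal(cors, rep(0.7, 3), tolerance = 0.003)
  expect_equal(apply(e, 2, var), 1 - h2, tolerance = 0.005,
               ignore_attr = TRUE)
  e0 <- simulate_residuals(2e5, h2, 0)
  expect_lt(max(abs(cor(e0)[upper.tri(diag(3))])), 0.01)
  expect_error(simulate_residuals(10, c(0, 0, 0), -0.6),
               "positive definite")
})

test_that("assembled traits are standardized and carry the signed genetic correlation", {
  set.seed(3)
  g <- simulate_genotypes(2000, 0.4)
  e <- simulate_residuals(2000, c(0.001, 0.001), 0)
  a <- c(-1, 1) * qtl_effect_size(c(0.001, 0.001), 0.4)
  Y <- assemble_traits(g, a, e)
  expect_equal(colMeans(Y), c(0, 0), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(apply(Y, 2, var), c(1, 1), tolerance = 1e-10,
               ignore_attr = TRUE)

  # a = 0: output is just the standardized residuals
  Y0 <- assemble_traits(g, c(0, 0), e)
  expect_equal(Y0, scale(e), tolerance = 1e-12, ignore_attr = TRUE)

  # opposite effect signs with rE = 0 induce corr(Y1, Y2) = -h2 at large n
  set.seed(4)
  n <- 1e6
  g <- simulate_genotypes(n, 0.4)
  e <- simulate_residuals(n, c(0.001, 0.001), 0)
  Y <- assemble_traits(g, c(-1, 1) * qtl_effect_size(c(0.001, 0.001), 0.4), e)
  expect_lt(abs(cor(Y)[1, 2] - (-0.001)), 3e-3)
  expect_lt(cor(Y)[1, 2], 0)
})

test_that("total trait correlation combines genetic and residual parts", {
  # corr = sign(a_j a_l) h2 + rE (1 - h2) for equal h2
  set.seed(5)
  n <- 5e5
  h2 <- 0.01  # larger h2 so the genetic part is visible above MC noise
  g <- simulate_genotypes(n, 0.4)
  e <- simulate_residuals(n, c(h2, h2), 0.3)
  Y <- assemble_traits(g, c(1, 1) * qtl_effect_size(h2, 0.4), e)
  expect_equal(cor(Y)[1, 2], h2 + 0.3 * (1 - h2), tolerance = 0.01)
})

test_that("datasets are bit-identical under the same spec and seed", {
  sp <- scenario_spec(maf = 0.25, h2 = c(0.001, 0, 0), residual_corr = 0.3,
                      seed = 77)
  d1 <- simulate_dataset(sp, 5)
  d2 <- simulate_dataset(sp, 5)
  expect_identical(d1$genotype, d2$genotype)
  expect_identical(d1$traits, d2$traits)
  d3 <- simulate_dataset(sp, 6)
  expect_false(identical(d1$traits, d3$traits))
})

test_that("the default scenario grid reproduces the published design", {
  grid <- scenario_grid()
  expect_length(grid, 30)
  for (sp in grid) {
    assoc <- sp$effect_sign != 0
    expect_true(all(sp$h2[assoc] == 0.001))
    expect_true(all(sp$h2[!assoc] == 0))
    expect_equal(sp$n_individuals, 1000L)
    expect_equal(sp$n_replicates, 1000L)
    expect_equal(sp$n_permutations, 10L)
  }
  n_assoc <- vapply(grid, function(s) sum(s$effect_sign != 0), 0L)
  expect_equal(as.vector(table(n_assoc)), c(6L, 12L, 12L))
  expect_setequal(unique(vapply(grid, `[[`, 0, "maf")), c(0.01, 0.4))
  expect_setequal(unique(vapply(grid, `[[`, 0, "residual_corr")),
                  c(0, 0.3, 0.7))
  # distinct per-scenario seeds
  expect_equal(anyDuplicated(vapply(grid, `[[`, 0L, "seed")), 0L)

  uneq <- scenario_grid_unequal_h2()
  expect_length(uneq, 12)
  for (sp in uneq) expect_equal(sp$h2, c(0.001, 0.002, 0.0005))

  supp <- scenario_grid(maf = c(0.05, 0.10, 0.25))
  expect_length(supp, 45)
})

test_that("scenario validation rejects inconsistent parameterizations", {
  expect_error(scenario_spec(h2 = c(0.001, 0, 0),
                             effect_sign = c(0, 1, 0)),
               "if and only if")
  expect_error(scenario_spec(maf = 0.7), "minor allele")
  expect_error(scenario_spec(h2 = c(0.5, 0.5, 0.5), residual_corr = -0.6),
               "positive")
  expect_error(scenario_spec(maf = 0, h2 = c(0.001, 0, 0)), "monomorphic")
})
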