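sp_null <- scenario_spec(maf = 0.4, h2 = c(0, 0, 0),
                         effect_sign = c(0, 0, 0), residual_corr = 0.3,
                         n_individuals = 1000, seed = 100)

test_that("canonical correlation test agrees with a MANOVA oracle", {
  set.seed(51)
  for (i in 1:5) {
    g <- sample(0:2, 20, replace = TRUE, prob = c(0.36, 0.48, 0.16))
    if (max(g) == min(g)) next
    Y <- matrix(rnorm(60), 20, 3)
    expect_equal(cca_test(g, Y)$measure, oracle_manova_p(g, Y),
                 tolerance = 1e-8)
  }
})

test_that("canonical correlation test has exact degenerate reductions", {
  set.seed(52)
  d <- simulate_dataset(sp_null, 1)
  # k = 1: F = t^2, identical p
  y1 <- d$traits[, 1, drop = FALSE]
  expect_equal(cca_test(d$genotype, y1)$measure,
               uv_linear_test(d$genotype, y1[, 1])$p, tolerance = 1e-12)
  # genotype orthogonalized against the traits in-sample: r = 0, p = 1
  g <- d$genotype
  Y <- d$traits
  Yt <- Y - tcrossprod(rep(1, nrow(Y)) / nrow(Y), colSums(Y))  # centered
  g_orth <- resid(lm(g ~ Y))
  # orthogonal *traits*: regress each trait column on g and keep residuals
  Y_orth <- apply(Y, 2, function(y) resid(lm(y ~ g)))
  expect_equal(cca_test(g, Y_orth)$measure, 1)
  expect_equal(cca_test(g, Y_orth)$detail$r, 0)
  # rank-deficient traits rejected
  expect_error(cca_test(g, cbind(Y, Y[, 1])), "rank deficient")
  expect_error(cca_test(rep(1, 1000), Y), class = "mvqtlsim_monomorphic")
})

test_that("canonical correlation test is affine invariant in the traits", {
  set.seed(53)
  d <- simulate_dataset(sp_null, 2)
  A <- matrix(c(2, 0.5, -1, 0, 1, 3, 0.2, 0, 1), 3, 3)
  shift <- c(5, -2, 0.1)
  Y2 <- sweep(d$traits %*% A, 2, shift, "+")
  expect_equal(cca_test(d$genotype, Y2)$measure,
               cca_test(d$genotype, d$traits)$measure, tolerance = 1e-9)
})

test_that("multivariate Bayes factor matches quadrature in one dimension", {
  set.seed(54)
  n <- 60
  g <- sample(0:2, n, replace = TRUE, prob = c(0.36, 0.48, 0.16))
  y <- 0.2 * g + rnorm(n)
  pri <- bayes_priors(v_b = 0.02, iw_scale = 6, iw_df = 4)
  got <- bayes_mv_bf(g, matrix(y), pri)$measure
  ora <- oracle_bf_quadrature(g, y, v_b = 0.02, Q = 6, cc = 4)
  expect_equal(got, ora, tolerance = 1e-3)
  # a second prior configuration
  pri2 <- bayes_priors(v_b = 0.1, iw_scale = 2, iw_df = 3)
  expect_equal(bayes_mv_bf(g, matrix(y), pri2)$measure,
               oracle_bf_quadrature(g, y, 0.1, 2, 3), tolerance = 1e-3)
})

test_that("multivariate Bayes factor has the analytic limits and monotonicity", {
  set.seed(55)
  d <- simulate_dataset(sp_null, 3)
  # v_b = 0: models coincide exactly
  expect_identical(
    bayes_mv_bf(d$genotype, d$traits, bayes_priors(v_b = 0))$measure, 0)
  # monotone in the simulated effect size at fixed seed
  bf <- vapply(c(0, 0.05, 0.1, 0.2), function(a) {
    Y <- d$traits
    Y[, 1] <- Y[, 1] + a * d$genotype
    bayes_mv_bf(d$genotype, scale(Y))$measure
  }, numeric(1))
  expect_true(all(diff(bf) > 0))
  # trait-order invariance
  expect_equal(bayes_mv_bf(d$genotype, d$traits)$measure,
               bayes_mv_bf(d$genotype, d$traits[, c(2, 3, 1)])$measure,
               tolerance = 1e-10)
  expect_error(bayes_mv_bf(d$genotype, d$traits,
                           bayes_priors(iw_df = 1)), "proper")
})

test_that("reverse ordinal regression is calibrated and reduces to logistic", {
  # asymptotic calibration: p-values uniform under the null
  p <- vapply(1:2000, function(i) {
    d <- simulate_dataset(sp_null, i)
    ordinal_reverse_lrt(d$genotype, d$traits)$measure
  }, numeric(1))
  expect_gt(ks.test(p, "punif")$p.value, 0.001)

  # two observed genotype categories: equals the logistic LRT oracle
  set.seed(57)
  n <- 300
  g <- rbinom(n, 1, 0.3)  # only categories 0/1
  Y <- matrix(rnorm(3 * n), n, 3)
  got <- ordinal_reverse_lrt(g, Y)
  expect_true(got$detail$binary)
  expect_equal(got$measure, oracle_logistic_lrt_p(g, Y), tolerance = 1e-6)

  # constant trait column dropped with warning, df reduced
  Yc <- cbind(Y, 5)
  colnames(Yc) <- paste0("Y", 1:4)
  d0 <- simulate_dataset(sp_null, 9)
  expect_warning(r <- ordinal_reverse_lrt(d0$genotype,
                                          cbind(d0$traits, Y4 = 1)),
                 "constant")
  expect_equal(r$detail$df, 3)

  expect_error(ordinal_reverse_lrt(rep(2, 100), matrix(rnorm(300), 100)),
               class = "mvqtlsim_monomorphic")
})

test_that("ordinal fit matches the reference proportional-odds fitter", {
  set.seed(58)
  for (i in 1:3) {
    d <- simulate_dataset(sp_null, 20 + i)
    own <- ordinal_reverse_lrt(d$genotype, d$traits, se = TRUE)
    ref <- MASS::polr(factor(d$genotype, ordered = TRUE) ~ d$traits,
                      method = "logistic", Hess = TRUE)
    expect_equal(unname(own$detail$coef), unname(ref$coefficients),
                 tolerance = 1e-2)  # polr's optimizer tolerance is looser
    expect_equal(own$detail$lrt,
                 2 * (as.numeric(logLik(ref)) -
                        sum(table(d$genotype) *
                              log(table(d$genotype) / 1000))),
                 tolerance = 1e-6)
    expect_equal(unname(own$detail$se),
                 unname(sqrt(diag(vcov(ref))[1:3])), tolerance = 1e-3)
  }
})

test_that("partition-averaged Bayes factor reduces and bounds correctly", {
  set.seed(59)
  n <- 80
  g <- sample(0:2, n, replace = TRUE, prob = c(0.36, 0.48, 0.16))
  y <- 0.15 * g + rnorm(n)
  pri <- bayes_priors()
  # k = 1: the only partition is {D}; equals the grid-averaged
  # univariate conjugate BF, cross-checked by quadrature
  got <- bimbam_partition_bf(g, matrix(y), pri)$measure
  ora <- log(mean(exp(vapply(pri$sigma_a, function(s)
    oracle_bf_uni_quadrature(y, g, matrix(1, n), s), numeric(1))))) / log(10)
  expect_equal(got, ora, tolerance = 1e-3)

  # overall BF >= max partition BF / number of partitions
  d <- simulate_dataset(sp_null, 4)
  res <- bimbam_partition_bf(d$genotype, d$traits, pri)
  lps <- res$detail$log10_bf_partitions
  expect_gte(res$measure, max(lps) - log10(length(lps)) - 1e-10)
  # class posteriors are a proper distribution per trait
  expect_equal(unname(rowSums(res$detail$class_posterior)), rep(1, 3),
               tolerance = 1e-10)
  # trait-order invariance of the overall measure
  expect_equal(res$measure,
               bimbam_partition_bf(d$genotype,
                                   d$traits[, c(3, 1, 2)], pri)$measure,
               tolerance = 1e-10)
})

test_that("partition-averaged Bayes factor is null-consistent", {
  lbf <- vapply(1:300, function(i) {
    d <- simulate_dataset(sp_null, i)
    set.seed(child_seed(sp_null$seed, i, stream = 2L))
    dp <- permute_dataset(d)
    bimbam_partition_bf(dp$genotype, dp$traits)$measure
  }, numeric(1))
  expect_lte(median(lbf), 0)
})
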