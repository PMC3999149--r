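test_that("trait permutation preserves trait structure and the genotype", {
  sp <- scenario_spec(maf = 0.4, h2 = c(0.001, 0.001, 0),
                      effect_sign = c(1, 1, 0), residual_corr = 0.7,
                      seed = 61)
  d <- simulate_dataset(sp, 1)
  set.seed(61)
  dp <- permute_dataset(d)
  expect_identical(dp$genotype, d$genotype)
  expect_equal(cor(dp$traits), cor(d$traits), tolerance = 1e-12)
  expect_equal(sort(dp$traits[, 1]), sort(d$traits[, 1]))
  expect_false(identical(dp$traits, d$traits))

  # permuted replicates carry no association on average
  p_mean <- mean(vapply(1:400, function(i) {
    d <- simulate_dataset(sp, i)
    set.seed(child_seed(sp$seed, i, stream = 1L))
    dp <- permute_dataset(d)
    uv_linear_test(dp$genotype, dp$traits[, 1])$p
  }, numeric(1)))
  expect_lt(abs(p_mean - 0.5), 3 * sqrt(1 / 12 / 400))
})

test_that("empirical threshold is the mean of the bracketing order statistics", {
  expect_equal(as.numeric(empirical_threshold((1:10000) / 10000, 0.05,
                                              "p_value")),
               (0.0500 + 0.0501) / 2)
  # uniform null: threshold close to alpha
  set.seed(62)
  u <- runif(10000)
  thr <- empirical_threshold(u, 0.05, "p_value")
  expect_lt(abs(thr - 0.05), 3 * sqrt(0.05 * 0.95 / 10000))
  # BF direction: exactly 500 of 10,000 exceed the threshold
  set.seed(63)
  bf <- rnorm(10000)
  thr_bf <- empirical_threshold(bf, 0.05, "log10_bf")
  expect_identical(sum(bf > thr_bf), 500L)
  # shifting all BF measures shifts the threshold by the same constant
  thr_shift <- empirical_threshold(bf + 2.5, 0.05, "log10_bf")
  expect_equal(as.numeric(thr_shift), as.numeric(thr_bf) + 2.5,
               tolerance = 1e-12)
  # ill-posed requests are refused; heavy ties produce a warning
  expect_error(empirical_threshold(runif(10), 0.05, "p_value"), "too few")
  expect_warning(empirical_threshold(rep(c(0.03, 0.5), c(30, 70)) , 0.05,
                                     "p_value"), "ties")
})

test_that("family-wise univariate threshold matches the independence closed form", {
  set.seed(64)
  minp <- apply(matrix(runif(30000), ncol = 3), 1, min)
  thr <- uv_adjusted_threshold(minp, 0.05)
  expect_lt(abs(thr - (1 - 0.95^(1 / 3))), 0.003)
  # single trait: no adjustment
  thr1 <- uv_adjusted_threshold(runif(10000), 0.05)
  expect_lt(abs(thr1 - 0.05), 0.01)
})

test_that("power computation counts strict exceedances with a Wilson interval", {
  pw <- compute_power(c(0.2, 0.3, 0.4), 0.1, "p_value")
  expect_equal(pw$power, 0)
  pw2 <- compute_power(seq(0.001, 1, length.out = 1000), 0.05, "p_value")
  expect_equal(pw2$power, 100 * mean(seq(0.001, 1, length.out = 1000) < 0.05))
  expect_true(pw2$ci[1] < pw2$power && pw2$power < pw2$ci[2])
  # calibrated null vs its own threshold: power = alpha by construction
  set.seed(65)
  u <- runif(10000)
  thr <- empirical_threshold(u, 0.05, "p_value")
  expect_equal(compute_power(u, thr, "p_value")$power, 5, tolerance = 1e-8)
  # BF direction
  bf <- rnorm(2000, 1)
  expect_equal(compute_power(bf, quantile(bf, 0.9), "log10_bf")$power, 10,
               tolerance = 0.2)
})

test_that("univariate power agrees with the noncentral-t closed form", {
  sp <- scenario_spec(maf = 0.4, h2 = c(0.001, 0, 0), residual_corr = 0,
                      seed = 66)
  n_rep <- 1000
  p1 <- vapply(1:n_rep, function(i) {
    d <- simulate_dataset(sp, i)
    uv_linear_test(d$genotype, d$traits[, 1])$p
  }, numeric(1))
  alpha_adj <- 1 - 0.95^(1 / 3)
  pw <- compute_power(p1, alpha_adj, "p_value")
  analytic <- 100 * oracle_uv_power(1000, 0.001, alpha_adj)
  expect_lt(abs(pw$power - analytic), (pw$ci[2] - pw$ci[1]) / 2 + 0.5)
})

test_that("the study driver is deterministic and correctly shaped", {
  sp <- scenario_spec(maf = 0.4, h2 = c(0.001, 0, 0), residual_corr = 0.7,
                      n_replicates = 40, n_permutations = 5, seed = 67)
  st1 <- run_study(sp, methods = c("uv", "cca", "bayes"), verbose = FALSE)
  st2 <- run_study(sp, methods = c("uv", "cca", "bayes"), verbose = FALSE)
  expect_identical(st1$thresholds, st2$thresholds)
  expect_identical(st1$power, st2$power)
  expect_equal(nrow(st1$power), 3)
  expect_setequal(st1$thresholds$measure_kind[st1$thresholds$method == "bayes"],
                  "log10_bf")
  expect_true(all(st1$power$power >= 0 & st1$power$power <= 100))
  expect_true(all(st1$thresholds$n_null == 200))

  # grid bookkeeping: scenarios x methods rows
  grid2 <- scenario_grid(maf = 0.4, rE = c(0, 0.3),
                         n_replicates = 30, n_permutations = 4, seed = 68)
  st3 <- run_study(grid2[1:2], methods = c("uv", "cca"), verbose = FALSE)
  expect_equal(nrow(st3$power), 4)
})

test_that("multivariate power is not below univariate power in a matched run", {
  # one associated trait, high residual correlation: the canonical test
  # should dominate the per-trait analysis at matched type-I error
  sp <- scenario_spec(maf = 0.4, h2 = c(0.001, 0, 0), residual_corr = 0.7,
                      n_replicates = 400, n_permutations = 10, seed = 69)
  st <- run_study(sp, methods = c("uv", "cca"), verbose = FALSE)
  p_uv <- st$power$power[st$power$method == "uv"]
  p_cca <- st$power$power[st$power$method == "cca"]
  ci_w <- with(st$power[st$power$method == "cca", ], ci_upper - ci_lower)
  expect_gte(p_cca, p_uv - ci_w / 2)
})
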