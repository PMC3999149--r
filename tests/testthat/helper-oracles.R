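# Independent oracles used across the test files. These deliberately take
# different computational routes than the package implementations.

# OLS slope t-test via explicit normal equations on the design matrix.
oracle_ols <- function(g, y) {
  X <- cbind(1, g)
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  resid <- y - X %*% beta
  n <- length(y)
  s2 <- sum(resid^2) / (n - 2)
  se <- sqrt(s2 * solve(XtX)[2, 2])
  tval <- beta[2] / se
  list(slope = beta[2], se = se, t = tval,
       p = 2 * pt(-abs(tval), df = n - 2))
}

# Wilks'-lambda MANOVA of the traits on the genotype via R's manova().
oracle_manova_p <- function(g, Y) {
  fit <- manova(Y ~ g)
  summary(fit, test = "Wilks")$stats["g", "Pr(>F)"]
}

# log10 Bayes factor for the k = 1 conjugate model by brute-force 2-D
# quadrature over (b, sigma2) in log space. Mirrors the model definition:
# flat prior on the mean (integrated analytically), b ~ N(0, v_b*sigma2),
# sigma2 ~ inverse-gamma(c/2, Q/2) (the 1-D inverse Wishart IW(Q, c)).
oracle_bf_quadrature <- function(g, y, v_b, Q, cc) {
  n <- length(y)
  yc <- y - mean(y)
  gc <- g - mean(g)
  syy <- sum(yc^2)
  s2hat <- syy / (n - 1)
  log_lik <- function(b, s2) {
    -(n - 1) / 2 * log(2 * pi * s2) - 0.5 * log(n) -
      sum((yc - b * gc)^2) / (2 * s2)
  }
  log_prior_s2 <- function(s2) {
    (cc / 2) * log(Q / 2) - lgamma(cc / 2) - (cc / 2 + 1) * log(s2) -
      Q / (2 * s2)
  }
  s2_grid <- exp(seq(log(s2hat / 8), log(s2hat * 8), length.out = 400))
  ds2 <- diff(c(s2_grid[1] * s2_grid[1] / s2_grid[2], s2_grid))
  b_sd <- sqrt(v_b * s2hat)
  b_grid <- seq(-8 * b_sd, 8 * b_sd, length.out = 401)
  db <- b_grid[2] - b_grid[1]
  # null model: b = 0
  l0 <- log_lik(0, s2_grid) + log_prior_s2(s2_grid) + log(ds2)
  log_m0 <- logsumexp(l0)
  # alternative: grid over (b, sigma2)
  l1 <- matrix(NA_real_, length(b_grid), length(s2_grid))
  for (i in seq_along(s2_grid)) {
    s2 <- s2_grid[i]
    l1[, i] <- vapply(b_grid, function(b) log_lik(b, s2), numeric(1)) +
      dnorm(b_grid, 0, sqrt(v_b * s2), log = TRUE) +
      log_prior_s2(s2) + log(ds2[i])
  }
  log_m1 <- logsumexp(as.vector(l1) + log(db))
  (log_m1 - log_m0) / log(10)
}

# log Bayes factor for one trait in the conditional-factorization model:
# y = X0 gamma + g b + e, flat gamma, Jeffreys sigma2, b ~ N(0, sa^2*sigma2).
# Quadrature over (b, sigma2) after residualizing on X0 (the flat-prior
# marginalization over gamma, done analytically as in standard references).
oracle_bf_uni_quadrature <- function(y, g, X0, sa) {
  qr0 <- qr(X0)
  yt <- qr.resid(qr0, y)
  gt <- qr.resid(qr0, g)
  df <- length(y) - ncol(X0)
  s2hat <- sum(yt^2) / df
  log_lik <- function(b, s2) {
    -df / 2 * log(2 * pi * s2) - sum((yt - b * gt)^2) / (2 * s2)
  }
  s2_grid <- exp(seq(log(s2hat / 10), log(s2hat * 10), length.out = 400))
  ds2 <- diff(c(s2_grid[1]^2 / s2_grid[2], s2_grid))
  b_sd <- sa * sqrt(s2hat)
  b_grid <- seq(-8 * b_sd, 8 * b_sd, length.out = 401)
  db <- b_grid[2] - b_grid[1]
  l0 <- log_lik(0, s2_grid) - log(s2_grid) + log(ds2)
  log_m0 <- logsumexp(l0)
  l1 <- matrix(NA_real_, length(b_grid), length(s2_grid))
  for (i in seq_along(s2_grid)) {
    s2 <- s2_grid[i]
    l1[, i] <- vapply(b_grid, function(b) log_lik(b, s2), numeric(1)) +
      dnorm(b_grid, 0, sa * sqrt(s2), log = TRUE) - log(s2) + log(ds2[i])
  }
  log_m1 <- logsumexp(as.vector(l1) + log(db))
  log_m1 - log_m0
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Binary logistic-regression LRT of genotype presence on all traits.
oracle_logistic_lrt_p <- function(gb, Y) {
  fit <- glm(gb ~ Y, family = binomial())
  null <- glm(gb ~ 1, family = binomial())
  lrt <- null$deviance - fit$deviance
  pchisq(lrt, df = ncol(Y), lower.tail = FALSE)
}

# Analytic two-sided power of the univariate slope t-test at level alpha.
oracle_uv_power <- function(n, h2, alpha) {
  ncp <- sqrt(n * h2 / (1 - h2))
  tc <- qt(1 - alpha / 2, df = n - 2)
  pt(-tc, df = n - 2, ncp = ncp) + pt(tc, df = n - 2, ncp = ncp,
                                      lower.tail = FALSE)
}
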