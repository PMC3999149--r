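#' Canonical correlation association test (MANOVA-type F test)
#'
#' With a single genetic variant, canonical correlation analysis between
#' the genotype and a set of traits reduces to one canonical correlation
#' `r`, where `r^2` equals the R-squared of the OLS regression of genotype
#' on the traits. The p-value comes from the exact F statistic
#' `F = ((n - 1 - k)/k) * r^2 / (1 - r^2)` on `(k, n - 1 - k)` degrees of
#' freedom (Rao's F for Wilks' lambda with one variate).
#'
#' @param genotype Numeric genotype vector.
#' @param traits `n x k` trait matrix (full column rank).
#' @return An [assoc_result()] (`method = "cca"`); detail carries the
#'   canonical correlation, the trait loadings (correlations of each trait
#'   with the canonical variate) and the raw coefficients.
#' @examples
#' d <- simulate_dataset(scenario_spec(seed = 3))
#' cca_test(d$genotype, d$traits)
#' @export
cca_test <- function(genotype, traits) {
  Y <- as_trait_matrix(traits)
  n <- nrow(Y)
  k <- ncol(Y)
  stopifnot(n > k + 1)
  g <- check_genotype(genotype, n)
  gc <- g - mean(g)
  yc <- sweep(Y, 2, colMeans(Y))
  Syy <- crossprod(yc)
  R <- tryCatch(chol(Syy), error = function(e) NULL)
  if (is.null(R) || min(diag(R)) < 1e-7 * max(diag(R))) {
    stop("trait matrix is rank deficient: canonical correlation undefined",
         call. = FALSE)
  }
  b <- backsolve(R, backsolve(R, crossprod(yc, gc), transpose = TRUE))
  r2 <- as.numeric(crossprod(gc, yc %*% b)) / sum(gc^2)
  r2 <- min(max(r2, 0), 1 - 1e-12)
  Fstat <- ((n - 1 - k) / k) * r2 / (1 - r2)
  p <- if (r2 == 0) 1 else
    stats::pf(Fstat, k, n - 1 - k, lower.tail = FALSE)
  variate <- as.numeric(yc %*% b)
  loadings <- if (stats::sd(variate) > 0)
    as.numeric(stats::cor(yc, variate)) else rep(0, k)
  assoc_result("cca", max(p, .Machine$double.xmin), "p_value",
               detail = list(r = sqrt(r2), F = Fstat, df = c(k, n - 1 - k),
                             loadings = loadings, coef = as.numeric(b)))
}

#' Priors for the Bayesian multivariate tests
#'
#' Bundles the prior hyperparameters of [bayes_mv_bf()] (effect prior scale
#' `v_b` and the two scalars of the inverse-Wishart error prior) and of
#' [bimbam_partition_bf()] (the grid of prior effect standard deviations).
#'
#' The inverse-Wishart parameters follow the convention
#' `Sigma ~ IW(scale = iw_scale * I_k, df = iw_df)`; both scalars are
#' exposed explicitly because published front-ends differ in convention.
#' Defaults match the study configuration: `v_b = 0.02`, `iw_scale = 6`,
#' `iw_df = 4`, `sigma_a` grid `(0.1, 0.2)`.
#'
#' @param v_b Prior scale of the per-trait genotype effect: given the error
#'   covariance `Sigma`, the effect row is `N(0, v_b * Sigma)`.
#' @param iw_scale Scalar multiplying the identity scale matrix of the
#'   inverse-Wishart prior on the error covariance.
#' @param iw_df Degrees of freedom of the inverse-Wishart prior (must
#'   exceed `k - 1` for a proper prior).
#' @param sigma_a Grid of prior effect standard deviations for the
#'   partition-averaged Bayes factor (equal-weight averaging).
#' @return A list of class `"bayes_priors"`.
#' @export
bayes_priors <- function(v_b = 0.02, iw_scale = 6, iw_df = 4,
                         sigma_a = c(0.1, 0.2)) {
  stopifnot(v_b >= 0, iw_scale > 0, all(sigma_a > 0))
  structure(list(v_b = v_b, iw_scale = iw_scale, iw_df = iw_df,
                 sigma_a = sigma_a),
            class = "bayes_priors")
}

logdet_chol <- function(A) 2 * sum(log(diag(chol(A))))

#' Conjugate Bayesian multivariate-regression log10 Bayes factor
#'
#' Closed-form Bayes factor for the multivariate linear model
#' `Y = 1 mu' + g beta' + E` against the null `beta = 0`, with rows of `E`
#' iid `N(0, Sigma)`, a matrix-normal prior `beta ~ N(0, v_b * Sigma)` on
#' the effect row, an inverse-Wishart prior `IW(iw_scale * I, iw_df)` on
#' `Sigma`, and a flat prior on the mean (removed by centering, which
#' shifts the posterior degrees of freedom to `iw_df + n - 1`). Both
#' marginal likelihoods are matrix-variate t densities, so the Bayes
#' factor reduces to a ratio of determinant powers; no sampling is
#' involved. `v_b = 0` returns exactly 0 (the models coincide).
#'
#' Genotypes are used as supplied, so expected dosages are accepted; with
#' hard calls they equal the integer genotypes.
#'
#' @param genotype Numeric genotype (or expected dosage) vector.
#' @param traits `n x k` trait matrix.
#' @param priors A [bayes_priors()] object.
#' @return An [assoc_result()] with `measure_kind = "log10_bf"`; detail
#'   carries the posterior mean effect vector.
#' @export
bayes_mv_bf <- function(genotype, traits, priors = bayes_priors()) {
  Y <- as_trait_matrix(traits)
  n <- nrow(Y)
  k <- ncol(Y)
  stopifnot(inherits(priors, "bayes_priors"), n > k + 1)
  if (priors$iw_df <= k - 1) {
    stop("`iw_df` must exceed k - 1 for a proper inverse-Wishart prior",
         call. = FALSE)
  }
  g <- check_genotype(genotype, n)
  if (priors$v_b == 0) {
    return(assoc_result("bayes", 0, "log10_bf",
                        detail = list(beta_post = rep(0, k))))
  }
  gc <- g - mean(g)
  yc <- sweep(Y, 2, colMeans(Y))
  Sgg <- sum(gc^2)
  Syg <- as.numeric(crossprod(yc, gc))
  A <- priors$iw_scale * diag(k) + crossprod(yc)
  lambda <- 1 / priors$v_b
  Sn <- A - tcrossprod(Syg) / (Sgg + lambda)
  nu_n <- priors$iw_df + n - 1
  log_bf <- (k / 2) * (log(lambda) - log(lambda + Sgg)) +
    (nu_n / 2) * (logdet_chol(A) - logdet_chol(Sn))
  assoc_result("bayes", log_bf / log(10), "log10_bf",
               detail = list(beta_post = Syg / (Sgg + lambda)))
}

#' Reverse proportional-odds regression likelihood-ratio test
#'
#' Regresses the ordered genotype category (0 < 1 < 2) on all traits
#' jointly with a proportional-odds (ordinal logistic) model and tests all
#' trait coefficients simultaneously with a likelihood-ratio test against
#' the intercepts-only model, referred to chi-squared with one degree of
#' freedom per (non-degenerate) trait.
#'
#' When the rarest genotype category holds fewer than `collapse_threshold`
#' observations (common at low minor allele frequency, where the original
#' proportional-odds fitters are known to fail), the rare category is
#' merged with its neighbour; with two categories the model is an ordinary
#' binary logistic regression. Constant trait columns are dropped with a
#' warning and the degrees of freedom reduced accordingly.
#'
#' @param genotype Integer genotype vector with values in `{0, 1, 2}`.
#' @param traits `n x k` trait matrix.
#' @param collapse_threshold Minimum count for the rarest genotype
#'   category before collapsing.
#' @param se Also compute per-trait standard errors and marginal p-values
#'   (requires the Hessian; slower).
#' @return An [assoc_result()] (`method = "ordinal"`); detail carries the
#'   per-trait coefficients (and their marginal z-based p-values when
#'   `se = TRUE`), the degrees of freedom used, and whether categories
#'   were collapsed.
#' @export
ordinal_reverse_lrt <- function(genotype, traits, collapse_threshold = 5L,
                                se = FALSE) {
  Y <- as_trait_matrix(traits)
  n <- nrow(Y)
  stopifnot(length(genotype) == n, n > ncol(Y))
  keep <- apply(Y, 2, function(y) stats::sd(y) > 0)
  if (!all(keep)) {
    warning("dropping constant trait column(s): ",
            paste(colnames(Y)[!keep], collapse = ", "))
    Y <- Y[, keep, drop = FALSE]
  }
  k <- ncol(Y)
  if (k == 0L) stop_monomorphic("trait")
  g <- as.integer(round(genotype))
  counts <- table(g)
  if (length(counts) < 2L) stop_monomorphic("genotype")
  collapsed <- FALSE
  while (length(counts) > 2L && min(counts) < collapse_threshold) {
    # merge the rarest category into its ordered neighbour
    rare <- as.integer(names(counts)[which.min(counts)])
    g[g == rare] <- if (rare == max(g)) rare - 1L else rare + 1L
    counts <- table(g)
    collapsed <- TRUE
  }
  if (length(counts) == 2L) {
    gb <- as.integer(g == max(g))
    fit <- stats::glm.fit(cbind(1, Y), gb, family = stats::binomial())
    null_dev <- -2 * sum(stats::dbinom(gb, 1, mean(gb), log = TRUE))
    lrt <- max(null_dev - fit$deviance, 0)
    coefs <- fit$coefficients[-1]
    detail <- list(coef = coefs, df = k, collapsed = TRUE, binary = TRUE)
  } else {
    fit <- polr_fit(Y, g, hessian = se)
    if (!fit$converged) {
      stop_convergence(
        "proportional-odds fit failed to converge",
        diagnostics = list(counts = as.integer(counts),
                           message = fit$message))
    }
    ll1 <- fit$loglik
    nc <- as.numeric(counts)
    ll0 <- sum(nc * log(nc / n))
    lrt <- max(2 * (ll1 - ll0), 0)
    coefs <- fit$beta
    detail <- list(coef = coefs, zeta = fit$zeta, df = k,
                   collapsed = collapsed, binary = FALSE)
    if (se) {
      detail$se <- fit$se
      detail$p_marginal <- 2 * stats::pnorm(-abs(coefs / fit$se))
    }
  }
  p <- max(stats::pchisq(lrt, df = k, lower.tail = FALSE),
           .Machine$double.xmin)
  detail$lrt <- lrt
  assoc_result("ordinal", p, "p_value", detail = detail)
}

# Conjugate univariate regression log Bayes factor: y ~ [X0] + g * b with
# b ~ N(0, sigma_a^2 * sigma^2), flat priors on the X0 coefficients and
# Jeffreys prior on sigma^2; X0 always contains the intercept.
log_bf_uni <- function(y_resid, g_resid, rss0, sigma_a, df) {
  gg <- sum(g_resid^2)
  lambda <- 1 / sigma_a^2
  rss1 <- rss0 - sum(g_resid * y_resid)^2 / (gg + lambda)
  0.5 * (log(lambda) - log(gg + lambda)) +
    (df / 2) * (log(rss0) - log(rss1))
}

log_mean_exp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

#' Partition-averaged multivariate Bayes factor
#'
#' Considers every assignment of the `k` traits to the classes
#' unaffected (U), directly affected (D) and indirectly affected (I) with
#' at least one directly affected trait. Each partition's Bayes factor
#' against the global null (all traits unaffected) follows the conditional
#' factorization: D traits are regressed on genotype with the U traits as
#' covariates under a conjugate normal effect prior (averaged with equal
#' weight over the `sigma_a` grid of prior effect standard deviations); I
#' traits depend on the D traits only and U traits are independent of
#' genotype, so those factors cancel against the null. The overall Bayes
#' factor is the equal-weight average over all partitions, and the detail
#' reports each trait's marginal posterior probability of being U, D or I
#' given association.
#'
#' @param genotype Numeric genotype vector.
#' @param traits `n x k` trait matrix (`k <= 10`).
#' @param priors A [bayes_priors()]; only the `sigma_a` grid is used.
#' @return An [assoc_result()] with `measure_kind = "log10_bf"`; detail
#'   carries the per-partition log10 Bayes factors and the per-trait class
#'   posteriors.
#' @export
bimbam_partition_bf <- function(genotype, traits, priors = bayes_priors()) {
  Y <- as_trait_matrix(traits)
  n <- nrow(Y)
  k <- ncol(Y)
  if (k > 10L) stop("partition enumeration guarded at k <= 10", call. = FALSE)
  g <- check_genotype(genotype, n)
  classes <- c("U", "D", "I")
  part <- as.matrix(expand.grid(rep(list(classes), k),
                                stringsAsFactors = FALSE))
  colnames(part) <- colnames(Y)
  part <- part[rowSums(part == "D") > 0, , drop = FALSE]

  # cache residualizations per distinct U-set
  cache <- new.env(parent = emptyenv())
  get_resid <- function(u_idx) {
    key <- paste0("u", paste(u_idx, collapse = ","))
    if (!is.null(cache[[key]])) return(cache[[key]])
    X0 <- cbind(1, Y[, u_idx, drop = FALSE])
    qr0 <- qr(X0)
    res <- list(
      g = qr.resid(qr0, g),
      Y = qr.resid(qr0, Y),
      df = n - ncol(X0)
    )
    res$rss0 <- colSums(res$Y^2)
    cache[[key]] <- res
    res
  }
  log_bf_part <- vapply(seq_len(nrow(part)), function(i) {
    u_idx <- which(part[i, ] == "U")
    d_idx <- which(part[i, ] == "D")
    r <- get_resid(u_idx)
    sum(vapply(d_idx, function(j) {
      log_mean_exp(vapply(
        priors$sigma_a,
        function(s) log_bf_uni(r$Y[, j], r$g, r$rss0[j], s, r$df),
        numeric(1)))
    }, numeric(1)))
  }, numeric(1))
  log_bf <- log_mean_exp(log_bf_part)
  w <- exp(log_bf_part - max(log_bf_part))
  w <- w / sum(w)
  post <- sapply(classes, function(cl)
    colSums(w * (part == cl)))  # k x 3, P(trait j in class | association)
  assoc_result("bimbam", log_bf / log(10), "log10_bf",
               detail = list(log10_bf_partitions = log_bf_part / log(10),
                             partitions = part,
                             class_posterior = post))
}
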