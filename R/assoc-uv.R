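#' Univariate additive association test (OLS slope t-test)
#'
#' Fits `trait ~ intercept + genotype` by ordinary least squares and returns
#' the two-sided p-value of the slope from the t distribution with `n - 2`
#' degrees of freedom, together with the slope, its standard error and the
#' effect direction.
#'
#' @param genotype Numeric genotype vector (minor-allele dosage).
#' @param trait Numeric trait vector.
#' @return A list with `p`, `direction` (-1/0/+1), `slope`, `se`, `n`.
#' @examples
#' d <- simulate_dataset(scenario_spec(seed = 7))
#' uv_linear_test(d$genotype, d$traits[, 1])$p
#' @export
uv_linear_test <- function(genotype, trait) {
  n <- length(genotype)
  stopifnot(length(trait) == n, n >= 3)
  g <- as.numeric(genotype) - mean(genotype)
  y <- as.numeric(trait) - mean(trait)
  sxx <- sum(g^2)
  if (sxx == 0) stop_monomorphic("genotype")
  syy <- sum(y^2)
  if (syy == 0) stop_monomorphic("trait")
  slope <- sum(g * y) / sxx
  rss <- max(syy - slope^2 * sxx, 0)
  se <- sqrt(rss / ((n - 2) * sxx))
  if (se == 0) {
    p <- if (slope == 0) 1 else .Machine$double.xmin
  } else {
    p <- 2 * stats::pt(-abs(slope / se), df = n - 2)
  }
  list(p = max(p, .Machine$double.xmin), direction = sign(slope),
       slope = slope, se = se, n = n)
}

#' Univariate tests of every trait against the genotype
#'
#' @param genotype Numeric genotype vector.
#' @param traits `n x k` trait matrix.
#' @return A data frame with one row per trait: `trait`, `p`, `direction`,
#'   `slope`, `se`, `n`.
#' @export
uv_linear_tests <- function(genotype, traits) {
  Y <- as_trait_matrix(traits)
  n <- nrow(Y)
  g <- check_genotype(genotype, n)
  gc <- g - mean(g)
  sxx <- sum(gc^2)
  yc <- sweep(Y, 2, colMeans(Y))
  sxy <- as.numeric(crossprod(yc, gc))
  syy <- colSums(yc^2)
  if (any(syy == 0)) stop_monomorphic("trait")
  slope <- sxy / sxx
  rss <- pmax(syy - slope^2 * sxx, 0)
  se <- sqrt(rss / ((n - 2) * sxx))
  tval <- ifelse(se > 0, slope / se, ifelse(slope == 0, 0, Inf))
  p <- pmax(2 * stats::pt(-abs(tval), df = n - 2), .Machine$double.xmin)
  data.frame(trait = colnames(Y), p = p, direction = sign(slope),
             slope = slope, se = se, n = n, row.names = NULL)
}

#' Minimum univariate p-value across traits
#'
#' The statistic used for family-wise calibration of the univariate
#' analysis: the smallest of the per-trait p-values. Its permutation null
#' distribution yields the adjusted per-trait significance threshold that
#' fixes the overall false-positive rate.
#'
#' @param p Numeric vector of per-trait p-values, or a data frame from
#'   [uv_linear_tests()].
#' @return The minimum p-value.
#' @export
uv_min_p <- function(p) {
  if (is.data.frame(p)) p <- p$p
  stopifnot(length(p) >= 1)
  min(p)
}

#' Univariate test of the first principal component of the traits
#'
#' Extracts the first principal component of the trait matrix
#' (covariance-based, which for standardized traits coincides with the
#' correlation-based one) and tests it against the genotype with
#' [uv_linear_test()].
#'
#' @param genotype Numeric genotype vector.
#' @param traits `n x k` trait matrix.
#' @return An [assoc_result()] with `measure_kind = "p_value"`; detail
#'   carries the PC1 loadings and its explained-variance share.
#' @export
uv_pca_test <- function(genotype, traits) {
  Y <- as_trait_matrix(traits)
  g <- check_genotype(genotype, nrow(Y))
  yc <- sweep(Y, 2, colMeans(Y))
  if (ncol(Y) == 1L) {
    r <- uv_linear_test(g, yc[, 1])
    return(assoc_result("uvpca", r$p, "p_value",
                        detail = list(loadings = 1, var_share = 1)))
  }
  S <- stats::cov(yc)
  ee <- eigen(S, symmetric = TRUE)
  v1 <- ee$vectors[, 1]
  pc1 <- as.numeric(yc %*% v1)
  r <- uv_linear_test(g, pc1)
  assoc_result("uvpca", r$p, "p_value",
               detail = list(loadings = v1,
                             var_share = ee$values[1] / sum(ee$values)))
}

clamp_p <- function(p, eps = 1e-300, upper = TRUE) {
  if (any(p < eps) || (upper && any(p >= 1))) {
    warning("extreme p-values clamped to [", eps, ", 1) before ",
            "transformation")
  }
  if (upper) pmin(pmax(p, eps), 1 - 1e-16) else pmax(p, eps)
}

#' Sample-size-weighted meta-analysis of univariate results
#'
#' The "samplesize" combination scheme: each trait's two-sided p-value is
#' converted to a signed Z score using its effect direction,
#' `Z_j = dir_j * qnorm(1 - p_j / 2)`, weighted by the square root of its
#' sample size, and combined as `Z = sum(w_j Z_j) / sqrt(sum(w_j^2))`; the
#' combined two-sided p-value is `2 * pnorm(-|Z|)`. Opposite effect
#' directions cancel, which is why this scheme loses power under negative
#' genetic correlation.
#'
#' @param p Per-trait two-sided p-values (or a data frame from
#'   [uv_linear_tests()], in which case `direction` and `n` are taken from
#'   it).
#' @param direction Per-trait effect directions in `{-1, +1}` (0 allowed,
#'   contributing a zero Z).
#' @param n Per-trait sample sizes (recycled if scalar).
#' @return An [assoc_result()] (`method = "meta"`); detail carries the
#'   combined Z and the per-trait Z scores.
#' @export
meta_samplesize <- function(p, direction = NULL, n = NULL) {
  if (is.data.frame(p)) {
    direction <- p$direction
    n <- p$n
    p <- p$p
  }
  stopifnot(length(direction) == length(p))
  if (is.null(n)) n <- 1
  n <- rep_len(n, length(p))
  z <- direction * stats::qnorm(1 - clamp_p(p) / 2)
  w <- sqrt(n)
  Z <- sum(w * z) / sqrt(sum(w^2))
  assoc_result("meta", max(2 * stats::pnorm(-abs(Z)), .Machine$double.xmin),
               "p_value", detail = list(Z = Z, z_per_trait = z))
}

#' Fisher's method for combining univariate p-values
#'
#' `X = -2 * sum(log p_j)` referred to the upper tail of a chi-squared
#' distribution with `2k` degrees of freedom. Uses p-values only, so it is
#' immune to opposite effect signs (unlike the signed-Z meta-analysis).
#'
#' @param p Per-trait p-values (or a data frame from [uv_linear_tests()]).
#' @return An [assoc_result()] (`method = "fisher"`); detail carries the
#'   statistic `X`.
#' @export
fisher_combine <- function(p) {
  if (is.data.frame(p)) p <- p$p
  p <- clamp_p(p, upper = FALSE)  # p = 1 is a valid input (log 1 = 0)
  X <- -2 * sum(log(p))
  assoc_result("fisher",
               max(stats::pchisq(X, df = 2 * length(p), lower.tail = FALSE),
                   .Machine$double.xmin),
               "p_value", detail = list(X = X))
}
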