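#' Scenario specification for a single-QTL multi-trait simulation
#'
#' A scenario fixes everything needed to reproduce one simulation condition:
#' sample size, minor allele frequency of the QTL, per-trait QTL
#' heritabilities, the sign of each per-trait allelic effect (which sets the
#' sign of the QTL-induced genetic correlation), the pairwise residual
#' correlation between traits, replicate counts and the random seed.
#'
#' @param n_individuals Number of individuals per replicate.
#' @param maf Minor allele frequency of the QTL, in `(0, 0.5]` (0 allowed
#'   for degenerate monomorphic scenarios).
#' @param h2 Numeric vector of per-trait QTL heritabilities in `[0, 1)`;
#'   its length sets the number of traits.
#' @param effect_sign Integer vector in `{-1, 0, 1}`, one per trait; must be
#'   0 exactly where `h2` is 0. Defaults to `+1` for every associated trait.
#' @param residual_corr Common pairwise residual correlation between traits
#'   (after removing the QTL effect), in `(-1, 1)` and above
#'   `-1/(k - 1)` so the residual covariance is positive definite.
#' @param n_replicates Number of simulated datasets for the scenario.
#' @param n_permutations Number of trait-permuted copies per dataset used to
#'   build the null distribution.
#' @param seed Integer master seed; every replicate derives its own child
#'   seed from it, so a spec reproduces bit-identical data.
#' @param id Optional scenario label.
#'
#' @return An object of class `"scenario_spec"`.
#' @examples
#' sp <- scenario_spec(maf = 0.4, h2 = c(0.001, 0, 0), residual_corr = 0.7)
#' d <- simulate_dataset(sp, replicate = 1)
#' colMeans(d$traits)
#' @export
scenario_spec <- function(n_individuals = 1000L,
                          maf = 0.4,
                          h2 = c(0.001, 0, 0),
                          effect_sign = NULL,
                          residual_corr = 0,
                          n_replicates = 1000L,
                          n_permutations = 10L,
                          seed = 1L,
                          id = NULL) {
  n_individuals <- as.integer(n_individuals)
  stopifnot(n_individuals >= 1L, is.numeric(maf), length(maf) == 1L)
  if (maf < 0 || maf > 0.5) {
    stop("`maf` must lie in [0, 0.5]: it is the minor allele frequency.",
         call. = FALSE)
  }
  if (any(h2 < 0) || any(h2 >= 1)) {
    stop("per-trait heritabilities must lie in [0, 1)", call. = FALSE)
  }
  k <- length(h2)
  if (is.null(effect_sign)) effect_sign <- ifelse(h2 > 0, 1L, 0L)
  effect_sign <- as.integer(effect_sign)
  if (length(effect_sign) != k) {
    stop("`h2` and `effect_sign` must have one entry per trait", call. = FALSE)
  }
  if (!all(effect_sign %in% c(-1L, 0L, 1L))) {
    stop("`effect_sign` entries must be -1, 0 or +1", call. = FALSE)
  }
  if (any((h2 == 0) != (effect_sign == 0L))) {
    stop("a trait has zero heritability if and only if its effect sign is 0",
         call. = FALSE)
  }
  if (any(h2 > 0) && maf == 0) {
    stop("a QTL effect is undefined for a monomorphic locus (maf = 0)",
         call. = FALSE)
  }
  if (abs(residual_corr) >= 1 ||
      (k > 1 && residual_corr <= -1 / (k - 1))) {
    stop("`residual_corr` does not define a positive-definite ",
         "equicorrelation matrix for ", k, " traits", call. = FALSE)
  }
  # explicit PD check on the implied residual covariance
  Sigma <- residual_covariance(h2, residual_corr)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("implied residual covariance matrix is not positive definite",
         call. = FALSE)
  }
  spec <- list(
    n_individuals = n_individuals,
    maf = maf,
    h2 = as.numeric(h2),
    effect_sign = effect_sign,
    residual_corr = residual_corr,
    n_traits = k,
    n_replicates = as.integer(n_replicates),
    n_permutations = as.integer(n_permutations),
    seed = as.integer(seed),
    id = if (is.null(id)) default_scenario_id(effect_sign, residual_corr, maf) else id
  )
  class(spec) <- "scenario_spec"
  spec
}

default_scenario_id <- function(effect_sign, residual_corr, maf) {
  n_assoc <- sum(effect_sign != 0L)
  rg <- if (n_assoc < 2) "0" else if (prod(range(sign(effect_sign[effect_sign != 0]))) < 0) "-" else "+"
  sprintf("a%d_rG%s_rE%.1f_q%.2f", n_assoc, rg, residual_corr, maf)
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("Scenario", x$id, "\n")
  cat(sprintf("  N = %d individuals, %d traits, MAF q = %g\n",
              x$n_individuals, x$n_traits, x$maf))
  cat(sprintf("  h2 = (%s), effect signs = (%s), residual corr = %g\n",
              paste(signif(x$h2, 3), collapse = ", "),
              paste(x$effect_sign, collapse = ", "), x$residual_corr))
  cat(sprintf("  %d replicates x %d permutations, seed %d\n",
              x$n_replicates, x$n_permutations, x$seed))
  invisible(x)
}

#' The default 30-scenario grid
#'
#' Enumerates the study's main simulation grid: one, two or all three of
#' three traits associated with the QTL (each associated trait explaining
#' `h2_assoc` of its variance), with positive- and negative-sign variants of
#' the QTL-induced genetic correlation when two or more traits are
#' associated, crossed with residual correlations `rE` and minor allele
#' frequencies `maf`. With the defaults this yields
#' (1 + 2 + 2) sign patterns x 3 rE x 2 MAF = 30 scenarios.
#'
#' Supplementary grids are exposed through the arguments: intermediate
#' allele frequencies via `maf = c(0.05, 0.10, 0.25)` and the
#' unequal-heritability variant via [scenario_grid_unequal_h2()].
#'
#' @param maf Minor allele frequencies to cross.
#' @param rE Residual correlations to cross.
#' @param h2_assoc QTL heritability of each associated trait.
#' @param n_traits Number of traits (sign patterns are defined for 3).
#' @param n_individuals,n_replicates,n_permutations,seed Passed to
#'   [scenario_spec()]; each scenario receives a distinct child seed derived
#'   from `seed`.
#' @return A list of `scenario_spec` objects.
#' @examples
#' length(scenario_grid())  # 30
#' @export
scenario_grid <- function(maf = c(0.01, 0.4),
                          rE = c(0, 0.3, 0.7),
                          h2_assoc = 0.001,
                          n_traits = 3L,
                          n_individuals = 1000L,
                          n_replicates = 1000L,
                          n_permutations = 10L,
                          seed = 1L) {
  stopifnot(n_traits == 3L)
  sign_patterns <- list(
    c(1L, 0L, 0L),            # one associated trait (rG undefined/0)
    c(1L, 1L, 0L),            # two associated, positive rG
    c(-1L, 1L, 0L),           # two associated, negative rG
    c(1L, 1L, 1L),            # three associated, positive rG
    c(-1L, 1L, 1L)            # three associated, negative rG
  )
  grid <- list()
  i <- 0L
  for (sgn in sign_patterns) {
    for (r in rE) {
      for (q in maf) {
        i <- i + 1L
        grid[[i]] <- scenario_spec(
          n_individuals = n_individuals,
          maf = q,
          h2 = h2_assoc * as.numeric(sgn != 0L),
          effect_sign = sgn,
          residual_corr = r,
          n_replicates = n_replicates,
          n_permutations = n_permutations,
          seed = child_seed(seed, i)
        )
      }
    }
  }
  names(grid) <- vapply(grid, `[[`, "", "id")
  grid
}

#' Unequal-heritability scenario grid
#'
#' The supplementary variant in which all three traits are associated with
#' the QTL but with different explained variances (0.1%, 0.2% and 0.05% by
#' default), again with both signs of the genetic correlation.
#'
#' @inheritParams scenario_grid
#' @param h2 Per-trait heritabilities of the three associated traits.
#' @return A list of `scenario_spec` objects (12 with the defaults).
#' @export
scenario_grid_unequal_h2 <- function(h2 = c(0.001, 0.002, 0.0005),
                                     maf = c(0.01, 0.4),
                                     rE = c(0, 0.3, 0.7),
                                     n_individuals = 1000L,
                                     n_replicates = 1000L,
                                     n_permutations = 10L,
                                     seed = 1L) {
  stopifnot(length(h2) == 3L, all(h2 > 0))
  sign_patterns <- list(c(1L, 1L, 1L), c(-1L, 1L, 1L))
  grid <- list()
  i <- 0L
  for (sgn in sign_patterns) {
    for (r in rE) {
      for (q in maf) {
        i <- i + 1L
        grid[[i]] <- scenario_spec(
          n_individuals = n_individuals, maf = q, h2 = h2,
          effect_sign = sgn, residual_corr = r,
          n_replicates = n_replicates, n_permutations = n_permutations,
          seed = child_seed(seed, 1000L + i)
        )
      }
    }
  }
  names(grid) <- paste0("uneq_", vapply(grid, `[[`, "", "id"))
  grid
}
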