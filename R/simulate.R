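#' Deterministic child seeds
#'
#' Derives a stream of reproducible child seeds from a master seed so that
#' replicates (and their permutation streams) are independently seeded and
#' safe to regenerate in any order. Kept strictly below 2^31.
#'
#' @param master Integer master seed.
#' @param index Replicate index (1-based) or any non-negative offset.
#' @param stream Sub-stream selector (0 = data, 1 = permutations, ...).
#' @return An integer seed in `[1, 2147483562]`.
#' @export
child_seed <- function(master, index, stream = 0L) {
  m <- 2147483563
  x <- (as.double(master) %% m) * 48271 +
    as.double(index) * 69621 +
    as.double(stream) * 1013904 + 12345
  as.integer(x %% (m - 1)) + 1L
}

#' Simulate genotypes for one bi-allelic locus under Hardy-Weinberg
#'
#' Each genotype is the sum of two independently sampled alleles, each a
#' Bernoulli draw with success probability `q` (the minor allele
#' frequency), so genotype frequencies follow the Hardy-Weinberg
#' proportions (p^2, 2pq, q^2) with p = 1 - q. Genotypes count copies of
#' the minor allele, which is the effect allele throughout the package.
#'
#' @param n Number of individuals.
#' @param q Minor allele frequency in `[0, 0.5]`.
#' @return Integer vector of length `n` with values in `{0, 1, 2}`.
#' @examples
#' set.seed(1)
#' table(simulate_genotypes(1000, 0.4))
#' @export
simulate_genotypes <- function(n, q) {
  stopifnot(n >= 1)
  if (!is.numeric(q) || length(q) != 1L || q < 0 || q > 0.5) {
    stop("`q` must be a single minor allele frequency in [0, 0.5]",
         call. = FALSE)
  }
  stats::rbinom(n, size = 2L, prob = q)
}

#' Per-allele QTL effect size from heritability and allele frequency
#'
#' For a standardized trait with residual variance `1 - h2`, the additive
#' allelic effect that makes the QTL explain exactly the fraction `h2` of
#' the trait variance under Hardy-Weinberg is
#' `a = sqrt(h2 / (2 p q))` with `p = 1 - q`: the genotype then contributes
#' variance `a^2 * 2pq = h2`. Effects are therefore larger for rarer
#' alleles at fixed heritability.
#'
#' @param h2 QTL heritability of the trait, in `[0, 1)`.
#' @param q Minor allele frequency (must be positive when `h2 > 0`).
#' @return The per-allele effect (non-negative; apply a sign separately).
#' @export
qtl_effect_size <- function(h2, q) {
  stopifnot(all(h2 >= 0), all(h2 < 1))
  if (any(h2 > 0 & q <= 0)) {
    stop("QTL effect undefined for a monomorphic locus (q = 0 with h2 > 0)",
         call. = FALSE)
  }
  ifelse(h2 == 0, 0, sqrt(h2 / (2 * (1 - q) * q)))
}

#' Residual covariance matrix implied by heritabilities and rE
#'
#' Trait `j` has residual variance `1 - h2[j]`; off-diagonals are
#' `rE * sqrt((1 - h2[j]) (1 - h2[l]))`, i.e. `rE` is the residual
#' *correlation* and is invariant to the heritabilities.
#'
#' @param h2 Per-trait heritability vector.
#' @param rE Common pairwise residual correlation.
#' @return A `k x k` covariance matrix.
#' @export
residual_covariance <- function(h2, rE) {
  sd_e <- sqrt(1 - h2)
  Sigma <- rE * tcrossprod(sd_e)
  diag(Sigma) <- sd_e^2
  Sigma
}

#' Simulate correlated multivariate-normal residuals
#'
#' Draws the non-genetic component of the traits from a multivariate normal
#' with mean zero and covariance [residual_covariance()].
#'
#' @param n Number of individuals.
#' @param h2 Per-trait heritability vector (length k).
#' @param rE Common pairwise residual correlation.
#' @return An `n x k` matrix of residuals.
#' @export
simulate_residuals <- function(n, h2, rE) {
  k <- length(h2)
  if (k > 1 && rE <= -1 / (k - 1)) {
    stop("`rE` below -1/(k-1): residual covariance not positive definite",
         call. = FALSE)
  }
  Sigma <- residual_covariance(h2, rE)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("residual covariance matrix is not positive definite", call. = FALSE)
  }
  MASS::mvrnorm(n, mu = rep(0, k), Sigma = Sigma)
}

#' Assemble standardized traits from genotype, effects and residuals
#'
#' Each trait is the additive QTL contribution plus its residual,
#' `Y_j = a_j * G + e_j`, after which every column is centered and scaled
#' to sample mean 0 and sample variance 1. Before scaling, the QTL induces
#' a cross-trait covariance `a_j * a_l * 2pq`, whose sign
#' `sign(a_j) * sign(a_l)` realises the sign of the genetic correlation.
#'
#' @param genotype Integer genotype vector (minor-allele counts).
#' @param a Signed per-trait allelic effects.
#' @param residuals `n x k` residual matrix.
#' @return An `n x k` matrix of standardized traits.
#' @export
assemble_traits <- function(genotype, a, residuals) {
  n <- length(genotype)
  stopifnot(nrow(residuals) == n, ncol(residuals) == length(a))
  Y <- residuals + tcrossprod(genotype, a)
  Y <- scale(Y)  # sample mean 0, sample (n-1) variance 1 per column
  attr(Y, "scaled:center") <- NULL
  attr(Y, "scaled:scale") <- NULL
  Y
}

#' Simulate one replicate dataset for a scenario
#'
#' Seeds the RNG with the replicate's child seed (derived from the
#' scenario's master seed), draws genotypes and residuals, assembles and
#' standardizes the traits. Identical spec + replicate always reproduces a
#' bit-identical dataset.
#'
#' @param spec A [scenario_spec()].
#' @param replicate Replicate index (1-based).
#' @return A list of class `"sim_dataset"` with elements `genotype`
#'   (integer vector), `traits` (`n x k` standardized matrix), and `truth`
#'   (the generating `scenario_spec`, the realized signed effects `a`, and
#'   the replicate seed).
#' @export
simulate_dataset <- function(spec, replicate = 1L) {
  stopifnot(inherits(spec, "scenario_spec"))
  seed <- child_seed(spec$seed, replicate, stream = 0L)
  set.seed(seed)
  g <- simulate_genotypes(spec$n_individuals, spec$maf)
  a <- spec$effect_sign * qtl_effect_size(spec$h2, spec$maf)
  e <- simulate_residuals(spec$n_individuals, spec$h2, spec$residual_corr)
  Y <- assemble_traits(g, a, e)
  colnames(Y) <- paste0("Y", seq_len(spec$n_traits))
  structure(
    list(genotype = g, traits = Y,
         truth = list(spec = spec, a = a, replicate = as.integer(replicate),
                      seed = seed)),
    class = "sim_dataset"
  )
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("sim_dataset: %d individuals x %d traits (scenario %s, replicate %d)\n",
              length(x$genotype), ncol(x$traits), x$truth$spec$id,
              x$truth$replicate))
  cat("genotype counts:", paste(tabulate(x$genotype + 1L, 3L), collapse = "/"),
      "\n")
  invisible(x)
}
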