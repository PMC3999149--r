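#' Permute the trait rows of a dataset
#'
#' The trait matrix rows are permuted as a block against the fixed
#' genotype vector, which preserves the trait-trait correlation structure
#' exactly while destroying genotype-trait association in expectation.
#' This is the null-generating operation behind all empirical thresholds.
#'
#' @param dataset A `sim_dataset` (or any list with `genotype` and
#'   `traits`).
#' @param perm Optional explicit permutation of `1:n`; drawn from the
#'   current RNG stream when `NULL`.
#' @return The dataset with permuted trait rows.
#' @export
permute_dataset <- function(dataset, perm = NULL) {
  n <- nrow(dataset$traits)
  if (is.null(perm)) perm <- sample.int(n)
  stopifnot(length(perm) == n)
  dataset$traits <- dataset$traits[perm, , drop = FALSE]
  dataset
}

#' Empirical significance threshold from a null distribution
#'
#' Sorts `M` null association measures in the significance direction
#' (ascending for p-values, descending for log10 Bayes factors) and
#' returns the mean of the `floor(alpha * M)`-th and next order
#' statistics, so that exactly `alpha * M` of the measures fall on the
#' significant side when no ties straddle the cut (a warning reports the
#' achieved rate otherwise). With the study sizes (`M = 10000`,
#' `alpha = 0.05`) this is the mean of the 500th and 501st order
#' statistics.
#'
#' @param measures Numeric vector of null association measures.
#' @param alpha Target false-positive rate.
#' @param measure_kind `"p_value"` or `"log10_bf"`.
#' @return The threshold (scalar), with attribute `achieved_rate`.
#' @examples
#' empirical_threshold((1:10000) / 10000, 0.05, "p_value")  # 0.05005
#' @export
empirical_threshold <- function(measures, alpha = 0.05,
                                measure_kind = c("p_value", "log10_bf")) {
  measure_kind <- match.arg(measure_kind)
  measures <- measures[!is.na(measures)]
  M <- length(measures)
  stopifnot(alpha > 0, alpha < 1)
  i <- floor(alpha * M)
  if (i < 1 || i >= M) {
    stop("too few null measures (M = ", M, ") for alpha = ", alpha,
         call. = FALSE)
  }
  s <- sort(measures, decreasing = (measure_kind == "log10_bf"))
  thr <- mean(s[c(i, i + 1L)])
  achieved <- if (measure_kind == "p_value") mean(measures < thr)
              else mean(measures > thr)
  if (abs(achieved - i / M) > 0.5 / M) {
    warning(sprintf(
      "ties at the cut: achieved rate %.4f differs from target %.4f",
      achieved, i / M))
  }
  structure(thr, achieved_rate = achieved)
}

#' Family-wise adjusted threshold for the univariate analysis
#'
#' Applies [uv_min_p()] per permuted replicate and derives the empirical
#' threshold of the minimum p-value, fixing the false-positive rate at
#' `alpha` for all traits combined. For independent traits this
#' approaches the closed form `1 - (1 - alpha)^(1/k)` (about 1.7% for
#' three traits at 5%) and relaxes towards `alpha` as the traits become
#' correlated.
#'
#' @param min_p_null Vector of per-replicate minimum p-values under the
#'   null (one entry per permuted replicate).
#' @param alpha Target family-wise false-positive rate.
#' @return The threshold on the minimum p-value.
#' @export
uv_adjusted_threshold <- function(min_p_null, alpha = 0.05) {
  empirical_threshold(min_p_null, alpha, "p_value")
}

wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  phat <- x / n
  den <- 1 + z^2 / n
  ctr <- (phat + z^2 / (2 * n)) / den
  hw <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / den
  c(lower = max(ctr - hw, 0), upper = min(ctr + hw, 1))
}

#' Power against an empirical threshold
#'
#' Power is the percentage of replicates whose association measure passes
#' the empirical threshold: strictly smaller for p-values, strictly larger
#' for log10 Bayes factors. A Wilson 95% binomial confidence interval is
#' attached.
#'
#' @param measures Per-replicate association measures under the
#'   alternative.
#' @param threshold Empirical threshold from the matching null.
#' @param measure_kind `"p_value"` or `"log10_bf"`.
#' @return A list: `power` (percent), `ci` (percent, Wilson 95%),
#'   `n_replicates`, `n_significant`.
#' @export
compute_power <- function(measures, threshold,
                          measure_kind = c("p_value", "log10_bf")) {
  measure_kind <- match.arg(measure_kind)
  measures <- measures[!is.na(measures)]
  n <- length(measures)
  stopifnot(n >= 1)
  sig <- if (measure_kind == "p_value") sum(measures < threshold)
         else sum(measures > threshold)
  ci <- wilson_ci(sig, n)
  list(power = 100 * sig / n, ci = 100 * ci,
       n_replicates = n, n_significant = sig)
}

#' Available association methods
#'
#' @return Character vector of method identifiers understood by
#'   [run_study()] and [assoc_measure()].
#' @export
mv_methods <- function() {
  c("uv", "uvpca", "meta", "fisher", "tates",
    "cca", "bayes", "ordinal", "bimbam", "pch")
}

#' Apply one association method to a dataset
#'
#' Uniform dispatcher used by the evaluation engine: runs the named method
#' on a genotype vector and trait matrix and returns its [assoc_result()].
#' `"uv"` denotes the minimum univariate p-value (the statistic whose null
#' distribution sets the family-wise univariate threshold).
#'
#' @param method One of [mv_methods()].
#' @param genotype Numeric genotype vector.
#' @param traits `n x k` trait matrix.
#' @param priors [bayes_priors()] for the Bayesian methods.
#' @param pch [pch_settings()] for the heritability-component test.
#' @return An [assoc_result()].
#' @export
assoc_measure <- function(method, genotype, traits,
                          priors = bayes_priors(),
                          pch = pch_settings()) {
  switch(
    method,
    uv = {
      res <- uv_linear_tests(genotype, traits)
      assoc_result("uv", uv_min_p(res), "p_value",
                   detail = list(per_trait = res))
    },
    uvpca = uv_pca_test(genotype, traits),
    meta = meta_samplesize(uv_linear_tests(genotype, traits)),
    fisher = fisher_combine(uv_linear_tests(genotype, traits)),
    tates = tates(uv_linear_tests(genotype, traits),
                  stats::cor(as_trait_matrix(traits))),
    cca = cca_test(genotype, traits),
    bayes = bayes_mv_bf(genotype, traits, priors),
    ordinal = ordinal_reverse_lrt(genotype, traits),
    bimbam = bimbam_partition_bf(genotype, traits, priors),
    pch = pch_test(genotype, traits, pch),
    stop("unknown method id: ", method, call. = FALSE)
  )
}

measure_kind_of <- function(method) {
  if (method %in% c("bayes", "bimbam")) "log10_bf" else "p_value"
}

#' Run the full threshold + power study over a scenario grid
#'
#' For every scenario and method: simulates `n_replicates` datasets and
#' `n_permutations` trait-permuted copies of each, derives the empirical
#' significance threshold from the permuted replicates, and computes the
#' power of each method at its own threshold over the simulated
#' replicates. Per-replicate method errors (monomorphic inputs,
#' non-convergence) are caught and counted; a scenario-method cell is
#' aborted only if its error rate exceeds `error_cap`. All randomness
#' derives from each scenario's seed, so two runs of the same grid produce
#' identical tables.
#'
#' @param scenarios A list of [scenario_spec()]s (e.g. [scenario_grid()]),
#'   or a single spec.
#' @param methods Character vector of method ids from [mv_methods()].
#' @param alpha Target false-positive rate for the thresholds.
#' @param n_replicates,n_permutations Optional overrides of the per-spec
#'   counts (useful for reduced runs).
#' @param priors,pch Method settings passed to [assoc_measure()].
#' @param error_cap Maximum tolerated per-cell error rate.
#' @param return_nulls Also return the raw null measures (memory-heavy).
#' @param verbose Print per-scenario progress.
#' @return A list of class `"mv_study"` with data frames `thresholds`
#'   (scenario, method, measure_kind, threshold, achieved rate, error
#'   counts) and `power` (scenario, method, power %, Wilson 95% CI,
#'   replicate counts), plus `nulls` when requested.
#' @export
run_study <- function(scenarios, methods = c("uv", "cca", "bayes"),
                      alpha = 0.05,
                      n_replicates = NULL, n_permutations = NULL,
                      priors = bayes_priors(), pch = pch_settings(),
                      error_cap = 0.1, return_nulls = FALSE,
                      verbose = interactive()) {
  if (inherits(scenarios, "scenario_spec")) scenarios <- list(scenarios)
  stopifnot(all(methods %in% mv_methods()))
  thr_rows <- list()
  pow_rows <- list()
  nulls <- list()
  for (spec in scenarios) {
    R <- if (is.null(n_replicates)) spec$n_replicates else as.integer(n_replicates)
    P <- if (is.null(n_permutations)) spec$n_permutations else as.integer(n_permutations)
    alt <- matrix(NA_real_, R, length(methods),
                  dimnames = list(NULL, methods))
    nul <- matrix(NA_real_, R * P, length(methods),
                  dimnames = list(NULL, methods))
    for (r in seq_len(R)) {
      d <- simulate_dataset(spec, r)
      for (m in methods) {
        alt[r, m] <- tryCatch(
          assoc_measure(m, d$genotype, d$traits, priors, pch)$measure,
          error = function(e) NA_real_)
      }
      set.seed(child_seed(spec$seed, r, stream = 1L))
      for (p in seq_len(P)) {
        dp <- permute_dataset(d)
        for (m in methods) {
          nul[(r - 1L) * P + p, m] <- tryCatch(
            assoc_measure(m, dp$genotype, dp$traits, priors, pch)$measure,
            error = function(e) NA_real_)
        }
      }
    }
    for (m in methods) {
      kind <- measure_kind_of(m)
      err_null <- sum(is.na(nul[, m]))
      err_alt <- sum(is.na(alt[, m]))
      if (err_null / (R * P) > error_cap || err_alt / R > error_cap) {
        stop(sprintf(
          "scenario %s, method %s: error rate above cap (%d null, %d alt)",
          spec$id, m, err_null, err_alt), call. = FALSE)
      }
      thr <- suppressWarnings(empirical_threshold(nul[, m], alpha, kind))
      pw <- compute_power(alt[, m], thr, kind)
      thr_rows[[length(thr_rows) + 1L]] <- data.frame(
        scenario = spec$id, method = m, measure_kind = kind,
        threshold = as.numeric(thr),
        achieved_rate = attr(thr, "achieved_rate"),
        n_null = sum(!is.na(nul[, m])), n_errors_null = err_null)
      pow_rows[[length(pow_rows) + 1L]] <- data.frame(
        scenario = spec$id, method = m, power = pw$power,
        ci_lower = pw$ci[["lower"]], ci_upper = pw$ci[["upper"]],
        n_replicates = pw$n_replicates, threshold = as.numeric(thr),
        n_errors = err_alt)
    }
    if (return_nulls) nulls[[spec$id]] <- nul
    if (verbose) {
      message(sprintf("scenario %s done (%d replicates x %d permutations)",
                      spec$id, R, P))
    }
  }
  out <- list(thresholds = do.call(rbind, thr_rows),
              power = do.call(rbind, pow_rows),
              alpha = alpha)
  if (return_nulls) out$nulls <- nulls
  class(out) <- "mv_study"
  out
}

#' @export
print.mv_study <- function(x, ...) {
  cat(sprintf("mv_study: %d scenario x method cells at alpha = %g\n",
              nrow(x$power), x$alpha))
  print(utils::head(x$power, 12))
  if (nrow(x$power) > 12) cat("...\n")
  invisible(x)
}
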