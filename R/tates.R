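.tates_env <- new.env(parent = emptyenv())

#' Trait-correlation to p-value-correlation mapping (empirical)
#'
#' Under the null, per-trait test statistics are approximately jointly
#' normal with the trait correlation matrix, and two-sided p-values are
#' `2 * pnorm(-|z|)`. The correlation between two such p-values is a smooth
#' even function of the underlying z correlation; this function estimates
#' it once by Monte Carlo on a grid of correlations (fixed internal random
#' stream, so the mapping is deterministic) and memoises the lookup table
#' for interpolation.
#'
#' @param n_sim Monte-Carlo sample size used to build the table.
#' @return A list with grid `r` and estimated p-value correlations `pc`.
#' @keywords internal
tates_pcor_table <- function(n_sim = 50000L) {
  if (!is.null(.tates_env$table)) return(.tates_env$table)
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(285713L)
  z1 <- stats::rnorm(n_sim)
  z0 <- stats::rnorm(n_sim)
  p1 <- 2 * stats::pnorm(-abs(z1))
  r_grid <- seq(0, 1, by = 0.01)
  pc <- vapply(r_grid, function(r) {
    z2 <- r * z1 + sqrt(max(1 - r^2, 0)) * z0
    stats::cor(p1, 2 * stats::pnorm(-abs(z2)))
  }, numeric(1))
  pc[1] <- 0      # independent z => independent p
  pc[length(pc)] <- 1
  pc <- pmin(pmax(pc, 0), 1)
  .tates_env$table <- list(r = r_grid, pc = pc)
  .tates_env$table
}

map_pvalue_correlation <- function(R, mode, poly_coef = NULL) {
  k <- ncol(R)
  if (mode == "empirical") {
    tab <- tates_pcor_table()
    Rp <- matrix(stats::approx(tab$r, tab$pc, xout = abs(R), rule = 2)$y, k, k)
  } else {
    stopifnot(!is.null(poly_coef))
    Rp <- matrix(0, k, k)
    for (i in seq_along(poly_coef)) Rp <- Rp + poly_coef[i] * R^i
  }
  diag(Rp) <- 1
  Rp
}

li_ji_eff <- function(ev) {
  ev <- pmax(ev, 0)
  # snap floating-point near-integers before floor(): the rule is
  # discontinuous at integers and eigen() returns e.g. 2.9999999999999996
  # for exactly collinear inputs
  near <- abs(ev - round(ev)) < 1e-8
  ev[near] <- round(ev[near])
  sum((ev >= 1) + (ev - floor(ev)))
}

#' Extended-Simes (TATES) trait-based combination of univariate p-values
#'
#' Combines sorted per-trait p-values into a single trait-based p-value
#' while accounting for the correlation between the traits. The trait
#' correlation matrix is mapped to the correlation matrix of the p-values;
#' for each `j` the effective number of tests `m_e(j)` among the `j` most
#' significant traits is computed with the Li-Ji eigenvalue rule
#' `sum(I(lambda >= 1) + (lambda - floor(lambda)))`, and the combined
#' p-value is `min_j m_e * p_(j) / m_e(j)` (capped at 1) with
#' `m_e = m_e(k)`. Depends on p-values only, never on effect direction.
#'
#' @param p Per-trait two-sided p-values (or a data frame from
#'   [uv_linear_tests()]).
#' @param trait_corr `k x k` trait correlation matrix, normally the sample
#'   correlation matrix of the analyzed trait matrix.
#' @param mode `"empirical"` maps trait to p-value correlations with the
#'   memoised Monte-Carlo table ([tates_pcor_table()]); `"polynomial"`
#'   applies user-supplied coefficients `poly_coef` as
#'   `sum_i coef[i] * r^i`.
#' @param poly_coef Coefficients for `mode = "polynomial"`.
#' @param use_abs Use the absolute p-value correlation matrix in the
#'   eigen-decompositions (default; switchable for sensitivity checks).
#' @return An [assoc_result()] (`method = "tates"`); detail carries the
#'   sorted p-values and the `m_e(j)` sequence.
#' @examples
#' tates(c(0.01, 0.5, 0.9), diag(3))$measure  # Simes: 0.03
#' @export
tates <- function(p, trait_corr, mode = c("empirical", "polynomial"),
                  poly_coef = NULL, use_abs = TRUE) {
  mode <- match.arg(mode)
  if (is.data.frame(p)) p <- p$p
  k <- length(p)
  if (k == 1L) {
    return(assoc_result("tates", p, "p_value",
                        detail = list(p_sorted = p, m_eff = 1)))
  }
  trait_corr <- as.matrix(trait_corr)
  stopifnot(nrow(trait_corr) == k, ncol(trait_corr) == k)
  if (max(abs(trait_corr - t(trait_corr))) > 1e-8 ||
      max(abs(diag(trait_corr) - 1)) > 1e-8) {
    stop("`trait_corr` must be symmetric with unit diagonal", call. = FALSE)
  }
  ev_full <- eigen(trait_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev_full) < -1e-8) {
    stop("`trait_corr` must be positive semidefinite", call. = FALSE)
  }
  ord <- order(p)
  ps <- p[ord]
  Rp <- map_pvalue_correlation(trait_corr[ord, ord, drop = FALSE],
                               mode, poly_coef)
  if (use_abs) Rp <- abs(Rp)
  me_j <- vapply(seq_len(k), function(j) {
    if (j == 1L) return(1)
    li_ji_eff(eigen(Rp[1:j, 1:j], symmetric = TRUE, only.values = TRUE)$values)
  }, numeric(1))
  me <- me_j[k]
  T_stat <- min(pmin(me * ps / me_j, 1))
  assoc_result("tates", T_stat, "p_value",
               detail = list(p_sorted = ps, m_eff = me_j, order = ord))
}
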