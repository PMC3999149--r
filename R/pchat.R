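#' Settings for the principal-component-of-heritability test
#'
#' Controls the split/bagging/permutation sizes of [pch_test()]. The
#' defaults are the study configuration: 200 training/test splits for the
#' observed statistic, 50 splits for each permutation replicate, 50
#' bootstrap bags per split, training subsets of 150 individuals, and
#' 1,000 permutations for the internal null distribution. Tests and small
#' examples should scale these down; the procedure is by far the most
#' expensive method in the package.
#'
#' @param n_splits Training/test splits for the observed statistic.
#' @param n_splits_null Splits per permutation replicate.
#' @param n_bags Bootstrap bags per split.
#' @param train_size Individuals per training subset (drawn without
#'   replacement).
#' @param n_null Permutation replicates for the internal null.
#' @param aggregate How per-split statistics are pooled (`"mean"`).
#' @return A list of class `"pch_settings"`.
#' @export
pch_settings <- function(n_splits = 200L, n_splits_null = 50L,
                         n_bags = 50L, train_size = 150L,
                         n_null = 1000L, aggregate = "mean") {
  stopifnot(aggregate == "mean", n_splits >= 1, n_bags >= 1,
            train_size >= 10, n_null >= 20)
  structure(list(n_splits = as.integer(n_splits),
                 n_splits_null = as.integer(n_splits_null),
                 n_bags = as.integer(n_bags),
                 train_size = as.integer(train_size),
                 n_null = as.integer(n_null),
                 aggregate = aggregate),
            class = "pch_settings")
}

# One pass of the split/bag procedure: returns the pooled t-like statistic,
# the bag-averaged weights, and the number of skipped splits.
pch_pass <- function(g, Y, n_splits, n_bags, train_size) {
  n <- length(g)
  k <- ncol(Y)
  stats_s <- numeric(n_splits)
  used <- logical(n_splits)
  skipped <- 0L
  w_acc <- rep(0, k)
  for (s in seq_len(n_splits)) {
    tr <- sample.int(n, train_size)
    w_sum <- rep(0, k)
    n_ok <- 0L
    for (b in seq_len(n_bags)) {
      idx <- tr[sample.int(train_size, train_size, replace = TRUE)]
      gb <- g[idx]
      gc <- gb - mean(gb)
      sgg <- sum(gc^2)
      if (sgg == 0) next
      Yb <- Y[idx, , drop = FALSE]
      Yc <- sweep(Yb, 2, colMeans(Yb))
      a_hat <- as.numeric(crossprod(Yc, gc)) / sgg
      resid <- Yc - tcrossprod(gc, a_hat)
      Se <- crossprod(resid) / (train_size - 2)
      w <- tryCatch(solve(Se, a_hat), error = function(e) NULL)
      if (is.null(w)) next
      nw <- sqrt(sum(w^2))
      if (nw == 0) next
      w_sum <- w_sum + w / nw
      n_ok <- n_ok + 1L
    }
    if (n_ok == 0L) { skipped <- skipped + 1L; next }
    w_bar <- w_sum / n_ok
    nw <- sqrt(sum(w_bar^2))
    if (nw == 0) { skipped <- skipped + 1L; next }
    w_bar <- w_bar / nw
    te <- setdiff(seq_len(n), tr)
    gte <- g[te]
    if (max(gte) == min(gte)) { skipped <- skipped + 1L; next }
    score <- as.numeric(Y[te, , drop = FALSE] %*% w_bar)
    fit <- uv_linear_test(gte, score)
    stats_s[s] <- fit$slope / fit$se
    used[s] <- TRUE
    w_acc <- w_acc + w_bar
  }
  n_used <- sum(used)
  if (n_used == 0L) {
    stop_convergence("all training splits skipped (monomorphic subsets)",
                     diagnostics = list(skipped = skipped))
  }
  list(stat = mean(stats_s[used]), weights = w_acc / n_used,
       skipped = skipped)
}

#' Principal-component-of-heritability association test
#'
#' Splits the sample into a training set, on which the trait combination
#' maximizing the heritable component is estimated (weights proportional
#' to `solve(Sigma_e_hat, a_hat)`, normalized to unit length, averaged
#' over bootstrap bags), and a test set, on which the combined score is
#' regressed on genotype. The per-split t statistics are averaged across
#' splits. The null distribution of the pooled statistic is obtained by
#' running the identical procedure on trait-permuted data; the final
#' p-value is computed from a scaled-t reference whose standard deviation
#' and degrees of freedom are moment-matched to that permutation
#' distribution.
#'
#' @param genotype Numeric genotype vector.
#' @param traits `n x k` trait matrix.
#' @param settings A [pch_settings()] object.
#' @return An [assoc_result()] (`method = "pch"`); detail carries the
#'   pooled statistic, the averaged trait weights, the moment-matched null
#'   parameters and the skipped-split counts.
#' @export
pch_test <- function(genotype, traits, settings = pch_settings()) {
  Y <- as_trait_matrix(traits)
  n <- nrow(Y)
  stopifnot(inherits(settings, "pch_settings"),
            settings$train_size < n)
  g <- check_genotype(genotype, n)
  obs <- pch_pass(g, Y, settings$n_splits, settings$n_bags,
                  settings$train_size)
  t_null <- vapply(seq_len(settings$n_null), function(r) {
    Yp <- Y[sample.int(n), , drop = FALSE]
    pch_pass(g, Yp, settings$n_splits_null, settings$n_bags,
             settings$train_size)$stat
  }, numeric(1))
  m0 <- mean(t_null)
  v0 <- stats::var(t_null)
  ex_kurt <- mean((t_null - m0)^4) / v0^2 - 3
  df <- min(max(6 / max(ex_kurt, 1e-6) + 4, 5), 1000)
  s0 <- sqrt(v0 * (df - 2) / df)
  p <- 2 * stats::pt(-abs((obs$stat - m0) / s0), df = df)
  assoc_result("pch", max(p, .Machine$double.xmin), "p_value",
               detail = list(stat = obs$stat, weights = obs$weights,
                             null_mean = m0, null_sd = s0, null_df = df,
                             skipped_splits = obs$skipped))
}
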