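# Lean proportional-odds (ordinal logistic) maximum-likelihood fitter.
#
# Model: ordered categories c = 1..C with cutpoints zeta_1 < ... <
# zeta_{C-1} and linear predictor eta_i = x_i' beta;
# P(y_i <= c) = plogis(zeta_c - eta_i). Maximized by Newton-Raphson with
# the analytic gradient and Hessian (step-halving to keep the cutpoints
# ordered and the likelihood increasing), with a quasi-Newton fallback.
# This avoids the formula-interface and generic-optimizer overhead of
# general-purpose fitters, which dominates at permutation-replicate scale.

polr_fit <- function(X, y, hessian = FALSE, maxit = 50L) {
  X <- as.matrix(X)
  n <- nrow(X)
  k <- ncol(X)
  lev <- sort(unique(y))
  C <- length(lev)
  stopifnot(C >= 3L)
  cat_i <- match(y, lev)
  counts <- tabulate(cat_i, C)
  cum <- cumsum(counts[-C]) / n
  theta <- c(rep(0, k), stats::qlogis(cum))
  np <- k + C - 1L
  zi <- k + seq_len(C - 1L)

  # per-observation pieces; u/v (and their derivatives) are 0 at the
  # infinite outer bounds, which the formulas absorb automatically
  pieces <- function(th) {
    beta <- th[seq_len(k)]
    zeta <- th[zi]
    if (is.unsorted(zeta, strictly = TRUE)) return(NULL)
    eta <- as.numeric(X %*% beta)
    a <- ifelse(cat_i < C, zeta[pmin(cat_i, C - 1L)] - eta, Inf)
    b <- ifelse(cat_i > 1L, zeta[pmax(cat_i - 1L, 1L)] - eta, -Inf)
    Fa <- stats::plogis(a)
    Fb <- stats::plogis(b)
    u <- Fa * (1 - Fa)
    v <- Fb * (1 - Fb)
    list(P = pmax(Fa - Fb, 1e-300), u = u, v = v,
         up = u * (1 - 2 * Fa), vp = v * (1 - 2 * Fb))
  }
  loglik <- function(pc) sum(log(pc$P))
  grad <- function(pc) {
    w <- (pc$u - pc$v) / pc$P
    g <- numeric(np)
    g[seq_len(k)] <- -as.numeric(crossprod(X, w))
    ua <- pc$u / pc$P
    vb <- pc$v / pc$P
    for (c in seq_len(C - 1L)) {
      g[k + c] <- sum(ua[cat_i == c]) - sum(vb[cat_i == c + 1L])
    }
    g
  }
  hess <- function(pc) {
    P2 <- pc$P^2
    d_ee <- ((pc$up - pc$vp) * pc$P - (pc$u - pc$v)^2) / P2
    d_eu <- (-pc$up * pc$P + pc$u * (pc$u - pc$v)) / P2
    d_el <- (pc$vp * pc$P - pc$v * (pc$u - pc$v)) / P2
    d_uu <- (pc$up * pc$P - pc$u^2) / P2
    d_ll <- -(pc$vp * pc$P + pc$v^2) / P2
    d_ul <- pc$u * pc$v / P2
    H <- matrix(0, np, np)
    H[seq_len(k), seq_len(k)] <- crossprod(X, X * d_ee)
    for (c in seq_len(C - 1L)) {
      su <- cat_i == c        # zeta_c is the upper bound
      sl <- cat_i == c + 1L   # zeta_c is the lower bound
      hb <- as.numeric(crossprod(X[su, , drop = FALSE], d_eu[su])) +
        as.numeric(crossprod(X[sl, , drop = FALSE], d_el[sl]))
      H[seq_len(k), k + c] <- hb
      H[k + c, seq_len(k)] <- hb
      H[k + c, k + c] <- sum(d_uu[su]) + sum(d_ll[sl])
      if (c < C - 1L) {
        cr <- sum(d_ul[cat_i == c + 1L])
        H[k + c, k + c + 1L] <- cr
        H[k + c + 1L, k + c] <- cr
      }
    }
    H
  }

  pc <- pieces(theta)
  ll <- loglik(pc)
  converged <- FALSE
  msg <- "max iterations reached"
  for (it in seq_len(maxit)) {
    g <- grad(pc)
    H <- hess(pc)
    step <- tryCatch(solve(-H, g), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) {
      msg <- "singular Hessian"
      break
    }
    # step-halving: keep cutpoints ordered and the likelihood rising
    ok <- FALSE
    fac <- 1
    for (h in 1:30) {
      cand <- theta + fac * step
      pc_new <- pieces(cand)
      if (!is.null(pc_new)) {
        ll_new <- loglik(pc_new)
        if (is.finite(ll_new) && ll_new >= ll - 1e-10) { ok <- TRUE; break }
      }
      fac <- fac / 2
    }
    if (!ok) {
      msg <- "step-halving failed"
      break
    }
    delta <- ll_new - ll
    theta <- cand
    pc <- pc_new
    ll <- ll_new
    if (max(abs(grad(pc))) < 1e-6 * max(1, n / 1000) && delta < 1e-10) {
      converged <- TRUE
      msg <- sprintf("converged in %d iterations", it)
      break
    }
  }
  if (!converged) {
    # quasi-Newton fallback from the Newton iterate
    opt <- stats::optim(theta, function(th) {
      p <- pieces(th)
      if (is.null(p)) 1e10 else -loglik(p)
    }, function(th) {
      p <- pieces(th)
      if (is.null(p)) rep(0, np) else -grad(p)
    }, method = "BFGS", control = list(maxit = 200L, reltol = 1e-12))
    theta <- opt$par
    pc <- pieces(theta)
    if (!is.null(pc)) ll <- loglik(pc)
    gn <- if (is.null(pc)) Inf else max(abs(grad(pc)))
    converged <- opt$convergence == 0 && is.finite(ll) && gn < 1e-3
    msg <- paste(msg, "; BFGS fallback code", opt$convergence)
  }
  se <- NULL
  if (hessian && converged) {
    vc <- tryCatch(solve(-hess(pc)), error = function(e) NULL)
    if (!is.null(vc)) se <- sqrt(pmax(diag(vc)[seq_len(k)], 0))
  }
  list(beta = stats::setNames(theta[seq_len(k)], colnames(X)),
       zeta = theta[zi],
       loglik = ll,
       converged = converged,
       message = msg,
       se = se)
}
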