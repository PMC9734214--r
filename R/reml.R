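# REML engines.
#
# Two solvers: a single-kernel fast path working in the eigenbasis of the
# projected kernel (grid search plus local refinement on the variance
# ratio), and a multi-kernel solver using expectation-maximization warm-up
# followed by average-information steps with non-negativity enforced by
# boundary pinning. Both operate on training data only; prediction uses the
# conditional Gaussian expectation with cross-kernel blocks.

# Restricted log-likelihood pieces shared by both solvers.
reml_loglik <- function(y, V, X) {
  n <- length(y)
  ch <- chol(V)
  Vi <- chol2inv(ch)
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  beta <- solve(XtViX, crossprod(ViX, y))
  resid <- y - X %*% beta
  quad <- drop(crossprod(resid, Vi %*% resid))
  ll <- -0.5 * (2 * sum(log(diag(ch))) +
                  as.numeric(determinant(XtViX)$modulus) + quad +
                  (n - ncol(X)) * log(2 * pi))
  list(ll = ll, Vi = Vi, beta = drop(beta), resid = drop(resid))
}

# Single-kernel REML via spectral decomposition (EMMA-style). Returns
# variance components for y = X beta + g + e with g ~ N(0, K s2g),
# e ~ N(0, I s2e).
reml_single <- function(y, K, X = NULL, n_grid = 100L) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1L)
  q <- ncol(X)
  S <- diag(n) - X %*% solve(crossprod(X), t(X))
  SKS <- S %*% K %*% S
  e <- eigen((SKS + t(SKS)) / 2, symmetric = TRUE)
  nq <- n - q
  theta <- pmax(e$values[seq_len(nq)], 0)
  U <- e$vectors[, seq_len(nq), drop = FALSE]
  eta <- drop(crossprod(U, y))
  prof_ll <- function(log_delta) {
    delta <- exp(log_delta)
    denom <- theta + delta
    s2g <- sum(eta ^ 2 / denom) / nq
    -0.5 * (nq * log(2 * pi * s2g) + sum(log(denom)) + nq)
  }
  grid <- seq(log(1e-6), log(1e6), length.out = n_grid)
  vals <- vapply(grid, prof_ll, 0)
  i <- which.max(vals)
  opt <- stats::optimize(prof_ll,
                         c(grid[max(1L, i - 1L)], grid[min(n_grid, i + 1L)]),
                         maximum = TRUE, tol = 1e-8)
  delta <- exp(opt$maximum)
  s2g <- sum(eta ^ 2 / (theta + delta)) / nq
  s2e <- delta * s2g
  V <- s2g * K + diag(s2e, n)
  pieces <- reml_loglik(y, V, X)
  list(
    sigma2 = c(g = s2g, resid = s2e), delta = delta,
    beta = pieces$beta, Vi = pieces$Vi, resid = pieces$resid,
    loglik = pieces$ll, converged = TRUE, n_iter = 1L
  )
}

# Multi-kernel REML: EM warm start then average-information iterations.
# `Ks` is a named list of kernels; a residual identity component is always
# appended. Components are constrained to a lower bound of 1e-6 * var(y)
# by pinning.
reml_multi <- function(y, Ks, X = NULL, max_iter = 200L, tol = 1e-8,
                       n_em = 8L) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1L)
  comps <- c(Ks, list(resid = diag(n)))
  nc <- length(comps)
  vy <- stats::var(y)
  lb <- 1e-6 * vy
  sigma <- rep(vy / nc, nc)
  names(sigma) <- names(comps)

  eval_state <- function(sigma) {
    V <- Reduce(`+`, Map(`*`, comps, sigma))
    pieces <- tryCatch(reml_loglik(y, V, X), error = function(err) {
      reml_loglik(y, V + diag(1e-8 * mean(diag(V)), n), X)
    })
    ViX <- pieces$Vi %*% X
    P <- pieces$Vi - ViX %*% solve(crossprod(X, ViX), t(ViX))
    c(pieces, list(P = P))
  }

  st <- eval_state(sigma)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    Py <- st$P %*% y
    u <- lapply(comps, function(K) K %*% Py)
    yPKPy <- vapply(u, function(v) drop(crossprod(Py, v)), 0)
    trPK <- vapply(comps, function(K) sum(st$P * K), 0)
    score <- 0.5 * (yPKPy - trPK)
    # active set: components held at the lower bound with a negative score
    # want to leave the parameter space; exclude them from the update
    free <- !(sigma <= lb * (1 + 1e-8) & score < 0)
    if (!any(free)) break
    delta_em <- sigma ^ 2 * (yPKPy - trPK) / n
    delta_em[!free] <- 0
    delta <- if (it <= n_em) delta_em else {
      AI <- matrix(0, nc, nc)
      for (a in which(free)) for (b in which(free)[which(free) >= a]) {
        AI[a, b] <- AI[b, a] <- 0.5 * drop(crossprod(u[[a]], st$P %*% u[[b]]))
      }
      d <- numeric(nc)
      d[free] <- tryCatch(
        drop(solve(AI[free, free, drop = FALSE], score[free])),
        error = function(err) {
          drop(MASS::ginv(AI[free, free, drop = FALSE]) %*% score[free])
        }
      )
      d
    }
    try_step <- function(delta) {
      step <- 1
      for (half in 1:12) {
        prop <- pmax(sigma + step * delta, lb)
        st_prop <- eval_state(prop)
        if (st_prop$ll >= st$ll - 1e-10) {
          return(list(prop = prop, st = st_prop, gain = st_prop$ll - st$ll))
        }
        step <- step / 2
      }
      NULL
    }
    cand <- try_step(delta)
    # near-singular AI systems (e.g. duplicated kernels) can stall the AI
    # direction well short of the optimum; fall back to EM steps while they
    # still make real progress, but do not crawl once gains are negligible
    if (it > n_em && (is.null(cand) || cand$gain < tol)) {
      cand_em <- try_step(delta_em)
      if (!is.null(cand_em) &&
          (is.null(cand) || cand_em$gain > cand$gain)) {
        cand <- cand_em
      }
      if (!is.null(cand) && cand$gain < 1e-6) {
        sigma <- cand$prop
        st <- cand$st
        converged <- TRUE
        break
      }
    }
    if (is.null(cand)) break
    sigma <- cand$prop
    st <- cand$st
    if (it > n_em && abs(cand$gain) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged && it >= max_iter) {
    warning("reml_multi: maximum iterations reached; returning best iterate")
  }
  pinned <- sigma <= lb * (1 + 1e-8)
  if (any(pinned)) {
    message("reml_multi: component(s) pinned at lower bound: ",
            paste(names(sigma)[pinned], collapse = ", "))
  }
  list(
    sigma2 = sigma, beta = st$beta, Vi = st$Vi, resid = st$resid,
    loglik = st$ll, converged = converged || it < max_iter, n_iter = it
  )
}
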