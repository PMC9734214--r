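# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Clean two-cluster inbred panel used by several files.
two_pop_panel <- function() {
  cached("two_pop", {
    sim <- simulate_genotypes(sim_config(
      n_samples = 200, n_markers = 500, k_pops = 2,
      fst_like_divergence = 0.3, admixture_concentration = 0.05,
      pop_size_weights = c(0.5, 0.5), missing_rate = 0, het_rate = 0,
      seed = 7
    ))
    sim
  })
}

# Large unstructured-ish panel shared by the evaluation tests.
null_world_panel <- function() {
  cached("panel_400", simulate_genotypes(sim_config(
    400, 1000, k_pops = 3, missing_rate = 0, het_rate = 0, seed = 71
  ))$genotypes)
}

# Tiny deterministic toy panel: explicit dosages, no randomness.
toy_panel <- function(dosage) {
  genotype_matrix(dosage,
                  sample_ids = paste0("s", seq_len(nrow(dosage))),
                  marker_ids = paste0("m", seq_len(ncol(dosage))))
}

# Dense Henderson mixed-model-equation oracle: independent route for
# predictions at fixed variance components. Model
# y = X beta + sum_b u_b + e over all samples, observed on `train_ids`;
# solves the MME with inverse kernels and returns X beta + sum_b u_b for
# the test samples. Kernels must be positive definite.
mme_oracle <- function(y, kernels, sigma2, train_ids, test_ids,
                       covariates = NULL) {
  ids <- rownames(kernels[[1L]])
  n <- length(ids)
  X <- matrix(1, n, 1L, dimnames = list(ids, NULL))
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates)[ids, , drop = FALSE])
  tr <- ids %in% train_ids
  W <- diag(n)[tr, , drop = FALSE]           # incidence of observed records
  Xo <- X[tr, , drop = FALSE]
  s2e <- sigma2[["resid"]]
  nb <- length(kernels)
  p <- ncol(X)
  dim_all <- p + nb * n
  C <- matrix(0, dim_all, dim_all)
  rhs <- numeric(dim_all)
  yo <- y[ids][tr]
  C[1:p, 1:p] <- crossprod(Xo) / s2e
  rhs[1:p] <- crossprod(Xo, yo) / s2e
  for (b in seq_len(nb)) {
    rb <- p + (b - 1L) * n + seq_len(n)
    C[1:p, rb] <- crossprod(Xo, W) / s2e
    C[rb, 1:p] <- t(C[1:p, rb])
    for (b2 in seq_len(nb)) {
      rb2 <- p + (b2 - 1L) * n + seq_len(n)
      C[rb, rb2] <- C[rb, rb2] + crossprod(W) / s2e
    }
    C[rb, rb] <- C[rb, rb] + solve(kernels[[b]]) / sigma2[[names(kernels)[b]]]
    rhs[rb] <- rhs[rb] + crossprod(W, yo) / s2e
  }
  sol <- solve(C, rhs)
  beta <- sol[1:p]
  pred <- drop(X %*% beta)
  for (b in seq_len(nb)) {
    pred <- pred + sol[p + (b - 1L) * n + seq_len(n)]
  }
  names(pred) <- ids
  list(beta = beta, predicted = pred[test_ids])
}

# Small positive-definite toy kernel set built from a random inbred panel.
toy_kernel_panel <- function(n = 10L, m = 40L, seed = 5L) {
  cached(sprintf("toykern_%d_%d_%d", n, m, seed), {
    sim <- simulate_genotypes(sim_config(
      n_samples = n, n_markers = m, k_pops = 2,
      fst_like_divergence = 0.3, admixture_concentration = 0.1,
      pop_size_weights = c(0.5, 0.5), missing_rate = 0, het_rate = 0,
      seed = seed
    ))
    g <- sim$genotypes
    G <- suppressWarnings(vanraden_g(g)) + diag(1e-6, n)  # PD for the MME oracle
    dimnames(G) <- list(g$sample_ids, g$sample_ids)
    H <- epistatic_h(G)
    y <- with_test_seed(seed + 1L, stats::setNames(
      10 + G %*% stats::rnorm(n) * 0.5 + stats::rnorm(n, sd = 0.5),
      g$sample_ids
    ))
    list(sim = sim, g = g, G = G, H = H, y = drop(y))
  })
}

# Marker-space Henderson MME oracle for ridge-regression families whose
# equivalent kernels are singular (subpopulation blocks have zero rows).
# Model y = X beta + sum_b Z_b a_b + e with a_b ~ N(0, I s2_b); the MME
# ridge matrix is always invertible. Predictions are
# X beta + sum_b Z_b[test, ] a_b.
mme_marker_oracle <- function(y, blocks, sigma2, train_ids, test_ids,
                              covariates = NULL) {
  ids <- rownames(blocks[[1L]])
  X <- matrix(1, length(ids), 1L, dimnames = list(ids, NULL))
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates)[ids, , drop = FALSE])
  Xo <- X[train_ids, , drop = FALSE]
  Zo <- lapply(blocks, function(Z) Z[train_ids, , drop = FALSE])
  s2e <- sigma2[["resid"]]
  p <- ncol(X)
  ms <- vapply(blocks, ncol, 0L)
  offs <- p + c(0L, cumsum(ms))[seq_along(blocks)]
  dim_all <- p + sum(ms)
  C <- matrix(0, dim_all, dim_all)
  rhs <- numeric(dim_all)
  yo <- y[train_ids]
  C[1:p, 1:p] <- crossprod(Xo) / s2e
  rhs[1:p] <- crossprod(Xo, yo) / s2e
  for (b in seq_along(blocks)) {
    rb <- offs[b] + seq_len(ms[b])
    C[1:p, rb] <- crossprod(Xo, Zo[[b]]) / s2e
    C[rb, 1:p] <- t(C[1:p, rb])
    for (b2 in seq_along(blocks)) {
      rb2 <- offs[b2] + seq_len(ms[b2])
      C[rb, rb2] <- C[rb, rb2] + crossprod(Zo[[b]], Zo[[b2]]) / s2e
    }
    C[rb, rb] <- C[rb, rb] +
      diag(ms[b]) / sigma2[[names(blocks)[b]]]
    rhs[rb] <- rhs[rb] + crossprod(Zo[[b]], yo) / s2e
  }
  sol <- solve(C, rhs)
  beta <- sol[1:p]
  pred <- drop(X[test_ids, , drop = FALSE] %*% beta)
  for (b in seq_along(blocks)) {
    a_b <- sol[offs[b] + seq_len(ms[b])]
    pred <- pred + drop(blocks[[b]][test_ids, , drop = FALSE] %*% a_b)
  }
  stats::setNames(pred, test_ids)
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
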