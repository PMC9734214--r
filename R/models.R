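# Model fitting front-ends: G-BLUP, EG-BLUP, RR-BLUP, GSA-RRBLUP, W-BLUP.
#
# All fitters estimate variance components by REML on the training samples
# and predict held-out samples through the conditional Gaussian expectation
# using cross-kernel blocks, which is algebraically identical to solving the
# joint mixed-model equations over training and test samples.

new_model_fit <- function(family, fit, fixed_effects, random_blups,
                          fitted_train, predicted_test, extra = list()) {
  structure(
    c(list(
      family = family,
      variance_components = fit$sigma2,
      fixed_effects = fixed_effects,
      random_blups = random_blups,
      fitted_train = fitted_train,
      predicted_test = predicted_test,
      loglik_reml = fit$loglik,
      converged = fit$converged,
      n_iter = fit$n_iter
    ), extra),
    class = "model_fit"
  )
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("model_fit [%s]: logLik(REML) = %.3f, %s in %d iteration(s)\n",
              x$family, x$loglik_reml,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  cat("variance components:\n")
  print(round(x$variance_components, 6))
  invisible(x)
}

check_train_test <- function(y, ids, train_ids, test_ids) {
  if (!all(train_ids %in% ids)) stop("train_ids missing from kernel/design")
  if (!all(test_ids %in% ids)) stop("test_ids missing from kernel/design")
  y_tr <- y[train_ids]
  if (anyNA(y_tr)) stop("y must be observed for every training sample")
  y_tr
}

#' Fit G-BLUP
#'
#' Single-kernel model y = 1 mu + g + e with g ~ N(0, G s2g) and
#' e ~ N(0, I s2e). REML uses the spectral fast path on the training block
#' of G; test-sample genetic values are the conditional expectations
#' `G[test, train] (G[train, train] + lambda I)^-1 (y - mu)` with
#' `lambda = s2e / s2g`.
#'
#' @param y Named numeric vector of BLUEs (NA allowed outside training).
#' @param G Additive relationship matrix covering train and test samples.
#' @param train_ids,test_ids Character vectors of sample IDs.
#' @param family Label stored on the fit.
#' @return A `model_fit`.
#' @export
fit_gblup <- function(y, G, train_ids, test_ids = character(0),
                      family = "G-BLUP") {
  y_tr <- check_train_test(y, rownames(G), train_ids, test_ids)
  fit <- reml_single(y_tr, G[train_ids, train_ids])
  mu <- fit$beta[1L]
  alpha <- fit$Vi %*% fit$resid
  g_tr <- drop(fit$sigma2[["g"]] * G[train_ids, train_ids] %*% alpha)
  g_te <- drop(fit$sigma2[["g"]] * G[test_ids, train_ids, drop = FALSE] %*% alpha)
  new_model_fit(
    family, fit,
    fixed_effects = c(mu = mu),
    random_blups = list(g = stats::setNames(g_tr, train_ids)),
    fitted_train = stats::setNames(mu + g_tr, train_ids),
    predicted_test = stats::setNames(mu + g_te, test_ids)
  )
}

#' Fit a multi-kernel BLUP model
#'
#' REML over two or more variance components (plus a residual), e.g.
#' EG-BLUP with kernels `list(G = G, H = H)`. Predictions sum the
#' per-component conditional means.
#'
#' @param y Named numeric vector of BLUEs.
#' @param kernels Named list of n x n kernels covering train and test.
#' @param train_ids,test_ids Character vectors of sample IDs.
#' @param family Label stored on the fit.
#' @return A `model_fit`; `random_blups` holds one BLUP vector per kernel.
#' @export
fit_multikernel <- function(y, kernels, train_ids, test_ids = character(0),
                            family = "multikernel") {
  ids <- rownames(kernels[[1L]])
  y_tr <- check_train_test(y, ids, train_ids, test_ids)
  Ks_tr <- lapply(kernels, function(K) K[train_ids, train_ids])
  fit <- reml_multi(y_tr, Ks_tr)
  mu <- fit$beta[1L]
  alpha <- fit$Vi %*% fit$resid
  nm <- names(kernels)
  blups_tr <- lapply(nm, function(b) {
    drop(fit$sigma2[[b]] * kernels[[b]][train_ids, train_ids] %*% alpha)
  })
  names(blups_tr) <- nm
  pred_te <- rep(0, length(test_ids))
  for (b in nm) {
    pred_te <- pred_te +
      drop(fit$sigma2[[b]] * kernels[[b]][test_ids, train_ids, drop = FALSE] %*% alpha)
  }
  fitted <- mu + Reduce(`+`, blups_tr)
  new_model_fit(
    family, fit,
    fixed_effects = c(mu = mu),
    random_blups = lapply(blups_tr, stats::setNames, train_ids),
    fitted_train = stats::setNames(fitted, train_ids),
    predicted_test = stats::setNames(mu + pred_te, test_ids)
  )
}

#' Fit ridge-regression BLUP model families in kernel space
#'
#' Each design block Z_b contributes an equivalent kernel Z_b Z_b' whose
#' scale is absorbed by its variance component, so general plus
#' subpopulation-specific models (hard-label or admixture-weighted) are fit
#' as multi-kernel models on 1 + k components. Marker-effect BLUPs are
#' recovered by back-solving `a_b = s2_b Z_b' V^-1 (y - mu)`. Subpopulations
#' with no training sample are dropped with a warning. A design with no
#' subpopulation blocks is plain RR-BLUP.
#'
#' @param y Named numeric vector of BLUEs.
#' @param design A `design_matrices` from [build_design()].
#' @param train_ids,test_ids Character vectors of sample IDs.
#' @param family Label stored on the fit.
#' @param marker_effects If TRUE, back-solve marker-effect BLUPs.
#' @return A `model_fit` with an extra `marker_effects` element (general
#'   vector `a` plus one vector per retained subpopulation block).
#' @export
fit_rr_family <- function(y, design, train_ids, test_ids = character(0),
                          family = "GSA-RRBLUP", marker_effects = FALSE) {
  stopifnot(inherits(design, "design_matrices"))
  ids <- design$sample_ids
  y_tr <- check_train_test(y, ids, train_ids, test_ids)
  blocks <- c(list(A = design$Z_A), design$Z_S)
  for (b in names(blocks)) rownames(blocks[[b]]) <- ids
  tr_mask <- ids %in% train_ids
  keep <- vapply(blocks, function(Z) {
    sum(Z[tr_mask, , drop = FALSE] ^ 2) > 0
  }, logical(1L))
  if (!all(keep)) {
    warning("dropping design block(s) with no training signal: ",
            paste(names(blocks)[!keep], collapse = ", "))
    blocks <- blocks[keep]
  }
  kernels <- lapply(blocks, tcrossprod)
  for (b in names(kernels)) dimnames(kernels[[b]]) <- list(ids, ids)
  res <- fit_multikernel(y, kernels, train_ids, test_ids, family = family)
  if (marker_effects) {
    # a_b = s2_b Z_b' V^-1 (y - mu) on the training block
    Vtr <- Reduce(`+`, Map(
      function(K, s) s * K[train_ids, train_ids],
      kernels, res$variance_components[names(kernels)]
    )) + diag(res$variance_components[["resid"]], length(train_ids))
    rhs <- solve(Vtr, y[train_ids] - res$fixed_effects[["mu"]])
    res$marker_effects <- lapply(names(blocks), function(b) {
      drop(res$variance_components[[b]] *
             crossprod(blocks[[b]][train_ids, , drop = FALSE], rhs))
    })
    names(res$marker_effects) <- names(blocks)
  }
  res
}

#' Fit W-BLUP
#'
#' Mixed model y = 1 mu + F_G a_F + g + e with the r selected markers as
#' fixed allele-content covariates and g ~ N(0, G_r s2g), where G_r is the
#' relationship matrix rebuilt without those markers. Collinear fixed
#' columns (including columns constant over the training set) are dropped
#' with a warning; an empty marker set is an error, callers should fall back
#' to G-BLUP.
#'
#' @param y Named numeric vector of BLUEs.
#' @param G_r Reduced-marker relationship matrix covering train and test.
#' @param F_G n x r allele-content matrix (rownames = sample IDs).
#' @param train_ids,test_ids Character vectors of sample IDs.
#' @param family Label stored on the fit.
#' @return A `model_fit`; `fixed_effects` holds the intercept and `a_F`.
#' @export
fit_wblup <- function(y, G_r, F_G, train_ids, test_ids = character(0),
                      family = "W-BLUP") {
  F_G <- as.matrix(F_G)
  if (ncol(F_G) == 0L) {
    stop("W-BLUP needs r >= 1 fixed markers; fall back to G-BLUP")
  }
  y_tr <- check_train_test(y, rownames(G_r), train_ids, test_ids)
  X_all <- cbind(`(Intercept)` = rep(1, nrow(F_G)), F_G)
  rownames(X_all) <- rownames(F_G)
  X_tr <- X_all[train_ids, , drop = FALSE]
  # greedy rank filter keeps the intercept and non-collinear marker columns
  keep <- 1L
  for (j in 2:ncol(X_tr)) {
    if (qr(X_tr[, c(keep, j), drop = FALSE])$rank == length(keep) + 1L) {
      keep <- c(keep, j)
    }
  }
  if (length(keep) < ncol(X_tr)) {
    warning("dropping collinear fixed marker column(s): ",
            paste(colnames(X_tr)[-keep], collapse = ", "))
  }
  X_tr <- X_tr[, keep, drop = FALSE]
  fit <- reml_single(y_tr, G_r[train_ids, train_ids], X = X_tr)
  beta <- stats::setNames(fit$beta, colnames(X_tr))
  alpha <- fit$Vi %*% fit$resid
  g_tr <- drop(fit$sigma2[["g"]] * G_r[train_ids, train_ids] %*% alpha)
  g_te <- drop(fit$sigma2[["g"]] * G_r[test_ids, train_ids, drop = FALSE] %*% alpha)
  X_te <- X_all[test_ids, keep, drop = FALSE]
  new_model_fit(
    family, fit,
    fixed_effects = beta,
    random_blups = list(g = stats::setNames(g_tr, train_ids)),
    fitted_train = stats::setNames(drop(X_tr %*% beta) + g_tr, train_ids),
    predicted_test = stats::setNames(drop(X_te %*% beta) + g_te, test_ids),
    extra = list(fixed_markers = setdiff(colnames(X_tr), "(Intercept)"))
  )
}

#' BLUP prediction at fixed variance components
#'
#' Computes generalized-least-squares fixed effects and conditional-mean
#' predictions for held-out samples at user-supplied variance components,
#' without REML. This is the prediction kernel shared by every model
#' family: `pred_test = X_test beta + sum_b s2_b K_b[test, train] V^-1
#' (y_train - X_train beta)` with `V = sum_b s2_b K_b[train, train] + s2e
#' I`.
#'
#' @param y Named numeric vector of BLUEs.
#' @param kernels Named list of n x n kernels covering train and test.
#' @param sigma2 Named variance components: one per kernel plus `resid`.
#' @param train_ids,test_ids Character vectors of sample IDs.
#' @param covariates Optional n x c fixed-covariate matrix (rownames =
#'   sample IDs); an intercept is always included.
#' @return A list `beta`, `predicted_test`, `blups_train` (per kernel).
#' @export
predict_fixed_vc <- function(y, kernels, sigma2, train_ids,
                             test_ids = character(0), covariates = NULL) {
  ids <- rownames(kernels[[1L]])
  y_tr <- check_train_test(y, ids, train_ids, test_ids)
  if (!all(c(names(kernels), "resid") %in% names(sigma2))) {
    stop("sigma2 must name every kernel plus 'resid'")
  }
  n_tr <- length(train_ids)
  Vtr <- diag(sigma2[["resid"]], n_tr)
  for (b in names(kernels)) {
    Vtr <- Vtr + sigma2[[b]] * kernels[[b]][train_ids, train_ids]
  }
  X_all <- matrix(1, length(ids), 1L, dimnames = list(ids, "(Intercept)"))
  if (!is.null(covariates)) {
    X_all <- cbind(X_all, as.matrix(covariates)[ids, , drop = FALSE])
  }
  X_tr <- X_all[train_ids, , drop = FALSE]
  Vi <- chol2inv(chol(Vtr))
  ViX <- Vi %*% X_tr
  beta <- drop(solve(crossprod(X_tr, ViX), crossprod(ViX, y_tr)))
  alpha <- Vi %*% (y_tr - X_tr %*% beta)
  blups <- lapply(names(kernels), function(b) {
    stats::setNames(
      drop(sigma2[[b]] * kernels[[b]][train_ids, train_ids] %*% alpha),
      train_ids
    )
  })
  names(blups) <- names(kernels)
  pred <- drop(X_all[test_ids, , drop = FALSE] %*% beta)
  for (b in names(kernels)) {
    pred <- pred +
      drop(sigma2[[b]] * kernels[[b]][test_ids, train_ids, drop = FALSE] %*% alpha)
  }
  list(beta = stats::setNames(beta, colnames(X_tr)),
       predicted_test = stats::setNames(pred, test_ids),
       blups_train = blups)
}

#' Genomic heritability implied by a single-kernel fit
#'
#' The variance of the genetic values across samples is
#' `s2g * (mean(diag(G)) - mean(G))`; with VanRaden centering `mean(G)` is
#' exactly 0 and `diag(G)` averages about 2 on a fully inbred panel, so the
#' raw component ratio `s2g / (s2g + s2e)` would understate heritability.
#' This helper applies the kernel scaling.
#'
#' @param fit A `model_fit` from [fit_gblup()].
#' @param G The kernel used for fitting.
#' @param train_ids Training sample IDs.
#' @return Estimated heritability in \[0, 1\].
#' @export
genomic_h2 <- function(fit, G, train_ids) {
  Gtr <- G[train_ids, train_ids]
  s2g <- fit$variance_components[["g"]]
  s2e <- fit$variance_components[["resid"]]
  vg <- s2g * (mean(diag(Gtr)) - mean(Gtr))
  vg / (vg + s2e)
}

#' Specify one of the compared prediction models
#'
#' The model vocabulary covers the ten compared variants: `"GBLUP"`,
#' `"EGBLUP"`, `"RRBLUP"`, `"WBLUP"` (with `strategy` S1-S4) and
#' `"GSA_RRBLUP"` (with `k` subpopulations, hard-label or
#' admixture-weighted).
#'
#' @param family One of `"GBLUP"`, `"EGBLUP"`, `"RRBLUP"`, `"WBLUP"`,
#'   `"GSA_RRBLUP"`.
#' @param strategy W-BLUP marker-set strategy: `"S1"`, `"S2"`, `"S3"`,
#'   `"S4"`.
#' @param k Number of subpopulations (GSA-RRBLUP).
#' @param admixed Use admixture-weighted designs (GSA-RRBLUP).
#' @param label Display label; a default is derived from the fields.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(family = c("GBLUP", "EGBLUP", "RRBLUP", "WBLUP",
                                  "GSA_RRBLUP"),
                       strategy = NULL, k = NULL, admixed = FALSE,
                       label = NULL) {
  family <- match.arg(family)
  if (family == "WBLUP") {
    strategy <- match.arg(strategy, c("S1", "S2", "S3", "S4"))
  }
  if (family == "GSA_RRBLUP" && is.null(k)) {
    stop("GSA_RRBLUP requires k")
  }
  if (is.null(label)) {
    label <- switch(family,
      GBLUP = "G-BLUP",
      EGBLUP = "EG-BLUP",
      RRBLUP = "RR-BLUP",
      WBLUP = paste0("W-BLUP-", strategy),
      GSA_RRBLUP = sprintf("GSA-RRBLUP-k%d%s", k, if (admixed) "-adm" else "")
    )
  }
  structure(list(family = family, strategy = strategy, k = k,
                 admixed = isTRUE(admixed), label = label),
            class = "model_spec")
}

# Fit one model spec inside a CV fold (or on the full phenotyped set).
# `ctx` carries panel-wide objects prepared once: genotypes, G, H, designs
# per (k, admixed), GWAS settings. Returns a model_fit, or a list with
# `infeasible = TRUE` when a W-BLUP marker-set precondition is not met.
fit_model <- function(spec, y, train_ids, test_ids, ctx) {
  switch(spec$family,
    GBLUP = fit_gblup(y, ctx$G, train_ids, test_ids, family = spec$label),
    EGBLUP = fit_multikernel(y, list(g = ctx$G, g1 = ctx$H), train_ids,
                             test_ids, family = spec$label),
    RRBLUP = fit_gblup(y, ctx$K_A, train_ids, test_ids, family = spec$label),
    GSA_RRBLUP = {
      key <- paste0(spec$k, if (spec$admixed) "adm" else "hard")
      fit_rr_family(y, ctx$designs[[key]], train_ids, test_ids,
                    family = spec$label)
    },
    WBLUP = {
      scan <- gwas_scan(y, ctx$genotypes, ctx$G, train_ids,
                        alpha = ctx$alpha %||% 0.05)
      sel <- select_marker_set(scan, spec$strategy)
      if (!sel$feasible) {
        return(list(infeasible = TRUE, strategy = spec$strategy,
                    reason = "precondition not met"))
      }
      g_r <- drop_markers(ctx$genotypes, sel$markers)
      G_r <- vanraden_g(g_r)
      F_G <- allele_content(ctx$genotypes, sel$markers)
      fit_wblup(y, G_r, F_G, train_ids, test_ids, family = spec$label)
    },
    stop("unknown model family: ", spec$family)
  )
}

#' Serialize a model fit
#'
#' Writes the variance components and convergence information to JSON and
#' the BLUPs/predictions to CSV next to it.
#'
#' @param fit A `model_fit`.
#' @param prefix Output path prefix (`<prefix>.json`, `<prefix>_blups.csv`).
#' @return The JSON path, invisibly.
#' @export
write_model_fit <- function(fit, prefix) {
  jsonlite::write_json(
    list(
      family = fit$family,
      variance_components = as.list(fit$variance_components),
      fixed_effects = as.list(fit$fixed_effects),
      loglik_reml = fit$loglik_reml,
      converged = fit$converged,
      n_iter = fit$n_iter
    ),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA
  )
  preds <- rbind(
    data.frame(sample_id = names(fit$fitted_train), set = "train",
               value = unname(fit$fitted_train)),
    data.frame(sample_id = names(fit$predicted_test), set = "test",
               value = unname(fit$predicted_test))
  )
  utils::write.csv(preds, paste0(prefix, "_predictions.csv"), row.names = FALSE)
  invisible(paste0(prefix, ".json"))
}
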