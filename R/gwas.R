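# Mixed-linear-model association scan, simpleM multiple-testing correction,
# per-marker explained variance, and the four W-BLUP marker-set strategies.

#' Mixed-linear-model association scan (P3D)
#'
#' Variance components of the null kinship model are estimated once by REML
#' on the training samples; every marker is then tested as a fixed effect by
#' generalized least squares under V = G s2g + I s2e with a Wald p-value
#' (population parameters previously determined, the standard fast mode of
#' kinship-corrected scans). Markers monomorphic in the training set get
#' effect 0 and p = 1 and are flagged.
#'
#' @param y Named numeric vector of BLUEs.
#' @param g A QC'd [genotype_matrix()].
#' @param G Kinship (additive relationship) matrix.
#' @param train_ids Training sample IDs (the scan runs inside CV training
#'   folds).
#' @return A data.frame `marker_id`, `effect`, `p_value`, `monomorphic`,
#'   with the null variance components in attribute `varcomp`.
#' @export
mlm_scan <- function(y, g, G, train_ids) {
  y_tr <- y[train_ids]
  if (anyNA(y_tr)) stop("y must be observed for all training samples")
  Z <- g$dosage[train_ids, , drop = FALSE]
  n <- length(train_ids)
  null_fit <- reml_single(y_tr, G[train_ids, train_ids])
  Vi <- null_fit$Vi
  ones <- rep(1, n)
  Vi1 <- Vi %*% ones
  Viy <- Vi %*% y_tr
  ViZ <- Vi %*% Z
  a11 <- drop(crossprod(ones, Vi1))
  b1 <- drop(crossprod(ones, Viy))
  a12 <- drop(crossprod(ones, ViZ))
  a22 <- colSums(Z * ViZ)
  b2 <- drop(crossprod(Z, Viy))
  det2 <- a11 * a22 - a12 ^ 2
  col_var <- colMeans(Z ^ 2) - colMeans(Z) ^ 2
  mono <- col_var < 1e-12 | det2 <= 1e-10 * a11 * pmax(a22, 1e-12)
  effect <- ifelse(mono, 0, (a11 * b2 - a12 * b1) / det2)
  var_b2 <- ifelse(mono, Inf, a11 / det2)
  wald <- effect ^ 2 / var_b2
  p <- ifelse(mono, 1, stats::pchisq(wald, df = 1L, lower.tail = FALSE))
  out <- data.frame(
    marker_id = g$marker_ids,
    effect = effect,
    p_value = pmax(p, .Machine$double.xmin),
    monomorphic = mono,
    row.names = NULL
  )
  attr(out, "varcomp") <- null_fit$sigma2
  out
}

#' Effective number of independent tests (simpleM)
#'
#' Computes the composite-LD correlation matrix of the markers on the given
#' samples blockwise (default block size 133 markers, the reference
#' practice), eigendecomposes each block, and returns the summed smallest
#' eigenvalue counts whose cumulative share reaches `var_threshold`
#' (default 0.995, the published default). Zero-variance markers are
#' removed from the correlation computation.
#'
#' @param g A [genotype_matrix()].
#' @param var_threshold Cumulative eigenvalue share to reach.
#' @param block_size Markers per block.
#' @param sample_ids Optional subset of samples (e.g. a training fold).
#' @return Integer `m_eff`.
#' @export
simple_m <- function(g, var_threshold = 0.995, block_size = 133L,
                     sample_ids = NULL) {
  d <- g$dosage
  if (!is.null(sample_ids)) d <- d[sample_ids, , drop = FALSE]
  if (anyNA(d)) stop("genotypes contain missing calls; run apply_qc() first")
  keep <- apply(d, 2L, stats::sd) > 0
  d <- d[, keep, drop = FALSE]
  m <- ncol(d)
  if (m == 0L) return(0L)
  starts <- seq(1L, m, by = block_size)
  m_eff <- 0L
  for (s in starts) {
    idx <- s:min(s + block_size - 1L, m)
    C <- stats::cor(d[, idx, drop = FALSE])
    ev <- pmax(eigen(C, symmetric = TRUE, only.values = TRUE)$values, 0)
    m_eff <- m_eff + which(cumsum(ev) / sum(ev) >= var_threshold)[1L]
  }
  as.integer(m_eff)
}

#' Phenotypic variance share explained by a marker
#'
#' `share = var(z) * effect^2 / var(y)` on the training samples, capped at
#' 1, with `effect` the marker's scan effect on the dosage scale. The
#' empirical marker variance is used rather than the Hardy-Weinberg form
#' 2p(1-p), which would understate the dosage variance of an inbred panel
#' by a factor of up to two.
#'
#' @param y Named numeric vector of BLUEs.
#' @param g A [genotype_matrix()].
#' @param marker_id Marker to assess.
#' @param effect Scan effect for that marker (dosage scale).
#' @param train_ids Training sample IDs (default: all samples with a BLUE).
#' @return Share in \[0, 1\].
#' @export
variance_explained <- function(y, g, marker_id, effect,
                               train_ids = names(y)[!is.na(y)]) {
  z <- g$dosage[train_ids, marker_id]
  vy <- stats::var(y[train_ids])
  if (vy == 0) return(0)
  min(1, stats::var(z) * effect ^ 2 / vy)
}

#' Association scan with simpleM threshold and explained variance
#'
#' Bundles [mlm_scan()], [simple_m()] and [variance_explained()] into the
#' result the marker-set strategies consume. The significance threshold is
#' `alpha / m_eff`; markers with p strictly below it are significant.
#'
#' @param y Named numeric vector of BLUEs.
#' @param g A QC'd [genotype_matrix()].
#' @param G Kinship matrix.
#' @param train_ids Training sample IDs.
#' @param alpha Nominal significance level (default 0.05).
#' @param var_threshold simpleM eigenvalue-share threshold.
#' @return A list of class `gwas_result`: the scan table plus `m_eff`,
#'   `threshold`, `significant` (marker IDs) and `variance_explained`
#'   (named, per marker).
#' @export
gwas_scan <- function(y, g, G, train_ids, alpha = 0.05,
                      var_threshold = 0.995) {
  scan <- mlm_scan(y, g, G, train_ids)
  m_eff <- simple_m(g, var_threshold = var_threshold, sample_ids = train_ids)
  threshold <- alpha / m_eff
  significant <- scan$marker_id[scan$p_value < threshold]
  share <- vapply(seq_len(nrow(scan)), function(i) {
    variance_explained(y, g, scan$marker_id[i], scan$effect[i], train_ids)
  }, 0)
  structure(
    list(
      scan = scan,
      m_eff = m_eff,
      threshold = threshold,
      significant = significant,
      variance_explained = stats::setNames(share, scan$marker_id)
    ),
    class = "gwas_result"
  )
}

#' @export
print.gwas_result <- function(x, ...) {
  cat(sprintf(
    "gwas_result: %d markers, m_eff = %d, threshold = %.3g, %d significant\n",
    nrow(x$scan), x$m_eff, x$threshold, length(x$significant)
  ))
  invisible(x)
}

#' Select the W-BLUP fixed-marker set
#'
#' The four strategies: S1 takes the single marker with the strongest
#' association even if not significant (always feasible); S2 takes the one
#' significant marker explaining most of the trait's variance; S3 sorts the
#' significant markers by explained variance (descending) and takes the
#' shortest prefix jointly explaining at least 10% of the phenotypic
#' variance; S4 takes all significant markers. S2-S4 are infeasible without
#' a significant marker; S3 additionally requires the cumulative share to
#' reach 0.10.
#'
#' @param scan A `gwas_result`.
#' @param strategy `"S1"`, `"S2"`, `"S3"` or `"S4"`.
#' @param s3_share Cumulative-share target for S3 (default 0.10).
#' @return A list `markers` (character, possibly empty), `feasible` (flag)
#'   and `strategy`.
#' @export
select_marker_set <- function(scan, strategy = c("S1", "S2", "S3", "S4"),
                              s3_share = 0.10) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(scan, "gwas_result"))
  sig <- scan$significant
  infeasible <- list(markers = character(0), feasible = FALSE,
                     strategy = strategy)
  res <- switch(strategy,
    S1 = list(markers = scan$scan$marker_id[which.min(scan$scan$p_value)],
              feasible = TRUE, strategy = strategy),
    S2 = {
      if (!length(sig)) infeasible else {
        shares <- scan$variance_explained[sig]
        list(markers = sig[which.max(shares)], feasible = TRUE,
             strategy = strategy)
      }
    },
    S3 = {
      if (!length(sig)) infeasible else {
        shares <- sort(scan$variance_explained[sig], decreasing = TRUE)
        cum <- cumsum(shares)
        if (cum[length(cum)] < s3_share) infeasible else {
          r <- which(cum >= s3_share)[1L]
          list(markers = names(shares)[seq_len(r)], feasible = TRUE,
               strategy = strategy)
        }
      }
    },
    S4 = {
      if (!length(sig)) infeasible else {
        list(markers = sig, feasible = TRUE, strategy = strategy)
      }
    }
  )
  res
}

#' Write a GWAS result to CSV and JSON
#'
#' @param scan A `gwas_result`.
#' @param prefix Output path prefix.
#' @return The CSV path, invisibly.
#' @export
write_gwas_result <- function(scan, prefix) {
  tab <- scan$scan
  tab$variance_explained <- unname(scan$variance_explained)
  tab$significant <- tab$marker_id %in% scan$significant
  utils::write.csv(tab, paste0(prefix, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(m_eff = scan$m_eff, threshold = scan$threshold,
         n_significant = length(scan$significant)),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(paste0(prefix, ".csv"))
}
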