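# Genomic relationship kernels and marker design matrices.

#' VanRaden method-1 additive genomic relationship matrix
#'
#' Dosages are centered by twice the allele frequency per marker and the
#' cross-product is normalized by 2 * sum(p (1 - p)):
#' G = Z Z' / (2 sum p(1-p)). Frequencies default to the observed
#' frequencies of the full panel (training and test samples jointly);
#' monomorphic markers contribute nothing to the normalizer and are excluded
#' with a warning.
#'
#' @param g A QC'd [genotype_matrix()].
#' @param p Optional vector of allele frequencies to center with (length =
#'   markers); defaults to observed panel frequencies.
#' @return n x n symmetric matrix with sample IDs as dimnames.
#' @export
vanraden_g <- function(g, p = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosage
  if (anyNA(d)) stop("genotypes contain missing calls; run apply_qc() first")
  if (is.null(p)) p <- colMeans(d) / 2
  if (length(p) != ncol(d)) stop("p must have one frequency per marker")
  poly <- p > 0 & p < 1
  if (!all(poly)) {
    warning(sprintf("excluding %d monomorphic marker(s) from G", sum(!poly)))
    d <- d[, poly, drop = FALSE]
    p <- p[poly]
  }
  if (!length(p)) stop("no polymorphic markers left for G")
  Z <- sweep(d, 2L, 2 * p)
  G <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  dimnames(G) <- list(g$sample_ids, g$sample_ids)
  G
}

#' Epistatic genomic relationship matrix
#'
#' The additive-by-additive kernel is the Hadamard square of the additive
#' kernel, H = G o G, positive semidefinite by the Schur product theorem.
#'
#' @param G Additive relationship matrix.
#' @return H, same dimnames as G.
#' @export
epistatic_h <- function(G) {
  G * G
}

#' Repair a kernel that is numerically indefinite
#'
#' Adds jitter `1e-8 * mean(diag(K))` to the diagonal when the smallest
#' eigenvalue is below `-1e-8`, with a message.
#'
#' @param K Symmetric matrix.
#' @return The (possibly jittered) matrix.
#' @export
ensure_psd <- function(K) {
  ev_min <- min(eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8) {
    message(sprintf("ensure_psd: min eigenvalue %.3g, adding diagonal jitter", ev_min))
    K <- K + diag(1e-8 * mean(diag(K)), nrow(K))
  }
  K
}

#' Build design matrices for ridge-regression model families
#'
#' `Z_A` is the dosage matrix centered by twice the panel allele
#' frequencies. Subpopulation-specific copies are either hard-label masked
#' (`Z_S[[j]]` keeps the rows of samples assigned to cluster j and zeroes
#' the rest) or admixture-weighted (`Z_Sadm[[j]] = diag(Q[, j]) Z_A`), so
#' the k admixture-weighted copies sum to `Z_A` exactly when Q rows lie on
#' the simplex.
#'
#' @param g A QC'd [genotype_matrix()].
#' @param admixture An `admixture_result` (or a list with `Q` and `labels`).
#' @param mode `"hard"` or `"admixed"`.
#' @param k Number of subpopulations; defaults to `ncol(Q)`.
#' @return A list of class `design_matrices` with `Z_A`, `Z_S` (list of k
#'   matrices) and `mode`.
#' @export
build_design <- function(g, admixture, mode = c("hard", "admixed"), k = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(g, "genotype_matrix"))
  Q <- as.matrix(admixture$Q)
  if (is.null(k)) k <- ncol(Q)
  if (k != ncol(Q)) stop("k does not match ncol(Q)")
  if (nrow(Q) != nrow(g$dosage)) stop("Q rows must match samples")
  d <- g$dosage
  if (anyNA(d)) stop("genotypes contain missing calls; run apply_qc() first")
  p <- colMeans(d) / 2
  Z_A <- sweep(d, 2L, 2 * p)
  labels <- admixture$labels %||% max.col(Q, ties.method = "first")
  Z_S <- lapply(seq_len(k), function(j) {
    w <- if (mode == "hard") as.numeric(labels == j) else Q[, j]
    Z_A * w
  })
  names(Z_S) <- paste0("S", seq_len(k))
  structure(list(Z_A = Z_A, Z_S = Z_S, mode = mode, k = k,
                 sample_ids = g$sample_ids),
            class = "design_matrices")
}

#' Raw allele-content matrix for selected markers
#'
#' Codes the uncentered allele content (dosage 0/1/2) of the selected
#' markers, used as the fixed-marker design of W-BLUP; centering is absorbed
#' by the model intercept.
#'
#' @param g A [genotype_matrix()].
#' @param marker_ids Markers to extract.
#' @return n x r numeric matrix.
#' @export
allele_content <- function(g, marker_ids) {
  missing_m <- setdiff(marker_ids, g$marker_ids)
  if (length(missing_m)) stop("unknown markers: ", paste(missing_m, collapse = ", "))
  g$dosage[, marker_ids, drop = FALSE]
}

#' Drop markers from a genotype matrix
#'
#' Used to rebuild the reduced-marker relationship matrix of W-BLUP (the
#' marker set is reduced by the r fixed markers, with its own normalizer).
#'
#' @param g A [genotype_matrix()].
#' @param marker_ids Markers to remove.
#' @return A [genotype_matrix()] without those markers.
#' @export
drop_markers <- function(g, marker_ids) {
  keep <- setdiff(g$marker_ids, marker_ids)
  if (!length(keep)) stop("dropping all markers")
  genotype_matrix(g$dosage[, keep, drop = FALSE],
                  sample_ids = g$sample_ids, marker_ids = keep)
}
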