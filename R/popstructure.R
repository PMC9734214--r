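# Population-structure analysis: Rogers' distances, principal coordinate
# analysis, admixture estimation with cross-entropy model choice, and
# phenotypic Euclidean distances.

distance_matrix <- function(values, ids, metric_name) {
  values <- as.matrix(values)
  dimnames(values) <- list(ids, ids)
  structure(list(ids = ids, values = values, metric_name = metric_name),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("distance_matrix (%s): %d x %d\n", x$metric_name,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Pairwise Rogers' distances between individuals
#'
#' Hexaploid wheat is treated as diploid, so per-individual allele
#' frequencies are dosage/2. For a biallelic marker the per-marker Rogers'
#' distance between individuals i and j is
#' sqrt(0.5 * sum over alleles of (p_i - p_j)^2) = |p_i - p_j|, and the
#' overall distance is the unweighted mean over markers, giving values in
#' \[0, 1\].
#'
#' @param g A QC'd [genotype_matrix()] (no missing calls).
#' @return A `distance_matrix` with `metric_name = "rogers"`.
#' @export
rogers_distance <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (anyNA(g$dosage)) {
    stop("genotypes contain missing calls; run apply_qc() first")
  }
  P <- g$dosage / 2
  D <- as.matrix(stats::dist(P, method = "manhattan")) / ncol(P)
  distance_matrix(D, g$sample_ids, "rogers")
}

#' Principal coordinate analysis (classical scaling)
#'
#' Double-centers -D^2/2, eigendecomposes, and returns coordinates scaled by
#' the square roots of the eigenvalues, ordered by descending eigenvalue.
#' Explained variance shares are computed over the positive eigenvalues
#' only. Requesting more axes than there are positive eigenvalues truncates
#' with a warning.
#'
#' @param d A `distance_matrix`.
#' @param n_axes Number of axes to return.
#' @return A list with `coordinates` (n x n_axes), `explained` (variance
#'   shares per returned axis) and `eigenvalues` (all eigenvalues).
#' @export
pcoa <- function(d, n_axes = 2L) {
  stopifnot(inherits(d, "distance_matrix"))
  D <- d$values
  A <- -0.5 * D ^ 2
  B <- A - outer(rowMeans(A), colMeans(A), `+`) + mean(A)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  npos <- sum(e$values > tol)
  if (n_axes > npos) {
    warning(sprintf("n_axes = %d exceeds the %d positive eigenvalues; truncated",
                    n_axes, npos))
    n_axes <- npos
  }
  idx <- seq_len(n_axes)
  coords <- e$vectors[, idx, drop = FALSE] %*%
    diag(sqrt(e$values[idx]), n_axes, n_axes)
  rownames(coords) <- d$ids
  colnames(coords) <- paste0("PCo", idx)
  pos_sum <- sum(e$values[e$values > tol])
  list(coordinates = coords,
       explained = e$values[idx] / pos_sum,
       eigenvalues = e$values)
}

# One masked alternating-least-squares factorization run. P is the n x m
# individual allele-frequency matrix (dosage/2); masked entries are held out
# for the cross-entropy score and refilled with the current model prediction
# each sweep.
admixture_als <- function(P, k, max_iter, mask, rep_seed, eps = 1e-4) {
  n <- nrow(P)
  m <- ncol(P)
  col_mean <- colMeans(P)
  Pw <- P
  Pw[mask] <- col_mean[((mask - 1L) %/% n) + 1L]
  if (k == 1L) {
    Q <- matrix(1, n, 1L)
    Fm <- matrix(colMeans(Pw), 1L, m)
    pred <- Q %*% Fm
  } else {
    Q <- with_seed(rep_seed, {
      Q0 <- matrix(stats::rgamma(n * k, 1), n, k)
      Q0 / rowSums(Q0)
    })
    Fm <- NULL
    pred <- NULL
    prev_Q <- Q
    for (it in seq_len(max_iter)) {
      Fm <- solve(crossprod(Q) + 1e-6 * diag(k), crossprod(Q, Pw))
      Fm <- clip(Fm, eps, 1 - eps)
      Qn <- Pw %*% t(Fm) %*% solve(tcrossprod(Fm) + 1e-6 * diag(k))
      Q <- project_rows_simplex(Qn)
      pred <- Q %*% Fm
      Pw[mask] <- pred[mask]
      if (max(abs(Q - prev_Q)) < 1e-6) break
      prev_Q <- Q
    }
  }
  # Binomial (per-allele) log-loss of predicted frequencies on held-out calls.
  q <- clip(pred[mask], eps, 1 - eps)
  x <- 2 * P[mask]
  ce <- -mean(x * log(q) + (2 - x) * log(1 - q)) / 2
  list(Q = Q, F = clip(Fm, eps, 1 - eps), cross_entropy = ce)
}

#' Estimate admixture proportions
#'
#' Factorizes the n x m individual allele-frequency matrix (dosage/2) into a
#' row-simplex Q (n x k) and ancestral frequency profiles F (k x m) by
#' alternating least squares with Euclidean simplex projection. A random
#' fraction of entries is masked before fitting and the fit is scored by the
#' binomial cross-entropy of the predicted frequencies Q F on the held-out
#' calls; the best of `n_repeats` independently initialized runs is
#' returned. This mirrors the interface of sparse-NMF style admixture
#' estimators (k scan, repeated runs, cross-entropy model choice) without
#' reproducing any particular published algorithm.
#'
#' @param g A QC'd [genotype_matrix()].
#' @param k Number of ancestral populations (1 <= k <= n).
#' @param n_repeats Number of independently initialized runs.
#' @param max_iter Maximum ALS sweeps per run.
#' @param masked_fraction Fraction of entries held out for scoring.
#' @param seed Integer seed; run r uses a seed derived from `seed` and r so
#'   the same masks are reused across values of `k`.
#' @return An `admixture_result`: `Q`, `ancestral_freqs`, `k`,
#'   `cross_entropy` (best run), `cross_entropy_repeats` (all runs) and
#'   `labels` (argmax of each Q row, ties to the lowest index).
#' @export
estimate_admixture <- function(g, k, n_repeats = 5L, max_iter = 100L,
                               masked_fraction = 0.05, seed = 1L) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (anyNA(g$dosage)) stop("genotypes contain missing calls; run apply_qc() first")
  n <- nrow(g$dosage)
  if (k < 1 || k > n) stop("k must satisfy 1 <= k <= n")
  stopifnot_scalar(masked_fraction, "masked_fraction", 0, 1, strict_upper = TRUE)
  P <- g$dosage / 2
  runs <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    mask_seed <- derive_seed(seed, r)
    mask <- with_seed(mask_seed, {
      n_mask <- max(1L, round(masked_fraction * length(P)))
      sample.int(length(P), n_mask)
    })
    runs[[r]] <- admixture_als(P, k, max_iter, mask,
                               rep_seed = derive_seed(seed, 1000L + r))
  }
  ces <- vapply(runs, `[[`, numeric(1L), "cross_entropy")
  best <- runs[[which.min(ces)]]
  Q <- best$Q
  rownames(Q) <- g$sample_ids
  colnames(Q) <- paste0("Pop", seq_len(k))
  structure(
    list(
      Q = Q,
      ancestral_freqs = best$F,
      k = as.integer(k),
      cross_entropy = min(ces),
      cross_entropy_repeats = ces,
      labels = stats::setNames(max.col(Q, ties.method = "first"), g$sample_ids)
    ),
    class = "admixture_result"
  )
}

#' @export
print.admixture_result <- function(x, ...) {
  cat(sprintf("admixture_result: n = %d, k = %d, cross-entropy = %.4f\n",
              nrow(x$Q), x$k, x$cross_entropy))
  cat("cluster sizes:", paste(tabulate(x$labels, x$k), collapse = ", "), "\n")
  invisible(x)
}

#' Scan candidate numbers of ancestral populations
#'
#' Runs [estimate_admixture()] for each k in `k_range` and aggregates the
#' cross-entropy scores over the repeated runs.
#'
#' @inheritParams estimate_admixture
#' @param k_range Integer vector of candidate k values.
#' @return A data.frame with columns `k`, `mean_cross_entropy`,
#'   `sd_cross_entropy` and `best_cross_entropy`, plus attribute `results`
#'   holding the `admixture_result` per k.
#' @export
choose_k <- function(g, k_range, n_repeats = 5L, max_iter = 100L,
                     masked_fraction = 0.05, seed = 1L) {
  results <- lapply(k_range, function(k) {
    estimate_admixture(g, k, n_repeats = n_repeats, max_iter = max_iter,
                       masked_fraction = masked_fraction, seed = seed)
  })
  tab <- data.frame(
    k = as.integer(k_range),
    mean_cross_entropy = vapply(results, function(r) mean(r$cross_entropy_repeats), 0),
    sd_cross_entropy = vapply(results, function(r) stats::sd(r$cross_entropy_repeats), 0),
    best_cross_entropy = vapply(results, `[[`, 0, "cross_entropy")
  )
  attr(tab, "results") <- stats::setNames(results, paste0("k", k_range))
  tab
}

#' Euclidean phenotype distances on standardized BLUEs
#'
#' Restricted to samples with complete records for all requested traits;
#' traits are standardized to unit variance before distances are computed
#' (the traits sit on incommensurate scales), unless `standardize = FALSE`.
#'
#' @param blues Long data.frame with columns `sample_id`, `trait`, `value`.
#' @param traits Character vector of traits to use (default: all present).
#' @param standardize Standardize each trait to unit variance first.
#' @return A `distance_matrix` (`metric_name = "euclidean_phenotype"`) over
#'   the complete-case samples; the retained IDs are in `$ids`.
#' @export
phenotype_euclidean <- function(blues, traits = NULL, standardize = TRUE) {
  stopifnot(all(c("sample_id", "trait", "value") %in% names(blues)))
  traits <- traits %||% unique(blues$trait)
  wide <- stats::reshape(
    blues[blues$trait %in% traits, c("sample_id", "trait", "value")],
    idvar = "sample_id", timevar = "trait", direction = "wide"
  )
  colnames(wide) <- sub("^value\\.", "", colnames(wide))
  missing_traits <- setdiff(traits, colnames(wide))
  if (length(missing_traits)) {
    stop("traits absent from BLUE table: ", paste(missing_traits, collapse = ", "))
  }
  mat <- as.matrix(wide[, traits, drop = FALSE])
  complete <- stats::complete.cases(mat)
  if (!any(complete)) stop("no sample has complete records for all requested traits")
  mat <- mat[complete, , drop = FALSE]
  ids <- wide$sample_id[complete]
  if (standardize) {
    sds <- apply(mat, 2L, stats::sd)
    sds[sds == 0] <- 1
    mat <- sweep(mat, 2L, sds, "/")
  }
  distance_matrix(as.matrix(stats::dist(mat)), ids, "euclidean_phenotype")
}

#' Mean between-subpopulation distances
#'
#' For every unordered pair of labels, the mean and standard deviation of
#' the cross-group pairwise distances; the most contrasting pair is recorded
#' in the `max_pair` attribute.
#'
#' @param d A `distance_matrix`.
#' @param labels Vector of subpopulation labels, one per ID in `d` (named
#'   vectors are matched by name).
#' @return A data.frame `pop1`, `pop2`, `mean_distance`, `sd_distance`,
#'   `n_pairs`, with attribute `max_pair`.
#' @export
subpopulation_contrast <- function(d, labels) {
  stopifnot(inherits(d, "distance_matrix"))
  if (!is.null(names(labels))) labels <- labels[d$ids]
  if (length(labels) != length(d$ids)) stop("labels must cover every ID in d")
  lev <- sort(unique(labels))
  if (length(lev) < 2L) {
    out <- data.frame(pop1 = character(0), pop2 = character(0),
                      mean_distance = numeric(0), sd_distance = numeric(0),
                      n_pairs = integer(0))
    attr(out, "max_pair") <- NULL
    return(out)
  }
  pairs <- utils::combn(lev, 2L)
  rows <- apply(pairs, 2L, function(pr) {
    vals <- d$values[labels == pr[1L], labels == pr[2L], drop = FALSE]
    c(mean = mean(vals), sd = stats::sd(as.vector(vals)), n = length(vals))
  })
  out <- data.frame(
    pop1 = as.character(pairs[1L, ]),
    pop2 = as.character(pairs[2L, ]),
    mean_distance = rows["mean", ],
    sd_distance = rows["sd", ],
    n_pairs = as.integer(rows["n", ])
  )
  attr(out, "max_pair") <- unlist(out[which.max(out$mean_distance),
                                      c("pop1", "pop2")], use.names = FALSE)
  out
}
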