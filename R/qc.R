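# Marker quality control for inbred SNP panels.
#
# The pipeline filters markers in a fixed order:
#   step 1: drop markers with excess missingness, too few homozygous calls
#           for either allele, or excess heterozygosity;
#   step 2: impute remaining missing calls to the homozygous dosage of the
#           marker's dominant (modal) allele;
#   step 3: re-filter on minor allele frequency computed after imputation.
# Samples are never filtered, only markers.

#' QC configuration
#'
#' @param max_missing Markers with a missing-call fraction strictly greater
#'   than this are removed (default 0.10).
#' @param min_homozygous_per_allele Markers with strictly fewer homozygous
#'   genotypes than this for either allele are removed (default 10).
#' @param max_het Markers with a heterozygosity (among observed calls)
#'   strictly greater than this are removed (default 0.01).
#' @param min_maf Markers with post-imputation minor allele frequency
#'   strictly below this are removed (default 0.01; the threshold itself is
#'   inclusive, MAF equal to `min_maf` is kept).
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(max_missing = 0.10, min_homozygous_per_allele = 10,
                      max_het = 0.01, min_maf = 0.01) {
  stopifnot_scalar(max_missing, "max_missing", 0, 1, strict_upper = TRUE)
  stopifnot_scalar(min_homozygous_per_allele, "min_homozygous_per_allele", 0)
  stopifnot_scalar(max_het, "max_het", 0, 1)
  stopifnot_scalar(min_maf, "min_maf", 0, 0.5)
  structure(
    list(
      max_missing = max_missing,
      min_homozygous_per_allele = min_homozygous_per_allele,
      max_het = max_het,
      min_maf = min_maf
    ),
    class = "qc_config"
  )
}

#' Apply marker QC and dominant-allele imputation
#'
#' @param g A [genotype_matrix()].
#' @param cfg A [qc_config()].
#' @return A list with elements `genotypes` (the filtered, fully imputed
#'   [genotype_matrix()]) and `report` (a `qc_report` with per-step removal
#'   counts and the removed marker IDs).
#' @export
apply_qc <- function(g, cfg = qc_config()) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(cfg, "qc_config"))
  d <- g$dosage
  m <- ncol(d)
  obs <- !is.na(d)
  n_obs <- colSums(obs)
  miss_rate <- 1 - n_obs / nrow(d)
  hom_ref <- colSums(d == 0, na.rm = TRUE)
  hom_alt <- colSums(d == 2, na.rm = TRUE)
  het_rate <- ifelse(n_obs > 0, colSums(d == 1, na.rm = TRUE) / n_obs, 1)

  fail_missing <- miss_rate > cfg$max_missing
  fail_homcount <- hom_ref < cfg$min_homozygous_per_allele |
    hom_alt < cfg$min_homozygous_per_allele
  fail_het <- het_rate > cfg$max_het
  fail1 <- fail_missing | fail_homcount | fail_het

  d2 <- d[, !fail1, drop = FALSE]
  if (ncol(d2) == 0L) stop("empty panel: all markers removed by step-1 filters")

  # Dominant allele = modal allele among observed calls; imputed value is its
  # homozygous dosage (0 or 2), never 1 -- the panel is inbred. Ties go to
  # the reference allele.
  p_obs <- colMeans(d2, na.rm = TRUE) / 2
  impute_val <- ifelse(p_obs > 0.5, 2, 0)
  miss_idx <- which(is.na(d2), arr.ind = TRUE)
  if (nrow(miss_idx)) d2[miss_idx] <- impute_val[miss_idx[, 2L]]

  p_post <- colMeans(d2) / 2
  maf <- pmin(p_post, 1 - p_post)
  fail3 <- maf < cfg$min_maf
  d3 <- d2[, !fail3, drop = FALSE]
  if (ncol(d3) == 0L) stop("empty panel: all markers removed by the MAF re-filter")

  out <- genotype_matrix(d3, sample_ids = g$sample_ids,
                         marker_ids = colnames(d3))
  report <- structure(
    list(
      n_input = m,
      removed_missing = sum(fail_missing),
      removed_homcount = sum(fail_homcount),
      removed_het = sum(fail_het),
      removed_step1 = sum(fail1),
      removed_maf = sum(fail3),
      retained = ncol(d3),
      removed_step1_ids = g$marker_ids[fail1],
      removed_maf_ids = colnames(d2)[fail3],
      n_imputed = nrow(miss_idx)
    ),
    class = "qc_report"
  )
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    paste0(
      "QC report: %d markers in\n",
      "  step 1 removed %d (missingness %d, homozygote count %d, heterozygosity %d;\n",
      "    a marker may violate several criteria)\n",
      "  imputed %d missing calls to the dominant allele\n",
      "  step 3 (MAF re-filter) removed %d\n",
      "  retained %d\n"
    ),
    x$n_input, x$removed_step1, x$removed_missing, x$removed_homcount,
    x$removed_het, x$n_imputed, x$removed_maf, x$retained
  ))
  invisible(x)
}

#' Write a QC report to CSV
#'
#' @param report A `qc_report` from [apply_qc()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  df <- data.frame(
    step = c("input", "removed_step1", "removed_missing", "removed_homcount",
             "removed_het", "removed_maf", "retained"),
    n_markers = c(report$n_input, report$removed_step1, report$removed_missing,
                  report$removed_homcount, report$removed_het,
                  report$removed_maf, report$retained)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
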