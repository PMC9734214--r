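# Genotype container and file IO.
#
# Dosages are counts of the alternate (non-reference) allele per sample and
# marker: 0, 1 or 2, with NA marking missing calls. The panels targeted here
# are inbred lines, so heterozygous calls (dosage 1) are rare and subject to
# QC filtering.

#' Construct a genotype matrix
#'
#' Container for a samples x markers allele-dosage matrix with sample and
#' marker identifiers, an implicit missing-data mask (`NA` entries) and,
#' after QC, per-marker allele frequencies.
#'
#' @param dosage Numeric matrix (samples x markers) with entries in
#'   `{0, 1, 2, NA}`.
#' @param sample_ids Character vector of unique sample identifiers; defaults
#'   to `rownames(dosage)`.
#' @param marker_ids Character vector of unique marker identifiers; defaults
#'   to `colnames(dosage)`.
#' @return An object of class `genotype_matrix` with elements `dosage`,
#'   `sample_ids`, `marker_ids` and `allele_freq` (alternate-allele
#'   frequencies computed from observed calls).
#' @export
genotype_matrix <- function(dosage, sample_ids = rownames(dosage),
                            marker_ids = colnames(dosage)) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  n <- nrow(dosage)
  m <- ncol(dosage)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  if (is.null(marker_ids)) marker_ids <- paste0("M", seq_len(m))
  sample_ids <- as.character(sample_ids)
  marker_ids <- as.character(marker_ids)
  if (length(sample_ids) != n) stop("sample_ids length does not match rows")
  if (length(marker_ids) != m) stop("marker_ids length does not match columns")
  if (anyDuplicated(sample_ids)) stop("duplicate sample_ids")
  if (anyDuplicated(marker_ids)) stop("duplicate marker_ids")
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad)) stop("dosage entries must be 0, 1, 2 or NA")
  dimnames(dosage) <- list(sample_ids, marker_ids)
  structure(
    list(
      dosage = dosage,
      sample_ids = sample_ids,
      marker_ids = marker_ids,
      allele_freq = colMeans(dosage, na.rm = TRUE) / 2
    ),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  n_miss <- sum(is.na(x$dosage))
  cat(sprintf(
    "genotype_matrix: %d samples x %d markers (%.2f%% missing)\n",
    length(x$sample_ids), length(x$marker_ids),
    100 * n_miss / length(x$dosage)
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Read a genotype matrix from TSV or VCF
#'
#' The TSV layout is a header row of marker IDs, a first column `sample_id`,
#' and dosage entries in `{0, 1, 2}` or `NA`. VCF input is read with
#' \pkg{VariantAnnotation}; only biallelic SNP records are kept (skipped
#' records are reported), GT fields are mapped to alternate-allele dosages
#' (heterozygous to 1, any missing allele to NA).
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"vcf"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (!identical(colnames(tab)[1L], "sample_id")) {
      stop("malformed TSV (line 1): first column must be 'sample_id'")
    }
    ids <- as.character(tab[[1L]])
    mat <- as.matrix(tab[, -1L, drop = FALSE])
    storage.mode(mat) <- "double"
    bad_rows <- which(apply(mat, 1L, function(r) {
      any(!(r %in% c(0, 1, 2) | is.na(r)))
    }))
    if (length(bad_rows)) {
      stop(sprintf(
        "malformed TSV record at line %d: dosages must be 0/1/2/NA",
        bad_rows[1L] + 1L
      ))
    }
    return(genotype_matrix(mat, sample_ids = ids, marker_ids = colnames(mat)))
  }
  vcf <- tryCatch(
    VariantAnnotation::readVcf(path),
    error = function(e) stop("malformed VCF '", path, "': ", conditionMessage(e))
  )
  n_alt <- S4Vectors::elementNROWS(VariantAnnotation::alt(vcf))
  keep <- n_alt == 1L
  n_skipped <- sum(!keep)
  if (n_skipped > 0L) {
    message(sprintf("read_genotypes: skipped %d non-biallelic VCF site(s)", n_skipped))
    vcf <- vcf[keep, ]
  }
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  dos <- apply(gt, c(1L, 2L), gt_to_dosage)
  g <- t(dos)
  genotype_matrix(g, sample_ids = rownames(g), marker_ids = colnames(g))
}

gt_to_dosage <- function(gt) {
  alleles <- strsplit(gt, "[/|]")[[1L]]
  if (length(alleles) != 2L || any(alleles == ".")) return(NA_real_)
  sum(as.numeric(alleles))
}

#' Write a genotype matrix to TSV or VCF
#'
#' The VCF writer emits a minimal VCF v4.2 with synthesized chromosome
#' (`1`) and positions (marker index), REF `A`, ALT `G`, and GT-only
#' genotype fields (`0/0`, `0/1`, `1/1`, `./.`). This is sufficient for
#' round-tripping dosage panels; it is not a general-purpose VCF exporter.
#'
#' @param g A [genotype_matrix()].
#' @param path Output path.
#' @param format `"tsv"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  stopifnot(inherits(g, "genotype_matrix"))
  if (format == "tsv") {
    tab <- data.frame(sample_id = g$sample_ids, check.names = FALSE)
    tab <- cbind(tab, as.data.frame(g$dosage, check.names = FALSE))
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  m <- length(g$marker_ids)
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$sample_ids), collapse = "\t")
  )
  body <- vapply(seq_len(m), function(j) {
    calls <- g$dosage[, j]
    gt <- ifelse(is.na(calls), "./.", gt_code[as.character(calls)])
    paste(c("1", j, g$marker_ids[j], "A", "G", ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1L))
  writeLines(c(header, body), path)
  invisible(path)
}
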