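# Synthetic admixed inbred panels and trait values with known architecture.
#
# The generator emulates the data structure the model comparison assumes:
# k ancestral populations with allele-frequency profiles diverged around a
# shared base frequency (Balding-Nichols-style beta perturbation), one
# optional outgroup with elevated divergence, Dirichlet-distributed per
# sample admixture with unequal subpopulation sizes, essentially homozygous
# genotypes with rare heterozygous and missing calls, and traits built from
# general additive effects, admixture-weighted subpopulation-specific
# effects, additive-by-additive epistatic products, optional major QTL and
# Gaussian noise at a target heritability.

#' Simulation configuration for genotype panels
#'
#' @param n_samples Number of samples (inbred accessions).
#' @param n_markers Number of biallelic markers.
#' @param k_pops Number of ancestral populations.
#' @param fst_like_divergence Real in (0, 1); scales the spread of
#'   population allele frequencies around the shared base frequency
#'   (Balding-Nichols F parameter).
#' @param outgroup_index Optional population index (1..k) receiving elevated
#'   divergence (three times `fst_like_divergence`, capped at 0.9), giving
#'   one clearly distinct outgroup among otherwise similar clusters.
#' @param admixture_concentration Positive real; Dirichlet concentration for
#'   admixture rows. Small values give near-pure cluster members, large
#'   values strong admixture.
#' @param pop_size_weights Length-`k_pops` vector of sampling weights for
#'   the primary cluster of each sample; must sum to 1. Defaults to
#'   geometrically decaying weights so subpopulations are unequal in size.
#' @param missing_rate Fraction of calls set missing, in \[0, 1).
#' @param het_rate Fraction of observed calls made heterozygous, in \[0, 1).
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples, n_markers, k_pops = 1L,
                       fst_like_divergence = 0.15, outgroup_index = NULL,
                       admixture_concentration = 0.2,
                       pop_size_weights = NULL,
                       missing_rate = 0.02, het_rate = 0.005, seed = 1L) {
  stopifnot_scalar(n_samples, "n_samples", 1)
  stopifnot_scalar(n_markers, "n_markers", 1)
  stopifnot_scalar(k_pops, "k_pops", 1)
  stopifnot_scalar(fst_like_divergence, "fst_like_divergence", 0, 1,
                   strict_lower = TRUE, strict_upper = TRUE)
  stopifnot_scalar(admixture_concentration, "admixture_concentration", 0,
                   strict_lower = TRUE)
  stopifnot_scalar(missing_rate, "missing_rate", 0, 1, strict_upper = TRUE)
  stopifnot_scalar(het_rate, "het_rate", 0, 1, strict_upper = TRUE)
  if (n_markers < k_pops) {
    stop("n_markers < k_pops: allele-frequency profiles unidentifiable")
  }
  if (is.null(pop_size_weights)) {
    pop_size_weights <- 0.6 ^ seq_len(k_pops)
    pop_size_weights <- pop_size_weights / sum(pop_size_weights)
  }
  if (length(pop_size_weights) != k_pops) {
    stop("pop_size_weights must have length k_pops")
  }
  if (abs(sum(pop_size_weights) - 1) > 1e-8 || any(pop_size_weights < 0)) {
    stop("pop_size_weights must be non-negative and sum to 1")
  }
  if (!is.null(outgroup_index)) {
    stopifnot_scalar(outgroup_index, "outgroup_index", 1, k_pops)
  }
  structure(
    list(
      n_samples = as.integer(n_samples), n_markers = as.integer(n_markers),
      k_pops = as.integer(k_pops),
      fst_like_divergence = fst_like_divergence,
      outgroup_index = outgroup_index,
      admixture_concentration = admixture_concentration,
      pop_size_weights = pop_size_weights,
      missing_rate = missing_rate, het_rate = het_rate,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate an admixed inbred genotype panel
#'
#' Ancestral allele frequencies are drawn per population from a
#' Balding-Nichols beta distribution around a shared base frequency, with F
#' set by `fst_like_divergence` (tripled for the outgroup). Each sample
#' draws a primary cluster from `pop_size_weights` and an admixture row from
#' a Dirichlet whose concentration on the primary cluster is boosted by 1.
#' Dosages are sampled as fully homozygous draws from the admixture-mixed
#' allele frequency, with `het_rate` of observed calls flipped to
#' heterozygous and `missing_rate` of calls masked.
#'
#' @param config A [sim_config()].
#' @return A list with `genotypes` (a [genotype_matrix()]) and
#'   `true_admixture` (n x k matrix of ground-truth ancestry proportions,
#'   rows on the simplex).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  m <- config$n_markers
  k <- config$k_pops
  with_seed(config$seed, {
    base_p <- stats::runif(m, 0.1, 0.9)
    Fvec <- rep(config$fst_like_divergence, k)
    if (!is.null(config$outgroup_index)) {
      Fvec[config$outgroup_index] <- min(0.9, 3 * config$fst_like_divergence)
    }
    pop_freq <- matrix(0, k, m)
    for (j in seq_len(k)) {
      Fj <- Fvec[j]
      a <- base_p * (1 - Fj) / Fj
      b <- (1 - base_p) * (1 - Fj) / Fj
      pop_freq[j, ] <- clip(stats::rbeta(m, a, b), 0.01, 0.99)
    }
    primary <- sample.int(k, n, replace = TRUE, prob = config$pop_size_weights)
    alpha0 <- config$admixture_concentration
    Q <- matrix(stats::rgamma(n * k,
      shape = alpha0 + outer(primary, seq_len(k), `==`)
    ), n, k)
    Q <- Q / rowSums(Q)
    ind_freq <- Q %*% pop_freq
    dosage <- matrix(2 * stats::rbinom(n * m, 1L, ind_freq), n, m)
    if (config$het_rate > 0) {
      het <- matrix(stats::runif(n * m) < config$het_rate, n, m)
      dosage[het] <- 1
    }
    if (config$missing_rate > 0) {
      miss <- matrix(stats::runif(n * m) < config$missing_rate, n, m)
      dosage[miss] <- NA
    }
    g <- genotype_matrix(
      dosage,
      sample_ids = sprintf("S%04d", seq_len(n)),
      marker_ids = sprintf("M%05d", seq_len(m))
    )
    rownames(Q) <- g$sample_ids
    list(genotypes = g, true_admixture = Q,
         ancestral_freqs = pop_freq, primary_pop = primary)
  })
}

#' Trait architecture for the phenotype generator
#'
#' @param n_additive_qtl Number of markers carrying general additive effects.
#' @param n_epistatic_pairs Number of marker pairs carrying
#'   additive-by-additive effects (products of centered dosages).
#' @param subpop_effect_sd Standard deviation of subpopulation-specific
#'   additive deviations per QTL marker, relative to the unit standard
#'   deviation of general additive effects; 0 disables the component.
#' @param n_major_qtl Number of major QTL.
#' @param major_qtl_variance_share Share of phenotypic variance assigned to
#'   the major QTL jointly, in \[0, 1); must not exceed `heritability`.
#' @param heritability Target heritability in (0, 1].
#' @param phenotyped_fraction Fraction of samples receiving a BLUE, in
#'   (0, 1].
#' @param hard_labels If TRUE, subpopulation-specific effects enter via the
#'   hard cluster assignment (argmax of the admixture row) instead of being
#'   admixture-weighted.
#' @param stratified_missing Optional length-k vector of per-cluster
#'   phenotyped fractions, reproducing unbalanced training sets; overrides
#'   `phenotyped_fraction` when given.
#' @param seed Integer seed.
#' @return A list of class `trait_architecture`.
#' @export
trait_architecture <- function(n_additive_qtl = 50L, n_epistatic_pairs = 0L,
                               subpop_effect_sd = 0, n_major_qtl = 0L,
                               major_qtl_variance_share = 0,
                               heritability = 0.8, phenotyped_fraction = 1,
                               hard_labels = FALSE,
                               stratified_missing = NULL, seed = 1L) {
  stopifnot_scalar(n_additive_qtl, "n_additive_qtl", 0)
  stopifnot_scalar(n_epistatic_pairs, "n_epistatic_pairs", 0)
  stopifnot_scalar(subpop_effect_sd, "subpop_effect_sd", 0)
  stopifnot_scalar(n_major_qtl, "n_major_qtl", 0)
  stopifnot_scalar(major_qtl_variance_share, "major_qtl_variance_share", 0, 1,
                   strict_upper = TRUE)
  if (heritability == 0) stop("heritability = 0 is rejected: the trait would be pure noise")
  stopifnot_scalar(heritability, "heritability", 0, 1, strict_lower = TRUE)
  stopifnot_scalar(phenotyped_fraction, "phenotyped_fraction", 0, 1,
                   strict_lower = TRUE)
  if (major_qtl_variance_share > heritability) {
    stop("major_qtl_variance_share cannot exceed heritability")
  }
  structure(
    list(
      n_additive_qtl = as.integer(n_additive_qtl),
      n_epistatic_pairs = as.integer(n_epistatic_pairs),
      subpop_effect_sd = subpop_effect_sd,
      n_major_qtl = as.integer(n_major_qtl),
      major_qtl_variance_share = major_qtl_variance_share,
      heritability = heritability,
      phenotyped_fraction = phenotyped_fraction,
      hard_labels = isTRUE(hard_labels),
      stratified_missing = stratified_missing,
      seed = as.integer(seed)
    ),
    class = "trait_architecture"
  )
}

#' Simulate a trait with known genetic architecture
#'
#' The phenotype is built as mean + general additive effects +
#' admixture-weighted (or hard-label) subpopulation-specific additive
#' deviations + additive-by-additive epistatic products + Gaussian noise.
#' Genetic components are rescaled so that, empirically, the major QTL
#' jointly explain `major_qtl_variance_share` of the phenotypic variance,
#' the remaining genetic components explain `heritability -
#' major_qtl_variance_share`, and noise explains `1 - heritability` (on a
#' phenotypic variance standardized to 1). Exactly
#' `ceiling(phenotyped_fraction * n)` samples carry a BLUE.
#'
#' @param genotypes A [genotype_matrix()] (missing calls are treated as the
#'   dominant-allele homozygote for trait construction).
#' @param admixture n x k matrix of admixture coefficients (rows on the
#'   simplex), typically the truth from [simulate_genotypes()].
#' @param arch A [trait_architecture()].
#' @param trait_name Trait label used in the BLUE table.
#' @return A list with `blues` (data.frame `sample_id`, `trait`, `value`,
#'   one row per phenotyped sample) and `truth` (class `synthetic_truth`:
#'   general effects, subpopulation effects, epistatic pairs, true genetic
#'   values, the admixture used, and the realized heritability).
#' @export
simulate_trait <- function(genotypes, admixture, arch,
                           trait_name = "trait") {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(arch, "trait_architecture"))
  d <- genotypes$dosage
  n <- nrow(d)
  m <- ncol(d)
  admixture <- as.matrix(admixture)
  if (nrow(admixture) != n) stop("admixture rows must match samples")
  k <- ncol(admixture)
  if (arch$n_additive_qtl > m || arch$n_major_qtl > m) {
    stop("QTL counts cannot exceed n_markers")
  }
  # Missing calls enter the generative model as the dominant-allele
  # homozygote so truth is defined for every sample.
  if (anyNA(d)) {
    p_obs <- colMeans(d, na.rm = TRUE) / 2
    fill <- ifelse(p_obs > 0.5, 2, 0)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- fill[idx[, 2L]]
  }
  p <- colMeans(d) / 2
  Z <- sweep(d, 2L, 2 * p)

  with_seed(arch$seed, {
    g_other <- numeric(n)
    general <- numeric(m)
    subpop <- matrix(0, k, m)
    epi <- list()

    if (arch$n_additive_qtl > 0) {
      qtl <- sample.int(m, arch$n_additive_qtl)
      general[qtl] <- stats::rnorm(arch$n_additive_qtl)
      g_other <- g_other + Z %*% general
      if (arch$subpop_effect_sd > 0 && k > 1) {
        W <- if (arch$hard_labels) {
          lab <- max.col(admixture, ties.method = "first")
          outer(lab, seq_len(k), `==`) * 1
        } else {
          admixture
        }
        for (j in seq_len(k)) {
          subpop[j, qtl] <- stats::rnorm(arch$n_additive_qtl,
                                         sd = arch$subpop_effect_sd)
          g_other <- g_other + W[, j] * (Z %*% subpop[j, ])
        }
      }
    }
    if (arch$n_epistatic_pairs > 0) {
      pairs <- matrix(sample.int(m, 2L * arch$n_epistatic_pairs, replace = FALSE),
                      ncol = 2L)
      eff <- stats::rnorm(arch$n_epistatic_pairs)
      epi <- data.frame(marker_i = genotypes$marker_ids[pairs[, 1L]],
                        marker_j = genotypes$marker_ids[pairs[, 2L]],
                        effect = eff)
      g_other <- g_other + (Z[, pairs[, 1L], drop = FALSE] *
                              Z[, pairs[, 2L], drop = FALSE]) %*% eff
    } else {
      epi <- data.frame(marker_i = character(0), marker_j = character(0),
                        effect = numeric(0))
    }

    g_major <- numeric(n)
    major_ids <- character(0)
    major_eff <- numeric(0)
    if (arch$n_major_qtl > 0) {
      avail <- setdiff(seq_len(m), which(general != 0))
      mq <- sample(avail, arch$n_major_qtl)
      major_ids <- genotypes$marker_ids[mq]
      major_eff <- stats::rnorm(arch$n_major_qtl)
      g_major <- Z[, mq, drop = FALSE] %*% major_eff
    }

    # Rescale components to target shares on a unit phenotypic variance,
    # and scale the stored effects identically so truth matches realization.
    other_share <- arch$heritability - arch$major_qtl_variance_share
    g_other <- drop(g_other)
    g_major <- drop(g_major)
    v_other <- stats::var(g_other)
    c_other <- if (v_other > .Machine$double.eps && other_share > 0) {
      sqrt(other_share / v_other)
    } else 0
    v_major <- stats::var(g_major)
    c_major <- if (v_major > .Machine$double.eps &&
                   arch$major_qtl_variance_share > 0) {
      sqrt(arch$major_qtl_variance_share / v_major)
    } else 0
    g_other <- c_other * g_other
    g_major <- c_major * g_major
    general <- c_other * general
    subpop <- c_other * subpop
    epi$effect <- c_other * epi$effect
    major_eff <- c_major * major_eff
    genetic <- g_other + g_major
    if (other_share > 0 && c_other == 0 && c_major == 0) {
      warning("no genetic component realized; trait is pure noise")
    }
    noise <- stats::rnorm(n, sd = sqrt(1 - arch$heritability))
    y <- 10 + genetic + noise
    realized_h2 <- stats::var(genetic) / stats::var(y)

    pheno_idx <- if (!is.null(arch$stratified_missing)) {
      lab <- max.col(admixture, ties.method = "first")
      frac <- arch$stratified_missing
      if (length(frac) != k) stop("stratified_missing must have length k")
      unlist(lapply(seq_len(k), function(j) {
        members <- which(lab == j)
        if (!length(members)) return(integer(0))
        sample(members, ceiling(frac[j] * length(members)))
      }))
    } else {
      sample.int(n, ceiling(arch$phenotyped_fraction * n))
    }
    pheno_idx <- sort(pheno_idx)

    truth <- structure(
      list(
        general_effects = stats::setNames(general, genotypes$marker_ids),
        subpop_effects = subpop,
        epistatic_pairs = epi,
        major_qtl = data.frame(marker_id = major_ids, effect = major_eff),
        true_genetic_values = stats::setNames(genetic, genotypes$sample_ids),
        true_admixture = admixture,
        realized_h2 = realized_h2
      ),
      class = "synthetic_truth"
    )
    blues <- data.frame(
      sample_id = genotypes$sample_ids[pheno_idx],
      trait = trait_name,
      value = y[pheno_idx],
      stringsAsFactors = FALSE
    )
    list(blues = blues, truth = truth, phenotype_all = stats::setNames(y, genotypes$sample_ids))
  })
}

#' Write a simulated dataset to plain-text files
#'
#' Genotypes go out as both a TSV dosage table and a minimal VCF, BLUEs as a
#' CSV (`sample_id`, `trait`, `value`), and the ground truth as a JSON
#' sidecar.
#'
#' @param sim Output of [simulate_genotypes()].
#' @param trait Output of [simulate_trait()] (optional).
#' @param dir Output directory, created if needed.
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(sim, trait = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(sim$genotypes, file.path(dir, "genotypes.tsv"), "tsv")
  write_genotypes(sim$genotypes, file.path(dir, "genotypes.vcf"), "vcf")
  utils::write.csv(
    data.frame(sample_id = rownames(sim$true_admixture),
               sim$true_admixture, check.names = FALSE),
    file.path(dir, "true_admixture.csv"), row.names = FALSE
  )
  if (!is.null(trait)) {
    utils::write.csv(trait$blues, file.path(dir, "blues.csv"), row.names = FALSE)
    truth <- trait$truth
    jsonlite::write_json(
      list(
        general_effects = as.list(truth$general_effects[truth$general_effects != 0]),
        epistatic_pairs = truth$epistatic_pairs,
        major_qtl = truth$major_qtl,
        true_genetic_values = as.list(truth$true_genetic_values),
        realized_h2 = truth$realized_h2
      ),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
    )
  }
  invisible(dir)
}
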