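# Synthetic genotype and trait generators.

test_that("single population, fully inbred: ancestry all 1 and dosages in {0,2}", {
  sim <- simulate_genotypes(sim_config(4, 10, k_pops = 1,
                                       missing_rate = 0, het_rate = 0,
                                       seed = 1))
  expect_true(all(sim$true_admixture == 1))
  expect_true(all(sim$genotypes$dosage %in% c(0, 2)))
})

test_that("degenerate Dirichlet concentration puts ancestry rows at simplex vertices", {
  sim <- simulate_genotypes(sim_config(50, 30, k_pops = 3,
                                       admixture_concentration = 1e-4,
                                       missing_rate = 0, het_rate = 0,
                                       seed = 2))
  expect_true(all(apply(sim$true_admixture, 1L, max) > 0.99))
  expect_equal(unname(rowSums(sim$true_admixture)), rep(1, 50))
})

test_that("heterozygote and missing fractions track their configured rates", {
  sim <- simulate_genotypes(sim_config(400, 500, k_pops = 2,
                                       missing_rate = 0.05, het_rate = 0.02,
                                       seed = 3))
  d <- sim$genotypes$dosage
  expect_equal(mean(is.na(d)), 0.05, tolerance = 0.05)
  expect_equal(mean(d == 1, na.rm = TRUE), 0.02, tolerance = 0.05)
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(30, 40, k_pops = 2, missing_rate = 0.02, het_rate = 0.01,
                    seed = 11)
  s1 <- simulate_genotypes(cfg)
  s2 <- simulate_genotypes(cfg)
  expect_identical(s1$genotypes$dosage, s2$genotypes$dosage)
  expect_identical(s1$true_admixture, s2$true_admixture)
  arch <- trait_architecture(n_additive_qtl = 10, heritability = 0.8, seed = 12)
  t1 <- simulate_trait(s1$genotypes, s1$true_admixture, arch)
  t2 <- simulate_trait(s1$genotypes, s1$true_admixture, arch)
  expect_identical(t1$blues, t2$blues)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(10, 2, k_pops = 3), "unidentifiable")
  expect_error(sim_config(10, 10, pop_size_weights = c(0.5, 0.6), k_pops = 2),
               "sum to 1")
  expect_error(trait_architecture(heritability = 0), "heritability = 0")
  expect_error(trait_architecture(heritability = 0.4,
                                  n_major_qtl = 1,
                                  major_qtl_variance_share = 0.5),
               "cannot exceed")
})

test_that("h2 = 1 without noise components gives a perfect genetic correlation", {
  sim <- two_pop_panel()
  tr <- simulate_trait(sim$genotypes, sim$true_admixture,
                       trait_architecture(n_additive_qtl = 30,
                                          n_epistatic_pairs = 0,
                                          subpop_effect_sd = 0,
                                          heritability = 1, seed = 4))
  y <- tr$phenotype_all
  expect_equal(cor(y, tr$truth$true_genetic_values), 1, tolerance = 1e-12)
  expect_equal(tr$truth$realized_h2, 1, tolerance = 1e-12)
})

test_that("a lone major QTL at 50% share is recovered by single-marker regression", {
  sim <- two_pop_panel()
  tr <- simulate_trait(sim$genotypes, sim$true_admixture,
                       trait_architecture(n_additive_qtl = 0, n_major_qtl = 1,
                                          major_qtl_variance_share = 0.5,
                                          heritability = 0.5, seed = 5))
  y <- tr$phenotype_all
  z <- sim$genotypes$dosage[, tr$truth$major_qtl$marker_id]
  r2 <- summary(lm(y ~ z))$r.squared
  expect_equal(r2, 0.5, tolerance = 0.1)
})

test_that("phenotyped_fraction yields exactly ceiling(fraction * n) BLUEs", {
  sim <- simulate_genotypes(sim_config(33, 50, k_pops = 2, missing_rate = 0,
                                       het_rate = 0, seed = 6))
  tr <- simulate_trait(sim$genotypes, sim$true_admixture,
                       trait_architecture(n_additive_qtl = 10,
                                          phenotyped_fraction = 0.7, seed = 7))
  expect_equal(nrow(tr$blues), ceiling(0.7 * 33))
  expect_false(anyDuplicated(tr$blues$sample_id) > 0)
})

test_that("stratified phenotyping controls the per-cluster fractions", {
  sim <- two_pop_panel()
  tr <- simulate_trait(sim$genotypes, sim$true_admixture,
                       trait_architecture(n_additive_qtl = 10,
                                          stratified_missing = c(0.9, 0.2),
                                          seed = 8))
  lab <- max.col(sim$true_admixture, ties.method = "first")
  names(lab) <- sim$genotypes$sample_ids
  pheno_lab <- lab[tr$blues$sample_id]
  expect_equal(sum(pheno_lab == 1), ceiling(0.9 * sum(lab == 1)))
  expect_equal(sum(pheno_lab == 2), ceiling(0.2 * sum(lab == 2)))
})

test_that("between-cluster differentiation grows with the divergence parameter", {
  # Under the Balding-Nichols draw the expected between-cluster distance is
  # 2 p0 (1 - p0) regardless of F; the monotone quantity is the
  # between-minus-within contrast, 2 F p0 (1 - p0).
  contrast_at <- function(div) {
    sim <- simulate_genotypes(sim_config(
      80, 300, k_pops = 2, fst_like_divergence = div,
      admixture_concentration = 0.05, pop_size_weights = c(0.5, 0.5),
      missing_rate = 0, het_rate = 0, seed = 9
    ))
    d <- rogers_distance(sim$genotypes)
    lab <- max.col(sim$true_admixture, ties.method = "first")
    between <- mean(d$values[lab == 1, lab == 2])
    within <- mean(vapply(1:2, function(j) {
      v <- d$values[lab == j, lab == j]
      mean(v[upper.tri(v)])
    }, 0))
    between - within
  }
  contrasts <- vapply(c(0.05, 0.15, 0.35), contrast_at, 0)
  expect_true(all(diff(contrasts) > 0))
})

test_that("realized heritability is within 0.05 of its target at n = 500", {
  sim <- simulate_genotypes(sim_config(500, 400, k_pops = 2, missing_rate = 0,
                                       het_rate = 0, seed = 10))
  tr <- simulate_trait(sim$genotypes, sim$true_admixture,
                       trait_architecture(n_additive_qtl = 50,
                                          heritability = 0.7, seed = 11))
  y <- tr$phenotype_all
  expect_equal(var(tr$truth$true_genetic_values) / var(y), 0.7,
               tolerance = 0.05)
  expect_equal(tr$truth$realized_h2, 0.7, tolerance = 0.05)
})

test_that("the outgroup population is more distant than within-cluster spread", {
  sim <- simulate_genotypes(sim_config(
    500, 2000, k_pops = 5, fst_like_divergence = 0.15, outgroup_index = 5,
    admixture_concentration = 0.05, missing_rate = 0, het_rate = 0, seed = 7
  ))
  d <- rogers_distance(sim$genotypes)
  lab <- max.col(sim$true_admixture, ties.method = "first")
  out_mask <- lab == 5
  between_out <- mean(d$values[out_mask, !out_mask])
  within <- mean(vapply(1:5, function(j) {
    v <- d$values[lab == j, lab == j]
    mean(v[upper.tri(v)])
  }, 0), na.rm = TRUE)
  expect_gt(between_out, within)
})

test_that("write_simulation emits parseable files with matching content", {
  dir <- withr::local_tempdir()
  sim <- simulate_genotypes(sim_config(10, 15, k_pops = 2, missing_rate = 0.05,
                                       het_rate = 0, seed = 13))
  tr <- simulate_trait(sim$genotypes, sim$true_admixture,
                       trait_architecture(n_additive_qtl = 5, seed = 14))
  write_simulation(sim, tr, dir)
  g_tsv <- read_genotypes(file.path(dir, "genotypes.tsv"), "tsv")
  g_vcf <- read_genotypes(file.path(dir, "genotypes.vcf"), "vcf")
  expect_equal(g_tsv$dosage, sim$genotypes$dosage)
  expect_equal(g_vcf$dosage, sim$genotypes$dosage)
  blues <- read.csv(file.path(dir, "blues.csv"))
  expect_equal(blues$value, tr$blues$value)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$realized_h2, tr$truth$realized_h2, tolerance = 1e-9)
})
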