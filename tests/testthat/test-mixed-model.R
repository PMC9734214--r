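# REML fitters: single-kernel, multi-kernel, ridge families, W-BLUP.

test_that("pure-noise traits shrink test predictions to the mean", {
  tk <- toy_kernel_panel(n = 60L, m = 80L, seed = 31L)
  y <- with_test_seed(32, stats::setNames(rnorm(60), tk$g$sample_ids))
  fit <- fit_gblup(y, tk$G, tk$g$sample_ids[1:45], tk$g$sample_ids[46:60])
  mu <- fit$fixed_effects[["mu"]]
  expect_lt(max(abs(fit$predicted_test - mu)),
            0.25 * sd(y[1:45]))
})

test_that("fixed-variance-component predictions match the Henderson MME oracle", {
  tk <- toy_kernel_panel()
  ids <- tk$g$sample_ids
  train <- ids[1:7]
  test <- ids[8:10]
  sigma2 <- c(g = 0.6, resid = 0.4)
  impl <- predict_fixed_vc(tk$y, list(g = tk$G), sigma2, train, test)
  oracle <- mme_oracle(tk$y, list(g = tk$G), sigma2, train, test)
  expect_equal(impl$predicted_test, oracle$predicted, tolerance = 1e-8)
  # two-kernel version
  sigma2b <- c(g = 0.5, g1 = 0.3, resid = 0.4)
  impl2 <- predict_fixed_vc(tk$y, list(g = tk$G, g1 = tk$H), sigma2b, train, test)
  oracle2 <- mme_oracle(tk$y, list(g = tk$G, g1 = tk$H), sigma2b, train, test)
  expect_equal(impl2$predicted_test, oracle2$predicted, tolerance = 1e-8)
})

test_that("REML is invariant to phenotype shifts and equivariant to scaling", {
  tk <- toy_kernel_panel(n = 40L, m = 80L, seed = 33L)
  ids <- tk$g$sample_ids
  y <- with_test_seed(34, stats::setNames(
    drop(10 + t(chol(tk$G)) %*% rnorm(40) + rnorm(40, sd = 0.7)), ids
  ))
  base <- fit_gblup(y, tk$G, ids)
  shifted <- fit_gblup(y + 100, tk$G, ids)
  expect_equal(shifted$variance_components, base$variance_components,
               tolerance = 1e-5)
  expect_equal(shifted$fixed_effects[["mu"]], base$fixed_effects[["mu"]] + 100,
               tolerance = 1e-5)
  scaled <- fit_gblup(3 * y, tk$G, ids)
  expect_equal(scaled$variance_components, 9 * base$variance_components,
               tolerance = 1e-4)
})

test_that("duplicated kernels split variance but keep the total and predictions", {
  tk <- toy_kernel_panel(n = 60L, m = 120L, seed = 35L)
  ids <- tk$g$sample_ids
  y <- with_test_seed(36, stats::setNames(
    drop(5 + t(chol(tk$G)) %*% rnorm(60) * 0.8 + rnorm(60, sd = 0.5)), ids
  ))
  train <- ids[1:48]
  test <- ids[49:60]
  single <- fit_gblup(y, tk$G, train, test)
  dup <- suppressMessages(
    fit_multikernel(y, list(a = tk$G, b = tk$G), train, test)
  )
  expect_equal(sum(dup$variance_components[c("a", "b")]),
               single$variance_components[["g"]], tolerance = 1e-3)
  expect_equal(dup$predicted_test, single$predicted_test, tolerance = 1e-4)
})

test_that("EG-BLUP attributes little variance to H on purely additive traits", {
  shares <- vapply(1:5, function(s) {
    sim <- simulate_genotypes(sim_config(150, 400, k_pops = 2,
                                         missing_rate = 0, het_rate = 0,
                                         seed = 40 + s))
    tr <- simulate_trait(sim$genotypes, sim$true_admixture,
                         trait_architecture(n_additive_qtl = 60,
                                            heritability = 0.8,
                                            seed = 50 + s))
    y <- stats::setNames(tr$blues$value, tr$blues$sample_id)
    G <- suppressWarnings(vanraden_g(sim$genotypes))
    fit <- suppressMessages(
      fit_multikernel(y, list(g = G, g1 = epistatic_h(G)), names(y))
    )
    vc <- fit$variance_components
    vc[["g1"]] / (vc[["g"]] + vc[["g1"]])
  }, 0)
  expect_lt(median(shares), 0.2)
})

test_that("GSA-RRBLUP drops subpopulations absent from the training set", {
  sim <- two_pop_panel()
  g <- sim$genotypes
  lab <- max.col(sim$true_admixture, ties.method = "first")
  names(lab) <- g$sample_ids
  adm <- list(Q = sim$true_admixture, labels = lab)
  des <- build_design(g, adm, mode = "hard")
  tr <- simulate_trait(g, sim$true_admixture,
                       trait_architecture(n_additive_qtl = 30, seed = 60))
  y <- stats::setNames(tr$blues$value, tr$blues$sample_id)
  train <- names(lab)[lab == 1][1:60]   # cluster 2 unseen in training
  test <- names(lab)[lab == 2][1:10]
  expect_warning(
    fit <- suppressMessages(fit_rr_family(y, des, train, test)),
    "no training signal"
  )
  expect_length(fit$predicted_test, 10L)
})

test_that("marker-effect BLUPs reproduce the kernel-space predictions", {
  sim <- two_pop_panel()
  g <- sim$genotypes
  adm <- list(Q = sim$true_admixture,
              labels = stats::setNames(
                max.col(sim$true_admixture, ties.method = "first"),
                g$sample_ids
              ))
  des <- build_design(g, adm, mode = "admixed")
  tr <- simulate_trait(g, sim$true_admixture,
                       trait_architecture(n_additive_qtl = 30,
                                          subpop_effect_sd = 1, seed = 61))
  y <- stats::setNames(tr$blues$value, tr$blues$sample_id)
  ids <- g$sample_ids
  train <- ids[1:160]
  test <- ids[161:200]
  fit <- suppressMessages(
    fit_rr_family(y, des, train, test, marker_effects = TRUE)
  )
  # rebuilding predictions from marker effects must match the kernel route
  pred <- fit$fixed_effects[["mu"]] +
    drop(des$Z_A[test, , drop = FALSE] %*% fit$marker_effects$A) +
    Reduce(`+`, lapply(1:2, function(j) {
      drop(des$Z_S[[j]][test, , drop = FALSE] %*%
             fit$marker_effects[[paste0("S", j)]])
    }))
  expect_equal(unname(fit$predicted_test), unname(pred), tolerance = 1e-6)
})

test_that("W-BLUP recovers a planted major-QTL effect and validates inputs", {
  sim <- simulate_genotypes(sim_config(400, 600, k_pops = 2, missing_rate = 0,
                                       het_rate = 0, seed = 62))
  g <- sim$genotypes
  tr <- simulate_trait(g, sim$true_admixture,
                       trait_architecture(n_additive_qtl = 30, n_major_qtl = 1,
                                          major_qtl_variance_share = 0.5,
                                          heritability = 0.8, seed = 63))
  y <- stats::setNames(tr$blues$value, tr$blues$sample_id)
  qtl <- tr$truth$major_qtl$marker_id
  G_r <- suppressWarnings(vanraden_g(drop_markers(g, qtl)))
  F_G <- allele_content(g, qtl)
  fit <- fit_wblup(y, G_r, F_G, names(y)[1:320], names(y)[321:400])
  a_hat <- fit$fixed_effects[[qtl]]
  a_true <- tr$truth$major_qtl$effect
  expect_equal(sign(a_hat), sign(a_true))
  expect_lt(abs(a_hat - a_true) / abs(a_true), 0.25)
  # constant fixed column is collinear with the intercept
  Fc <- cbind(F_G, const = 2)
  expect_warning(fit_wblup(y, G_r, Fc, names(y)[1:320]), "collinear")
  expect_error(fit_wblup(y, G_r, F_G[, 0], names(y)[1:320]), "fall back")
})

test_that("masking integrity: test-set phenotypes never influence predictions", {
  tk <- toy_kernel_panel(n = 50L, m = 100L, seed = 64L)
  ids <- tk$g$sample_ids
  y <- with_test_seed(65, stats::setNames(
    drop(t(chol(tk$G)) %*% rnorm(50) + rnorm(50, sd = 0.5)), ids
  ))
  train <- ids[1:40]
  test <- ids[41:50]
  y_corrupt <- y
  y_corrupt[test] <- with_test_seed(66, rnorm(10, mean = 50))
  for (fitter in list(
    function(yy) fit_gblup(yy, tk$G, train, test),
    function(yy) suppressMessages(
      fit_multikernel(yy, list(g = tk$G, g1 = tk$H), train, test)
    )
  )) {
    expect_identical(fitter(y)$predicted_test, fitter(y_corrupt)$predicted_test)
  }
})
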