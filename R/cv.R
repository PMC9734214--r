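# Repeated fivefold cross-validation protocol and prediction-ability
# computation.
#
# Per repeat, the phenotyped samples are partitioned into five parts of
# sizes differing by at most one (per stratum when stratified). Each part is
# predicted from the remaining four; the five predicted vectors are
# concatenated and correlated with the observed BLUEs, so the prediction
# ability is one Pearson correlation per repeat, not a per-fold average.
# The same plan is reused across all models of a trait.

#' Build a cross-validation plan
#'
#' Deterministic under `seed`: repeat r draws its fold assignment from a
#' seed derived from (`seed`, r) by a fixed counter scheme, so plans are
#' reproducible and identical across models. Stratified mode partitions
#' within each label into equal fifths and merges fold-wise, minimizing
#' sampling bias between subpopulations.
#'
#' @param sample_ids IDs of the phenotyped samples entering CV.
#' @param n_folds Number of folds (default 5).
#' @param n_repeats Number of independent repetitions (default 100).
#' @param stratify_labels Optional labels (named or positional) to stratify
#'   by; every stratum must hold at least `n_folds` samples.
#' @param seed Master seed.
#' @return A `cv_plan`: list of per-repeat named fold-index vectors.
#' @export
make_cv_plan <- function(sample_ids, n_folds = 5L, n_repeats = 100L,
                         stratify_labels = NULL, seed = 1L) {
  sample_ids <- as.character(sample_ids)
  n <- length(sample_ids)
  if (n < n_folds) stop("fewer samples than folds")
  if (!is.null(stratify_labels)) {
    if (!is.null(names(stratify_labels))) {
      stratify_labels <- stratify_labels[sample_ids]
    }
    if (length(stratify_labels) != n) stop("stratify_labels must cover sample_ids")
    sizes <- table(stratify_labels)
    small <- names(sizes)[sizes < n_folds]
    if (length(small)) {
      stop("stratum smaller than n_folds: ", paste(small, collapse = ", "))
    }
  }
  assign_one <- function(ids) {
    k <- length(ids)
    folds <- rep(seq_len(n_folds), length.out = k)
    stats::setNames(folds, sample(ids))
  }
  assignments <- lapply(seq_len(n_repeats), function(r) {
    with_seed(derive_seed(seed, r), {
      a <- if (is.null(stratify_labels)) {
        assign_one(sample_ids)
      } else {
        do.call(c, unname(lapply(split(sample_ids, stratify_labels),
                                 assign_one)))
      }
      a[sample_ids]  # canonical order
    })
  })
  structure(
    list(assignments = assignments, sample_ids = sample_ids,
         n_folds = as.integer(n_folds), n_repeats = as.integer(n_repeats),
         stratified = !is.null(stratify_labels), seed = as.integer(seed)),
    class = "cv_plan"
  )
}

#' Prediction ability
#'
#' Pearson correlation between observed BLUEs and predictions. A constant
#' prediction (or observation) vector has an undefined correlation and is
#' reported as NA with a warning, never as 0.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return Correlation in \[-1, 1\], or NA.
#' @export
prediction_ability <- function(observed, predicted) {
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
    warning("constant predictions or observations: ability undefined, returning NA")
    return(NA_real_)
  }
  stats::cor(observed, predicted)
}

# Prepare the panel-wide fitting context shared by all folds of one run.
build_cv_context <- function(specs, genotypes, G, H, K_A, admixture, alpha) {
  need <- function(fam) any(vapply(specs, function(s) s$family == fam, TRUE))
  if (is.null(G) && (need("GBLUP") || need("EGBLUP") || need("WBLUP"))) {
    if (is.null(genotypes)) stop("need genotypes or G")
    G <- vanraden_g(genotypes)
  }
  if (is.null(H) && need("EGBLUP")) H <- epistatic_h(G)
  if (is.null(K_A) && need("RRBLUP")) {
    d <- genotypes$dosage
    p <- colMeans(d) / 2
    Z <- sweep(d, 2L, 2 * p)
    K_A <- tcrossprod(Z)
    dimnames(K_A) <- list(genotypes$sample_ids, genotypes$sample_ids)
  }
  designs <- list()
  for (s in specs) {
    if (s$family == "GSA_RRBLUP") {
      key <- paste0(s$k, if (s$admixed) "adm" else "hard")
      if (is.null(designs[[key]])) {
        if (is.null(admixture)) stop("GSA_RRBLUP requires an admixture result")
        designs[[key]] <- build_design(
          genotypes, admixture, mode = if (s$admixed) "admixed" else "hard",
          k = s$k
        )
      }
    }
  }
  list(genotypes = genotypes, G = G, H = H, K_A = K_A, designs = designs,
       alpha = alpha)
}

#' Run the cross-validation comparison
#'
#' For every repeat of the plan and every model: fit on the four training
#' parts (for W-BLUP the association scan and marker selection are re-run
#' inside each training fold; admixture-derived designs are fixed
#' panel-wide since they use no phenotypic data), predict the held-out
#' part, concatenate the five test predictions and correlate them with the
#' observed BLUEs. A W-BLUP model whose marker-set precondition fails in
#' any fold is marked infeasible for the trait.
#'
#' @param plan A [make_cv_plan()].
#' @param specs List of [model_spec()]s (possibly named).
#' @param y Named numeric vector of BLUEs covering the plan's samples.
#' @param genotypes A QC'd [genotype_matrix()] (needed by marker-based
#'   models; optional when precomputed kernels are supplied).
#' @param G,H,K_A Optional precomputed kernels (additive, epistatic,
#'   unnormalized ridge kernel).
#' @param admixture Optional `admixture_result` for GSA-RRBLUP designs.
#' @param labels Optional subpopulation labels; when given, per-subpopulation
#'   abilities (the concatenated predictions restricted to each label) are
#'   reported alongside the combined ability.
#' @param alpha GWAS significance level for W-BLUP.
#' @return A `cv_report`: data.frame `model`, `rep`, `scope`, `ability`,
#'   with a `feasible` attribute per model.
#' @export
run_cv <- function(plan, specs, y, genotypes = NULL, G = NULL, H = NULL,
                   K_A = NULL, admixture = NULL, labels = NULL,
                   alpha = 0.05) {
  stopifnot(inherits(plan, "cv_plan"))
  if (inherits(specs, "model_spec")) specs <- list(specs)
  ids <- plan$sample_ids
  if (anyNA(y[ids])) stop("every sample in the plan needs a BLUE")
  ctx <- build_cv_context(specs, genotypes, G, H, K_A, admixture, alpha)
  model_labels <- vapply(specs, `[[`, "", "label")
  feasible <- stats::setNames(rep(TRUE, length(specs)), model_labels)
  if (!is.null(labels) && !is.null(names(labels))) labels <- labels[ids]
  rows <- list()
  for (r in seq_len(plan$n_repeats)) {
    folds <- plan$assignments[[r]]
    for (si in seq_along(specs)) {
      spec <- specs[[si]]
      if (!feasible[[spec$label]]) next
      preds <- rep(NA_real_, length(ids))
      names(preds) <- ids
      ok <- TRUE
      for (f in seq_len(plan$n_folds)) {
        test_ids <- ids[folds == f]
        train_ids <- ids[folds != f]
        fit <- fit_model(spec, y, train_ids, test_ids, ctx)
        if (isTRUE(fit$infeasible)) {
          feasible[[spec$label]] <- FALSE
          ok <- FALSE
          break
        }
        preds[test_ids] <- fit$predicted_test[test_ids]
      }
      if (!ok) next
      rows[[length(rows) + 1L]] <- data.frame(
        model = spec$label, rep = r, scope = "combined",
        ability = prediction_ability(y[ids], preds)
      )
      if (!is.null(labels)) {
        for (lab in sort(unique(labels))) {
          sel <- labels == lab
          rows[[length(rows) + 1L]] <- data.frame(
            model = spec$label, rep = r, scope = as.character(lab),
            ability = prediction_ability(y[ids][sel], preds[sel])
          )
        }
      }
    }
  }
  report <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(model = character(0), rep = integer(0), scope = character(0),
               ability = numeric(0))
  }
  attr(report, "feasible") <- feasible
  class(report) <- c("cv_report", class(report))
  report
}

#' Summarize a CV report
#'
#' Mean and standard deviation of the prediction ability per model and
#' scope across repeats.
#'
#' @param report A `cv_report`.
#' @return A data.frame `model`, `scope`, `mean_ability`, `sd_ability`,
#'   `n_reps`.
#' @export
cv_summary <- function(report) {
  agg <- stats::aggregate(ability ~ model + scope, data = report,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                                              n = length(v)))
  out <- data.frame(
    model = agg$model, scope = agg$scope,
    mean_ability = agg$ability[, "mean"],
    sd_ability = agg$ability[, "sd"],
    n_reps = as.integer(agg$ability[, "n"])
  )
  out[order(out$scope, -out$mean_ability), ]
}

#' Contrasting-subpopulation scenario
#'
#' Selects the two most contrasting subpopulations by mean between-group
#' distance (genetic Rogers' distances or phenotypic Euclidean distances),
#' optionally downsamples the larger subpopulation to equal size, and runs
#' a stratified CV reporting combined and per-subpopulation abilities.
#'
#' @param genotypes A QC'd [genotype_matrix()].
#' @param blues Long BLUE table (`sample_id`, `trait`, `value`).
#' @param trait Trait to predict.
#' @param specs List of [model_spec()]s.
#' @param admixture An `admixture_result` providing the subpopulation
#'   labels.
#' @param distance_basis `"rogers"` or `"phenotype"`.
#' @param equalize Downsample the larger subpopulation to the size of the
#'   smaller one (seeded).
#' @param distance_traits Traits used for the phenotypic distance (default:
#'   all traits in `blues`; samples must be complete for all of them).
#' @param n_folds,n_repeats,seed CV settings.
#' @param alpha GWAS significance level for W-BLUP.
#' @return A list: `report` (`cv_report`), `pair` (the selected
#'   subpopulations), `contrast` (the full contrast table) and `sample_ids`
#'   (the samples that entered CV).
#' @export
contrast_scenario <- function(genotypes, blues, trait, specs, admixture,
                              distance_basis = c("rogers", "phenotype"),
                              equalize = FALSE, distance_traits = NULL,
                              n_folds = 5L, n_repeats = 10L, seed = 1L,
                              alpha = 0.05) {
  distance_basis <- match.arg(distance_basis)
  labels <- admixture$labels
  if (length(unique(labels)) < 2L) stop("need at least 2 subpopulations")
  d <- if (distance_basis == "rogers") {
    rogers_distance(genotypes)
  } else {
    phenotype_euclidean(blues, distance_traits)
  }
  contrast <- subpopulation_contrast(d, labels)
  pair <- as.integer(attr(contrast, "max_pair"))
  tr_blues <- blues[blues$trait == trait, ]
  y <- stats::setNames(tr_blues$value, tr_blues$sample_id)
  members <- names(labels)[labels %in% pair]
  members <- intersect(members, names(y))
  lab_m <- labels[members]
  if (equalize) {
    sizes <- table(lab_m)
    n_min <- min(sizes)
    members <- with_seed(derive_seed(seed, 999983L), {
      unlist(lapply(pair, function(pp) {
        grp <- members[lab_m == pp]
        if (length(grp) > n_min) sample(grp, n_min) else grp
      }))
    })
    lab_m <- labels[members]
  }
  plan <- make_cv_plan(members, n_folds = n_folds, n_repeats = n_repeats,
                       stratify_labels = lab_m, seed = seed)
  report <- run_cv(plan, specs, y, genotypes = genotypes,
                   admixture = admixture, labels = lab_m, alpha = alpha)
  list(report = report, pair = pair, contrast = contrast,
       sample_ids = members)
}

#' Write a CV report and its summary to CSV
#'
#' @param report A `cv_report`.
#' @param prefix Output path prefix.
#' @param trait Trait label column value.
#' @return The summary path, invisibly.
#' @export
write_cv_report <- function(report, prefix, trait = NA_character_) {
  tidy <- cbind(trait = trait, as.data.frame(report))
  utils::write.csv(tidy, paste0(prefix, ".csv"), row.names = FALSE)
  summ <- cbind(trait = trait, cv_summary(report))
  utils::write.csv(summ, paste0(prefix, "_summary.csv"), row.names = FALSE)
  invisible(paste0(prefix, "_summary.csv"))
}
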