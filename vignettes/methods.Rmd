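---
title: "Models and methods in genebankGP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in genebankGP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Genebank collections of inbred crop accessions are large, strongly
structured by geographic origin and breeding history, and only partially
phenotyped. Genomic prediction can fill the phenotypic gaps — fit a model
on the accessions that have adjusted phenotypes (BLUEs) and predict the
rest — but the right model depends on the trait's genetic architecture and
on the population structure of the collection. genebankGP implements a
family of mixed-model predictors spanning the main architectural
hypotheses, the supporting genotype QC and population-structure analyses,
and a repeated cross-validation protocol for comparing them, together with
a synthetic-data generator so every claim can be checked against known
ground truth.

## Models

All models share the base form $y = 1\mu + (\text{genetic terms}) + e$
with $e \sim N(0, I\sigma^2_e)$ and an intercept as the only base fixed
effect. Writing $Z$ for the column-centred dosage matrix (centring by
twice the allele frequency) and $G = ZZ^\top / (2\sum_j p_j(1-p_j))$ for
the VanRaden method-1 additive relationship matrix:

* **G-BLUP**: one additive term $g \sim N(0, G\sigma^2_g)$ — the
  infinitesimal baseline.
* **EG-BLUP**: adds $g_1 \sim N(0, H\sigma^2_{g_1})$ with
  $H = G \circ G$ (Hadamard square), the standard approximation to the
  additive-by-additive epistatic covariance of inbred lines.
* **RR-BLUP**: marker effects $a \sim N(0, I\sigma^2_a)$, fit in kernel
  space through the equivalent kernel $ZZ^\top$; predictions coincide with
  G-BLUP up to the kernel normalisation absorbed by REML.
* **GSA-RRBLUP**: one general marker-effect vector plus one per
  subpopulation. In hard-label mode the subpopulation design $Z_{S_k}$
  keeps the rows of samples assigned to cluster $k$ and zeroes the rest;
  in admixture mode $Z_{Sadm_k} = \mathrm{diag}(Q_{\cdot k}) Z$, so the
  $k$ weighted copies sum to $Z$ exactly. Fitting is in kernel space
  ($n \times n$), marker-effect BLUPs are back-solved on demand as
  $\hat a_b = \sigma^2_b Z_b^\top V^{-1}(y - \hat\mu)$.
* **W-BLUP**: markers selected by a GWAS inside the training set enter as
  fixed allele-content covariates next to a relationship matrix $G_r$
  rebuilt without them (own normaliser). Four marker-set strategies are
  supported: the single strongest association (S1, always feasible), the
  significant marker with the largest explained variance (S2), the
  shortest significant prefix jointly explaining at least 10% of the
  phenotypic variance (S3), and all significant markers (S4). S2–S4 can
  legitimately be infeasible; the CV machinery then records the model as
  infeasible rather than inventing a number.

## REML

Single-kernel models use the spectral fast path: eigendecompose the
projected kernel, profile the restricted likelihood over the variance
ratio $\delta = \sigma^2_e/\sigma^2_g$ on a log grid (100 points over
$[10^{-6}, 10^{6}]$), refine with a bounded optimiser. Multi-kernel models
use eight expectation–maximisation warm-up sweeps followed by
average-information steps with step-halving, convergence at
$|\Delta \log L| < 10^{-8}$, and at most 200 iterations. Components are
constrained non-negative by pinning at $10^{-6}\,\mathrm{var}(y)$; pinned
components with a negative score are held in an active set so that
boundary solutions do not stall the updates. When the AI direction stalls
(near-collinear kernels, e.g. duplicated blocks) EM fallback steps keep
making progress and iteration stops once gains drop below $10^{-6}$.

Two numerical behaviours are worth knowing. First, $H$ has a dominant
diagonal on weakly related panels ($\mathrm{diag}(G) \approx 2$ for fully
inbred lines, off-diagonals near zero), so $\sigma^2_{g_1}$ and
$\sigma^2_e$ are nearly unidentifiable and REML may park either at the
boundary; predictions are essentially unaffected because only
$\sigma^2_{g_1} H + \sigma^2_e I$ matters. Second, heritability read off a
fit must account for the kernel scale: with VanRaden centring
$\mathrm{mean}(G) = 0$ exactly and the genetic variance across samples is
$\sigma^2_g \cdot \mathrm{mean}(\mathrm{diag}\,G)$, about $2\sigma^2_g$
for inbreds — `genomic_h2()` applies this.

Predictions always use the conditional Gaussian expectation with
cross-kernel blocks,
$\hat g_{test} = \sum_b \sigma^2_b K_b[test,train]\,V^{-1}(y - X\hat\beta)$,
which is algebraically identical to solving the joint mixed-model
equations; the test suite enforces the identity against an independent
dense Henderson-MME oracle at fixed variance components (tolerance
$10^{-8}$).

## Genotype QC

Markers are filtered in a fixed order: (1) drop markers with more than 10%
missing calls, fewer than 10 homozygous genotypes for either allele, or
more than 1% heterozygosity among observed calls; (2) impute every
remaining missing call to the homozygous dosage of the marker's modal
allele (never a heterozygote — the panel is inbred; ties go to the
reference allele); (3) re-filter at minor allele frequency below 1%
(the threshold itself inclusive). Samples are never filtered. All
boundaries follow the strict/inclusive conventions exactly as stated. Note
an arithmetic interaction: at 20 samples the homozygote-count filter
already forces MAF = 0.5, so exercising the MAF re-filter on toy panels
requires relaxing that one threshold, which the configuration object
allows.

## Population structure

Rogers' distances treat the (hexaploid) lines as diploid: per-individual
allele frequencies are dosage/2, the per-marker distance for biallelic
data reduces to $|p_i - p_j|$, and markers are averaged with equal
weights. PCoA is classical scaling (double-centre $-D^2/2$,
eigendecompose, scale eigenvectors by root eigenvalues), with explained
shares over positive eigenvalues only.

Admixture is estimated by masked alternating least squares: factorise the
individual allele-frequency matrix into a row-simplex $Q$ (Euclidean
simplex projection each sweep) and ancestral frequency profiles clipped to
$[10^{-4}, 1-10^{-4}]$, hold out a random 5% of entries, refill them with
the current prediction each sweep, and score the run by the binomial
cross-entropy of the predicted frequencies on the held-out calls. The best
of the repeated, independently initialised runs is kept; the scan over $k$
reuses the same masks per repeat so cross-entropies are comparable. This
deliberately reproduces the *interface* of sparse-NMF admixture tools
(k scan, repeats, cross-entropy choice, hard assignment by the largest
coefficient with ties to the lowest index), not any particular published
algorithm, so numeric $Q$ values will differ from other estimators.

## GWAS and simpleM

The scan is P3D: the kinship-model variance components are estimated once
per training set, then every marker is tested as a fixed effect by
generalised least squares under $V = G\sigma^2_g + I\sigma^2_e$ with a
Wald p-value. The tested marker stays in $G$ (panel convention).
Multiple testing uses the effective number of independent tests: marker
correlation matrices are eigendecomposed in blocks of 133 markers and
$m_{\mathrm{eff}}$ is the summed smallest eigenvalue count reaching 99.5%
cumulative share; the significance threshold is $0.05 / m_{\mathrm{eff}}$.
The per-marker explained variance is the closed form
$\mathrm{var}(z)\hat a^2/\mathrm{var}(y)$ using the *empirical* marker
variance: the Hardy–Weinberg form $2p(1-p)$ would understate the dosage
variance of an inbred panel by up to a factor of two and would break the
generator's own recovery checks.

## Cross-validation

Phenotyped samples are split into five parts with sizes differing by at
most one (remainders spread one per fold), each part predicted from the
other four, the five predicted vectors concatenated, and the prediction
ability computed as one Pearson correlation per repeat — the
combined-then-correlate definition, which differs materially from
averaging per-fold correlations and is enforced by a hand-computed test.
Plans are deterministic under a master seed (per-repeat seeds via a fixed
counter scheme) and shared across all models of a trait. W-BLUP re-runs
its GWAS and marker selection inside every training fold; admixture-based
designs are fixed panel-wide because they use no phenotypes. Stratified
mode partitions within each subpopulation and merges fold-wise; the
contrast scenarios select the two most distant subpopulations by mean
between-group Rogers' or standardized phenotypic Euclidean distance,
optionally downsample the larger to equal size, and report combined and
per-subpopulation abilities. Constant predictions yield an undefined
correlation, reported as missing, never as zero.

## The synthetic world

The generator states one world and the tests live in it:

* Ancestral allele frequencies: shared base frequency $p_0 \sim U(0.1,
  0.9)$ per marker, per-population Balding–Nichols beta draws with $F$
  equal to `fst_like_divergence` (default 0.15), tripled (capped at 0.9)
  for the designated outgroup — one distinct cluster among otherwise
  similar ones.
* Admixture: each sample draws a primary cluster from unequal weights
  (default geometric decay) and a Dirichlet row with concentration
  `admixture_concentration` (default 0.2) plus 1 on the primary cluster;
  small concentration gives near-pure members.
* Genotypes: fully homozygous draws from the admixture-mixed frequency,
  with small heterozygous (0.5%) and missing (2%) call rates for QC
  testing — mirroring a "<1% heterozygosity after QC" inbred panel.
* Traits: general additive effects (standard normal per QTL),
  subpopulation-specific deviations (sd relative to the general effects,
  admixture-weighted by default, hard-label variant available),
  additive-by-additive products of centred dosages, optional major QTL,
  Gaussian noise. Components are rescaled so the major QTL explain their
  stated share of phenotypic variance, the remaining genetic components
  jointly explain heritability minus that share (keeping their drawn
  relative magnitudes — the architecture type has no per-component share
  fields), and noise explains $1 - h^2$. When the major QTL is the only
  genetic component its share necessarily equals $h^2$. Stored effect
  sizes are post-scaling so recovery tests compare like with like.

What the generator does **not** emulate: linkage maps and LD decay,
selection, pedigree structure. That has one visible consequence: with
$m$ mutually independent markers the theoretical G-BLUP accuracy is
roughly $\sqrt{n_{train}/(n_{train}+M_e)}$ with $M_e \approx m$, about
0.65 at $n = 400$, $m = 1000$ even at heritability 1. A green CV test
therefore establishes correct protocol and model behaviour, not the
absolute ability levels reachable on real LD-rich panels. Similarly,
increasing the divergence parameter raises the between-minus-within
cluster distance contrast ($2Fp_0(1-p_0)$ in expectation), not the raw
between-cluster distance, and that contrast is what the monotonicity test
asserts.

## Tunable parameters that matter

| Parameter | Default | Why |
|---|---|---|
| QC max missing | 0.10 (strict >) | stated filter pipeline |
| QC min homozygotes/allele | 10 (strict <) | stated filter pipeline |
| QC max heterozygosity | 0.01 (strict >) | stated filter pipeline |
| QC min MAF | 0.01 (inclusive ≥) | post-imputation re-filter |
| admixture masked fraction | 0.05 | held-out cross-entropy scoring |
| simpleM variance threshold | 0.995 | published default |
| simpleM block size | 133 | reference implementation practice |
| GWAS alpha | 0.05 | stated significance level |
| S3 cumulative share | 0.10 | stated strategy definition |
| CV folds × repeats | 5 × 100 (tests use fewer) | stated protocol; tests scale repeats down to fit time budgets, stated per test |
| REML convergence | 1e-8, ≤200 iterations | tightened from 1e-6 so the k=1 GSA ≡ RR-BLUP identity holds to 1e-6 |
| component lower bound | 1e-6·var(y) | non-negative variance components |

## Design choices where the design was open

* Centring frequencies for $Z$ and $G$ come from the full panel (training
  and test jointly): prediction happens within one genotyped collection.
  A sensitivity flag was considered and rejected as out of scope.
* The W-BLUP fixed design codes raw allele content (0/1/2); centring is
  absorbed by the intercept. Collinear columns (including markers constant
  in a training fold) are dropped with a warning.
* `vanraden_g()` accepts externally supplied allele frequencies; degenerate
  panels (e.g. two identical samples) are otherwise entirely monomorphic.
* Ties in the hard assignment (argmax of a $Q$ row) go to the lowest
  cluster index; ties in the modal allele go to the reference allele.
* Best-model ties in the full study resolve toward the simpler family
  (G-BLUP before EG-BLUP before GSA-RRBLUP before W-BLUP).
* Phenotype distances standardize each trait to unit variance by default
  (days, cm, g and a 1–9 score are not commensurable); a flag disables it.

## Known limitations

* The admixture estimator is a least-squares surrogate scored by
  cross-entropy; it recovers planted structure well at moderate divergence
  but is not a drop-in numerical replacement for likelihood-based sNMF.
* Per-marker explained variance uses a closed form, not a per-marker
  variance-component fit; rankings agree, absolute shares can differ.
* CV abilities under a null trait carry the usual small negative bias
  (predictions are near training-fold means that exclude the predicted
  sample), shrinking with $n$.
* Runtime scales with $n^3$ per REML fit; the 5×100 protocol on panels of
  thousands of samples is a batch job, not an interactive one.

## A worked example

```{r example}
library(genebankGP)

sim <- simulate_genotypes(sim_config(
  n_samples = 250, n_markers = 600, k_pops = 2,
  fst_like_divergence = 0.3, admixture_concentration = 0.05,
  pop_size_weights = c(0.5, 0.5), seed = 7
))
qc <- apply_qc(sim$genotypes, qc_config(min_homozygous_per_allele = 2))
trait <- simulate_trait(qc$genotypes, sim$true_admixture,
                        trait_architecture(n_additive_qtl = 40,
                                           n_epistatic_pairs = 40,
                                           heritability = 0.8, seed = 8))
y <- setNames(trait$blues$value, trait$blues$sample_id)
adm <- estimate_admixture(qc$genotypes, k = 2, n_repeats = 3, seed = 9)
plan <- make_cv_plan(names(y), n_folds = 5, n_repeats = 10, seed = 10)
report <- run_cv(plan,
                 list(model_spec("GBLUP"), model_spec("EGBLUP"),
                      model_spec("GSA_RRBLUP", k = 2, admixed = TRUE)),
                 y, genotypes = qc$genotypes, admixture = adm)
cv_summary(report)
```
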