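---
title: "Detecting candidate adaptive loci from candidate-gene panels: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting candidate adaptive loci from candidate-gene panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptscan)
```

# The problem

Forest trees planted in a common garden carry the genetic imprint of the
climates their source populations (provenances) adapted to.  Given a
candidate-gene SNP panel genotyped across such a trial — provenances
spread over correlated climatic gradients, a handful of individuals per
provenance, provenance-level phenotypes — the analysis asks three
questions:

1. which loci show genotype–environment (GEA) or genotype–phenotype (GPA)
   associations beyond what population structure explains;
2. how the variance at those candidate loci partitions into geographic,
   climatic, and phenotypic components; and
3. whether the cumulative signal (an additive polygenic score) tracks the
   environmental gradient.

`adaptscan` implements this pipeline end to end, together with a synthetic
data generator that reproduces the statistical structure the analysis
assumes, so every stage is testable without access to any particular
study's genotypes.

# The synthetic study system

`sim_config()` defaults describe a range-wide candidate-gene study of a
temperate broadleaf tree: 47 provenances, 92 individuals, 2909 biallelic
SNPs placed on ~380 single-gene contigs.

**Environment.** Each provenance carries three latent climate factors
(standard normal).  The 19 bioclim-style variables load on them through a
fixed sparse matrix (9 variables on a continentality factor, 5 on a
precipitation factor, 3 on a diurnal/summer-heat factor, 2 split) with
residual noise `env_noise_sd = 0.4`, so the top three principal components
of the standardized table recover 84–90% of the variance.  Longitude,
latitude, and altitude are generated negatively correlated with factors
1, 3, and 2 (|r| ≈ 0.7–0.9), mimicking a west–east continentality axis
and north–south moisture/heat axes.

**Genotypes.** Neutral loci follow the Balding–Nichols model: an
ancestral frequency p0 with a U-shaped spectrum (symmetric Beta with
shape `p0_shape = 0.6`, truncated to (0.01, 0.99) — the shape a SNP panel
without ascertainment against rare variants shows), cluster frequencies
Beta-distributed around p0 with divergence `fst = 0.1`.  Three ancestral
clusters are patterned along the longitudinal gradient through a
Dirichlet concentration that moves smoothly with site position
(`admix_conc = 0.55`, giving roughly three quarters of individuals a
maximum membership above 0.70).  These values were fixed once so that the
generated matrix has mean expected heterozygosity near 0.29 and the
admixture pattern of a weakly structured, largely outcrossing tree;
`fst = 0.1` is deliberately weak — strong divergence is simulated by
raising it explicitly (the cluster-recovery tests use 0.3).

**Planted clines.** `n_adaptive = 60` loci receive a logistic cline on a
latent factor: individual-level frequency
`plogis(qlogis(base) + cline_slope * factor)`, where `base` is the locus's
Balding–Nichols frequency.  Building the cline *on top of* the cluster
structure means a zero slope reduces exactly to neutral generation — the
truth table is then genuinely null, which the calibration tests exploit.
`cline_slope = 0.75` gives a mean dosage–factor correlation near 0.4, a
moderate polygenic signal.  The driving factor defaults to factor 2 (the
precipitation/altitude axis) rather than the longitudinal axis that
patterns the clusters: with both on the same axis, selection and drift
leave statistically indistinguishable imprints at this effect size and no
structure-aware method can separate them — a deliberate design choice,
and a caveat worth remembering with real data, where partial confounding
of climate and ancestry is the rule rather than the exception.

**Phenotypes.** Provenance-level spring phenology is linear in the
driving factor (plus noise, `pheno_noise_sd = 0.8`, keeping the
correlation in 0.5–0.9); autumn phenology, height, and survival load on
the factors and on a shared "vigor" channel that makes survival and
height positively correlated.  The growing-season proxy L = S − A is
derived, not simulated.

**What the generator does not emulate.** Linkage disequilibrium within
genes (loci are conditionally independent given the cline and cluster
frequencies), ascertainment bias of capture panels, genotyping error
correlated with depth, spatial autocorrelation beyond the three-factor
climate model, and — important for interpreting the collinearity
prescreen — the near-independence of common-garden phenotypes from
source-climate variables that the emulated design reported: here spring
phenology must track the driving factor, so it is partially collinear
with altitude and the precipitation PC, and the |r| > 0.7 prescreen
occasionally removes it.  Passing tests therefore demonstrate correctness
of the machinery and calibration under this model, not performance
guarantees on real panels.

# Filtering and annotation

`filter_variants()` masks genotypes below 10 reads (when depth is
present), then drops loci with minor allele frequency ≤ 5% or missingness
≥ 25%.  `snp_density_filter()` removes whole contigs with fewer than 10 bp
per SNP — a guard against collapsed paralogs.  `ld_prune()` removes one
of each within-contig pair with r² > 0.5 using a greedy keep-first scan;
contigs are single genes here, so the exhaustive scan is cheap and
parameter-free, and the audit invariant (no retained pair above the
threshold) is checked on every run.  r² uses pairwise-complete dosages;
depth masking is per-genotype, the conservative reading of a depth rule.

`annotate_snps()` classifies loci by containment against GFF3 gene
models: CDS and UTR labels within exons, `intron` inside a gene but no
exon, `flank` within 500 bp of the gene span (inclusive — a SNP exactly
500 bp away is flank, 501 bp is not), `unclassified` otherwise.  Labels
overlap (a CDS SNP is also an exon SNP, as capture-panel tables report
them); the primary category projects to {exon, intron, flank,
unclassified}, which partitions the panel.

# Ancestry by constrained matrix factorization

`fit_ancestry()` factorizes A = G/2 as QF with Q rows on the probability
simplex and F in [0,1], minimizing squared reconstruction error over
observed entries by alternating projected-gradient steps.  Step sizes are
1/L with L the blockwise Lipschitz constant (twice the top eigenvalue of
FFᵀ or QᵀQ), so the training loss decreases monotonically — a property
the tests assert.  A random 5% of observed entries is held out; the
binomial cross-entropy on that holdout scores each of the restarts, and
the best restart is kept.  `select_k()` averages the holdout
cross-entropy over restarts per K and applies a one-standard-error rule:
the smallest K within one SE of the minimum.  On a flat profile
(unstructured data) this returns K = 1.  The Evanno-style second
difference `delta_k()` is provided for replicate score matrices as a
second, independent criterion.  Missing genotypes are imputed as
`round(2 qᵢᵀf_l)` (`impute_ancestry()`); the masked-entry tests show this
beats modal imputation whenever structure is real.

# The latent-factor association scan

`lfmm_scan()` is a deterministic latent-factor association model: per
locus, OLS of dosage on [1, v, U] where U holds the first K left singular
vectors (scaled by singular values) of the column-centered genotype
matrix, and z = coefficient / SE with n − K − 2 residual df.  The
genomic inflation factor λ = median(z²)/median(χ²₁) recalibrates the
p-values; Benjamini–Hochberg adjustment controls the FDR; a locus is a
candidate when q ≤ 1% **and** its calibrated p < 0.001 (the q-value
controls the error rate, the calibrated p supplies a fixed significance
floor — the two thresholds are distinct quantities and both are exposed
in `run_config()`).

**How many factors?** With K clusters, the between-cluster signal spans a
(K−1)-dimensional subspace of the centered genotype space (ancestry rows
sum to one).  A hard SVD projection with K factors therefore absorbs one
axis *beyond* population structure, and in data carrying a polygenic
cline that extra axis is typically the cline itself — the scan's own
target.  Bayesian latent-factor samplers regularize their factors jointly
with the effects and do not collapse this way, but a projection analogue
must be more careful: `run_full()` uses `max(K* − 1, 1)` factors, where
K* comes from `select_k()`.  `fit_latent_factors()` itself takes any K,
and K = 0 reduces the scan to simple regression (asserted against the
closed-form oracle).

Provenance-level predictors (phenotypes, climate PCs, geography) are
expanded to individuals by provenance lookup before scanning.

# Redundancy analysis and outlier detection

`fit_rda()` is the two-step constrained ordination written from linear
algebra: OLS of the centered response on the centered predictors, then
SVD of the fitted matrix.  Eigenvalues are d²/(n−1); R² is fitted over
total sum of squares; adjusted R² applies the Ezekiel correction; locus
loadings are right singular vectors scaled so squared loadings sum to the
axis eigenvalue; site scores are left singular vectors.  The
implementation is verified against an explicit fitted-matrix + full-PCA
oracle to 1e−8 on random instances and against an independent constrained
ordination implementation where available.

**Response scaling.** The classical covariance-style ordination (center
only) weights each locus by its variance.  Under a U-shaped frequency
spectrum the loading distribution is then strongly leptokurtic: the ±3 SD
outlier rule fires on high-heterozygosity loci far above its nominal
two-sided normal tail of 0.27%, inflating false positives.  `fit_rda()`
keeps `scale = "center"` as its default (the classical definition), but
the pipeline's outlier-detection RDA uses `scale = "standardize"`
(`rda_scale` in `run_config()`), which gives every locus equal weight and
brings the tail rate back toward nominal.  The variance-partition models
stay covariance-style, matching the way partitioned inertia tables are
conventionally reported.

Significance: `anova_global()` uses the pseudo-F
(constrained/q)/(residual/(n−q−1)) with unrestricted row permutations of
the predictors and the add-one estimator p = (#{F* ≥ F} + 1)/(B + 1);
`anova_axes()` tests axes sequentially, partialling earlier axes' site
scores out of both sides, and stops at the first non-significant axis.
`detect_outliers()` flags loci beyond ±3 SD of the mean loading,
per axis, on the sequentially significant axes (capped at two);
`assign_predictor()` labels each outlier with its most correlated
constraining variable.  On weak-signal draws the second axis can fail the
permutation test, in which case the ordination contributes few or no
outliers and detection rests on the scan — the gate is the protocol, not
a failure mode.

Predictors are prescreened for collinearity (`prescreen_predictors()`):
while any pair exceeds |r| > 0.7, the lower-priority member of the worst
pair is dropped; the default priority keeps the first climate PC over
longitude and altitude over latitude and the second PC.

`regional_rda()` repeats the whole protocol inside one genetic cluster
(members by `assign_clusters()` at q ≥ 0.70), refiltering monomorphic
loci and re-running the prescreen; clusters smaller than rank(X) + 2, or
with a non-significant global test, yield no candidates by design.

# Variance partitioning

`variance_partition()` runs four models on the combined candidate loci:
the simple RDA on [geography, climate, phenotype] and the three partial
RDAs isolating each block's unique inertia by conditioning on the other
two (`partial_rda()` residualizes response and predictors on the
conditioning block before fitting; its unique inertia matches an explicit
projector oracle).  The joint fraction is Model 1's inertia minus the
three unique inertias; percentages are reported relative to Model 1 so
the rows sum to 100% (the share of total response inertia is also kept).
Small negative joint fractions are reported as-is with a warning — they
indicate suppressor structure, not an error.  Permutation p-values use
999 permutations by default, permuting the (residualized) predictor rows.

# Polygenic scores and trend fits

For each focal variable, `polarize_alleles()` marks the ALT allele
favored at a locus when the dosage–variable correlation is positive (REF
otherwise; exact zeros go to REF and are logged).  `polygenic_scores()`
sums favored-allele counts over the combined candidate set — polarization
uses the full union, not per-variable subsets, so scores for different
variables are comparable.  Scores are invariant to REF/ALT recoding, and
missing genotypes contribute the locus mean favored dosage.
`score_models()` fits linear and quadratic trends of score on variable,
compares them by least-squares AIC (n·ln(RSS/n) + 2k; additive constants
cancel within a variable), and reports the linear Pearson R with its
two-sided p and the quadratic R² with its model-F p.  With truly linear
data the quadratic still wins occasionally (the chance a superfluous
parameter beats a penalty of 2 is about 16% asymptotically) — model
selection frequencies, not single draws, are the meaningful check.
`het_env_regression()` relates per-individual candidate-locus
heterozygosity to the variables by backward elimination at p < 0.05,
refitting after each drop.

# Numerical and procedural choices

- Dosages count the ALT allele; every correlation-based statistic is
  invariant to global recoding (tested).
- Modal imputation ties break toward the lower dosage; the ordination
  uses modal imputation, the scan uses ancestry-based imputation.
- Permutation p-values can never be zero (add-one rule); a perfect fit
  yields p = 1/(B+1) via an infinite pseudo-F guarded against floating
  point cancellation in the residual inertia.
- Cross-entropy clipping ε = 1e−6; holdout fraction 5%; both
  configurable.
- The single pipeline seed fans out to per-stage seeds through a string
  hash, so stages rerun in isolation reproduce their in-pipeline results;
  all derived seeds stay below 2³¹.
- Reported problem sizes in the test-suite: the oracle equivalences run
  on 30 × 200 instances; the calibration studies use 92 individuals with
  2000 neutral loci (20 replicates) and 3000 loci with 60 planted clines
  (10 replicates); cluster recovery uses 500 loci at fst = 0.3.  These
  sizes keep the full suite to a few minutes while leaving every rate
  estimate enough resolution to be meaningful.

# Known limitations

- The scan's hard-projection factors make its power sensitive to the
  choice of K in a way Bayesian samplers soften; the K − 1 rule is the
  right default for discrete-cluster structure but not for continuous
  isolation-by-distance, where a scree-based choice would serve better.
- The sequential axis test is conservative when the residual response
  retains strong internal covariance (a random predictor set can capture
  a large top eigenvalue by chance), so second-axis significance — and
  with it part of the ordination's detection — is data-dependent.
- Candidate sets inherit every threshold of the emulated protocol (MAF,
  FDR, ±3 SD, |r| prescreen); these are exposed in `run_config()` but the
  defaults are fixed to the protocol, not tuned per dataset.
- The generator's clines are monotone logistic on one factor; epistasis,
  antagonistic pleiotropy, or multi-factor clines are out of scope.
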