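#' Pipeline configuration
#'
#' All thresholds of the analysis with the study's standard defaults:
#' genotype depth >= 10 reads, MAF > 5%, per-locus missingness < 25%,
#' 10 bp per SNP contig density, LD pruning at r^2 > 0.5, |r| > 0.7
#' predictor prescreen, +-3 SD loading outliers on the first two axes,
#' FDR 1% with adjusted p < 0.001 for the latent-factor scan, 1000
#' permutations for RDA tests and 999 for the variance partition, 500 bp
#' annotation flank, 150 bp proximity window, membership threshold 0.70.
#'
#' @param min_depth,maf,max_missing,min_bp_per_snp,r2_prune variant filters.
#' @param prescreen_r predictor collinearity threshold.
#' @param sd_mult loading outlier SD multiplier.
#' @param fdr,p_cut candidate thresholds of the latent-factor scan.
#' @param n_perm_rda,n_perm_partition permutation counts.
#' @param k_range candidate cluster numbers.
#' @param n_reps_k restarts per K during selection.
#' @param flank annotation flank (bp).
#' @param proximity_bp cross-method proximity window (bp).
#' @param q_threshold cluster-membership threshold.
#' @param priority predictor keep-preference for the prescreen.
#' @param rda_scale response scaling for the outlier-detection RDA:
#'   `"standardize"` (default; equal locus weight in the loading tails) or
#'   `"center"` (classical covariance-style ordination).
#' @param seed master seed; every stage derives its own from it.
#' @return list of class `run_config`.
#' @export
run_config <- function(min_depth = 10, maf = 0.05, max_missing = 0.25,
                       min_bp_per_snp = 10, r2_prune = 0.5,
                       prescreen_r = 0.7, sd_mult = 3, fdr = 0.01,
                       p_cut = 0.001, n_perm_rda = 1000,
                       n_perm_partition = 999, k_range = 1:6, n_reps_k = 3,
                       flank = 500, proximity_bp = 150, q_threshold = 0.70,
                       priority = c("PC1", "altitude", "PC3", "spring",
                                    "autumn", "height", "survival"),
                       rda_scale = "standardize", seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Run the full candidate-locus association pipeline
#'
#' Orchestrates environmental PCA -> variant filtering and annotation ->
#' ancestry estimation -> latent-factor association scan -> global and
#' regional RDA outlier detection -> candidate combination -> variance
#' partitioning -> polygenic scores, on an in-memory dataset (from
#' [simulate_dataset()] or [read_dataset()]).
#'
#' @param data list with `sites`, `env`, `pheno`, `geno`, and `gff`
#'   components.
#' @param config a [run_config()].
#' @return list of class `adaptscan_run` with each stage's results.
#' @export
run_full <- function(data, config = run_config()) {
  seed <- config$seed
  G <- data$geno
  sites <- data$sites
  # alignment checks
  if (!all(G$samples$provenance %in% sites$provenance)) {
    bad <- setdiff(G$samples$provenance, sites$provenance)
    stop("samples reference unknown provenances: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!setequal(rownames(data$env), sites$provenance) ||
      !setequal(data$pheno$provenance, sites$provenance))
    stop("environment/phenotype tables misaligned with the site table",
         call. = FALSE)

  ## environmental PCA, phenotype derivation, variable tables
  pca <- env_pca(data$env[sites$provenance, , drop = FALSE])
  pcs <- pca$scores[, 1:3, drop = FALSE]
  pheno <- data$pheno[match(sites$provenance, data$pheno$provenance), ]
  pheno$L <- derive_growing_season(pheno)
  prov_vars <- data.frame(
    longitude = sites$longitude, latitude = sites$latitude,
    altitude = sites$altitude,
    PC1 = pcs[, 1], PC2 = pcs[, 2], PC3 = pcs[, 3],
    spring = pheno$spring, autumn = pheno$autumn,
    height = pheno$height, survival = pheno$survival,
    row.names = sites$provenance)
  cca <- canonical_correlation(prov_vars[, c("longitude", "latitude",
                                             "altitude")],
                               prov_vars[, c("PC1", "PC2", "PC3")])

  ## genotype filtering and annotation
  G <- filter_variants(G, config$min_depth, config$maf, config$max_missing)
  if (!is.null(G$contig_lengths))
    G <- snp_density_filter(G, config$min_bp_per_snp)
  G <- ld_prune(G, config$r2_prune)
  annotation <- if (!is.null(data$gff)) annotate_snps(G, data$gff,
                                                      config$flank) else NULL
  he <- expected_heterozygosity(G)

  ## ancestry
  ks <- select_k(G, config$k_range, seed = derive_seed(seed, "selectk"),
                 n_reps = config$n_reps_k)
  anc <- fit_ancestry(G, ks$K, seed = derive_seed(seed, "ancestry"),
                      n_reps = 10L)
  labels <- assign_clusters(anc$Q, config$q_threshold)

  ## per-individual predictor table
  ind_vars <- prov_vars[G$samples$provenance, , drop = FALSE]
  rownames(ind_vars) <- G$samples$id

  ## latent-factor association scan (ancestry-imputed genotypes).
  ## K* clusters span a (K*-1)-dimensional subspace of the centered
  ## genotype space, so the scan uses K* - 1 hard-projection factors.
  G_lfmm <- impute_ancestry(G, anc)
  n_factors <- max(ks$K - 1L, 1L)
  scan <- suppressWarnings(
    lfmm_scan(G_lfmm, ind_vars, K = n_factors, fdr = config$fdr,
              p_cut = config$p_cut))
  lfmm_cands <- candidate_list(scan)

  ## global RDA (major-genotype imputation)
  G_rda <- impute_major(G)
  X_kept <- prescreen_predictors(ind_vars, config$prescreen_r,
                                 config$priority)
  poly <- apply(G_rda$dosage, 2, var) > 0
  G_rda <- subset_loci(G_rda, poly)
  rda_model <- fit_rda(G_rda$dosage, X_kept, scale = config$rda_scale)
  rda_global <- anova_global(rda_model, config$n_perm_rda,
                             derive_seed(seed, "anova"))
  rda_axes <- anova_axes(rda_model, config$n_perm_rda,
                         derive_seed(seed, "axes"), max_axes = 2)
  n_sig <- sum(!is.na(rda_axes$p) & rda_axes$p <= 0.05)
  rda_out <- detect_outliers(rda_model, n_axes = max(n_sig, 1),
                             sd_mult = config$sd_mult)
  rda_out <- assign_predictor(rda_out, G_rda, X_kept)
  if (nrow(rda_out)) rda_out$scope <- "global"

  ## regional RDA within each assigned cluster
  regional <- list()
  for (cl in setdiff(unique(labels), "admixed")) {
    regional[[cl]] <- regional_rda(G_rda, labels, cl, ind_vars,
                                   n_perm = config$n_perm_rda,
                                   seed = derive_seed(seed, paste0("reg", cl)),
                                   sd_mult = config$sd_mult,
                                   priority = config$priority,
                                   scale = config$rda_scale)
  }

  ## combine candidate sets (global scope)
  combined <- combine_candidates(lfmm_cands$union, rda_out$locus,
                                 annotation, G$loci,
                                 proximity_bp = config$proximity_bp)
  regional_loci <- unique(unlist(lapply(regional, function(r)
    r$outliers$locus)))
  combined$grand_union <- union(combined$union, regional_loci)

  ## variance partitioning on the combined candidate loci
  partition <- NULL
  if (length(combined$union) >= 2) {
    Yc <- G_rda$dosage[, combined$union, drop = FALSE]
    geo_block <- X_kept[, intersect(c("longitude", "latitude", "altitude"),
                                    names(X_kept)), drop = FALSE]
    clim_block <- X_kept[, intersect(c("PC1", "PC2", "PC3"), names(X_kept)),
                         drop = FALSE]
    phen_block <- X_kept[, intersect(c("spring", "autumn", "height",
                                       "survival"), names(X_kept)),
                         drop = FALSE]
    if (ncol(geo_block) && ncol(clim_block) && ncol(phen_block))
      partition <- variance_partition(Yc, geo_block, clim_block, phen_block,
                                      config$n_perm_partition,
                                      derive_seed(seed, "partition"))
  }

  ## polygenic scores and heterozygosity regression
  scores <- het_reg <- NULL
  if (length(combined$union) >= 2) {
    Gc <- subset_loci(G_rda, match(combined$union, G_rda$loci$locus_id))
    scores <- score_trend_table(Gc$dosage, ind_vars)
    het <- individual_heterozygosity(G, combined$union)
    het_reg <- het_env_regression(het, ind_vars)
  }

  structure(list(
    config = config, pca = pca, cca = cca, prov_vars = prov_vars,
    ind_vars = ind_vars, geno = G, annotation = annotation, he = he,
    k_selection = ks, ancestry = anc, cluster_labels = labels,
    lfmm = scan, lfmm_candidates = lfmm_cands,
    rda = list(model = rda_model, global = rda_global, axes = rda_axes,
               outliers = rda_out, predictors = names(X_kept)),
    regional = regional, combined = combined, partition = partition,
    polyscores = scores, het_regression = het_reg
  ), class = "adaptscan_run")
}

#' Combine latent-factor and ordination candidate sets
#'
#' Locus-level union and intersection, proximity pairs (a scan candidate
#' within `proximity_bp` of an ordination outlier on the same contig), and
#' gene-level overlap via the SNP annotation.
#'
#' @param lfmm_set character vector of scan candidate locus ids.
#' @param rda_set character vector of ordination outlier locus ids.
#' @param annotation output of [annotate_snps()] (or NULL).
#' @param loci locus metadata table (locus_id, contig, pos) for proximity.
#' @param proximity_bp window for cross-method proximity (bp, inclusive).
#' @return list: union, intersection, lfmm_only, rda_only, proximity_pairs
#'   (data.frame lfmm_locus, rda_locus, distance), gene-level sets and
#'   tallies.
#' @export
combine_candidates <- function(lfmm_set, rda_set, annotation = NULL,
                               loci = NULL, proximity_bp = 150) {
  lfmm_set <- unique(lfmm_set); rda_set <- unique(rda_set)
  inter <- intersect(lfmm_set, rda_set)
  uni <- union(lfmm_set, rda_set)
  stopifnot(length(uni) == length(lfmm_set) + length(rda_set) - length(inter))
  prox <- data.frame(lfmm_locus = character(0), rda_locus = character(0),
                     distance = integer(0))
  if (!is.null(loci) && length(lfmm_set) && length(rda_set)) {
    lf <- loci[loci$locus_id %in% setdiff(lfmm_set, rda_set), ]
    rd <- loci[loci$locus_id %in% rda_set, ]
    for (i in seq_len(nrow(lf))) {
      same <- rd[rd$contig == lf$contig[i], ]
      if (!nrow(same)) next
      d <- abs(same$pos - lf$pos[i])
      j <- which.min(d)
      if (d[j] <= proximity_bp)
        prox <- rbind(prox, data.frame(lfmm_locus = lf$locus_id[i],
                                       rda_locus = same$locus_id[j],
                                       distance = d[j]))
    }
  }
  genes <- NULL
  if (!is.null(annotation)) {
    gene_of <- setNames(annotation$gene, annotation$locus_id)
    g_lfmm <- unique(stats::na.omit(gene_of[lfmm_set]))
    g_rda <- unique(stats::na.omit(gene_of[rda_set]))
    genes <- list(lfmm = g_lfmm, rda = g_rda,
                  both = intersect(g_lfmm, g_rda),
                  union = union(g_lfmm, g_rda))
  }
  list(union = uni, intersection = inter,
       lfmm_only = setdiff(lfmm_set, rda_set),
       rda_only = setdiff(rda_set, lfmm_set),
       proximity_pairs = prox, genes = genes,
       n = c(lfmm = length(lfmm_set), rda = length(rda_set),
             union = length(uni), intersection = length(inter)))
}

#' Summarize a pipeline run
#'
#' Builds the human-readable summary tables (annotation tallies, variance
#' partition, polygenic trend fits, per-method candidate counts) and, when
#' `dir` is given, writes them as TSV plus a machine-readable JSON summary.
#'
#' @param run an [run_full()] result.
#' @param dir optional output directory.
#' @return list of class `adaptscan_report` with `summary` (named scalars)
#'   and `tables`.
#' @export
make_report <- function(run, dir = NULL) {
  stopifnot(inherits(run, "adaptscan_run"))
  cmb <- run$combined
  summary <- list(
    n_loci = ncol(run$geno$dosage),
    n_individuals = nrow(run$geno$dosage),
    mean_he = run$he$mean,
    pca_top3_variance_pct = 100 * sum(run$pca$explained[1:3]),
    canonical_R = run$cca$cor[1],
    K = run$k_selection$K,
    n_admixed = sum(run$cluster_labels == "admixed"),
    lfmm_candidates = length(run$lfmm_candidates$union),
    rda_outliers = length(unique(run$rda$outliers$locus)),
    combined_candidates = length(cmb$union),
    in_both_methods = length(cmb$intersection),
    proximity_pairs = nrow(cmb$proximity_pairs),
    rda_R2 = run$rda$model$R2,
    rda_adj_R2 = run$rda$model$adj_R2,
    rda_global_p = run$rda$global$p
  )
  tables <- list(
    annotation_tally = if (!is.null(run$annotation))
      annotation_tally(run$annotation) else NULL,
    rda_axes = run$rda$axes,
    partition = if (!is.null(run$partition)) run$partition$table else NULL,
    trend_fits = if (!is.null(run$polyscores)) run$polyscores$table else NULL,
    rda_outliers = run$rda$outliers,
    lfmm_per_variable = data.frame(
      variable = names(run$lfmm_candidates$per_variable) %||% character(0),
      n = lengths(run$lfmm_candidates$per_variable))
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    jsonlite::write_json(summary, file.path(dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    for (nm in names(tables)) {
      if (!is.null(tables[[nm]]))
        write.table(tables[[nm]], file.path(dir, paste0(nm, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  structure(list(summary = summary, tables = tables),
            class = "adaptscan_report")
}

#' @export
print.adaptscan_report <- function(x, ...) {
  s <- x$summary
  cat("adaptscan run summary\n")
  cat("  loci:", s$n_loci, " individuals:", s$n_individuals, "\n")
  cat("  mean He:", round(s$mean_he, 3), "  K:", s$K, "\n")
  cat("  candidates: scan", s$lfmm_candidates, "| ordination",
      s$rda_outliers, "| combined", s$combined_candidates,
      "(", s$in_both_methods, "in both )\n")
  invisible(x)
}
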