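#' Configuration for the synthetic common-garden dataset
#'
#' Builds and validates the parameter set for the synthetic-data generator.
#' The defaults emulate a range-wide candidate-gene study of a broadleaf
#' forest tree: 47 provenances on correlated climatic gradients, 92 sampled
#' individuals with weak three-cluster admixture, ~2909 biallelic SNPs with
#' mean expected heterozygosity near 0.29, and a planted subset of loci whose
#' allele frequencies follow logistic clines on the latent environmental
#' factors.
#'
#' @param n_sites number of provenances (sampling sites).
#' @param n_ind number of sampled individuals; must be >= `n_sites`.
#' @param n_snps number of biallelic SNP loci.
#' @param n_adaptive number of loci carrying a planted environmental cline.
#' @param n_env number of bioclimatic variables (BIO1..BIOn).
#' @param n_clusters number of ancestral genetic clusters.
#' @param fst Balding-Nichols divergence parameter in (0, 1).
#' @param cline_slope logit-scale effect of the driving latent factor on
#'   adaptive-locus allele frequency.
#' @param pheno_noise_sd standard deviation of provenance-level phenotypic
#'   noise, on the scale of the standardized latent factors.
#' @param env_noise_sd residual standard deviation of each bioclim variable
#'   around its latent-factor reconstruction (variables have unit-variance
#'   systematic part).
#' @param missing_rate fraction of genotype calls masked as missing.
#' @param p0_range support of the ancestral allele frequency distribution.
#' @param p0_shape shape of the symmetric Beta law for the ancestral
#'   frequency (truncated to `p0_range`); values below 1 give the U-shaped
#'   spectrum typical of SNP panels, 1 recovers a uniform law.
#' @param admix_conc Dirichlet concentration scale governing admixture;
#'   smaller values give purer cluster membership.
#' @param driving_factor index (1..3) of the latent factor driving the
#'   planted clines.  The default (factor 2, the precipitation/altitude
#'   axis) is deliberately distinct from the longitudinal axis that patterns
#'   the cluster structure, so selection and drift leave different imprints.
#' @param seed integer seed; every downstream draw derives from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_sites = 47, n_ind = 92, n_snps = 2909,
                       n_adaptive = 60, n_env = 19, n_clusters = 3,
                       fst = 0.1, cline_slope = 0.75, pheno_noise_sd = 0.8,
                       env_noise_sd = 0.4, missing_rate = 0.0075,
                       p0_range = c(0.01, 0.99), p0_shape = 0.6,
                       admix_conc = 0.55, driving_factor = 2L, seed = 1L) {
  cfg <- list(n_sites = as.integer(n_sites), n_ind = as.integer(n_ind),
              n_snps = as.integer(n_snps), n_adaptive = as.integer(n_adaptive),
              n_env = as.integer(n_env), n_clusters = as.integer(n_clusters),
              fst = fst, cline_slope = cline_slope,
              pheno_noise_sd = pheno_noise_sd, env_noise_sd = env_noise_sd,
              missing_rate = missing_rate, p0_range = p0_range,
              p0_shape = p0_shape, admix_conc = admix_conc,
              driving_factor = as.integer(driving_factor),
              seed = as.integer(seed))
  if (any(c(cfg$n_sites, cfg$n_ind, cfg$n_snps, cfg$n_env, cfg$n_clusters) <= 0))
    stop("invalid config: all dimensions must be positive", call. = FALSE)
  if (cfg$n_adaptive < 0 || cfg$n_adaptive > cfg$n_snps)
    stop("invalid config: n_adaptive must be in [0, n_snps]", call. = FALSE)
  if (cfg$n_ind < cfg$n_sites)
    stop("invalid config: n_ind must be >= n_sites", call. = FALSE)
  if (cfg$fst <= 0 || cfg$fst >= 1)
    stop("invalid config: fst must lie in (0, 1)", call. = FALSE)
  if (cfg$pheno_noise_sd < 0 || cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("invalid config: noise / missing rate out of range", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

# Fixed 19 x 3 loading matrix of the latent climate factors.  Factor 1 is a
# continentality axis (9 variables, mixed signs), factor 2 a precipitation
# axis (5 variables), factor 3 a diurnal/summer-heat axis (3 variables);
# two variables load on two factors.  Loadings near 0.9 keep communalities
# high so the top-3 PCA of the standardized table recovers >= 80% variance.
env_loadings <- function(n_env = 19) {
  L <- matrix(0, n_env, 3,
              dimnames = list(paste0("BIO", seq_len(n_env)), paste0("F", 1:3)))
  f1_pos <- intersect(c(6, 9, 11, 14, 17, 19), seq_len(n_env))
  f1_neg <- intersect(c(4, 7, 15), seq_len(n_env))
  f2 <- intersect(c(8, 12, 13, 16, 18), seq_len(n_env))
  f3 <- intersect(c(2, 3, 5), seq_len(n_env))
  L[f1_pos, 1] <- 0.9
  L[f1_neg, 1] <- -0.9
  L[f2, 2] <- 0.9
  L[f3, 3] <- 0.9
  if (n_env >= 1 && all(L[1, ] == 0)) L[1, ] <- c(0.75, 0, 0.45)
  if (n_env >= 10 && all(L[10, ] == 0)) L[10, ] <- c(0, 0.55, 0.65)
  # any remaining unassigned variable gets a moderate factor-1 loading
  left <- rowSums(abs(L)) == 0
  L[left, 1] <- 0.7
  L
}

#' Simulate provenances and their environmental table
#'
#' Draws `n_sites` provenances with three standard-normal latent climate
#' factors, builds the bioclim table from a fixed loading matrix plus
#' independent noise, and generates longitude, latitude, and altitude
#' negatively correlated with factors 1, 3, and 2 respectively (|r| around
#' 0.7-0.9), mimicking the west-east continentality and north-south
#' moisture/heat gradients of a European range.
#'
#' @param cfg a [sim_config()].
#' @return list with `sites` (provenance, longitude, latitude, altitude),
#'   `env` (n_sites x n_env matrix), and `factors` (n_sites x 3 matrix of
#'   the latent values; the simulation truth).
#' @export
simulate_sites <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, "sites"))
  n <- cfg$n_sites
  fac <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("F", 1:3)))
  L <- env_loadings(cfg$n_env)
  env <- fac %*% t(L) + matrix(rnorm(n * cfg$n_env, sd = cfg$env_noise_sd),
                               n, cfg$n_env)
  colnames(env) <- rownames(L)
  rho <- c(lon = 0.85, lat = 0.8, alt = 0.78)
  mix <- function(f, r) -r * f + sqrt(1 - r^2) * rnorm(n)
  lon_std <- mix(fac[, 1], rho["lon"])
  lat_std <- mix(fac[, 3], rho["lat"])
  alt_std <- mix(fac[, 2], rho["alt"])
  sites <- data.frame(
    provenance = sprintf("P%02d", seq_len(n)),
    longitude = 10 + 9 * lon_std,
    latitude = 48 + 4 * lat_std,
    altitude = 600 + 300 * alt_std
  )
  rownames(env) <- sites$provenance
  rownames(fac) <- sites$provenance
  list(sites = sites, env = env, factors = fac)
}

#' Simulate admixed genotypes with planted environmental clines
#'
#' Neutral loci follow the Balding-Nichols model: ancestral frequency p0
#' drawn uniformly from `cfg$p0_range`, cluster frequencies
#' Beta(p0(1-F)/F, (1-p0)(1-F)/F) with F = `cfg$fst`.  Individual ancestry
#' is Dirichlet with concentration varying smoothly along the longitudinal
#' gradient, so clusters are geographically patterned.  Adaptive loci ignore
#' cluster structure and take individual-level frequencies
#' `plogis(qlogis(p0) + cline_slope * factor)` evaluated at the individual's
#' site, i.e. a logistic cline on the driving latent factor.  Genotypes are
#' Binomial(2, p) dosages; missing calls are injected uniformly at
#' `cfg$missing_rate`.
#'
#' @param cfg a [sim_config()].
#' @param sim_sites output of [simulate_sites()].
#' @return list with `geno` (a [genotype_matrix()]), `truth` (per-locus truth
#'   table: locus_id, is_adaptive, driving_factor, true_slope), and `Q_true`
#'   (n_ind x n_clusters ancestry fractions).
#' @export
simulate_genotypes <- function(cfg, sim_sites) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, "genotypes"))
  n <- cfg$n_ind; L <- cfg$n_snps; K <- cfg$n_clusters
  site_of <- rep(seq_len(cfg$n_sites), length.out = n)

  # geographically patterned admixture: Gaussian bump weights along the
  # standardized longitude, scaled by the concentration parameter
  u <- as.numeric(scale(sim_sites$sites$longitude))[site_of]
  centers <- seq(-1.2, 1.2, length.out = K)
  w <- exp(-outer(u, centers, function(a, b) (a - b)^2) / (2 * 0.6^2))
  alpha <- cfg$admix_conc * (w / rowSums(w)) * K + 0.02
  Q_true <- rdirichlet(n, alpha)

  # truncated symmetric Beta ancestral spectrum (U-shaped for shape < 1)
  sh <- cfg$p0_shape %||% 1
  lo <- stats::pbeta(cfg$p0_range[1], sh, sh)
  hi <- stats::pbeta(cfg$p0_range[2], sh, sh)
  p0 <- stats::qbeta(runif(L, lo, hi), sh, sh)
  is_adaptive <- rep(FALSE, L)
  if (cfg$n_adaptive > 0) is_adaptive[seq_len(cfg$n_adaptive)] <- TRUE
  # planted loci get moderate ancestral frequencies so the cline has room
  p0[is_adaptive] <- runif(sum(is_adaptive), 0.25, 0.75)

  shape1 <- p0 * (1 - cfg$fst) / cfg$fst
  shape2 <- (1 - p0) * (1 - cfg$fst) / cfg$fst
  Fmat <- matrix(rbeta(K * L, rep(shape1, each = K), rep(shape2, each = K)),
                 K, L)
  P <- Q_true %*% Fmat                     # individual expected frequencies
  if (any(is_adaptive)) {
    # logistic cline on the driving factor, superimposed on the cluster
    # structure so that a zero slope reduces exactly to neutral generation
    fac_val <- sim_sites$factors[site_of, cfg$driving_factor]
    idx <- which(is_adaptive)
    base <- pmin(pmax(P[, idx, drop = FALSE], 0.02), 0.98)
    P[, idx] <- plogis(qlogis(base) + cfg$cline_slope * fac_val)
  }
  P <- pmin(pmax(P, 0), 1)   # guard fp overshoot of q'f
  dosage <- matrix(rbinom(n * L, 2L, as.numeric(P)), n, L)
  if (cfg$missing_rate > 0) {
    miss <- runif(n * L) < cfg$missing_rate
    dosage[miss] <- NA_integer_
  }

  locus_id <- sprintf("snp%05d", seq_len(L))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, L, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  loci <- data.frame(locus_id = locus_id, contig = "unplaced",
                     pos = seq_len(L), ref = ref, alt = alt,
                     stringsAsFactors = FALSE)
  samples <- data.frame(id = sprintf("ind%03d", seq_len(n)),
                        provenance = sim_sites$sites$provenance[site_of],
                        stringsAsFactors = FALSE)
  dimnames(dosage) <- list(samples$id, locus_id)
  geno <- genotype_matrix(dosage, loci, samples)
  truth <- data.frame(
    locus_id = locus_id,
    is_adaptive = is_adaptive,
    driving_factor = ifelse(is_adaptive, cfg$driving_factor, NA_integer_),
    true_slope = ifelse(is_adaptive, cfg$cline_slope, 0),
    stringsAsFactors = FALSE
  )
  list(geno = geno, truth = truth, Q_true = Q_true)
}

#' Simulate provenance-level phenotypes
#'
#' Spring phenology is linear in the driving latent factor; autumn phenology,
#' height, and survival are generated from configurable loadings on the
#' latent factors and a shared vigor channel (so survival and height are
#' positively correlated, as in common-garden trials).  The growing-season
#' proxy L = S - A is appended.
#'
#' @param cfg a [sim_config()].
#' @param sim_sites output of [simulate_sites()].
#' @param truth ignored (kept for pipeline symmetry).
#' @param spring_loading loading of spring phenology on the driving factor.
#' @return data.frame with provenance, spring, autumn, height, survival, L.
#' @export
simulate_phenotypes <- function(cfg, sim_sites, truth = NULL,
                                spring_loading = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(derive_seed(cfg$seed, "phenotypes"))
  fac <- sim_sites$factors
  n <- nrow(fac)
  sdn <- cfg$pheno_noise_sd
  drv <- fac[, cfg$driving_factor]
  spring <- 4 + spring_loading * drv + rnorm(n, sd = sdn)
  autumn <- 3 + 0.4 * fac[, 2] + rnorm(n, sd = sdn)
  vigor <- 0.5 * drv + rnorm(n, sd = sdn)           # shared vigor channel
  height <- 150 + 20 * vigor + rnorm(n, sd = 10 * sdn)
  survival <- 70 + 10 * (0.7 * vigor + 0.3 * fac[, 3]) + rnorm(n, sd = 5 * sdn)
  data.frame(provenance = sim_sites$sites$provenance,
             spring = spring, autumn = autumn, height = height,
             survival = survival, L = spring - autumn)
}

#' Simulate gene models and place SNPs on them
#'
#' Builds one gene per contig (three exons, two introns, terminal UTRs and a
#' central CDS) and assigns each locus a contig and position so that the SNP
#' category proportions match `proportions` (defaults near a candidate-gene
#' capture design: exon 65%, intron 23%, flank 12%).  The placement record is
#' the annotation truth used by round-trip tests.
#'
#' @param cfg a [sim_config()].
#' @param geno a [genotype_matrix()]; its loci are placed in-place.
#' @param proportions named numeric: target shares for exon, intron, flank.
#' @param snps_per_gene average loci per gene model.
#' @return list with `geno` (coordinates filled in), `gff` (GFF3-style
#'   data.frame), `placement` (locus_id, gene, category truth).
#' @export
simulate_gene_models <- function(cfg, geno,
                                 proportions = c(exon = 0.65, intron = 0.23,
                                                 flank = 0.12),
                                 snps_per_gene = 7.65) {
  stopifnot(inherits(cfg, "sim_config"), inherits(geno, "adaptscan_geno"))
  proportions <- proportions / sum(proportions)
  set.seed(derive_seed(cfg$seed, "genemodels"))
  L <- ncol(geno$dosage)
  n_genes <- max(1L, as.integer(round(L / snps_per_gene)))

  exon_len <- 300L; intron_len <- 400L; utr_len <- 100L; margin <- 2000L
  gene_start <- margin + 1L
  gene_end <- gene_start + 3L * exon_len + 2L * intron_len - 1L
  contig_len <- gene_end + margin
  exon_starts <- gene_start + (0:2) * (exon_len + intron_len)
  exon_ends <- exon_starts + exon_len - 1L
  cds_start <- exon_starts[1] + utr_len      # 5'UTR occupies exon1 head
  cds_end <- exon_ends[3] - utr_len          # 3'UTR occupies exon3 tail

  gff <- do.call(rbind, lapply(seq_len(n_genes), function(g) {
    ctg <- sprintf("contig%04d", g); gid <- sprintf("gene%04d", g)
    rbind(
      data.frame(seqid = ctg, type = "gene", start = gene_start,
                 end = gene_end, gene = gid),
      data.frame(seqid = ctg, type = "exon", start = exon_starts,
                 end = exon_ends, gene = gid),
      data.frame(seqid = ctg, type = "CDS",
                 start = pmax(exon_starts, cds_start),
                 end = pmin(exon_ends, cds_end), gene = gid),
      data.frame(seqid = ctg, type = "five_prime_UTR", start = exon_starts[1],
                 end = cds_start - 1L, gene = gid),
      data.frame(seqid = ctg, type = "three_prime_UTR", start = cds_end + 1L,
                 end = exon_ends[3], gene = gid)
    )
  }))
  validate_gene_models(gff)

  category <- sample(names(proportions), L, replace = TRUE, prob = proportions)
  gene_of <- rep(seq_len(n_genes), length.out = L)
  intron_rng <- cbind(exon_ends[-3] + 1L, exon_starts[-1] - 1L)
  pos <- integer(L)
  for (i in seq_len(L)) {
    pos[i] <- switch(category[i],
      exon = {
        e <- sample(3, 1)
        sample(exon_starts[e]:exon_ends[e], 1)
      },
      intron = {
        j <- sample(2, 1)
        sample(intron_rng[j, 1]:intron_rng[j, 2], 1)
      },
      flank = if (runif(1) < 0.5) sample((gene_start - 500L):(gene_start - 1L), 1)
              else sample((gene_end + 1L):(gene_end + 500L), 1)
    )
  }
  # unique positions within each contig (resample collisions)
  for (g in seq_len(n_genes)) {
    sel <- which(gene_of == g)
    while (anyDuplicated(pos[sel])) {
      d <- sel[duplicated(pos[sel])]
      pos[d] <- pos[d] + sample(c(-1L, 1L), length(d), replace = TRUE)
    }
  }
  geno$loci$contig <- sprintf("contig%04d", gene_of)
  geno$loci$pos <- pos
  ord <- order(geno$loci$contig, geno$loci$pos)
  geno <- subset_loci(geno, ord)
  geno$contig_lengths <- setNames(rep(contig_len, n_genes),
                                  sprintf("contig%04d", seq_len(n_genes)))
  placement <- data.frame(locus_id = geno$loci$locus_id,
                          gene = sprintf("gene%04d", gene_of[ord]),
                          category = category[ord], stringsAsFactors = FALSE)
  list(geno = geno, gff = gff, placement = placement)
}

#' Validate gene-model feature containment
#'
#' Checks that exons lie within their gene span, CDS and UTR segments lie
#' within exons, and exons of a gene do not overlap each other.
#'
#' @param gff data.frame with seqid, type, start, end, gene columns.
#' @return invisibly TRUE; stops with an invalid-model error otherwise.
#' @export
validate_gene_models <- function(gff) {
  for (gid in unique(gff$gene)) {
    gg <- gff[gff$gene == gid, ]
    gene <- gg[gg$type == "gene", ]
    ex <- gg[gg$type == "exon", ]
    if (nrow(gene) != 1L)
      stop("invalid gene model: ", gid, " must have exactly one gene feature",
           call. = FALSE)
    if (any(ex$start < gene$start | ex$end > gene$end))
      stop("invalid gene model: exon outside gene span in ", gid, call. = FALSE)
    ex <- ex[order(ex$start), ]
    if (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)]))
      stop("invalid gene model: overlapping exons in ", gid, call. = FALSE)
    sub <- gg[gg$type %in% c("CDS", "five_prime_UTR", "three_prime_UTR"), ]
    if (nrow(sub)) {
      inside <- vapply(seq_len(nrow(sub)), function(i)
        any(sub$start[i] >= ex$start & sub$end[i] <= ex$end), logical(1))
      if (!all(inside))
        stop("invalid gene model: CDS/UTR not contained in an exon in ", gid,
             call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Simulate a complete study dataset
#'
#' Convenience wrapper chaining [simulate_sites()], [simulate_genotypes()],
#' [simulate_gene_models()], and [simulate_phenotypes()].
#'
#' @param cfg a [sim_config()].
#' @return list with sites, env, factors, geno, truth, Q_true, gff,
#'   placement, pheno, and the config itself.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  ss <- simulate_sites(cfg)
  sg <- simulate_genotypes(cfg, ss)
  gm <- simulate_gene_models(cfg, sg$geno)
  ph <- simulate_phenotypes(cfg, ss, sg$truth)
  # keep the truth table aligned with the coordinate-sorted loci
  truth <- sg$truth[match(gm$geno$loci$locus_id, sg$truth$locus_id), ]
  rownames(truth) <- NULL
  list(config = cfg, sites = ss$sites, env = ss$env, factors = ss$factors,
       geno = gm$geno, truth = truth, Q_true = sg$Q_true, gff = gm$gff,
       placement = gm$placement, pheno = ph)
}

#' Write a simulated dataset to disk
#'
#' Emits a VCF v4.2 (diploid GT, missing as "./."), TSV tables for sites,
#' environment and phenotypes, a GFF3 of the gene models, the truth table,
#' and a JSON manifest recording the seed and configuration.  Files round-trip
#' losslessly through [read_dataset()].
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_dataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, "genotypes.vcf"),
    sites = file.path(dir, "sites.tsv"),
    env = file.path(dir, "env.tsv"),
    pheno = file.path(dir, "pheno.tsv"),
    gff = file.path(dir, "genes.gff3"),
    truth = file.path(dir, "truth.tsv"),
    samples = file.path(dir, "samples.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  write_vcf(sim$geno, paths["vcf"])
  write.table(sim$sites, paths["sites"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  env_df <- data.frame(provenance = rownames(sim$env), sim$env,
                       check.names = FALSE)
  write.table(env_df, paths["env"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$pheno, paths["pheno"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_gff3(sim$gff, paths["gff"])
  write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$geno$samples, paths["samples"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(list(seed = sim$config$seed,
                            config = unclass(sim$config)),
                       paths["manifest"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read back a dataset written by [write_dataset()]
#'
#' @param dir directory containing the files.
#' @return list mirroring [simulate_dataset()] (without latent truth factors).
#' @export
read_dataset <- function(dir) {
  geno <- read_vcf(file.path(dir, "genotypes.vcf"))
  samples <- read.delim(file.path(dir, "samples.tsv"))
  geno$samples <- samples[match(geno$samples$id, samples$id), ]
  sites <- read.delim(file.path(dir, "sites.tsv"))
  env_df <- read.delim(file.path(dir, "env.tsv"), check.names = FALSE)
  env <- as.matrix(env_df[, -1, drop = FALSE])
  rownames(env) <- env_df[[1]]
  pheno <- read.delim(file.path(dir, "pheno.tsv"))
  truth <- read.delim(file.path(dir, "truth.tsv"))
  gff <- read_gff3(file.path(dir, "genes.gff3"))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  list(sites = sites, env = env, pheno = pheno, geno = geno, truth = truth,
       gff = gff, manifest = manifest)
}
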