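test_that("config validation rejects impossible designs", {
  expect_error(sim_config(n_sites = 0), "positive")
  expect_error(sim_config(n_snps = -5), "positive")
  expect_error(sim_config(n_adaptive = 50, n_snps = 10), "n_adaptive")
  expect_error(sim_config(n_ind = 10, n_sites = 20), "n_ind")
  expect_error(sim_config(fst = 1.2), "fst")
  expect_error(sim_config(fst = 0), "fst")
})

test_that("simulated sites carry the documented factor structure", {
  cfg <- sim_config(seed = 1)
  ss <- simulate_sites(cfg)
  expect_equal(dim(ss$env), c(47, 19))
  expect_false(anyNA(ss$env))
  expect_equal(nrow(ss$sites), 47)

  # top-3 PCA of the standardized table recovers >= 80% variance
  pca <- env_pca(ss$env)
  expect_gte(sum(pca$explained[1:3]), 0.80)

  # geography is negatively tied to the latent factors
  expect_lt(cor(ss$sites$longitude, ss$factors[, 1]), -0.5)
  expect_lt(cor(ss$sites$latitude, ss$factors[, 3]), -0.5)
  expect_lt(cor(ss$sites$altitude, ss$factors[, 2]), -0.5)
})

test_that("noiseless environmental table has rank exactly 3", {
  cfg <- sim_config(env_noise_sd = 0, seed = 4)
  ss <- simulate_sites(cfg)
  expect_equal(qr(scale(ss$env, scale = FALSE))$rank, 3)
  expect_equal(sum(env_pca(ss$env)$eigenvalues > 1e-8), 3)
})

test_that("neutral-only simulation matches the Balding-Nichols He oracle", {
  cfg <- sim_config(n_sites = 20, n_ind = 60, n_snps = 800, n_adaptive = 0,
                    missing_rate = 0, seed = 2)
  ss <- simulate_sites(cfg)
  sg <- simulate_genotypes(cfg, ss)
  expect_equal(sum(sg$truth$is_adaptive), 0)

  # Monte-Carlo oracle of E[2 p(1-p)] for the sample-level allele frequency:
  # draw the ancestral spectrum, cluster frequencies, and mix with the
  # ancestry weights actually realised in the simulation
  set.seed(99)
  n_mc <- 1e5
  sh <- cfg$p0_shape
  lo <- pbeta(cfg$p0_range[1], sh, sh); hi <- pbeta(cfg$p0_range[2], sh, sh)
  p0 <- qbeta(runif(n_mc, lo, hi), sh, sh)
  f <- matrix(rbeta(3 * n_mc, rep(p0 * (1 - cfg$fst) / cfg$fst, each = 3),
                    rep((1 - p0) * (1 - cfg$fst) / cfg$fst, each = 3)), 3)
  w <- colMeans(sg$Q_true)
  pbar <- as.numeric(w %*% f)
  he_oracle <- mean(2 * pbar * (1 - pbar))
  he_sim <- expected_heterozygosity(sg$geno)$mean
  expect_lt(abs(he_sim - he_oracle), 0.05)
})

test_that("default conditions give overall mean He near 0.29", {
  hes <- vapply(1:3, function(s) {
    cfg <- sim_config(n_snps = 1200, seed = s)
    ss <- simulate_sites(cfg)
    expected_heterozygosity(simulate_genotypes(cfg, ss)$geno)$mean
  }, numeric(1))
  expect_lt(abs(mean(hes) - 0.29), 0.03)
})

test_that("a zero cline makes planted loci indistinguishable from neutral", {
  cfg <- sim_config(n_sites = 30, n_ind = 90, n_snps = 600, n_adaptive = 200,
                    cline_slope = 0, missing_rate = 0, seed = 3)
  ss <- simulate_sites(cfg)
  sg <- simulate_genotypes(cfg, ss)
  fac <- ss$factors[match(sg$geno$samples$provenance, ss$sites$provenance),
                    cfg$driving_factor]
  r <- abs(as.numeric(suppressWarnings(cor(sg$geno$dosage, fac))))
  ok <- !is.na(r)   # fixed loci have undefined correlations
  ks <- suppressWarnings(ks.test(r[sg$truth$is_adaptive & ok],
                                 r[!sg$truth$is_adaptive & ok]))
  expect_gt(ks$p.value, 0.01)
})

test_that("planted-cline signal grows with the slope", {
  slopes <- c(0.2, 0.7, 1.5)
  mean_r <- vapply(slopes, function(sl) {
    rs <- vapply(1:5, function(s) {
      cfg <- sim_config(n_sites = 20, n_ind = 60, n_snps = 80,
                        n_adaptive = 40, cline_slope = sl,
                        missing_rate = 0, seed = s)
      ss <- simulate_sites(cfg)
      sg <- simulate_genotypes(cfg, ss)
      fac <- ss$factors[match(sg$geno$samples$provenance,
                              ss$sites$provenance), cfg$driving_factor]
      mean(abs(cor(sg$geno$dosage[, sg$truth$is_adaptive], fac)))
    }, numeric(1))
    mean(rs)
  }, numeric(1))
  expect_true(all(diff(mean_r) > 0))
})

test_that("simulation is deterministic given the seed", {
  a <- simulate_dataset(small_cfg(seed = 7))
  b <- simulate_dataset(small_cfg(seed = 7))
  expect_identical(a$geno$dosage, b$geno$dosage)
  expect_identical(a$pheno, b$pheno)
  expect_identical(a$gff, b$gff)
  c <- simulate_dataset(small_cfg(seed = 8))
  expect_false(identical(a$geno$dosage, c$geno$dosage))
})

test_that("phenotypes follow their planted loadings", {
  cfg <- sim_config(pheno_noise_sd = 0, seed = 5)
  ss <- simulate_sites(cfg)
  ph <- simulate_phenotypes(cfg, ss)
  expect_equal(cor(ph$spring, ss$factors[, cfg$driving_factor]), 1)
  expect_equal(ph$L, ph$spring - ph$autumn)

  # default noise keeps the spring-factor correlation moderate-to-strong
  rs <- vapply(1:20, function(s) {
    cfg <- sim_config(seed = s)
    ss <- simulate_sites(cfg)
    cor(simulate_phenotypes(cfg, ss)$spring,
        ss$factors[, cfg$driving_factor])
  }, numeric(1))
  expect_true(all(rs >= 0.5 & rs <= 0.95))

  # the shared vigor channel links survival to height
  rh <- vapply(1:10, function(s) {
    cfg <- sim_config(seed = s)
    ss <- simulate_sites(cfg)
    ph <- simulate_phenotypes(cfg, ss)
    cor(ph$survival, ph$height)
  }, numeric(1))
  expect_gt(mean(rh), 0)
  expect_gt(mean(rh > 0), 0.8)
})

test_that("gene models validate containment and place SNPs as recorded", {
  sim <- simulate_dataset(small_cfg(seed = 2))
  gff <- sim$gff
  # CDS/UTR within exons, exons within genes
  expect_silent(validate_gene_models(gff))
  ann <- annotate_snps(sim$geno, gff, flank = 500)
  expect_equal(ann$category, sim$placement$category)
  expect_equal(ann$gene[ann$category != "flank"],
               sim$placement$gene[sim$placement$category != "flank"])

  bad <- gff[gff$gene == gff$gene[1], ]
  bad$end[bad$type == "exon"][1] <- bad$start[bad$type == "exon"][2] + 10
  expect_error(validate_gene_models(bad), "overlap")
})

test_that("single gene spanning all SNPs annotates everything as exon", {
  dos <- matrix(c(0L, 1L, 2L, 1L, 0L, 2L), 2, 3)
  G <- toy_geno(dos, contig = rep("c1", 3), pos = c(10L, 20L, 30L))
  gff <- data.frame(seqid = "c1", type = c("gene", "exon"),
                    start = c(1, 1), end = c(100, 100), gene = "g1")
  ann <- annotate_snps(G, gff)
  expect_true(all(ann$category == "exon"))
})

test_that("written dataset round-trips losslessly", {
  dir <- withr::local_tempdir()
  sim <- simulate_dataset(small_cfg(seed = 3))
  write_dataset(sim, dir)
  back <- read_dataset(dir)
  expect_identical(unname(back$geno$dosage), unname(sim$geno$dosage))
  expect_identical(is.na(back$geno$dosage), is.na(sim$geno$dosage))
  expect_equal(back$geno$loci$pos, sim$geno$loci$pos)
  expect_equal(back$geno$samples$provenance, sim$geno$samples$provenance)
  expect_equal(back$manifest$seed, 3)

  # VCF body has one record per locus and one genotype column per individual
  vcf_lines <- readLines(file.path(dir, "genotypes.vcf"))
  body <- vcf_lines[!startsWith(vcf_lines, "#")]
  expect_length(body, ncol(sim$geno$dosage))
  expect_equal(length(strsplit(body[1], "\t")[[1]]) - 9L,
               nrow(sim$geno$dosage))
})
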