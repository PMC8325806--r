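# builds a small VCF text file in code
write_test_vcf <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "test.vcf")
  writeLines(lines, path)
  path
}

vcf_header <- c(
  "##fileformat=VCFv4.2",
  "##contig=<ID=c1,length=1000>",
  "##contig=<ID=c2,length=100>",
  '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
  '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
  paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3"), collapse = "\t"))

test_that("VCF reading codes genotypes as ALT dosage and skips non-SNPs", {
  path <- write_test_vcf(c(
    vcf_header,
    "c1\t10\tv1\tA\tC\t.\tPASS\t.\tGT:DP\t0/0:20\t0/1:15\t1/1:30",
    "c1\t20\tv2\tA\tC,G\t.\tPASS\t.\tGT:DP\t0/0:20\t0/1:20\t0/0:20",
    "c1\t30\tv3\tAT\tA\t.\tPASS\t.\tGT:DP\t0/0:20\t0/0:20\t0/0:20",
    "c1\t40\tv4\tG\tT\t.\tPASS\t.\tGT:DP\t./.:0\t1/0:12\t0|1:9"))
  expect_message(G <- read_vcf(path), "2 non-biallelic-SNP")
  expect_equal(dim(G$dosage), c(3, 2))
  expect_equal(unname(G$dosage["s1", ]), c(0L, NA))
  expect_equal(unname(G$dosage["s2", ]), c(1L, 1L))
  expect_equal(unname(G$dosage["s3", ]), c(2L, 1L))
  expect_equal(G$contig_lengths, c(c1 = 1000L, c2 = 100L))
  expect_equal(unname(G$depth["s3", ]), c(30, 9))
})

test_that("empty VCF body yields a zero-locus matrix with a warning", {
  path <- write_test_vcf(vcf_header)
  expect_warning(G <- read_vcf(path), "no records")
  expect_equal(dim(G$dosage), c(3, 0))
})

test_that("VCF writing round-trips through reading", {
  sim <- simulate_dataset(small_cfg(seed = 9))
  dir <- withr::local_tempdir()
  write_vcf(sim$geno, file.path(dir, "g.vcf"))
  back <- read_vcf(file.path(dir, "g.vcf"))
  expect_identical(unname(back$dosage), unname(sim$geno$dosage))
  expect_equal(back$loci$ref, sim$geno$loci$ref)
})

test_that("variant filters apply MAF, missingness and depth rules", {
  # locus 1: alt freq 0.04 -> dropped; locus 2: fine; locus 3: 30% missing
  n <- 50
  d1 <- c(rep(1L, 2), rep(0L, n - 2))          # alt freq 0.02
  d2 <- c(rep(1L, 20), rep(0L, n - 20))
  d3 <- c(rep(NA_integer_, 15), rep(1L, 20), rep(0L, 15))
  G <- toy_geno(cbind(d1, d2, d3))
  Gf <- filter_variants(G)
  expect_equal(Gf$loci$locus_id, "L02")
  # exactly 30% missing is >= the 0.3 cut (strict rule) -> still dropped
  expect_equal(filter_variants(G, max_missing = 0.3)$loci$locus_id, "L02")
  expect_equal(filter_variants(G, max_missing = 0.35)$loci$locus_id,
               c("L02", "L03"))

  # all-pass matrix unchanged; filtering is idempotent
  G2 <- toy_geno(cbind(d2, rev(d2)))
  expect_identical(filter_variants(G2)$dosage, G2$dosage)
  expect_identical(filter_variants(Gf)$dosage, Gf$dosage)

  # low-depth genotypes are masked before the locus filters
  dep <- matrix(30, n, 3); dep[1:30, 2] <- 5
  Gd <- toy_geno(cbind(d1, d2, d3), depth = dep)
  Gdf <- filter_variants(Gd)
  expect_false("L02" %in% Gdf$loci$locus_id)  # masked to 60% missing
})

test_that("SNP-density contig filter removes dense contigs and is idempotent", {
  # c1: 100 bp, 15 SNPs (6.7 bp/SNP) -> removed; c2: 1000 bp, 10 SNPs -> kept
  dos <- matrix(rep(c(0L, 1L, 2L, 1L), 25), 4, 25)
  G <- toy_geno(dos, contig = rep(c("c1", "c2"), c(15, 10)),
                pos = c(1:15 * 6, 1:10 * 100),
                contig_lengths = c(c1 = 100L, c2 = 1000L))
  Gf <- snp_density_filter(G, 10)
  expect_true(all(Gf$loci$contig == "c2"))
  expect_identical(snp_density_filter(Gf, 10)$dosage, Gf$dosage)
})

test_that("LD pruning removes duplicates and audits the r2 bound", {
  set.seed(21)
  n <- 60
  base <- rbinom(n, 2, 0.5)
  noisy <- base; noisy[1:5] <- 2 - noisy[1:5]
  indep <- matrix(rbinom(n * 6, 2, 0.5), n, 6)
  dos <- cbind(base, base, noisy, indep)
  G <- toy_geno(dos, pos = seq_len(ncol(dos)))
  Gp <- ld_prune(G, 0.5)
  expect_false("L02" %in% Gp$loci$locus_id)  # identical copy removed
  # audit: every retained within-contig pair is below the threshold
  R <- suppressWarnings(cor(Gp$dosage, use = "pairwise.complete.obs"))
  diag(R) <- 0
  expect_lte(max(R^2, na.rm = TRUE), 0.5)

  # loci on different contigs are never compared
  G2 <- toy_geno(cbind(base, base), contig = c("cA", "cB"), pos = c(1L, 1L))
  expect_equal(ncol(ld_prune(G2)$dosage), 2)

  # independent loci survive (null removal rate near zero at n = 200)
  set.seed(22)
  Gi <- toy_geno(matrix(rbinom(200 * 50, 2, 0.5), 200, 50), pos = 1:50)
  expect_gte(ncol(ld_prune(Gi)$dosage), 48)
})

test_that("annotation respects containment and the 500 bp flank boundary", {
  # gene on c1 spanning 1000..2999 with one exon 1000..1999 (CDS 1200..1799),
  # intron implied 2000..2999 would be outside exon; add second exon
  gff <- data.frame(
    seqid = "c1",
    type = c("gene", "exon", "CDS", "five_prime_UTR", "exon"),
    start = c(1000, 1000, 1200, 1000, 2500),
    end = c(2999, 1999, 1799, 1199, 2999),
    gene = "g1")
  pos <- c(499L,   # gene_start - 501 -> unclassified
           500L,   # gene_start - 500 -> flank
           1100L,  # 5'UTR (exon)
           1500L,  # CDS (exon)
           2200L,  # intron
           3499L,  # gene_end + 500 -> flank
           3500L)  # gene_end + 501 -> unclassified
  dos <- matrix(0L, 2, length(pos))
  G <- toy_geno(dos, contig = rep("c1", length(pos)), pos = pos)
  ann <- annotate_snps(G, gff, flank = 500)
  expect_equal(ann$category,
               c("unclassified", "flank", "exon", "exon", "intron", "flank",
                 "unclassified"))
  labs <- strsplit(ann$labels, ",")
  expect_true(all(c("CDS", "exon") %in% labs[[4]]))
  expect_true(all(c("5'UTR", "exon") %in% labs[[3]]))
  # primary categories partition the loci
  tal <- annotation_tally(ann)
  prim <- tal[tal$label %in% c("exon", "intron", "flank", "unclassified"), ]
  expect_equal(sum(prim$n), nrow(ann))
  # CDS counted within exon tally too
  expect_equal(tal$n[tal$label == "CDS"], 1)
  expect_equal(tal$n[tal$label == "exon"], 2)
  # SNP on a contig absent from the models is unclassified
  G2 <- toy_geno(matrix(0L, 2, 1), contig = "cX", pos = 1L)
  expect_equal(annotate_snps(G2, gff)$category, "unclassified")
})

test_that("expected heterozygosity matches the allele-counting oracle", {
  G <- toy_geno(cbind(rep(0L, 10), rep(1L, 10), c(rep(0L, 5), rep(2L, 5))))
  he <- expected_heterozygosity(G)
  expect_equal(unname(he$per_locus), c(0, 0.5, 0.5))
  set.seed(23)
  dos <- matrix(rbinom(30 * 100, 2, runif(100, 0.05, 0.95)), 30, 100,
                byrow = TRUE)
  dos[sample(length(dos), 200)] <- NA
  G2 <- toy_geno(dos)
  he2 <- expected_heterozygosity(G2)
  oracle <- vapply(seq_len(100), function(j) {
    alleles <- c(dos[, j], dos[, j])  # two allele draws per genotype
    g <- dos[!is.na(dos[, j]), j]
    cnt_alt <- sum(g); cnt_tot <- 2 * length(g)
    p <- cnt_alt / cnt_tot
    1 - p^2 - (1 - p)^2
  }, numeric(1))
  expect_equal(unname(he2$per_locus), oracle, tolerance = 1e-12)
  expect_true(all(he2$per_locus >= 0 & he2$per_locus <= 0.5))
})

test_that("individual heterozygosity counts het calls over the subset", {
  dos <- rbind(rep(0L, 10),
               c(rep(1L, 3), rep(0L, 7)),
               c(rep(1L, 5), rep(NA_integer_, 5)))
  G <- toy_geno(dos)
  het <- individual_heterozygosity(G)
  expect_equal(unname(het), c(0, 0.3, 1))
  # mean weighted by called genotypes equals the matrix-wide het fraction
  called <- sum(!is.na(dos))
  expect_equal(sum(het * rowSums(!is.na(dos))) / called,
               sum(dos == 1, na.rm = TRUE) / called)
  expect_equal(unname(individual_heterozygosity(G, c("L01", "L04"))[2]), 0.5)
})

test_that("major-genotype imputation fills with the locus mode", {
  d1 <- c(rep(0L, 5), rep(1L, 3), rep(2L, 1), NA)
  d2 <- c(rep(1L, 4), rep(2L, 4), NA, NA)    # clear mode 1 (first max)
  d3 <- c(rep(0L, 4), rep(2L, 4), NA, NA)    # tie 0 vs 2 -> lower dosage
  G <- toy_geno(cbind(d1, d2, d3))
  Gi <- impute_major(G)
  expect_equal(Gi$dosage[10, 1], 0L)
  expect_equal(unname(Gi$dosage[9:10, 2]), c(1L, 1L))
  expect_equal(unname(Gi$dosage[9:10, 3]), c(0L, 0L))
  expect_false(anyNA(Gi$dosage))
  # no missing -> identity
  expect_identical(impute_major(Gi)$dosage, Gi$dosage)
  # fully missing locus is an error
  Gbad <- toy_geno(cbind(d1, rep(NA_integer_, 10)))
  expect_error(impute_major(Gbad), "fully missing")
})
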