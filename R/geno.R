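#' Genotype matrix container
#'
#' Bundles an individuals x loci dosage matrix (ALT-allele counts 0/1/2 with
#' NA for missing), per-locus metadata, sample-to-provenance mapping, optional
#' per-genotype sequencing depth, and contig lengths from the VCF header.
#'
#' @param dosage integer matrix, individuals in rows, loci in columns.
#' @param loci data.frame with locus_id, contig, pos, ref, alt.
#' @param samples data.frame with id and provenance columns.
#' @param contig_lengths optional named vector of contig lengths.
#' @param depth optional matrix of per-genotype read depths, same shape as
#'   `dosage`.
#' @return object of class `adaptscan_geno`.
#' @export
genotype_matrix <- function(dosage, loci, samples, contig_lengths = NULL,
                            depth = NULL) {
  stopifnot(is.matrix(dosage), nrow(loci) == ncol(dosage),
            nrow(samples) == nrow(dosage))
  ok <- is.na(dosage) | dosage %in% 0:2
  if (!all(ok)) stop("dosage entries must be 0, 1, 2, or NA", call. = FALSE)
  for (ctg in unique(loci$contig)) {
    p <- loci$pos[loci$contig == ctg]
    if (is.unsorted(p, strictly = TRUE))
      stop("positions must be strictly increasing within contig ", ctg,
           call. = FALSE)
  }
  structure(list(dosage = dosage, loci = loci, samples = samples,
                 contig_lengths = contig_lengths, depth = depth),
            class = "adaptscan_geno")
}

#' @export
print.adaptscan_geno <- function(x, ...) {
  cat("genotype matrix:", nrow(x$dosage), "individuals x", ncol(x$dosage),
      "loci;", sum(is.na(x$dosage)), "missing calls\n")
  invisible(x)
}

#' Subset a genotype matrix by locus index
#'
#' @param G a [genotype_matrix()].
#' @param idx integer or logical index over loci.
#' @return the subsetted `adaptscan_geno`.
#' @export
subset_loci <- function(G, idx) {
  G$dosage <- G$dosage[, idx, drop = FALSE]
  G$loci <- G$loci[idx, , drop = FALSE]
  rownames(G$loci) <- NULL
  if (!is.null(G$depth)) G$depth <- G$depth[, idx, drop = FALSE]
  G
}

#' Read biallelic SNP genotypes from a VCF file
#'
#' Multiallelic records and non-SNP alleles are skipped with a logged count;
#' "./." (and ".|.") genotypes become NA.  Per-genotype DP is retained when
#' present.  Contig lengths are taken from `##contig` header lines.
#'
#' @param path VCF v4.x file.
#' @return a [genotype_matrix()]; attribute `skipped` records the number of
#'   non-biallelic-SNP records dropped.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  n_rec <- nrow(fix)
  samples_ids <- colnames(v@gt)[-1]
  if (n_rec == 0L) {
    warning("VCF has no records")
    dos <- matrix(integer(0), nrow = length(samples_ids), ncol = 0,
                  dimnames = list(samples_ids, NULL))
    loci <- data.frame(locus_id = character(0), contig = character(0),
                       pos = integer(0), ref = character(0),
                       alt = character(0))
    samples <- data.frame(id = samples_ids, provenance = NA_character_)
    return(genotype_matrix(dos, loci, samples, vcf_contig_lengths(path)))
  }
  keep <- !is.na(fix$ALT) & !grepl(",", fix$ALT) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  skipped <- sum(!keep)
  if (skipped > 0)
    message(skipped, " non-biallelic-SNP records skipped")
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  code <- function(g) {
    g <- gsub("\\|", "/", g)
    out <- rep(NA_integer_, length(g))
    out[g == "0/0"] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g == "1/1"] <- 2L
    out
  }
  dos <- t(matrix(code(c(gt)), nrow = nrow(gt)))
  fixk <- fix[keep, , drop = FALSE]
  ids <- fixk$ID
  ids[is.na(ids) | ids == "."] <- paste0(fixk$CHROM, ":", fixk$POS)[is.na(ids) | ids == "."]
  loci <- data.frame(locus_id = ids, contig = fixk$CHROM,
                     pos = as.integer(fixk$POS), ref = fixk$REF,
                     alt = fixk$ALT, stringsAsFactors = FALSE)
  dimnames(dos) <- list(colnames(gt), ids)
  depth <- NULL
  if (any(grepl("DP", v@gt[keep, 1L]))) {
    dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP",
                                            as.numeric = TRUE))
    if (!all(is.na(dp))) depth <- t(dp[keep, , drop = FALSE])
  }
  samples <- data.frame(id = rownames(dos), provenance = NA_character_,
                        stringsAsFactors = FALSE)
  G <- genotype_matrix(dos, loci, samples, vcf_contig_lengths(path), depth)
  attr(G, "skipped") <- skipped
  G
}

vcf_contig_lengths <- function(path) {
  hdr <- grep("^##contig", readLines(path, n = 5000L), value = TRUE)
  if (!length(hdr)) return(NULL)
  id <- sub('.*ID=([^,>]+).*', "\\1", hdr)
  len <- suppressWarnings(as.integer(sub('.*length=([0-9]+).*', "\\1", hdr)))
  setNames(len, id)
}

#' Write a genotype matrix as a VCF v4.2 text file
#'
#' @param G a [genotype_matrix()].
#' @param path output file.
#' @return invisibly `path`.
#' @export
write_vcf <- function(G, path) {
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write ", path, call. = FALSE)
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2", "##source=adaptscan"), con)
  if (!is.null(G$contig_lengths))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(G$contig_lengths),
                       as.integer(G$contig_lengths)), con)
  writeLines('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", G$samples$id), collapse = "\t"), con)
  gt_code <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(ncol(G$dosage)), function(j) {
    g <- G$dosage[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    paste(c(G$loci$contig[j], G$loci$pos[j], G$loci$locus_id[j],
            G$loci$ref[j], G$loci$alt[j], ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

write_gff3 <- function(gff, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tadaptscan\t%s\t%d\t%d\t.\t+\t.\tID=%s;gene_id=%s",
                     gff$seqid, gff$type, as.integer(gff$start),
                     as.integer(gff$end),
                     paste0(gff$gene, "_", gff$type, "_", seq_len(nrow(gff))),
                     gff$gene))
  writeLines(lines, path)
  invisible(path)
}

read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  data.frame(seqid = as.character(GenomicRanges::seqnames(gr)),
             type = as.character(gr$type),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             gene = as.character(gr$gene_id),
             stringsAsFactors = FALSE)
}

#' Filter variants on depth, minor allele frequency, and missingness
#'
#' Genotypes with read depth below `min_depth` are masked missing (only when
#' depth is available), then loci with minor allele frequency <= `maf` or a
#' missing fraction >= `max_missing` are dropped.  The attached filter log
#' records locus counts after each step.
#'
#' @param G a [genotype_matrix()].
#' @param min_depth per-genotype depth threshold (reads).
#' @param maf minor-allele-frequency threshold; loci must exceed it.
#' @param max_missing maximum tolerated missing fraction per locus
#'   (exclusive).
#' @return filtered `adaptscan_geno` with attribute `filter_log`.
#' @export
filter_variants <- function(G, min_depth = 10, maf = 0.05,
                            max_missing = 0.25) {
  log <- data.frame(step = "input", loci = ncol(G$dosage))
  if (!is.null(G$depth)) {
    mask <- !is.na(G$depth) & G$depth < min_depth
    G$dosage[mask] <- NA_integer_
  }
  log <- rbind(log, data.frame(step = "depth_mask", loci = ncol(G$dosage)))

  n_called <- colSums(!is.na(G$dosage))
  p_alt <- colSums(G$dosage, na.rm = TRUE) / (2 * pmax(n_called, 1L))
  maf_hat <- pmin(p_alt, 1 - p_alt)
  keep_maf <- n_called > 0 & maf_hat > maf
  G <- subset_loci(G, keep_maf)
  log <- rbind(log, data.frame(step = "maf", loci = ncol(G$dosage)))

  miss_frac <- colMeans(is.na(G$dosage))
  keep_miss <- miss_frac < max_missing
  G <- subset_loci(G, keep_miss)
  log <- rbind(log, data.frame(step = "missingness", loci = ncol(G$dosage)))
  attr(G, "filter_log") <- log
  G
}

#' Remove SNP-dense contigs
#'
#' Drops whole contigs whose length per retained SNP falls below
#' `min_bp_per_snp`, a guard against collapsed-paralog mapping artifacts.
#' Contig lengths come from the VCF header (or gene-model file); contigs of
#' unknown length are kept with a warning.
#'
#' @param G a [genotype_matrix()] with `contig_lengths`.
#' @param min_bp_per_snp minimum base pairs per SNP.
#' @return filtered `adaptscan_geno`.
#' @export
snp_density_filter <- function(G, min_bp_per_snp = 10) {
  tab <- table(G$loci$contig)
  drop <- character(0)
  for (ctg in names(tab)) {
    len <- G$contig_lengths[ctg]
    if (is.null(G$contig_lengths) || is.na(len)) {
      warning("no length for contig ", ctg, "; kept")
      next
    }
    if (len / tab[[ctg]] < min_bp_per_snp) drop <- c(drop, ctg)
  }
  subset_loci(G, !(G$loci$contig %in% drop))
}

#' Prune loci in linkage disequilibrium
#'
#' Greedy left-to-right scan within each contig: a locus is kept iff its
#' squared Pearson correlation of dosages (pairwise-complete) with every
#' previously kept locus on the same contig is <= `r2_max`.  Pairs on
#' different contigs are never compared.
#'
#' @param G a [genotype_matrix()].
#' @param r2_max squared-correlation threshold.
#' @return pruned `adaptscan_geno`.
#' @export
ld_prune <- function(G, r2_max = 0.5) {
  keep <- rep(TRUE, ncol(G$dosage))
  for (ctg in unique(G$loci$contig)) {
    idx <- which(G$loci$contig == ctg)
    if (length(idx) < 2) next
    kept <- idx[1]
    for (j in idx[-1]) {
      r <- suppressWarnings(
        cor(G$dosage[, j], G$dosage[, kept, drop = FALSE],
            use = "pairwise.complete.obs"))
      r2 <- r^2
      if (any(!is.na(r2) & r2 > r2_max)) keep[j] <- FALSE
      else kept <- c(kept, j)
    }
  }
  subset_loci(G, keep)
}

#' Annotate SNPs against gene models
#'
#' Assigns each locus the full set of overlapping feature labels (gene, exon,
#' CDS, 5'/3' UTR) plus derived labels: `intron` for loci inside a gene but
#' in no exon, `flank` for loci within `flank` bp outside the gene span
#' (inclusive), and `unclassified` otherwise.  The primary category projects
#' the label set to {exon, intron, flank, unclassified}; these partition the
#' loci.
#'
#' @param G a [genotype_matrix()].
#' @param gene_models GFF3-style data.frame (seqid, type, start, end, gene)
#'   with 1-based inclusive coordinates, or a path to a GFF3 file.
#' @param flank flank width in bp, inclusive.
#' @return data.frame: locus_id, gene, category (primary), labels
#'   (comma-separated full set).
#' @export
annotate_snps <- function(G, gene_models, flank = 500) {
  if (is.character(gene_models)) gene_models <- read_gff3(gene_models)
  gff <- gene_models
  snp <- GenomicRanges::GRanges(G$loci$contig,
                                IRanges::IRanges(G$loci$pos, G$loci$pos))
  feat <- GenomicRanges::GRanges(gff$seqid,
                                 IRanges::IRanges(gff$start, gff$end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(snp, feat))
  L <- nrow(G$loci)
  labels <- vector("list", L)
  gene_id <- rep(NA_character_, L)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  type_map <- c(gene = "gene", exon = "exon", CDS = "CDS",
                five_prime_UTR = "5'UTR", three_prime_UTR = "3'UTR")
  for (k in seq_along(qh)) {
    i <- qh[k]
    ty <- type_map[gff$type[sh[k]]]
    if (is.na(ty)) next
    labels[[i]] <- union(labels[[i]], ty)
    if (is.na(gene_id[i])) gene_id[i] <- gff$gene[sh[k]]
  }
  # intron: inside gene but not exon
  for (i in seq_len(L)) {
    if (!is.null(labels[[i]]) && "gene" %in% labels[[i]] &&
        !("exon" %in% labels[[i]]))
      labels[[i]] <- union(labels[[i]], "intron")
  }
  # flank: within `flank` bp of a gene span, outside it
  genes <- gff[gff$type == "gene", , drop = FALSE]
  gflank <- GenomicRanges::GRanges(
    genes$seqid,
    IRanges::IRanges(pmax(1L, genes$start - as.integer(flank)),
                     genes$end + as.integer(flank)))
  fh <- suppressWarnings(GenomicRanges::findOverlaps(snp, gflank))
  for (k in seq_along(S4Vectors::queryHits(fh))) {
    i <- S4Vectors::queryHits(fh)[k]
    if (is.null(labels[[i]]) || !("gene" %in% labels[[i]])) {
      labels[[i]] <- union(labels[[i]], "flank")
      if (is.na(gene_id[i]))
        gene_id[i] <- genes$gene[S4Vectors::subjectHits(fh)[k]]
    }
  }
  primary <- vapply(labels, function(lb) {
    if (is.null(lb)) "unclassified"
    else if ("exon" %in% lb) "exon"
    else if ("intron" %in% lb) "intron"
    else if ("flank" %in% lb) "flank"
    else "unclassified"
  }, character(1))
  data.frame(
    locus_id = G$loci$locus_id,
    gene = gene_id,
    category = primary,
    labels = vapply(labels, function(lb)
      if (is.null(lb)) "unclassified"
      else paste(sort(setdiff(lb, "gene")), collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
}

#' Tally annotation categories
#'
#' Counts loci per label (exon, CDS, UTRs, intron, flank, unclassified) the
#' way capture-panel studies report them: labels overlap (a CDS SNP is also
#' an exon SNP), so percentages need not sum to 100.
#'
#' @param annotation output of [annotate_snps()].
#' @return data.frame with label, n, percent.
#' @export
annotation_tally <- function(annotation) {
  all_labels <- unlist(strsplit(annotation$labels, ","))
  lv <- c("exon", "CDS", "5'UTR", "3'UTR", "intron", "flank", "unclassified")
  n <- vapply(lv, function(l) sum(all_labels == l), numeric(1))
  data.frame(label = lv, n = n,
             percent = round(100 * n / nrow(annotation), 2),
             row.names = NULL)
}

#' Per-locus and mean expected heterozygosity
#'
#' He = 1 - p^2 - (1-p)^2 with p the ALT-allele frequency over non-missing
#' alleles; the probability that two randomly drawn alleles differ.
#'
#' @param G a [genotype_matrix()].
#' @return list with `per_locus` (named vector; all-missing loci excluded
#'   with a warning) and `mean`.
#' @export
expected_heterozygosity <- function(G) {
  n_called <- colSums(!is.na(G$dosage))
  if (any(n_called == 0)) warning(sum(n_called == 0), " all-missing loci excluded")
  ok <- n_called > 0
  p <- colSums(G$dosage[, ok, drop = FALSE], na.rm = TRUE) /
    (2 * n_called[ok])
  he <- 1 - p^2 - (1 - p)^2
  names(he) <- G$loci$locus_id[ok]
  list(per_locus = he, mean = mean(he))
}

#' Per-individual heterozygosity over a locus subset
#'
#' Fraction of heterozygous calls among non-missing genotypes in the subset.
#'
#' @param G a [genotype_matrix()].
#' @param loci_subset locus ids or column indices.
#' @return named numeric vector; individuals with no called genotype in the
#'   subset get NA with a warning.
#' @export
individual_heterozygosity <- function(G, loci_subset = NULL) {
  idx <- if (is.null(loci_subset)) seq_len(ncol(G$dosage))
         else if (is.character(loci_subset)) match(loci_subset, G$loci$locus_id)
         else loci_subset
  if (!length(idx)) stop("empty locus subset", call. = FALSE)
  d <- G$dosage[, idx, drop = FALSE]
  called <- rowSums(!is.na(d))
  het <- rowSums(d == 1L, na.rm = TRUE) / called
  if (any(called == 0)) {
    warning(sum(called == 0), " individuals with no called genotype in subset")
    het[called == 0] <- NA_real_
  }
  setNames(het, G$samples$id)
}

#' Impute missing genotypes with the most common genotype
#'
#' Each missing entry is replaced by the modal genotype (0/1/2) of its locus
#' across all individuals; ties break toward the lower dosage.
#'
#' @param G a [genotype_matrix()].
#' @return complete `adaptscan_geno`.
#' @export
impute_major <- function(G) {
  d <- G$dosage
  for (j in which(colSums(is.na(d)) > 0)) {
    g <- d[, j]
    if (all(is.na(g)))
      stop("locus ", G$loci$locus_id[j],
           " is fully missing; filter before imputing", call. = FALSE)
    counts <- tabulate(g + 1L, nbins = 3L)
    mode_g <- which.max(counts) - 1L   # which.max takes the first tie
    d[is.na(g), j] <- mode_g
  }
  G$dosage <- d
  G
}
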