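# Shared fixtures built in code: small study configurations, a hand-sized
# genotype object, and a cluster-relabelling helper for comparing ancestry
# matrices under label switching.

small_cfg <- function(seed = 1, ...) {
  args <- modifyList(list(n_sites = 12, n_ind = 24, n_snps = 120,
                          n_adaptive = 10, seed = seed), list(...))
  do.call(sim_config, args)
}

# tiny deterministic genotype object for unit tests
toy_geno <- function(dosage, contig = NULL, pos = NULL, contig_lengths = NULL,
                     depth = NULL, provenance = NULL) {
  n <- nrow(dosage); L <- ncol(dosage)
  loci <- data.frame(
    locus_id = sprintf("L%02d", seq_len(L)),
    contig = contig %||% rep("c1", L),
    pos = pos %||% seq_len(L),
    ref = rep("A", L), alt = rep("C", L),
    stringsAsFactors = FALSE)
  dimnames(dosage) <- list(sprintf("i%02d", seq_len(n)), loci$locus_id)
  samples <- data.frame(id = rownames(dosage),
                        provenance = provenance %||% rep("P1", n),
                        stringsAsFactors = FALSE)
  genotype_matrix(dosage, loci, samples, contig_lengths, depth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# best cluster relabelling (exhaustive over permutations, K <= 6) minimizing
# mean |Qhat P - Q_true|
align_Q <- function(Qhat, Qtrue) {
  K <- ncol(Qhat)
  perms <- combinat_perms(K)
  best <- Inf; bestQ <- Qhat
  for (i in seq_len(nrow(perms))) {
    Qp <- Qhat[, perms[i, ], drop = FALSE]
    err <- mean(abs(Qp - Qtrue))
    if (err < best) { best <- err; bestQ <- Qp }
  }
  list(Q = bestQ, err = best)
}

combinat_perms <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- combinat_perms(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, matrix(setdiff(seq_len(k), i)[sub], nrow(sub)))
  }))
}

# latent factor value of each individual's site
factor_of_individuals <- function(sim, which_factor = NULL) {
  wf <- which_factor %||% sim$config$driving_factor
  site_of <- match(sim$geno$samples$provenance, sim$sites$provenance)
  sim$factors[site_of, wf]
}
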