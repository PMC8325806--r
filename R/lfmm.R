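#' Latent factors for population-structure control
#'
#' The first K left singular vectors of the column-centered dosage matrix,
#' scaled by their singular values — the subspace a latent-factor association
#' model uses to absorb population structure.
#'
#' @param G_complete complete dosage matrix (individuals x loci) or a
#'   [genotype_matrix()] without missing entries.
#' @param K number of factors; 0 gives an empty factor set.
#' @return n x K matrix U.
#' @export
fit_latent_factors <- function(G_complete, K) {
  Y <- if (inherits(G_complete, "adaptscan_geno")) G_complete$dosage
       else as.matrix(G_complete)
  if (anyNA(Y)) stop("latent factors require a complete matrix", call. = FALSE)
  if (K >= min(dim(Y))) stop("K must be < min(n, loci)", call. = FALSE)
  if (K == 0) return(matrix(numeric(0), nrow(Y), 0))
  Yc <- scale(Y, scale = FALSE)
  sv <- svd(Yc, nu = K, nv = 0)
  U <- sv$u %*% diag(sv$d[seq_len(K)], K, K)
  rownames(U) <- rownames(Y)
  colnames(U) <- paste0("U", seq_len(K))
  U
}

#' Per-locus association scan with latent-factor adjustment
#'
#' For every locus, ordinary least squares of dosage on [1, v, U]; the
#' z-score is the coefficient of v divided by its standard error with
#' residual df = n - K - 2.  Provenance-level variables must already be
#' expanded to individuals (see [expand_to_individuals()]).
#'
#' @param G_complete complete dosage matrix or `adaptscan_geno`.
#' @param v numeric predictor per individual.
#' @param U latent factor matrix from [fit_latent_factors()] (may have 0
#'   columns).
#' @return data.frame: locus, beta, se, z.
#' @export
association_scan <- function(G_complete, v, U = NULL) {
  Y <- if (inherits(G_complete, "adaptscan_geno")) G_complete$dosage
       else as.matrix(G_complete)
  if (anyNA(Y) || anyNA(v)) stop("scan requires complete data", call. = FALSE)
  if (is.null(U)) U <- matrix(numeric(0), nrow(Y), 0)
  n <- nrow(Y); K <- ncol(U)
  X <- cbind(`(Intercept)` = 1, v = v, U)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    warning("predictor collinear with latent factors; z set missing")
    return(data.frame(locus = colnames(Y) %||% seq_len(ncol(Y)),
                      beta = NA_real_, se = NA_real_, z = NA_real_))
  }
  B <- qr.coef(qx, Y)                        # (K+2) x L coefficients
  res <- Y - X %*% B
  df <- n - K - 2
  sigma2 <- colSums(res^2) / df
  xtx_inv_v <- chol2inv(qr.R(qx))[2, 2]
  se <- sqrt(sigma2 * xtx_inv_v)
  z <- B[2, ] / se
  data.frame(locus = colnames(Y) %||% as.character(seq_len(ncol(Y))),
             beta = B[2, ], se = se, z = z, row.names = NULL)
}

#' Genomic inflation factor and calibrated p-values
#'
#' lambda = median(z^2) / median(chi-square_1), with the null median computed
#' from the quantile function; calibrated p-values are the upper chi-square_1
#' tail of z^2 / lambda.  A lambda outside [0.5, 2] triggers a calibration
#' warning.
#'
#' @param z vector of association z-scores.
#' @return list: `lambda`, `p` (calibrated per-locus p-values).
#' @export
genomic_inflation <- function(z) {
  z[is.nan(z)] <- NA_real_
  lambda <- median(z[!is.na(z)]^2) / qchisq(0.5, df = 1)
  if (lambda < 0.5 || lambda > 2)
    warning("genomic inflation factor ", signif(lambda, 4),
            " far from 1; calibration suspect")
  p <- pchisq(z^2 / lambda, df = 1, lower.tail = FALSE)
  list(lambda = lambda, p = p)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement.
#'
#' @param p vector of p-values in [0,1].
#' @return vector of q-values.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  p.adjust(p, method = "BH")
}

#' Expand a provenance-level variable to individuals
#'
#' @param value named vector (names = provenances) or data.frame with
#'   provenance plus one value column.
#' @param provenance_of character vector mapping each individual to its
#'   provenance.
#' @return numeric vector per individual.
#' @export
expand_to_individuals <- function(value, provenance_of) {
  if (is.data.frame(value))
    value <- setNames(value[[2]], value[[1]])
  out <- value[provenance_of]
  if (anyNA(out))
    stop("provenances without a value: ",
         paste(unique(provenance_of[is.na(out)]), collapse = ", "),
         call. = FALSE)
  unname(out)
}

#' Latent-factor association scan over a set of variables
#'
#' Runs [association_scan()], [genomic_inflation()], and [bh_adjust()] for
#' each column of `vars`, flagging candidates by the conjunctive rule
#' q <= fdr AND calibrated p < p_cut (the BH q controls the false-discovery
#' rate; the inflation-calibrated p-value supplies the fixed significance
#' floor).
#'
#' @param G_complete complete dosage matrix or `adaptscan_geno`.
#' @param vars data.frame/matrix of per-individual predictor columns.
#' @param K number of latent factors.
#' @param fdr threshold on the BH-adjusted q-value.
#' @param p_cut threshold on the calibrated p-value.
#' @return object of class `lfmm_scan`: `results` (long data.frame: locus,
#'   variable, beta, z, p, q, candidate), `lambda` (named per variable), `K`.
#' @export
lfmm_scan <- function(G_complete, vars, K, fdr = 0.01, p_cut = 0.001) {
  vars <- as.data.frame(vars)
  U <- fit_latent_factors(G_complete, K)
  out <- lapply(names(vars), function(nm) {
    sc <- association_scan(G_complete, vars[[nm]], U)
    gi <- genomic_inflation(sc$z)
    q <- bh_adjust(gi$p)
    data.frame(locus = sc$locus, variable = nm, beta = sc$beta, z = sc$z,
               p = gi$p, q = q, candidate = q <= fdr & gi$p < p_cut,
               lambda = gi$lambda, row.names = NULL)
  })
  res <- do.call(rbind, out)
  lambda <- vapply(out, function(d) d$lambda[1], numeric(1))
  names(lambda) <- names(vars)
  res$lambda <- NULL
  structure(list(results = res, lambda = lambda, K = K,
                 fdr = fdr, p_cut = p_cut), class = "lfmm_scan")
}

#' Candidate list from a latent-factor scan
#'
#' Per-variable candidate lists plus the deduplicated union across variables,
#' with per-variable membership retained.
#'
#' @param scan an [lfmm_scan()] result (or its `results` data.frame with a
#'   `candidate` column).
#' @return list: `per_variable` (named list of locus-id vectors), `union`
#'   (locus ids), `membership` (data.frame locus, variable).
#' @export
candidate_list <- function(scan) {
  res <- if (inherits(scan, "lfmm_scan")) scan$results else scan
  if (nrow(res) == 0)
    return(list(per_variable = list(), union = character(0),
                membership = data.frame(locus = character(0),
                                        variable = character(0))))
  cand <- res[res$candidate %in% TRUE, , drop = FALSE]
  per_var <- split(cand$locus, cand$variable)
  list(per_variable = per_var,
       union = unique(cand$locus),
       membership = cand[, c("locus", "variable")])
}
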