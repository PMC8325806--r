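#' Estimate ancestry coefficients by constrained matrix factorization
#'
#' Factorizes the scaled dosage matrix A = G/2 as Q F with Q rows on the
#' probability simplex (individual ancestry fractions) and F in [0,1]
#' (cluster allele frequencies), minimizing the squared reconstruction loss
#' over observed, non-held-out entries by alternating projected-gradient
#' steps (step size 1/L with L the blockwise Lipschitz constant, so the
#' training loss decreases monotonically).  A random `holdout` fraction of
#' observed entries is masked and used to score the fit by binomial
#' cross-entropy; the best of `n_reps` restarts by that criterion is kept.
#'
#' @param G a [genotype_matrix()]; missing entries are simply excluded from
#'   the loss.
#' @param K number of clusters (>= 1).
#' @param seed integer seed for restarts and the held-out mask.
#' @param n_reps number of random restarts.
#' @param holdout fraction of observed entries held out for cross-entropy.
#' @param max_iter maximum outer iterations per restart.
#' @param tol relative training-loss change declaring convergence.
#' @param eps clipping bound inside the cross-entropy logs.
#' @return object of class `ancestry_fit`: K, Q, F, cross_entropy (held-out),
#'   loss_trace (training loss per outer iteration), rep_cross_entropy,
#'   converged flag.
#' @export
fit_ancestry <- function(G, K, seed = 1L, n_reps = 10L, holdout = 0.05,
                         max_iter = 150L, tol = 1e-8, eps = 1e-6) {
  stopifnot(K >= 1)
  A <- G$dosage / 2
  obs <- !is.na(A)
  A0 <- A; A0[!obs] <- 0
  n <- nrow(A); L <- ncol(A)

  best <- NULL
  rep_ce <- numeric(n_reps)
  for (rep in seq_len(n_reps)) {
    set.seed(derive_seed(seed, paste0("ancestry_rep", rep)))
    ho <- obs & (matrix(runif(n * L), n, L) < holdout)
    train <- obs & !ho
    W <- train * 1         # 0/1 weight matrix
    At <- A0 * W

    if (K == 1L) {
      # exact minimizer: all-ones ancestry, training-mean frequencies
      Q <- matrix(1, n, 1)
      f <- colSums(At) / pmax(colSums(W), 1)
      Fm <- matrix(f, 1, L)
      R <- (At - (Q %*% Fm) * W)
      trace <- sum(R^2)
      conv <- TRUE
    } else {
      Q <- rdirichlet(n, rep(1, K))
      f0 <- colSums(At) / pmax(colSums(W), 1)
      Fm <- pmin(pmax(matrix(rep(f0, each = K), K, L) +
                        matrix(rnorm(K * L, sd = 0.05), K, L), 0), 1)
      loss <- function() sum(((Q %*% Fm) * W - At)^2)
      trace <- loss()
      conv <- FALSE
      for (it in seq_len(max_iter)) {
        # F block: projected gradient, step 1/L_F, clip to [0,1]
        LF <- 2 * max(eigen(crossprod(Q), symmetric = TRUE,
                            only.values = TRUE)$values)
        for (s in 1:2) {
          Rm <- (Q %*% Fm) * W - At
          Fm <- pmin(pmax(Fm - (2 / LF) * crossprod(Q, Rm), 0), 1)
        }
        # Q block: projected gradient, step 1/L_Q, simplex-project rows
        LQ <- 2 * max(eigen(tcrossprod(Fm), symmetric = TRUE,
                            only.values = TRUE)$values)
        for (s in 1:2) {
          Rm <- (Q %*% Fm) * W - At
          Qn <- Q - (2 / LQ) * tcrossprod(Rm, Fm)
          Q <- t(apply(Qn, 1, project_simplex))
        }
        cur <- loss()
        trace <- c(trace, cur)
        if (abs(trace[it] - cur) <= tol * max(trace[it], 1)) {
          conv <- TRUE
          break
        }
      }
    }
    # held-out binomial cross-entropy
    P <- pmin(pmax(Q %*% Fm, eps), 1 - eps)
    if (any(ho)) {
      a <- A[ho]; p <- P[ho]
      ce <- -mean(a * log(p) + (1 - a) * log(1 - p))
    } else ce <- NA_real_
    rep_ce[rep] <- ce
    if (is.null(best) || (!is.na(ce) && ce < best$cross_entropy)) {
      best <- list(K = as.integer(K), Q = Q, F = Fm, cross_entropy = ce,
                   loss_trace = trace, converged = conv)
    }
  }
  best$rep_cross_entropy <- rep_ce
  rownames(best$Q) <- rownames(G$dosage)
  colnames(best$F) <- colnames(G$dosage)
  class(best) <- "ancestry_fit"
  best
}

#' @export
print.ancestry_fit <- function(x, ...) {
  cat("ancestry fit: K =", x$K, "; held-out cross-entropy =",
      signif(x$cross_entropy, 5), "\n")
  invisible(x)
}

#' Choose the number of clusters by held-out cross-entropy
#'
#' Fits each K in `k_range` with `n_reps` restarts, averages the held-out
#' cross-entropies, and selects the smallest K whose mean lies within one
#' standard error of the overall minimum (one-standard-error rule; on a flat
#' profile this returns the smallest K).
#'
#' @param G a [genotype_matrix()].
#' @param k_range candidate cluster counts.
#' @param seed integer seed.
#' @param n_reps restarts per K.
#' @param ... passed to [fit_ancestry()].
#' @return list: `K` (selected), `profile` (data.frame k, mean_ce, se),
#'   `scores` (K x reps matrix of per-replicate cross-entropies, usable with
#'   [delta_k()]).
#' @export
select_k <- function(G, k_range = 1:10, seed = 1L, n_reps = 5L, ...) {
  stopifnot(length(k_range) >= 1)
  scores <- matrix(NA_real_, length(k_range), n_reps,
                   dimnames = list(as.character(k_range), NULL))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    for (r in seq_len(n_reps)) {
      fit <- fit_ancestry(G, k, seed = derive_seed(seed, paste0("k", k, "r", r)),
                          n_reps = 1L, ...)
      scores[i, r] <- fit$cross_entropy
    }
  }
  mean_ce <- rowMeans(scores)
  se <- apply(scores, 1, sd) / sqrt(n_reps)
  i_min <- which.min(mean_ce)
  within <- which(mean_ce <= mean_ce[i_min] + se[i_min])
  K <- k_range[min(within)]
  list(K = K,
       profile = data.frame(k = k_range, mean_ce = mean_ce, se = se),
       scores = scores)
}

#' Evanno-style second-difference criterion on replicate scores
#'
#' DeltaK(k) = |mean L(k+1) - 2 mean L(k) + mean L(k-1)| / sd(L(k)),
#' undefined at the endpoints of the K range.  L is a per-replicate model
#' score (log-likelihood, or negative cross-entropy).
#'
#' @param replicate_scores K x reps matrix with rownames giving k values
#'   (consecutive).
#' @return data.frame k, delta_k (NA at endpoints; Inf flagged when the
#'   replicate sd is zero).
#' @export
delta_k <- function(replicate_scores) {
  stopifnot(nrow(replicate_scores) >= 3, ncol(replicate_scores) >= 2)
  kv <- as.numeric(rownames(replicate_scores))
  if (any(diff(kv) != 1)) stop("k values must be consecutive", call. = FALSE)
  m <- rowMeans(replicate_scores)
  s <- apply(replicate_scores, 1, sd)
  dk <- rep(NA_real_, length(kv))
  for (i in 2:(length(kv) - 1)) {
    num <- abs(m[i + 1] - 2 * m[i] + m[i - 1])
    dk[i] <- if (s[i] == 0) {
      warning("zero replicate sd at k = ", kv[i], "; delta K infinite")
      Inf
    } else num / s[i]
  }
  data.frame(k = kv, delta_k = dk)
}

#' Assign individuals to clusters by a membership threshold
#'
#' Individuals whose maximum ancestry fraction falls below `threshold` are
#' labelled "admixed".
#'
#' @param Q individuals x K ancestry matrix.
#' @param threshold minimum membership for a hard assignment.
#' @return character vector ("K1".."Kk" or "admixed").
#' @export
assign_clusters <- function(Q, threshold = 0.70) {
  amax <- apply(Q, 1, which.max)
  qmax <- Q[cbind(seq_len(nrow(Q)), amax)]
  ifelse(qmax >= threshold, paste0("K", amax), "admixed")
}

#' Impute missing genotypes from an ancestry model
#'
#' Missing dosages become round(2 q_i' f_l), clipped to {0,1,2}: the
#' individual-specific expected dosage under the factorization.
#'
#' @param G a [genotype_matrix()].
#' @param model an [fit_ancestry()] result.
#' @return complete `adaptscan_geno`.
#' @export
impute_ancestry <- function(G, model) {
  miss <- which(is.na(G$dosage), arr.ind = TRUE)
  if (nrow(miss) == 0) return(G)
  P <- model$Q %*% model$F
  G$dosage[miss] <- pmin(pmax(round(2 * P[miss]), 0L), 2L)
  G
}
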