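#' Prescreen predictors for collinearity
#'
#' Greedy removal: while any pair of predictors has |r| > `r_max`, the worst
#' pair is found and its lower-priority member dropped.  Priority is a
#' character vector in keep-preference order (e.g. keep PC1 over longitude,
#' altitude over latitude and PC2); predictors not listed rank after listed
#' ones in column order.
#'
#' @param X data.frame or matrix of candidate predictors (>= 2 columns).
#' @param r_max absolute-correlation threshold.
#' @param priority character vector of predictor names, most-preferred first.
#' @return the retained predictor data.frame; attribute `dropped` logs
#'   removals (variable, partner, r).
#' @export
prescreen_predictors <- function(X, r_max = 0.7, priority = NULL) {
  X <- as.data.frame(X)
  if (ncol(X) < 2) stop("need at least two candidate predictors", call. = FALSE)
  rank_of <- function(nm) {
    i <- match(nm, priority)
    ifelse(is.na(i), length(priority) + match(nm, names(X)), i)
  }
  dropped <- data.frame(variable = character(0), partner = character(0),
                        r = numeric(0))
  repeat {
    if (ncol(X) < 2) break
    R <- cor(X)
    diag(R) <- 0
    if (max(abs(R)) <= r_max) break
    ij <- which(abs(R) == max(abs(R)), arr.ind = TRUE)[1, ]
    a <- colnames(R)[ij[1]]; b <- colnames(R)[ij[2]]
    loser <- if (rank_of(a) <= rank_of(b)) b else a
    winner <- setdiff(c(a, b), loser)
    dropped <- rbind(dropped, data.frame(variable = loser, partner = winner,
                                         r = R[ij[1], ij[2]]))
    X <- X[, setdiff(names(X), loser), drop = FALSE]
  }
  if (ncol(X) == 1 && nrow(dropped) > 0)
    message("prescreen reduced predictors to a single variable")
  attr(X, "dropped") <- dropped
  X
}

#' Fit a redundancy analysis from first principles
#'
#' Two-step constrained ordination: multivariate OLS of the column-centered
#' response on the column-centered predictors gives the fitted matrix; the
#' SVD of the fitted matrix gives the constrained axes.  Eigenvalues are
#' squared singular values over (n-1); R-squared is the fitted over total
#' sum of squares; locus loadings are the right singular vectors scaled so
#' each axis' squared loadings sum to its eigenvalue; site scores are the
#' left singular vectors.
#'
#' @param Y response matrix (individuals x loci), complete; centered
#'   internally.
#' @param X predictor data.frame/matrix; centered internally.
#' @param scale response scaling: `"center"` (covariance-style, the
#'   classical default) or `"standardize"` (correlation-style; equalizes
#'   locus variances so high-heterozygosity loci do not dominate the
#'   loading tails).  Constant response columns are only valid with
#'   `"center"`.
#' @return object of class `rda_fit`: coefficients, eigenvalues,
#'   prop_constrained / prop_total axis fractions, loadings, site_scores,
#'   R2, adj_R2, rank, plus the centered matrices for permutation tests.
#' @export
fit_rda <- function(Y, X, scale = c("center", "standardize")) {
  scale <- match.arg(scale)
  Y <- as.matrix(Y); X <- as.matrix(as.data.frame(X))
  stopifnot(nrow(Y) == nrow(X))
  if (anyNA(Y) || anyNA(X)) stop("RDA requires complete data", call. = FALSE)
  n <- nrow(Y)
  Yc <- if (scale == "standardize") {
    sds <- apply(Y, 2, stats::sd)
    if (any(sds == 0))
      stop("constant response columns cannot be standardized", call. = FALSE)
    base::scale(Y)
  } else base::scale(Y, scale = FALSE)
  Xc <- base::scale(X, scale = FALSE)
  qx <- qr(Xc)
  q <- qx$rank
  if (q < ncol(Xc)) warning("rank-deficient predictors: rank ", q, " of ",
                            ncol(Xc))
  if (n <= q + 1) stop("need n > rank(X) + 1", call. = FALSE)
  B <- qr.coef(qx, Yc)
  B[is.na(B)] <- 0
  Yhat <- qr.fitted(qx, Yc)
  r_ax <- min(q, n - 1, ncol(Yc))
  sv <- svd(Yhat, nu = r_ax, nv = r_ax)
  d <- sv$d[seq_len(r_ax)]
  keep <- d > max(d[1], 0) * 1e-10
  d <- d[keep]
  r_ax <- length(d)
  eig <- d^2 / (n - 1)
  tot <- sum(Yc^2) / (n - 1)
  constr <- sum(Yhat^2) / (n - 1)
  R2 <- constr / tot
  adj_R2 <- 1 - (1 - R2) * (n - 1) / (n - q - 1)
  loadings <- sweep(sv$v[, seq_len(r_ax), drop = FALSE], 2,
                    d / sqrt(n - 1), "*")
  site_scores <- sv$u[, seq_len(r_ax), drop = FALSE]
  an <- paste0("RDA", seq_len(r_ax))
  dimnames(loadings) <- list(colnames(Y), an)
  dimnames(site_scores) <- list(rownames(Y), an)
  structure(list(predictors = colnames(X), coefficients = B,
                 eigenvalues = setNames(eig, an),
                 prop_constrained = eig / sum(eig),
                 prop_total = eig / tot,
                 loadings = loadings, site_scores = site_scores,
                 R2 = R2, adj_R2 = adj_R2, rank = q, n = n,
                 total_inertia = tot, constrained_inertia = constr,
                 Yc = Yc, Xc = Xc), class = "rda_fit")
}

#' @export
print.rda_fit <- function(x, ...) {
  cat("RDA:", x$n, "sites,", ncol(x$Yc), "response columns,",
      length(x$predictors), "predictors (rank", x$rank, ")\n")
  cat("R2 =", signif(x$R2, 4), "; adjusted R2 =", signif(x$adj_R2, 4), "\n")
  invisible(x)
}

rda_pseudo_f <- function(constr, tot, n, q) {
  resid <- max(tot - constr, 0)   # guard fp cancellation at perfect fits
  if (resid == 0) return(Inf)
  (constr / q) / (resid / (n - q - 1))
}

#' Global permutation test of a redundancy analysis
#'
#' Pseudo-F = (constrained inertia / q) / (residual inertia / (n - q - 1));
#' the null distribution comes from unrestricted row permutations of the
#' predictor matrix; p = (#{F_perm >= F_obs} + 1) / (n_perm + 1).
#'
#' @param model an [fit_rda()] result.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list: `F`, `p`, `n_perm`.
#' @export
anova_global <- function(model, n_perm = 1000, seed = 1L) {
  n <- model$n; q <- model$rank
  F_obs <- rda_pseudo_f(model$constrained_inertia, model$total_inertia, n, q)
  Qx <- qr.Q(qr(model$Xc))[, seq_len(q), drop = FALSE]
  tot <- model$total_inertia
  set.seed(seed)
  F_perm <- vapply(seq_len(n_perm), function(b) {
    idx <- sample.int(n)
    cs <- sum(crossprod(Qx[order(idx), , drop = FALSE], model$Yc)^2) / (n - 1)
    # permuting rows of X == inverse-permuting rows of its orthonormal basis
    rda_pseudo_f(cs, tot, n, q)
  }, numeric(1))
  p <- (sum(F_perm >= F_obs) + 1) / (n_perm + 1)
  list(F = F_obs, p = p, n_perm = n_perm)
}

#' Sequential per-axis permutation tests
#'
#' Axis a is tested by the pseudo-F of its eigenvalue after partialling the
#' previous axes' site scores out of both response and predictors; testing
#' halts at the first axis with p > `alpha` (subsequent axes get NA).
#'
#' @param model an [fit_rda()] result.
#' @param n_perm permutations per axis.
#' @param seed integer seed (axis a uses seed + a - 1, so the first axis of
#'   a single-predictor model reproduces [anova_global()]).
#' @param alpha stopping threshold.
#' @param max_axes cap on the number of axes tested.
#' @return data.frame: axis, eigenvalue, F, p.
#' @export
anova_axes <- function(model, n_perm = 1000, seed = 1L, alpha = 0.05,
                       max_axes = length(model$eigenvalues)) {
  n <- model$n; q <- model$rank
  n_ax <- min(max_axes, length(model$eigenvalues))
  out <- data.frame(axis = seq_len(n_ax),
                    eigenvalue = unname(model$eigenvalues[seq_len(n_ax)]),
                    F = NA_real_, p = NA_real_)
  for (a in seq_len(n_ax)) {
    if (a == 1) {
      Yr <- model$Yc; Xr <- model$Xc
    } else {
      Z <- model$site_scores[, seq_len(a - 1), drop = FALSE]
      Pz <- diag(n) - Z %*% solve(crossprod(Z), t(Z))
      Yr <- Pz %*% model$Yc
      Xr <- Pz %*% model$Xc
    }
    qr_x <- qr(Xr)
    qa <- qr_x$rank
    Qx <- qr.Q(qr_x)[, seq_len(qa), drop = FALSE]
    tot_r <- sum(Yr^2) / (n - 1)
    df_res <- n - q - 1 - (a - 1)
    first_eig <- function(Yp) {
      fit <- crossprod(Qx, Yp)
      svd(fit, nu = 0, nv = 0)$d[1]^2 / (n - 1)
    }
    lam_obs <- first_eig(Yr)
    constr_r <- sum(crossprod(Qx, Yr)^2) / (n - 1)
    F_obs <- lam_obs / ((tot_r - constr_r) / df_res)
    set.seed(seed + a - 1)
    F_perm <- vapply(seq_len(n_perm), function(b) {
      idx <- sample.int(n)
      Qp <- Qx[order(idx), , drop = FALSE]
      lam <- svd(crossprod(Qp, Yr), nu = 0, nv = 0)$d[1]^2 / (n - 1)
      cs <- sum(crossprod(Qp, Yr)^2) / (n - 1)
      lam / ((tot_r - cs) / df_res)
    }, numeric(1))
    out$F[a] <- F_obs
    out$p[a] <- (sum(F_perm >= F_obs) + 1) / (n_perm + 1)
    if (out$p[a] > alpha) break
  }
  out
}

#' Detect outlier loci from ordination loadings
#'
#' Flags loci whose loading lies more than `sd_mult` standard deviations
#' from the mean loading on any of the first `n_axes` constrained axes;
#' the union over axes is deduplicated, recording the first axis of
#' detection.
#'
#' @param model an [fit_rda()] result.
#' @param n_axes number of (significant) axes to scan.
#' @param sd_mult the SD multiplier of the two-sided rule.
#' @return data.frame: locus, axis, loading.
#' @export
detect_outliers <- function(model, n_axes = 2, sd_mult = 3) {
  n_axes <- min(n_axes, ncol(model$loadings))
  found <- list()
  seen <- character(0)
  for (a in seq_len(n_axes)) {
    ld <- model$loadings[, a]
    lim <- sd_mult * sd(ld)
    hit <- names(ld)[abs(ld - mean(ld)) > lim]
    hit <- setdiff(hit, seen)
    if (length(hit))
      found[[a]] <- data.frame(locus = hit, axis = a,
                               loading = unname(ld[hit]))
    seen <- c(seen, hit)
  }
  if (!length(found))
    return(data.frame(locus = character(0), axis = integer(0),
                      loading = numeric(0)))
  out <- do.call(rbind, found)
  rownames(out) <- NULL
  out
}

#' Assign each outlier locus its most correlated predictor
#'
#' For each flagged locus, the best predictor is the constraining variable
#' with the largest |Pearson r| against the locus dosages; ties break by
#' predictor order.
#'
#' @param outliers data.frame from [detect_outliers()].
#' @param G a [genotype_matrix()] (or dosage matrix) covering the outlier
#'   loci.
#' @param X_full data.frame of the model's constraining variables
#'   (individual-level).
#' @return `outliers` with `predictor` and `r` columns appended.
#' @export
assign_predictor <- function(outliers, G, X_full) {
  if (nrow(outliers) == 0) {
    outliers$predictor <- character(0)
    outliers$r <- numeric(0)
    return(outliers)
  }
  dos <- if (inherits(G, "adaptscan_geno")) G$dosage else as.matrix(G)
  X_full <- as.data.frame(X_full)
  rmat <- suppressWarnings(
    cor(dos[, outliers$locus, drop = FALSE], X_full,
        use = "pairwise.complete.obs"))
  best <- apply(abs(rmat), 1, which.max)   # first max = tie toward order
  outliers$predictor <- names(X_full)[best]
  outliers$r <- rmat[cbind(seq_len(nrow(rmat)), best)]
  outliers
}

#' Redundancy analysis within one genetic cluster
#'
#' Re-runs the full RDA protocol (monomorphic-locus refiltering, collinearity
#' prescreen, fit, global and per-axis permutation tests, loading-based
#' outlier detection, predictor assignment) on the individuals assigned to
#' `target_cluster`.  Clusters smaller than rank(X) + 2 members, and
#' clusters whose global test is non-significant, yield no candidate loci.
#'
#' @param G complete [genotype_matrix()] (imputed).
#' @param cluster_labels per-individual labels (see [assign_clusters()]).
#' @param target_cluster label of the cluster to analyse.
#' @param X candidate predictor data.frame (individual-level, full set; the
#'   prescreen is re-applied within the cluster).
#' @param n_perm,seed,sd_mult,alpha test and outlier parameters.
#' @param priority prescreen priority, as in [prescreen_predictors()].
#' @param scale response scaling passed to [fit_rda()].
#' @return list: `scope`, `model`, `global` (F, p), `axes`, `outliers`
#'   (empty when non-significant), `skipped` flag with `reason`.
#' @export
regional_rda <- function(G, cluster_labels, target_cluster, X,
                         n_perm = 1000, seed = 1L, sd_mult = 3,
                         alpha = 0.05, priority = NULL,
                         scale = c("center", "standardize")) {
  scale <- match.arg(scale)
  sel <- which(cluster_labels == target_cluster)
  X <- as.data.frame(X)
  empty <- data.frame(locus = character(0), axis = integer(0),
                      loading = numeric(0), predictor = character(0),
                      r = numeric(0))
  if (length(sel) < ncol(X) + 2)
    return(list(scope = target_cluster, skipped = TRUE,
                reason = sprintf("cluster %s has %d members; need >= %d",
                                 target_cluster, length(sel), ncol(X) + 2),
                outliers = empty))
  Gs <- G
  Gs$dosage <- G$dosage[sel, , drop = FALSE]
  Gs$samples <- G$samples[sel, , drop = FALSE]
  poly <- apply(Gs$dosage, 2, function(g) var(g) > 0)
  Gs <- subset_loci(Gs, poly)
  Xs <- X[sel, , drop = FALSE]
  keep_var <- vapply(Xs, function(v) sd(v) > 0, logical(1))
  Xs <- prescreen_predictors(Xs[, keep_var, drop = FALSE], priority = priority)
  model <- fit_rda(Gs$dosage, Xs, scale = scale)
  glob <- anova_global(model, n_perm = n_perm, seed = seed)
  if (glob$p > alpha)
    return(list(scope = target_cluster, model = model, global = glob,
                skipped = FALSE, significant = FALSE, outliers = empty,
                reason = "global RDA not significant"))
  axes <- anova_axes(model, n_perm = n_perm, seed = seed, alpha = alpha,
                     max_axes = 2)
  n_sig <- sum(!is.na(axes$p) & axes$p <= alpha)
  out <- detect_outliers(model, n_axes = max(n_sig, 1), sd_mult = sd_mult)
  out <- assign_predictor(out, Gs, Xs)
  if (nrow(out)) out$scope <- target_cluster
  list(scope = target_cluster, model = model, global = glob, axes = axes,
       skipped = FALSE, significant = TRUE, outliers = out)
}
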