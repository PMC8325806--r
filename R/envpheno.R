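#' Principal component analysis of the bioclim table
#'
#' PCA on the correlation matrix: the bioclim variables mix units (degrees C,
#' mm), so each column is standardized to zero mean and unit variance before
#' the eigendecomposition.  Loadings are reported as correlations between
#' variables and component scores; each component is oriented so its
#' largest-magnitude loading is positive.
#'
#' @param env numeric matrix, provenances x variables, no missing values.
#' @return list of class `env_pca`: `loadings` (variable x component
#'   correlations), `explained` (variance fractions, summing to 1),
#'   `scores` (provenance x component, columns PC1, PC2, ...),
#'   `eigenvalues`.
#' @export
env_pca <- function(env) {
  env <- as.matrix(env)
  if (nrow(env) < 2) stop("need at least two rows", call. = FALSE)
  if (anyNA(env)) stop("missing values in environmental table", call. = FALSE)
  sds <- apply(env, 2, sd)
  if (any(sds == 0))
    stop("degenerate (constant) variable: ",
         paste(colnames(env)[sds == 0], collapse = ", "), call. = FALSE)
  Z <- scale(env)
  eig <- eigen(cor(env), symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  scores <- Z %*% eig$vectors
  # loadings as variable-score correlations: eigenvector * sqrt(eigenvalue)
  loadings <- sweep(eig$vectors, 2, sqrt(ev), "*")
  for (j in seq_len(ncol(loadings))) {
    if (loadings[which.max(abs(loadings[, j])), j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  cn <- paste0("PC", seq_len(ncol(scores)))
  dimnames(scores) <- list(rownames(env), cn)
  dimnames(loadings) <- list(colnames(env), cn)
  structure(list(loadings = loadings, explained = ev / sum(ev),
                 scores = scores, eigenvalues = ev), class = "env_pca")
}

#' @export
print.env_pca <- function(x, ...) {
  k <- min(3L, length(x$explained))
  cat("PCA of", nrow(x$loadings), "variables; first", k,
      "components explain", round(100 * sum(x$explained[1:k]), 2), "%\n")
  invisible(x)
}

#' Pearson correlation with two-sided t-test
#'
#' @param a,b numeric vectors of equal length n >= 3.
#' @return list with `r`, `p` (two-sided, from t = r sqrt((n-2)/(1-r^2)) on
#'   n-2 df), and `n`.
#' @export
pearson <- function(a, b) {
  ok <- complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3) stop("need n >= 3 complete pairs", call. = FALSE)
  if (sd(a) == 0 || sd(b) == 0)
    stop("undefined correlation: zero variance input", call. = FALSE)
  ct <- cor.test(a, b, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(a))
}

#' Canonical correlation analysis between two variable groups
#'
#' Canonical correlations and weight vectors via QR-orthonormalized bases and
#' the SVD of their cross-product (stats::cancor); significance of the full
#' set of correlations by Wilks' lambda with Rao's F approximation.
#' Rank-deficient sides are reduced to their column rank with a warning.
#'
#' @param X,Y numeric matrices with the same rows.
#' @return list of class `cancor_result`: `cor` (non-increasing, in [0,1]),
#'   `xcoef`, `ycoef`, `wilks_lambda`, `p` (first canonical pair), `n`.
#' @export
canonical_correlation <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  n <- nrow(X)
  reduce <- function(M, side) {
    Mc <- scale(M, scale = FALSE)
    q <- qr(Mc)
    if (q$rank < ncol(M)) {
      warning("rank-deficient ", side, " side reduced to rank ", q$rank)
      M <- M[, q$pivot[seq_len(q$rank)], drop = FALSE]
    }
    M
  }
  X <- reduce(X, "X"); Y <- reduce(Y, "Y")
  cc <- cancor(X, Y)
  rho <- pmin(pmax(cc$cor, 0), 1)
  p_dim <- ncol(X); q_dim <- ncol(Y)
  lambda <- prod(1 - rho^2)
  # Rao's F approximation for Wilks' lambda
  k <- p_dim * q_dim
  w <- n - 1 - (p_dim + q_dim + 1) / 2
  t_ <- if (p_dim^2 + q_dim^2 - 5 > 0)
    sqrt((k^2 - 4) / (p_dim^2 + q_dim^2 - 5)) else 1
  df2 <- w * t_ - k / 2 + 1
  lam_t <- lambda^(1 / t_)
  Fstat <- ((1 - lam_t) / lam_t) * (df2 / k)
  pval <- pf(Fstat, k, df2, lower.tail = FALSE)
  structure(list(cor = rho, xcoef = cc$xcoef, ycoef = cc$ycoef,
                 wilks_lambda = lambda, F = Fstat, df = c(k, df2), p = pval,
                 n = n), class = "cancor_result")
}

#' Growing-season proxy from phenology scores
#'
#' L = S - A: provenances flushing earliest in spring (high S) and ceasing
#' growth latest in autumn (low A) have the longest growing season.
#'
#' @param pheno data.frame with `spring` and `autumn` columns (or S and A).
#' @return numeric vector L.
#' @export
derive_growing_season <- function(pheno) {
  s <- pheno$spring %||% pheno$S
  a <- pheno$autumn %||% pheno$A
  if (is.null(s) || is.null(a))
    stop("phenotype table must contain spring/autumn (or S/A) columns",
         call. = FALSE)
  s - a
}
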