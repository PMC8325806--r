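#' Polarize alleles by their correlation with a focal variable
#'
#' For each candidate locus, the favored allele is ALT when the Pearson
#' correlation between dosage and the variable is positive and REF otherwise
#' (ties at exactly r = 0 go to REF and are logged).  Monomorphic loci are
#' excluded with a warning.
#'
#' @param G_candidates [genotype_matrix()] (or dosage matrix) restricted to
#'   candidate loci.
#' @param v numeric variable per individual.
#' @return data.frame: locus, r, favored ("ALT" or "REF").
#' @export
polarize_alleles <- function(G_candidates, v) {
  dos <- if (inherits(G_candidates, "adaptscan_geno")) G_candidates$dosage
         else as.matrix(G_candidates)
  if (ncol(dos) == 0) stop("no candidate loci to polarize", call. = FALSE)
  sds <- apply(dos, 2, sd, na.rm = TRUE)
  mono <- is.na(sds) | sds == 0
  if (any(mono)) {
    warning(sum(mono), " monomorphic candidate loci excluded")
    dos <- dos[, !mono, drop = FALSE]
  }
  r <- suppressWarnings(as.numeric(cor(dos, v, use = "pairwise.complete.obs")))
  ties <- !is.na(r) & r == 0
  if (any(ties)) message(sum(ties), " zero-correlation ties polarized to REF")
  data.frame(locus = colnames(dos), r = r,
             favored = ifelse(r > 0, "ALT", "REF"),
             stringsAsFactors = FALSE)
}

#' Additive polygenic scores
#'
#' Per individual, the number of favored alleles summed over the polarized
#' loci: the favored dosage is g at ALT-favored loci and 2 - g at
#' REF-favored loci.  Missing genotypes contribute the locus mean favored
#' dosage (logged via an attribute).
#'
#' @param G_candidates [genotype_matrix()] or dosage matrix covering the
#'   polarized loci.
#' @param favored_map data.frame from [polarize_alleles()].
#' @return named numeric vector of scores, attribute `n_loci`.
#' @export
polygenic_scores <- function(G_candidates, favored_map) {
  dos <- if (inherits(G_candidates, "adaptscan_geno")) G_candidates$dosage
         else as.matrix(G_candidates)
  dos <- dos[, favored_map$locus, drop = FALSE]
  fav <- dos
  flip <- favored_map$favored == "REF"
  fav[, flip] <- 2 - fav[, flip, drop = FALSE]
  if (anyNA(fav)) {
    mu <- colMeans(fav, na.rm = TRUE)
    idx <- which(is.na(fav), arr.ind = TRUE)
    fav[idx] <- mu[idx[, 2]]
  }
  out <- rowSums(fav)
  attr(out, "n_loci") <- ncol(fav)
  out
}

#' Linear and quadratic trend fits with AIC selection
#'
#' Fits score = b0 + b1 v and score = b0 + b1 v + b2 v^2, reporting the
#' linear Pearson R with its two-sided p, the quadratic R^2 with its model-F
#' p, and AIC = n log(RSS/n) + 2k (least-squares form, constants cancel in
#' the within-variable comparison); the best model minimizes AIC.
#'
#' @param scores numeric response (polygenic scores per individual).
#' @param v numeric explanatory variable.
#' @return data.frame of class `trend_fit`: model, R, R2, p, AIC, best.
#' @export
score_models <- function(scores, v) {
  ok <- complete.cases(scores, v)
  scores <- scores[ok]; v <- v[ok]
  n <- length(scores)
  if (n < 4) stop("need n >= 4", call. = FALSE)
  if (sd(v) == 0) stop("zero-variance explanatory variable", call. = FALSE)
  lin <- lm(scores ~ v)
  quad <- lm(scores ~ v + I(v^2))
  aic_ls <- function(fit) {
    rss <- sum(stats::residuals(fit)^2)
    n * log(rss / n) + 2 * length(coef(fit))
  }
  r_lin <- suppressWarnings(cor(scores, v))
  p_lin <- pearson(scores, v)$p
  sq <- summary(quad)
  p_quad <- pf(sq$fstatistic[1], sq$fstatistic[2], sq$fstatistic[3],
               lower.tail = FALSE)
  out <- data.frame(
    model = c("linear", "quadratic"),
    R = c(r_lin, NA_real_),
    R2 = c(summary(lin)$r.squared, sq$r.squared),
    p = c(p_lin, unname(p_quad)),
    AIC = c(aic_ls(lin), aic_ls(quad))
  )
  out$best <- out$AIC == min(out$AIC)
  class(out) <- c("trend_fit", class(out))
  out
}

#' Polygenic score trends across a table of variables
#'
#' Re-polarizes the candidate loci against each variable, recomputes the
#' scores, and fits the linear/quadratic pair, mirroring the per-variable
#' trend table of common-garden association studies.
#'
#' @param G_candidates [genotype_matrix()] or dosage matrix of the combined
#'   candidate loci.
#' @param vars data.frame of individual-level variables.
#' @return list: `table` (variable, linear R/p/AIC, quadratic R2/p/AIC,
#'   best), `scores` (individual x variable matrix).
#' @export
score_trend_table <- function(G_candidates, vars) {
  vars <- as.data.frame(vars)
  rows <- list(); smat <- NULL
  for (nm in names(vars)) {
    pol <- suppressWarnings(polarize_alleles(G_candidates, vars[[nm]]))
    sc <- polygenic_scores(G_candidates, pol)
    fits <- score_models(sc, vars[[nm]])
    rows[[nm]] <- data.frame(
      variable = nm,
      linear_R = fits$R[1], linear_p = fits$p[1], linear_AIC = fits$AIC[1],
      quadratic_R2 = fits$R2[2], quadratic_p = fits$p[2],
      quadratic_AIC = fits$AIC[2],
      best = fits$model[fits$best][1]
    )
    smat <- cbind(smat, sc)
  }
  colnames(smat) <- names(vars)
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       scores = smat)
}

#' Heterozygosity-variable multiple regression with backward elimination
#'
#' Starting from the full linear model of per-individual heterozygosity on
#' all variables, repeatedly drops the coefficient with the largest p-value
#' until every remaining one satisfies p < `alpha`; coefficients are
#' refitted at each step.  If nothing survives, the intercept-only model is
#' returned with a flag.
#'
#' @param het per-individual heterozygosity (response).
#' @param variables data.frame of candidate explanatory variables.
#' @param alpha retention threshold on coefficient p-values.
#' @return list: `fit` (lm), `retained` (variable names), `adj_R2`,
#'   `p` (overall model F-test p; NA for intercept-only),
#'   `intercept_only` flag.
#' @export
het_env_regression <- function(het, variables, alpha = 0.05) {
  variables <- as.data.frame(variables)
  if (ncol(variables) < 2)
    stop("need at least two candidate variables", call. = FALSE)
  dat <- cbind(data.frame(.het = het), variables)
  dat <- dat[complete.cases(dat), ]
  keep <- names(variables)
  repeat {
    if (!length(keep)) break
    fit <- lm(stats::reformulate(keep, ".het"), data = dat)
    cf <- summary(fit)$coefficients
    ps <- cf[-1, 4]
    names(ps) <- rownames(cf)[-1]
    if (all(ps < alpha)) break
    worst <- names(ps)[which.max(ps)]
    # reformulate keeps names verbatim, so direct match is safe
    keep <- setdiff(keep, worst)
  }
  if (!length(keep)) {
    fit <- lm(.het ~ 1, data = dat)
    return(list(fit = fit, retained = character(0), adj_R2 = 0, p = NA_real_,
                intercept_only = TRUE))
  }
  sf <- summary(fit)
  p_overall <- pf(sf$fstatistic[1], sf$fstatistic[2], sf$fstatistic[3],
                  lower.tail = FALSE)
  list(fit = fit, retained = keep, adj_R2 = sf$adj.r.squared,
       p = unname(p_overall), intercept_only = FALSE)
}
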