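#' Partial redundancy analysis
#'
#' Residualizes both the response and the predictors on the conditioning
#' matrix Z by OLS projection, then fits a plain RDA on the residuals.  The
#' permutation test permutes rows of the residualized predictors.
#'
#' @param Y response matrix (individuals x loci), complete.
#' @param X predictor block (data.frame/matrix).
#' @param Z conditioning block; NULL or zero columns reduces to plain RDA.
#' @param n_perm permutations for the significance test (0 skips it).
#' @param seed integer seed.
#' @return list of class `partial_rda`: `model` (an `rda_fit` on residuals),
#'   `inertia` (unique constrained inertia), `F`, `p`.
#' @export
partial_rda <- function(Y, X, Z = NULL, n_perm = 999, seed = 1L) {
  Y <- as.matrix(Y)
  X <- as.matrix(as.data.frame(X))
  if (is.null(Z) || NCOL(Z) == 0 || (is.data.frame(Z) && ncol(Z) == 0)) {
    model <- fit_rda(Y, X)
    test <- if (n_perm > 0) anova_global(model, n_perm, seed) else
      list(F = NA_real_, p = NA_real_)
    return(structure(list(model = model, inertia = model$constrained_inertia,
                          F = test$F, p = test$p, conditioned = FALSE),
                     class = "partial_rda"))
  }
  Z <- as.matrix(as.data.frame(Z))
  stopifnot(nrow(Y) == nrow(X), nrow(Y) == nrow(Z))
  Zc <- scale(Z, scale = FALSE)
  qz <- qr(Zc)
  if (qz$rank < ncol(Zc))
    warning("conditioning matrix not full column rank after centering")
  Yr <- qr.resid(qz, scale(Y, scale = FALSE))
  Xr <- qr.resid(qz, scale(X, scale = FALSE))
  if (all(abs(Xr) < 1e-12)) {
    warning("conditioning block spans the predictors; zero unique inertia")
    return(structure(list(model = NULL, inertia = 0, F = NA_real_,
                          p = NA_real_, conditioned = TRUE),
                     class = "partial_rda"))
  }
  model <- fit_rda(Yr, Xr)
  test <- if (n_perm > 0) anova_global(model, n_perm, seed) else
    list(F = NA_real_, p = NA_real_)
  structure(list(model = model, inertia = model$constrained_inertia,
                 F = test$F, p = test$p, conditioned = TRUE),
            class = "partial_rda")
}

#' Partition candidate-locus variance into geographic, climatic, and
#' phenotypic fractions
#'
#' Four models on the combined candidate-locus genotypes: Model 1 is the
#' simple RDA on all three blocks; Models 2-4 isolate each block's unique
#' fraction by conditioning on the other two; the joint fraction is Model
#' 1's inertia minus the three unique inertias.  Percentages are reported
#' relative to Model 1's constrained inertia (they sum to 100%); the share
#' of total response inertia is also logged.
#'
#' @param Y_candidates complete dosage matrix restricted to the combined
#'   candidate loci.
#' @param geo,climate,pheno predictor blocks (individual-level data.frames).
#' @param n_perm permutations per model.
#' @param seed integer seed.
#' @return object of class `variance_partition`: `table` (model, inertia,
#'   percentage, p), `joint`, `model1_inertia`, `total_inertia`.
#' @export
variance_partition <- function(Y_candidates, geo, climate, pheno,
                               n_perm = 999, seed = 1L) {
  Y <- as.matrix(Y_candidates)
  if (ncol(Y) == 0)
    stop("empty candidate set: run outlier detection first", call. = FALSE)
  geo <- as.data.frame(geo); climate <- as.data.frame(climate)
  pheno <- as.data.frame(pheno)
  full_X <- cbind(geo, climate, pheno)
  m1 <- partial_rda(Y, full_X, NULL, n_perm, derive_seed(seed, "m1"))
  m2 <- partial_rda(Y, geo, cbind(climate, pheno), n_perm,
                    derive_seed(seed, "m2"))
  m3 <- partial_rda(Y, climate, cbind(geo, pheno), n_perm,
                    derive_seed(seed, "m3"))
  m4 <- partial_rda(Y, pheno, cbind(geo, climate), n_perm,
                    derive_seed(seed, "m4"))
  uniq <- c(m2$inertia, m3$inertia, m4$inertia)
  joint <- m1$inertia - sum(uniq)
  if (joint < -1e-8)
    warning("negative joint fraction (", signif(joint, 4),
            "): suppressor structure among blocks")
  pct <- 100 * c(m1$inertia, uniq, joint) / m1$inertia
  tab <- data.frame(
    model = c("Model 1: Geo + Climate + Pheno",
              "Model 2: Geo | Climate + Pheno",
              "Model 3: Climate | Geo + Pheno",
              "Model 4: Pheno | Geo + Climate",
              "Joint: Geo ∩ Climate ∩ Pheno"),
    inertia = c(m1$inertia, uniq, joint),
    percentage = pct,
    p = c(m1$p, m2$p, m3$p, m4$p, NA_real_)
  )
  structure(list(table = tab, joint = joint, model1_inertia = m1$inertia,
                 total_inertia = m1$model$total_inertia,
                 models = list(m1 = m1, m2 = m2, m3 = m3, m4 = m4)),
            class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  tab <- x$table
  tab$inertia <- signif(tab$inertia, 4)
  tab$percentage <- round(tab$percentage, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}
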