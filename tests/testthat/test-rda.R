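# explicit two-step oracle: fitted matrix by lm.fit, then full PCA
rda_oracle <- function(Y, X) {
  Yc <- scale(Y, scale = FALSE)
  Xc <- scale(as.matrix(X), scale = FALSE)
  B <- solve(crossprod(Xc), crossprod(Xc, Yc))
  Yhat <- Xc %*% B
  pc <- prcomp(Yhat, center = FALSE)
  n <- nrow(Y)
  list(eig = pc$sdev^2 * (n - 1) / (n - 1),
       R2 = sum(Yhat^2) / sum(Yc^2),
       Yhat = Yhat, rotation = pc$rotation)
}

test_that("prescreen drops the lower-priority member of collinear pairs", {
  set.seed(51)
  n <- 40
  pc1 <- rnorm(n)
  lon <- -0.95 * pc1 + 0.1 * rnorm(n)     # |r| > 0.9 with PC1
  alt <- rnorm(n)
  X <- data.frame(longitude = lon, PC1 = pc1, altitude = alt)
  kept <- prescreen_predictors(X, r_max = 0.7, priority = c("PC1", "altitude"))
  expect_false("longitude" %in% names(kept))
  expect_true(all(c("PC1", "altitude") %in% names(kept)))
  expect_equal(attr(kept, "dropped")$variable, "longitude")

  # orthogonal predictors pass untouched
  Xo <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  expect_equal(names(prescreen_predictors(Xo)), names(Xo))

  # postcondition: no retained pair above the threshold
  set.seed(52)
  Xbig <- as.data.frame(matrix(rnorm(n * 6), n, 6) %*%
                          matrix(runif(36, -1, 1), 6, 6))
  keptb <- prescreen_predictors(Xbig, r_max = 0.7)
  R <- cor(keptb); diag(R) <- 0
  expect_lte(max(abs(R)), 0.7)
})

test_that("constrained ordination matches the explicit two-step oracle", {
  set.seed(53)
  for (i in 1:5) {
    Y <- matrix(rnorm(30 * 200), 30, 200)
    X <- matrix(rnorm(30 * 4), 30, 4,
                dimnames = list(NULL, paste0("x", 1:4)))
    fit <- fit_rda(Y, X)
    orc <- rda_oracle(Y, X)
    k <- length(fit$eigenvalues)
    expect_equal(unname(fit$eigenvalues), orc$eig[seq_len(k)],
                 tolerance = 1e-8)
    expect_equal(fit$R2, orc$R2, tolerance = 1e-10)
    expect_equal(fit$adj_R2, 1 - (1 - orc$R2) * 29 / (30 - 4 - 1),
                 tolerance = 1e-10)
    # loadings match the oracle rotation up to sign, axis-scaled
    for (a in 1:2) {
      v <- orc$rotation[, a] * sqrt(orc$eig[a])
      s <- sign(sum(v * fit$loadings[, a]))
      expect_lt(max(abs(fit$loadings[, a] - s * v)), 1e-8)
    }
    # conservation: eigenvalues sum to the constrained inertia
    expect_equal(sum(fit$eigenvalues), fit$constrained_inertia,
                 tolerance = 1e-10)
    expect_lt(fit$adj_R2, fit$R2)
  }
})

test_that("constrained ordination agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(54)
  Y <- matrix(rnorm(25 * 40), 25, 40)
  X <- data.frame(a = rnorm(25), b = rnorm(25), c = rnorm(25))
  fit <- fit_rda(Y, X)
  vfit <- vegan::rda(Y ~ a + b + c, data = X)
  expect_equal(unname(fit$eigenvalues),
               unname(vfit$CCA$eig), tolerance = 1e-8)
  expect_equal(fit$R2, unname(vegan::RsquareAdj(vfit)$r.squared),
               tolerance = 1e-8)
  expect_equal(fit$adj_R2, unname(vegan::RsquareAdj(vfit)$adj.r.squared),
               tolerance = 1e-8)
})

test_that("degenerate designs behave as expected", {
  set.seed(55)
  n <- 24
  # X orthogonal to Y by construction: regress X out of Y
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("x1", "x2")))
  Y0 <- matrix(rnorm(n * 30), n, 30)
  Y <- qr.resid(qr(cbind(1, X)), Y0)
  fit0 <- fit_rda(Y, X)
  expect_lt(fit0$R2, 1e-20)
  expect_lt(max(fit0$eigenvalues), 1e-20)

  # noiseless Y = XB: R2 = 1 and constrained axes reproduce the PCA of Y
  B0 <- matrix(rnorm(2 * 30), 2, 30)
  Yn <- X %*% B0
  fit1 <- fit_rda(Yn, X)
  expect_equal(fit1$R2, 1, tolerance = 1e-12)
  pcy <- prcomp(scale(Yn, scale = FALSE), center = FALSE)
  expect_equal(unname(fit1$eigenvalues),
               pcy$sdev[seq_along(fit1$eigenvalues)]^2, tolerance = 1e-8)
})

test_that("global permutation test is exact-bounded and detects signal", {
  set.seed(56)
  n <- 30
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("x1", "x2")))
  Yn <- X %*% matrix(rnorm(2 * 20), 2, 20)   # perfect fit
  fit <- fit_rda(Yn, X)
  t1 <- anova_global(fit, n_perm = 99, seed = 1)
  expect_equal(t1$p, 1 / 100)
  # bounds on any run
  Y <- matrix(rnorm(n * 20), n, 20)
  t2 <- anova_global(fit_rda(Y, X), n_perm = 99, seed = 1)
  expect_gte(t2$p, 1 / 100); expect_lte(t2$p, 1)
})

test_that("axis tests reduce to the global test for one predictor", {
  set.seed(57)
  n <- 28
  X <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "x"))
  Y <- matrix(rnorm(n * 25), n, 25) + X %*% matrix(rnorm(25), 1)
  fit <- fit_rda(Y, X)
  g <- anova_global(fit, n_perm = 199, seed = 7)
  a <- anova_axes(fit, n_perm = 199, seed = 7)
  expect_equal(a$p[1], g$p)

  # noiseless rank-1 signal + weak predictor: first axis significant
  X2 <- cbind(x1 = X[, 1], x2 = rnorm(n))
  Y2 <- cbind(X[, 1] %*% t(rep(1, 10)) * 3,
              matrix(rnorm(n * 40, sd = 1), n, 40))
  fit2 <- fit_rda(Y2, X2)
  a2 <- anova_axes(fit2, n_perm = 199, seed = 8)
  expect_lt(a2$p[1], 0.05)
})

test_that("loading outliers follow the three-SD rule", {
  set.seed(58)
  # synthetic loadings: inject via a model with known loading vector
  n <- 40
  X <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "x"))
  Y <- matrix(rnorm(n * 500), n, 500)
  colnames(Y) <- sprintf("L%03d", 1:500)
  fit <- fit_rda(Y, X)
  out <- detect_outliers(fit, n_axes = 1, sd_mult = 3)
  ld <- fit$loadings[, 1]
  manual <- names(ld)[abs(ld - mean(ld)) > 3 * sd(ld)]
  expect_setequal(out$locus, manual)
  # an infinite multiplier flags nothing
  expect_equal(nrow(detect_outliers(fit, sd_mult = Inf)), 0)
  # deduplication across axes records the first axis of detection
  fit2 <- fit_rda(Y, cbind(x1 = X[, 1], x2 = rnorm(n)))
  out2 <- detect_outliers(fit2, n_axes = 2)
  expect_false(anyDuplicated(out2$locus) > 0)
})

test_that("predictor assignment picks the strongest correlate", {
  set.seed(59)
  n <- 60
  pc1 <- rnorm(n); alt <- rnorm(n)
  X <- data.frame(PC1 = pc1, altitude = alt)
  dos <- cbind(L1 = round(pmin(pmax(pc1 + rnorm(n, sd = 0.3) + 1, 0), 2)),
               L2 = round(pmin(pmax(alt + rnorm(n, sd = 0.3) + 1, 0), 2)))
  out <- data.frame(locus = c("L1", "L2"), axis = 1L, loading = c(1, -1))
  asg <- assign_predictor(out, dos, X)
  expect_equal(asg$predictor, c("PC1", "altitude"))
  # invariant under predictor rescaling
  asg2 <- assign_predictor(out, dos,
                           data.frame(PC1 = 100 * pc1 + 5, altitude = -alt))
  expect_equal(asg2$predictor, asg$predictor)
})

test_that("regional analysis reduces to global for a single cluster", {
  sim <- simulate_dataset(small_cfg(seed = 6, missing_rate = 0,
                                    n_snps = 150, n_ind = 30))
  G <- impute_major(sim$geno)
  fac <- factor_of_individuals(sim)
  X <- data.frame(f = fac, noise = rnorm(30))
  labels <- rep("K1", 30)
  reg <- regional_rda(G, labels, "K1", X, n_perm = 99, seed = 3)
  expect_false(reg$skipped)
  glob_model <- fit_rda(subset_loci(G, apply(G$dosage, 2,
                                             function(g) var(g) > 0))$dosage,
                        prescreen_predictors(X))
  expect_equal(reg$model$R2, glob_model$R2, tolerance = 1e-12)

  # too-small cluster is skipped with a reason
  labels2 <- c("K2", rep("K1", 29))
  reg2 <- regional_rda(G, labels2, "K2", X, n_perm = 49, seed = 3)
  expect_true(reg2$skipped)
  expect_match(reg2$reason, "members")
})

test_that("a cline confined to one cluster is found regionally, not globally", {
  set.seed(60)
  n <- 60
  labels <- rep(c("K1", "K2"), each = n / 2)
  env <- rnorm(n)
  # locus with a strong cline only inside K1; others pure noise
  p_special <- ifelse(labels == "K1", plogis(2.5 * env), 0.5)
  dos <- cbind(matrix(rbinom(n * 120, 2, 0.5), n, 120),
               rbinom(n, 2, p_special))
  colnames(dos) <- sprintf("L%03d", 1:121)
  G <- toy_geno(dos, pos = 1:121)
  X <- data.frame(env = env, noise = rnorm(n))
  reg <- regional_rda(G, labels, "K1", X, n_perm = 199, seed = 4,
                      alpha = 0.3)
  glob <- fit_rda(G$dosage, X)
  glob_out <- detect_outliers(glob, n_axes = 1)
  expect_true("L121" %in% reg$outliers$locus)
  expect_false("L121" %in% glob_out$locus)
})
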