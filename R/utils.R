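#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef cor cor.test lm median pchisq pf prcomp pt qchisq
#'   quantile rbeta rbinom rgamma rnorm rpois runif sd setNames var anova
#'   p.adjust cancor complete.cases plogis qlogis
#' @importFrom utils head modifyList read.delim write.table
NULL

# Derive a stage-specific seed from a master seed so stages are reproducible
# in isolation.  Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 2654435L + h * 97L) %% 2147483629)
}

# Dirichlet draws via gamma normalisation; alpha is a length-K vector or
# n x K matrix.
rdirichlet <- function(n, alpha) {
  if (is.matrix(alpha)) {
    stopifnot(nrow(alpha) == n)
    x <- matrix(rgamma(length(alpha), shape = alpha), nrow = n)
  } else {
    x <- matrix(rgamma(n * length(alpha), shape = rep(alpha, each = n)), nrow = n)
  }
  x / rowSums(x)
}

# Euclidean projection of a vector onto the probability simplex (Duchi et al.
# style sort-and-threshold).
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u) - 1
  rho <- max(which(u - css / seq_along(u) > 0))
  theta <- css[rho] / rho
  pmax(v - theta, 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
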