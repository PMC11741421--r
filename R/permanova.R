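## Permutational distance-matrix linear model (PERMANOVA), used as the
## comparison method in the phylogenetic simulation study. Implemented from
## the McArdle-Anderson construction (Gower-centered inner products,
## pseudo-F, permutation p-value).

#' Gower-center a squared-distance matrix
#'
#' `G = -1/2 J (d o d) J` with `J = I - 11'/n`. The trace of `G` equals the
#' total sum of squares of any Euclidean embedding of `d`.
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @return the centered inner-product matrix `G` (row sums zero).
#' @export
gower_center <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  n <- nrow(d)
  a0 <- -0.5 * d^2
  rm_ <- rowMeans(a0); cm <- colMeans(a0); gm <- mean(a0)
  G <- a0 - outer(rm_, rep(1, n)) - outer(rep(1, n), cm) + gm
  (G + t(G)) / 2
}

#' PERMANOVA with a single covariate
#'
#' Partitions the Gower-centered distance structure by the hat matrix of the
#' intercept + covariate design: `R^2 = tr(H G H) / tr(G)`, pseudo-F from
#' the partition, and a permutation p-value from `n_permutations` random
#' relabelings (permutation of the distance matrix rows/columns, equivalent
#' to permuting residuals under the intercept-only reduced model).
#'
#' @param d symmetric distance matrix.
#' @param covariate numeric or binary vector aligned with `d`.
#' @param n_permutations number of permutations (default 999).
#' @param seed integer seed.
#' @return list of class `permanova_result`: `r2`, `pseudo_f`, `p_value`,
#'   `n_permutations`.
#' @export
permanova_test <- function(d, covariate, n_permutations = 999L, seed = 1L) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 4) stop("need n >= 4")
  covariate <- as.numeric(covariate)
  if (length(covariate) != n) stop("covariate must align with d")
  if (sd(covariate) == 0) stop("constant covariate")
  G <- gower_center(d)
  sst <- sum(diag(G))
  xc <- covariate - mean(covariate)
  ## with one centered covariate the explained SS is x'Gx / x'x
  ss_exp <- function(x) as.numeric(crossprod(x, G %*% x) / crossprod(x))
  obs <- ss_exp(xc)
  f_of <- function(ss) (ss / 1) / ((sst - ss) / (n - 2))
  f_obs <- f_of(obs)
  perm_f <- with_seed(seed, {
    P <- matrix(0, n, n_permutations)
    for (j in seq_len(n_permutations)) P[, j] <- xc[sample.int(n)]
    GP <- G %*% P
    ss <- colSums(P * GP) / colSums(P^2)
    f_of(ss)
  })
  p <- (1 + sum(perm_f >= f_obs)) / (1 + n_permutations)
  structure(list(r2 = obs / sst, pseudo_f = f_obs, p_value = p,
                 n_permutations = as.integer(n_permutations)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: R2 = %.4f, pseudo-F = %.3f, p = %.4g (%d permutations)\n",
              x$r2, x$pseudo_f, x$p_value, x$n_permutations))
  invisible(x)
}
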