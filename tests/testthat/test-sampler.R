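# The HMC engine itself: analytic gradients against finite differences and
# posterior correctness on a conjugate-style reference fit.

fd_grad <- function(id, data, th, eps = 1e-6) {
  vapply(seq_along(th), function(j) {
    tp <- th; tm <- th
    tp[j] <- tp[j] + eps; tm[j] <- tm[j] - eps
    (strainepi:::.model_logp_grad(id, data, tp)$lp -
       strainepi:::.model_logp_grad(id, data, tm)$lp) / (2 * eps)
  }, numeric(1))
}

test_that("model gradients match finite differences", {
  withr::with_seed(42, {
    n <- 12; p <- 2
    X <- cbind(1, rnorm(n))
    om <- tree_to_correlation(ape::rtree(n))
    L <- chol_psd(om$omega)
    y <- rnorm(n)
    yb <- rbinom(n, 1, .5)
    G <- 5
    Z <- matrix(rbinom(n * G, 1, .5), n, G)
    P <- 4; N <- 40
    cases <- list(
      list("pglmm", list(y = y, X = X, L = L, family = 0L, regularized = TRUE,
                         beta_sd = 5, sp_df = 3, sp_scale = 2.5, sr_df = 3,
                         sr_scale = 2.5), p + n + 2),
      list("pglmm", list(y = yb, X = X, L = L, family = 1L,
                         regularized = FALSE, beta_sd = 5, sp_df = 3,
                         sp_scale = 1, sr_df = 3, sr_scale = 2.5), p + n + 1),
      list("glm", list(y = y, X = X, family = 0L, beta_sd = 5, sr_df = 3,
                       sr_scale = 2.5), p + 1),
      list("pathway", list(y = rnorm(N), x = rnorm(N),
                           g = rbinom(N, 1, .5) + 0,
                           pidx = as.integer(sample(0:(P - 1), N, TRUE)),
                           P = P, EM = 0.3), 2 + 2 * P + 3),
      list("horseshoe", list(y = yb, X = X, Z = Z, family = 1L, beta_sd = 5,
                             tau0 = 0.05, slab_scale = 2.5, slab_df = 4),
           p + 2 * G + 2))
    for (cs in cases) {
      th <- rnorm(cs[[3]], 0, 0.5)
      r <- strainepi:::.model_logp_grad(cs[[1]], cs[[2]], th)
      gn <- fd_grad(cs[[1]], cs[[2]], th)
      expect_lt(max(abs(r$grad - gn) / pmax(1, abs(gn))), 1e-5)
    }
  })
})

test_that("sampler reproduces the reference linear-model posterior", {
  withr::with_seed(44, {
    n <- 250
    x <- rnorm(n)
    y <- 1 + 2 * x + rnorm(n, 0, 0.7)
  })
  fit <- suppressWarnings(fit_base_glm(
    y, matrix(x), "gaussian",
    settings = sampler_settings(chains = 2, warmup = 500, draws = 1000,
                                seed = 7)))
  ref <- lm(y ~ x)
  est <- colMeans(fit$draws[, 1:2])
  se_ref <- summary(ref)$coefficients[, 2]
  expect_lt(max(abs(est - coef(ref)) / se_ref), 0.3)
  expect_equal(mean(exp(fit$draws[, 3])), summary(ref)$sigma,
               tolerance = 0.05)
  # posterior spread matches the sampling-theory standard errors
  expect_equal(unname(apply(fit$draws[, 1:2], 2, sd)), unname(se_ref),
               tolerance = 0.2)
})

test_that("sampler runs are reproducible given a seed", {
  withr::with_seed(45, {
    y <- rnorm(40)
  })
  s <- sampler_settings(chains = 1, warmup = 200, draws = 100, seed = 9)
  f1 <- suppressWarnings(fit_base_glm(y, NULL, "gaussian", settings = s))
  f2 <- suppressWarnings(fit_base_glm(y, NULL, "gaussian", settings = s))
  expect_identical(f1$draws, f2$draws)
})

test_that("split-Rhat flags stuck chains and passes mixed ones", {
  withr::with_seed(46, {
    good <- list(matrix(rnorm(600), 300), matrix(rnorm(600), 300))
    stuck <- list(matrix(rnorm(600), 300), matrix(rnorm(600, 4), 300))
  })
  expect_lt(max(split_rhat(good)), 1.02)
  expect_gt(max(split_rhat(stuck)), 1.5)
})

test_that("Gauss-Hermite rule integrates Gaussian moments exactly", {
  gh <- strainepi:::gauss_hermite(21)
  expect_equal(sum(gh$weights), sqrt(pi))
  expect_equal(sum(gh$weights * gh$nodes^2), sqrt(pi) / 2)
  expect_equal(sum(gh$weights * gh$nodes^4), 3 * sqrt(pi) / 4)
  # E[X^2] under N(m, v) via the substitution used in the likelihood code
  m <- 0.7; v <- 1.9
  ex2 <- sum(gh$weights / sqrt(pi) * (m + sqrt(2 * v) * gh$nodes)^2)
  expect_equal(ex2, m^2 + v)
})

test_that("PSIS smoothing preserves well-behaved weights and flags heavy tails", {
  withr::with_seed(47, {
    lr <- rnorm(2000, 0, 0.3)          # light-tailed ratios
    sm <- psis_smooth(lr)
    expect_lt(sm$pareto_k, 0.5)
    # smoothing may pull the largest raw weight down, never up past the cap
    expect_lte(max(sm$log_weights), 0)
    expect_gt(max(sm$log_weights), -0.5)
    # order preserved outside the smoothed tail
    expect_equal(order(sm$log_weights)[1:100], order(lr - max(lr))[1:100])
    heavy <- log(1 / runif(2000)^2)     # k = 2: far beyond reliable range
    smh <- psis_smooth(heavy)
    expect_gt(smh$pareto_k, 0.7)
  })
})
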