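test_that("tree correlation: star trees give the identity", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  om <- tree_to_correlation(star)
  expect_equal(unname(om$omega), diag(4))
})

test_that("tree correlation matches the shared-path computation", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  om <- tree_to_correlation(tr)
  expect_equal(om$omega["A", "B"], 0.5)
  expect_equal(om$omega["A", "C"], 0)
  expect_equal(diag(om$omega), setNames(rep(1, 3), om$leaf_order))
})

test_that("ultrametric trees satisfy omega = 1 - d / (2 depth)", {
  withr::with_seed(21, tr <- ape::compute.brlen(ape::rtree(8)))
  tr <- ape::chronos(tr, quiet = TRUE)
  class(tr) <- "phylo"
  om <- tree_to_correlation(tr)
  d <- ape::cophenetic.phylo(tr)[om$leaf_order, om$leaf_order]
  depth <- max(ape::node.depth.edgelength(tr))
  expect_equal(unname(om$omega), unname(1 - d / (2 * depth)),
               tolerance = 1e-6)
})

test_that("phylogenetic R2 matches brute-force per-draw computation", {
  fake <- structure(list(sigma_p = c(1, 2, 0.1), sigma_r = c(1, 1, 2),
                         family = "gaussian"), class = "pglmm_fit")
  r2 <- phylo_r2(fake)
  expect_equal(r2$draws, fake$sigma_p^2 / (fake$sigma_p^2 + fake$sigma_r^2))
  expect_equal(phylo_r2(structure(list(sigma_p = c(3, 3), sigma_r = c(3, 3),
                                       family = "gaussian"),
                                  class = "pglmm_fit"))$draws, c(0.5, 0.5))
  fake$family <- "bernoulli"
  expect_error(phylo_r2(fake), "bernoulli")
})

test_that("null data yield near-zero posterior phylogenetic share", {
  sim <- simulate_phylo_dataset(200, sigma_p = 0, sigma_r = 1, seed = 41)
  expect_equal(sim$true_r2, 0)
  expect_equal(sd(sim$outcome), 1, tolerance = 0.25)
  fit <- suppressWarnings(fit_pglmm(sim$outcome, NULL, sim$omega, "gaussian",
                                    settings = test_settings(seed = 41)))
  expect_lt(phylo_r2(fit)$mean, 0.1)
})

test_that("integrated predictive collapses correctly when omega = identity", {
  # with an identity correlation the conditional law of each leaf effect is
  # its marginal: predictive = Normal(x b, sqrt(sigma_r^2 + sigma_p^2))
  n <- 6; S <- 50
  withr::with_seed(31, {
    fake <- structure(list(
      y = rnorm(n), X = matrix(1, n, 1), omega = diag(n),
      u = matrix(rnorm(S * n), S, n), beta = matrix(rnorm(S), S, 1),
      sigma_p = rexp(S) + .2, sigma_r = rexp(S) + .2,
      family = "gaussian", leaf_order = paste0("l", 1:n)),
      class = "pglmm_fit")
  })
  lo <- suppressWarnings(loo_elpd(fake))
  ll_direct <- sapply(seq_len(n), function(i)
    dnorm(fake$y[i], fake$beta[, 1],
          sqrt(fake$sigma_p^2 + fake$sigma_r^2), log = TRUE))
  expect_equal(lo$pointwise,
               apply(ll_direct, 2, function(l) {
                 sm <- psis_smooth(-l)
                 lw <- sm$log_weights - strainepi:::logsumexp(sm$log_weights)
                 strainepi:::logsumexp(lw + l)
               }))
})

test_that("bernoulli quadrature reduces to plug-in likelihood as sigma_p -> 0", {
  n <- 5; S <- 40
  withr::with_seed(32, {
    fake <- structure(list(
      y = rbinom(n, 1, .5), X = matrix(1, n, 1), omega = diag(n),
      u = matrix(0, S, n), beta = matrix(rnorm(S), S, 1),
      sigma_p = rep(1e-8, S), sigma_r = NULL,
      family = "bernoulli", leaf_order = paste0("l", 1:n)),
      class = "pglmm_fit")
  })
  lo <- suppressWarnings(loo_elpd(fake))
  eta <- fake$beta[, 1]
  ll <- sapply(seq_len(n), function(i)
    if (fake$y[i] == 1) plogis(eta, log.p = TRUE)
    else plogis(-eta, log.p = TRUE))
  direct <- apply(ll, 2, function(l) {
    sm <- psis_smooth(-l)
    lw <- sm$log_weights - strainepi:::logsumexp(sm$log_weights)
    strainepi:::logsumexp(lw + l)
  })
  expect_equal(lo$pointwise, direct, tolerance = 1e-6)
})

test_that("self-comparison of the base model stays within noise", {
  withr::with_seed(33, {
    n <- 80
    y <- rnorm(n)
  })
  b1 <- suppressWarnings(
    fit_base_glm(y, NULL, "gaussian", settings = test_settings(seed = 51)))
  b2 <- suppressWarnings(
    fit_base_glm(y, NULL, "gaussian", settings = test_settings(seed = 52)))
  l1 <- strainepi:::psis_loo_pointwise(b1$loglik)
  l2 <- strainepi:::psis_loo_pointwise(b2$loglik)
  dif <- l1$elpd - l2$elpd
  se <- sqrt(n * var(dif))
  expect_lt(abs(sum(dif)), 2 * se + 0.5)
})

test_that("strong phylogenetic signal produces a positive ELPD call", {
  sim <- simulate_phylo_dataset(100, sigma_p = 2.09, sigma_r = 0.418,
                                seed = 61)
  cmp <- suppressWarnings(compare_models(sim$outcome, NULL, sim$omega,
                                         "gaussian",
                                         settings = test_settings(seed = 61)))
  expect_true(cmp$positive_call)
  expect_gt(cmp$elpd_diff, 0)
  expect_equal(cmp$elpd_diff, cmp$elpd_pglmm - cmp$elpd_base)
  expect_equal(cmp$se_diff,
               sqrt(nrow(cmp$pointwise) *
                      var(cmp$pointwise[, 1] - cmp$pointwise[, 2])))
})

test_that("bernoulli PGLMM runs and detects lineage-structured risk", {
  sim <- simulate_phylo_dataset(80, sigma_p = 2, sigma_r = 1e-9, seed = 71)
  yb <- as.integer(sim$outcome > median(sim$outcome))
  names(yb) <- names(sim$outcome)
  fit <- suppressWarnings(fit_pglmm(yb, NULL, sim$omega, "bernoulli",
                                    settings = test_settings(seed = 71)))
  expect_null(fit$sigma_r)
  expect_equal(colnames(fit$u), sim$omega$leaf_order)
  lo <- suppressWarnings(loo_elpd(fit))
  expect_length(lo$pointwise, 80)
  expect_true(all(is.finite(lo$pointwise)))
})
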