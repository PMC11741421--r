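make_2x2_data <- function(tab) {
  # tab = matrix [[control&absent, control&present], [case&absent, case&present]]
  y <- rep(c(0, 1), rowSums(tab))
  pres <- c(rep(0:1, tab[1, ]), rep(0:1, tab[2, ]))
  ids <- sprintf("s%03d", seq_along(y))
  list(m = gene_matrix(matrix(pres, 1, dimnames = list("g1", ids))),
       meta = sample_metadata(ids, y))
}

test_that("per-gene logistic coefficient equals the closed-form log odds ratio", {
  d <- make_2x2_data(rbind(c(30, 10), c(10, 30)))
  res <- fit_gene_glms(d$m, d$meta)
  expect_equal(res$coefficient, log(9), tolerance = 1e-6)
  # presence independent of outcome: identical tables in both groups
  d0 <- make_2x2_data(rbind(c(20, 20), c(20, 20)))
  expect_equal(fit_gene_glms(d0$m, d0$meta)$coefficient, 0, tolerance = 1e-8)
})

test_that("constant covariates do not change the gene coefficient", {
  d <- make_2x2_data(rbind(c(25, 15), c(12, 28)))
  base <- fit_gene_glms(d$m, d$meta)
  meta2 <- sample_metadata(d$meta$sample_ids, d$meta$outcome,
                           covariates = data.frame(
                             batch = rep(1, length(d$meta$sample_ids))))
  withcov <- fit_gene_glms(d$m, meta2)
  expect_equal(withcov$coefficient, base$coefficient, tolerance = 1e-6)
})

test_that("constant genes are skipped and separation is flagged", {
  ids <- sprintf("s%02d", 1:20)
  y <- rep(c(0, 1), each = 10)
  pres <- rbind(g_const = rep(1, 20),
                g_sep = y,                      # perfect separation
                g_ok = rep(c(0, 1), 10))
  colnames(pres) <- ids
  m <- gene_matrix(pres)
  meta <- sample_metadata(ids, y)
  expect_warning(res <- fit_gene_glms(m, meta), "constant")
  expect_false("g_const" %in% res$gene)
  expect_true(is.na(res$coefficient[res$gene == "g_sep"]))
  # separated gene excluded from BH
  expect_true(is.na(res$q_value[res$gene == "g_sep"]))
  expect_true(is.finite(res$q_value[res$gene == "g_ok"]))
})

test_that("BH adjustment matches a brute-force implementation", {
  brute_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    running <- Inf
    for (i in m:1) {
      running <- min(running, m * p[o[i]] / i)
      q[o[i]] <- min(running, 1)
    }
    q
  }
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  withr::with_seed(8, {
    for (len in c(3, 17, 200, 1000)) {
      p <- runif(len)^2
      expect_equal(bh_adjust(p), brute_bh(p))
    }
  })
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("hit calling uses a strict threshold", {
  a <- data.frame(species = "x", gene = c("a", "b", "c"),
                  coefficient = 1, std_error = 1, p_value = 0.01,
                  q_value = c(0.049, 0.05, 0.2), is_hit = NA)
  class(a) <- c("gene_associations", "data.frame")
  out <- call_gene_hits(a, 0.05)
  expect_equal(out$is_hit, c(TRUE, FALSE, FALSE))
  empty <- a[0, ]
  expect_equal(nrow(call_gene_hits(empty)), 0L)
})

test_that("horseshoe finds a single strongly predictive gene", {
  withr::with_seed(77, {
    n <- 300; G <- 30
    pres <- matrix(rbinom(n * G, 1, 0.5), G, n,
                   dimnames = list(sprintf("g%02d", 1:G),
                                   sprintf("s%03d", 1:n)))
    y <- rbinom(n, 1, plogis(-1.5 + 3 * pres[1, ]))
  })
  gm <- gene_matrix(pres)
  meta <- sample_metadata(colnames(pres), y)
  hs <- suppressWarnings(
    fit_gene_horseshoe(gm, meta, settings = test_settings(seed = 3)))
  g1 <- hs[hs$gene == "g01", ]
  expect_gt(g1$interval_low, 0)
  expect_true(g1$is_hit)
  # sparse prior shrinks null genes: no other hit at default thresholds
  expect_equal(sum(hs$is_hit), 1L)
  expect_equal(formals(horseshoe_config)$p0, 0.01)
})

test_that("horseshoe collapses duplicate presence patterns", {
  withr::with_seed(5, {
    n <- 80
    pres <- rbind(gA = rbinom(n, 1, .5), gC = rbinom(n, 1, .5))
    pres <- rbind(pres, gB = pres["gA", ])   # exact duplicate of gA
    colnames(pres) <- sprintf("s%02d", 1:n)
    y <- rbinom(n, 1, .5)
  })
  hs <- suppressWarnings(fit_gene_horseshoe(
    gene_matrix(pres), sample_metadata(colnames(pres), y),
    settings = test_settings(warmup = 200, draws = 200)))
  expect_setequal(hs$gene, c("gA", "gB", "gC"))
  expect_equal(hs$coefficient[hs$gene == "gA"],
               hs$coefficient[hs$gene == "gB"])
  expect_equal(hs$collapsed_with[hs$gene == "gB"], "gA")
})
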