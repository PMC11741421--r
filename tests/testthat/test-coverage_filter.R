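test_that("sample statistics: zeros excluded, natural log, degenerate cases", {
  m <- gene_matrix(cbind(s1 = c(0, 0, exp(2), exp(4)),
                         s2 = c(0, 0, 0, 0)),
                   gene_ids = paste0("g", 1:4))
  st <- sample_stats(m)
  expect_equal(st$n_nonzero, c(2L, 0L))
  expect_equal(st$median_log_nonzero[1], 3)
  expect_true(is.na(st$median_log_nonzero[2]))
  # permuting gene order changes nothing
  m2 <- gene_matrix(m$abundance[c(3, 1, 4, 2), , drop = FALSE])
  expect_equal(sample_stats(m2)[, -1], st[, -1])
})

test_that("k-means labeling separates clear coverage clouds exactly", {
  m <- two_cloud_matrix(n_well = 12, n_poor = 10)
  lab <- kmeans_coverage_label(sample_stats(m), seed = 1)
  expect_equal(lab$labels$label,
               rep(c("well_covered", "poorly_covered"), c(12, 10)))
  # all-zero samples are labeled poor without entering the clustering
  ab <- cbind(m$abundance, zero = 0)
  lab0 <- kmeans_coverage_label(sample_stats(gene_matrix(ab)), seed = 1)
  expect_equal(lab0$labels$label[23], "poorly_covered")
})

test_that("k-means labels are invariant to sample order and duplication", {
  m <- two_cloud_matrix(seed = 7)
  lab <- kmeans_coverage_label(sample_stats(m), seed = 5)
  perm <- withr::with_seed(2, sample(ncol(m$abundance)))
  mp <- gene_matrix(m$abundance[, perm])
  labp <- kmeans_coverage_label(sample_stats(mp), seed = 5)
  expect_equal(labp$labels$label[match(lab$labels$sample_id,
                                       labp$labels$sample_id)],
               lab$labels$label)
  # duplicating every sample leaves each original's label unchanged
  ab2 <- cbind(m$abundance, m$abundance)
  colnames(ab2) <- c(m$sample_ids, paste0(m$sample_ids, "_dup"))
  lab2 <- kmeans_coverage_label(sample_stats(gene_matrix(ab2)), seed = 5)
  expect_equal(lab2$labels$label[seq_along(m$sample_ids)], lab$labels$label)
})

test_that("fewer than two eligible samples yields all-poor with warning", {
  m <- gene_matrix(cbind(s1 = c(1, 2), s2 = c(0, 0)))
  expect_warning(lab <- kmeans_coverage_label(sample_stats(m)), "fewer than 2")
  expect_true(all(lab$labels$label == "poorly_covered"))
})

test_that("prevalence bounds follow floor(fraction * N) with kept equality", {
  expect_equal(unname(prevalence_bounds(1262)), c(6, 1256))
  expect_equal(unname(prevalence_bounds(10)), c(0, 10))
  # N = 10: t = 0, nothing removed by either bound
  m <- gene_matrix(matrix(c(rep(0, 10), rep(1, 10), rbinom(80, 1, .5)),
                          10, 10, byrow = TRUE))
  expect_equal(nrow(prevalence_filter(m, 0.005)$abundance), 10)
  # counts equal to the bounds are kept; strictly outside are removed
  n <- 600  # t = 3
  ab <- rbind(rep(1, n),                      # count n > n - t: removed
              c(rep(1, 3), rep(0, n - 3)),    # count == t: kept
              c(rep(1, 2), rep(0, n - 2)),    # count < t: removed
              c(rep(0, 3), rep(1, n - 3)))    # count == n - t: kept
  f <- prevalence_filter(gene_matrix(ab), 0.005)
  expect_equal(f$gene_ids, c("g2", "g4"))
})

test_that("binarization is the indicator of positive abundance, idempotent", {
  m <- gene_matrix(cbind(s1 = c(0, 0.3, 7.1), s2 = c(0, 0, 0)))
  b <- binarize_presence(m)
  expect_equal(unname(b$abundance[, 1]), c(0, 1, 1))
  expect_equal(unname(b$abundance[, 2]), c(0, 0, 0))
  expect_identical(binarize_presence(b)$abundance, b$abundance)
})

test_that("filter pipeline binarizes unchanged data on the no-op path", {
  withr::with_seed(4, {
    ab <- matrix(rexp(40 * 30), 40, 30)   # all mid-prevalence, one cloud
    ab[ab < 0.4] <- 0
  })
  m <- gene_matrix(ab)
  res <- suppressWarnings(filter_pipeline(m, fraction = 0.005, seed = 2))
  keep <- res$labels$labels$label == "well_covered"
  expect_equal(ncol(res$matrix$abundance), sum(keep))
  expect_true(all(res$matrix$abundance %in% c(0, 1)))
})

test_that("final prevalence threshold uses the post-dropping sample count", {
  # 410 samples (t = 2) drop to 205 well covered (t = 1). A gene carried by
  # one well and one poor sample passes the initial filter (count 2 >= 2);
  # after the poor half is dropped its count is 1 — below the stale t = 2
  # but exactly at the recomputed t = 1, so it must survive.
  m <- two_cloud_matrix(n_well = 205, n_poor = 205, n_genes = 300, seed = 9)
  rare <- rep(0, 410)
  rare[c(1, 210)] <- 5               # one well + one poor carrier
  ab <- rbind(m$abundance, rare = rare)
  res <- filter_pipeline(gene_matrix(ab), fraction = 0.005, seed = 3)
  surv <- res$labels$labels$label == "well_covered"
  expect_equal(sum(surv), 205)
  expect_true("rare" %in% res$matrix$gene_ids)
  # and the stale threshold would have removed it
  expect_lt(sum(res$matrix$abundance["rare", ] > 0),
            prevalence_bounds(410)["lower"])
})

test_that("planted poorly covered subjects are removed by the pipeline", {
  sim <- simulate_gene_dataset(gene_sim_config(n_per_group = 60,
                                               n_genes = 400), seed = 31)
  res <- suppressWarnings(filter_pipeline(sim$genes, seed = 31))
  surv <- res$matrix$sample_ids
  # the filter errs conservative: very few truly-poor samples survive
  frac_poor_surviving <- mean(sim$truth$poor_samples %in% surv)
  expect_lt(frac_poor_surviving, 0.25)
})
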