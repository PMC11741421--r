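# Small fixtures built in code, shared across test files.

# tiny stratified HUMAnN-style abundance TSV on disk; returns the path
write_demo_stratified_tsv <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c(
    "# Gene Family\tsampleA\tsampleB",
    "SpecA|g1\t1.5\t0",
    "SpecA|g2\t0\t2.25",
    "UNMAPPED\t10\t12",
    "SpecB|g1\t3\t4"), path)
  path
}

# deterministic gene matrix with two well-separated coverage clouds:
# `n_well` samples carrying many genes at high abundance, `n_poor` with few
# genes at low abundance
two_cloud_matrix <- function(n_well = 12, n_poor = 10, n_genes = 1000,
                             seed = 1) {
  withr::with_seed(seed, {
    n <- n_well + n_poor
    k_well <- round(0.9 * n_genes)
    k_poor <- max(round(0.05 * n_genes), 2)
    ab <- matrix(0, n_genes, n)
    for (j in seq_len(n_well))
      ab[sample.int(n_genes, k_well), j] <- exp(rnorm(k_well, 5, 0.3))
    for (j in n_well + seq_len(n_poor))
      ab[sample.int(n_genes, k_poor), j] <- exp(rnorm(k_poor, 1, 0.3))
    gene_matrix(ab, sample_ids = sprintf("s%03d", seq_len(n)))
  })
}

# additive 4-taxon distance matrix from the tree ((A:1,B:2):1,(C:3,D:4))
additive_four_taxon <- function() {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):1);")
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# reduced sampler settings for test fits; posterior summaries used in tests
# are robust to the shorter runs
test_settings <- function(chains = 2L, warmup = 400L, draws = 400L, seed = 1L)
  sampler_settings(chains = chains, warmup = warmup, draws = draws,
                   seed = seed)

expect_no_false_calls <- function(calls, truth) {
  testthat::expect_equal(sum(calls & !truth), 0L)
}
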