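## Adaptive coverage filtering: decide, per species-sample pair, whether the
## species' gene repertoire is sequenced deeply enough (saturated) for
## strain-level analysis, using k-means (k = 2) on two per-sample statistics.

#' Per-sample coverage statistics for a species' gene profile
#'
#' For each sample, the number of genes observed at nonzero abundance and the
#' median natural-log abundance of those nonzero observations (collector's
#' curve logic: a well-covered species saturates its typical gene count).
#'
#' @param m a [gene_matrix()].
#' @return data.frame with columns `sample_id`, `n_nonzero`,
#'   `median_log_nonzero` (NA when `n_nonzero` is 0).
#' @export
sample_stats <- function(m) {
  stopifnot(inherits(m, "gene_matrix"), length(m$gene_ids) > 0)
  ab <- m$abundance
  n_nonzero <- colSums(ab > 0)
  med <- vapply(seq_len(ncol(ab)), function(j) {
    v <- ab[, j]
    v <- v[v > 0]
    if (length(v)) median(log(v)) else NA_real_
  }, numeric(1))
  data.frame(sample_id = m$sample_ids, n_nonzero = as.integer(n_nonzero),
             median_log_nonzero = med, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Label samples as well or poorly covered by k-means (k = 2)
#'
#' Both statistics are standardized to zero mean / unit variance (they live
#' on incommensurate scales), then clustered with k = 2; the cluster whose
#' centroid has the larger sum of standardized coordinates is labeled
#' `well_covered`. Samples with no nonzero genes are labeled
#' `poorly_covered` without entering the clustering.
#'
#' @param stats data.frame from [sample_stats()], or a [gene_matrix()].
#' @param seed integer seed for the k-means multi-start (10 restarts, best
#'   within-cluster sum of squares kept).
#' @return list of class `coverage_labels`: `labels` (data.frame joining the
#'   input statistics with a `label` column) and `centroids` (2 x 2 matrix in
#'   standardized statistic space, rows well/poor).
#' @export
kmeans_coverage_label <- function(stats, seed = 1L) {
  if (inherits(stats, "gene_matrix")) stats <- sample_stats(stats)
  stopifnot(all(c("sample_id", "n_nonzero", "median_log_nonzero") %in%
                  names(stats)))
  label <- rep("poorly_covered", nrow(stats))
  eligible <- which(stats$n_nonzero > 0)
  centroids <- NULL
  if (length(eligible) < 2) {
    warning("fewer than 2 samples with nonzero genes; all labeled poorly_covered")
  } else {
    x <- cbind(stats$n_nonzero, stats$median_log_nonzero)[eligible, , drop = FALSE]
    z <- scale(x)
    z[, apply(x, 2, sd) == 0] <- 0    # constant statistic: no information
    km <- with_seed(seed, stats::kmeans(z, centers = 2, nstart = 10))
    sums <- rowSums(km$centers)
    well <- if (sums[1] == sums[2]) {
      # tie-break on breadth of coverage (the primary saturation signal)
      which.max(km$centers[, 1])
    } else which.max(sums)
    label[eligible][km$cluster == well] <- "well_covered"
    centroids <- km$centers[c(well, 3 - well), , drop = FALSE]
    rownames(centroids) <- c("well_covered", "poorly_covered")
    colnames(centroids) <- c("n_nonzero_std", "median_log_nonzero_std")
  }
  structure(list(labels = cbind(stats, label = label,
                                stringsAsFactors = FALSE),
                 centroids = centroids),
            class = "coverage_labels")
}

#' @export
print.coverage_labels <- function(x, ...) {
  tb <- table(x$labels$label)
  cat("<coverage_labels>", paste(names(tb), tb, collapse = ", "), "\n")
  invisible(x)
}

#' Prevalence filter on gene nonzero counts
#'
#' With `N` samples and `t = floor(fraction * N)`, genes observed (nonzero)
#' in fewer than `t` samples or in more than `N - t` samples are removed;
#' counts exactly equal to either bound are kept. Near-absent genes carry no
#' information and near-universal genes are part of the core genome rather
#' than strain variation.
#'
#' @param m a [gene_matrix()].
#' @param fraction prevalence fraction in `[0, 0.5)`; default 0.005.
#' @return the filtered [gene_matrix()], gene order preserved.
#' @export
prevalence_filter <- function(m, fraction = 0.005) {
  stopifnot(inherits(m, "gene_matrix"), fraction >= 0, fraction < 0.5)
  N <- length(m$sample_ids)
  t <- floor(fraction * N)
  cnt <- rowSums(m$abundance > 0)
  keep <- cnt >= t & cnt <= N - t
  subset_genes(m, keep)
}

#' Prevalence-filter bounds
#'
#' @param n_samples number of samples N.
#' @param fraction prevalence fraction.
#' @return named vector with `lower` = floor(fraction * N) and
#'   `upper` = N - lower.
#' @export
prevalence_bounds <- function(n_samples, fraction = 0.005) {
  t <- floor(fraction * n_samples)
  c(lower = t, upper = n_samples - t)
}

#' Binarize gene abundances into presence indicators
#'
#' @param m a [gene_matrix()].
#' @return a [gene_matrix()] with entries 1 where abundance > 0, else 0.
#' @export
binarize_presence <- function(m) {
  stopifnot(inherits(m, "gene_matrix"))
  gene_matrix((m$abundance > 0) + 0, species_name = m$species_name)
}

#' Full adaptive filtering pipeline
#'
#' Three steps before binarization: an initial prevalence filter, k-means
#' coverage filtering that drops poorly covered samples, and a final
#' prevalence filter recomputed on the surviving sample count.
#'
#' @inheritParams prevalence_filter
#' @param seed seed passed to [kmeans_coverage_label()].
#' @return list: `matrix` (filtered, binarized [gene_matrix()]) and `labels`
#'   (the [kmeans_coverage_label()] result on the initially filtered matrix).
#' @export
filter_pipeline <- function(m, fraction = 0.005, seed = 1L) {
  m1 <- prevalence_filter(m, fraction)
  lab <- kmeans_coverage_label(sample_stats(m1), seed = seed)
  keep <- lab$labels$sample_id[lab$labels$label == "well_covered"]
  if (!length(keep)) {
    warning("no well-covered samples survive filtering")
    return(list(matrix = subset_samples(m1, character(0)), labels = lab))
  }
  m2 <- subset_samples(m1, keep)
  m3 <- prevalence_filter(m2, fraction)
  list(matrix = binarize_presence(m3), labels = lab)
}

#' Rank-abundance diagnostic table
#'
#' For each sample, genes' log abundances sorted descending with their rank:
#' the tabular analogue of the per-sample rank-abundance curves used to
#' visually confirm well/poor coverage separation.
#'
#' @param m a [gene_matrix()].
#' @param labels optional `coverage_labels` to join.
#' @return data.frame with columns `sample_id`, `rank`, `log_abundance`
#'   (nonzero genes only) and, if given, `label`.
#' @export
rank_abundance_table <- function(m, labels = NULL) {
  out <- do.call(rbind, lapply(seq_along(m$sample_ids), function(j) {
    v <- m$abundance[, j]
    v <- sort(v[v > 0], decreasing = TRUE)
    if (!length(v)) return(NULL)
    data.frame(sample_id = m$sample_ids[j], rank = seq_along(v),
               log_abundance = log(v), stringsAsFactors = FALSE)
  }))
  if (!is.null(labels))
    out$label <- labels$labels$label[match(out$sample_id,
                                           labels$labels$sample_id)]
  out
}

## deterministic seeded evaluation without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}
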