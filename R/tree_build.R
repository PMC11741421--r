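## Approximate per-species phylogenies from binarized gene presence tables:
## adaptive PCA -> Euclidean distance in the reduced space -> neighbor
## joining -> midpoint root -> ladderize.

#' Adaptive principal components of a gene presence table
#'
#' Genes (columns of the samples x genes view) are mean-centered but not
#' scaled (presence columns already share the \{0,1\} scale). Components are
#' kept up to and including the first eigenvalue smaller than one tenth of
#' the leading eigenvalue; if none falls below that threshold all components
#' are kept. The adaptive count absorbs the genuinely structured variation
#' while discarding dimensions dominated by noise.
#'
#' @param presence a binarized [gene_matrix()] (or any gene matrix; values
#'   are used as given, so log-abundance matrices work too).
#' @param ratio eigenvalue cutoff relative to the first eigenvalue
#'   (default 1/10).
#' @param inclusive keep the first sub-threshold eigenvalue itself
#'   (default TRUE).
#' @return list of class `pca_result`: `eigenvalues` (nonincreasing),
#'   `components_kept`, `scores` (samples x k).
#' @export
adaptive_pca <- function(presence, ratio = 0.1, inclusive = TRUE) {
  stopifnot(inherits(presence, "gene_matrix"))
  x <- t(presence$abundance)           # samples x genes
  if (nrow(x) < 3) stop("need >= 3 samples")
  if (ncol(x) < 2) stop("need >= 2 genes")
  x <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(x)
  ev <- sv$d^2 / (nrow(x) - 1)
  ev <- ev[ev > .Machine$double.eps * max(ev, 1)]
  if (!length(ev)) stop("no variation: all samples identical")
  below <- which(ev < ratio * ev[1])
  k <- if (!length(below)) length(ev)
       else if (inclusive) below[1] else max(below[1] - 1L, 1L)
  scores <- x %*% sv$v[, seq_len(k), drop = FALSE]
  rownames(scores) <- presence$sample_ids
  structure(list(eigenvalues = ev, components_kept = k, scores = scores),
            class = "pca_result")
}

#' Count of components kept by the adaptive eigenvalue rule
#'
#' @param eigenvalues nonincreasing nonnegative eigenvalues.
#' @inheritParams adaptive_pca
#' @export
adaptive_k <- function(eigenvalues, ratio = 0.1, inclusive = TRUE) {
  below <- which(eigenvalues < ratio * eigenvalues[1])
  if (!length(below)) length(eigenvalues)
  else if (inclusive) below[1] else max(below[1] - 1L, 1L)
}

#' Euclidean distances between samples in component space
#'
#' @param scores samples x k score matrix (e.g. from [adaptive_pca()]).
#' @return a symmetric matrix of pairwise Euclidean distances.
#' @export
pc_distance <- function(scores) {
  if (inherits(scores, "pca_result")) scores <- scores$scores
  as.matrix(stats::dist(scores))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining; negative estimated branch lengths are clipped
#' to zero with the deficit transferred to the adjacent edge, preserving
#' path lengths. The 2-taxon case degenerates to a single edge.
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @param names optional taxon names (default from `d`'s dimnames).
#' @return an unrooted `phylo` tree.
#' @export
neighbor_join <- function(d, names = rownames(d)) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  n <- nrow(d)
  if (is.null(names)) names <- paste0("t", seq_len(n))
  dimnames(d) <- list(names, names)
  if (n == 2) {
    tr <- ape::read.tree(text = sprintf("(%s:%f,%s:%f);", names[1],
                                        d[1, 2] / 2, names[2], d[1, 2] / 2))
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(d))
  clip_negative_edges(tr)
}

## clip negative branch lengths to 0, moving the deficit onto the adjacent
## edge (parent side) so root-to-tip path lengths are preserved
clip_negative_edges <- function(tr) {
  el <- tr$edge.length
  if (is.null(el) || all(el >= 0)) return(tr)
  edge <- tr$edge
  for (i in order(el)) {
    if (el[i] >= 0) next
    deficit <- el[i]
    el[i] <- 0
    # transfer to sibling/parent edges sharing this edge's parent node
    adj <- which(edge[, 1] == edge[i, 1] & seq_along(el) != i)
    if (length(adj)) el[adj] <- el[adj] + deficit
  }
  el[el < 0] <- 0
  tr$edge.length <- el
  tr
}

#' Ladderize a tree
#'
#' Reorders the children of every internal node by descendant-leaf count
#' while leaving the leaf set and all path lengths unchanged.
#'
#' @param tree a `phylo`.
#' @param right passed to the underlying ladderize.
#' @export
ladderize_tree <- function(tree, right = TRUE) {
  ape::ladderize(tree, right = right)
}

#' Gene-presence-to-phylogeny pipeline
#'
#' [adaptive_pca()] then [pc_distance()] then [neighbor_join()], midpoint
#' rooted (the phylogenetic covariance construction requires a root) and
#' ladderized. Deterministic given its input.
#'
#' @inheritParams adaptive_pca
#' @return a rooted, ladderized `phylo`.
#' @export
build_tree <- function(presence, ratio = 0.1) {
  pca <- adaptive_pca(presence, ratio = ratio)
  d <- pc_distance(pca$scores)
  tr <- neighbor_join(d)
  tr <- phangorn::midpoint(tr)
  ladderize_tree(tr)
}
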