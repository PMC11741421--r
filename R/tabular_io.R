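#' @useDynLib strainepi, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median sd var dnorm rnorm runif rbinom qnorm quantile
#'   setNames complete.cases
#' @importFrom utils read.delim write.table head
NULL

## ---------------------------------------------------------------------------
## Domain containers
## ---------------------------------------------------------------------------

#' Construct a species-scoped gene-by-sample abundance matrix
#'
#' A `gene_matrix` holds the gene-family profile of a single species: one row
#' per gene family, one column per sample, nonnegative abundances (relative
#' abundance or copy-number units; values are used as given).
#'
#' @param abundance numeric matrix, genes x samples, nonnegative.
#' @param species_name single string naming the species (or SGB/clade).
#' @param gene_ids,sample_ids optional character vectors; default to the
#'   dimnames of `abundance`.
#' @return An object of class `gene_matrix`.
#' @export
gene_matrix <- function(abundance, species_name = "species",
                        gene_ids = rownames(abundance),
                        sample_ids = colnames(abundance)) {
  abundance <- as.matrix(abundance)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(abundance)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(abundance)))
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(abundance) ||
      length(sample_ids) != ncol(abundance))
    stop("id lengths do not match matrix dimensions")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (anyNA(abundance) || any(abundance < 0))
    stop("abundance values must be nonnegative and non-missing")
  dimnames(abundance) <- list(gene_ids, sample_ids)
  structure(list(species_name = as.character(species_name)[1],
                 gene_ids = gene_ids, sample_ids = sample_ids,
                 abundance = abundance),
            class = "gene_matrix")
}

#' @export
print.gene_matrix <- function(x, ...) {
  cat(sprintf("<gene_matrix> %s: %d genes x %d samples\n",
              x$species_name, length(x$gene_ids), length(x$sample_ids)))
  invisible(x)
}

#' @export
dim.gene_matrix <- function(x) dim(x$abundance)

#' Construct a species-scoped pathway-by-sample abundance matrix
#'
#' Like [gene_matrix()] but for pathway profiles, additionally carrying the
#' overall abundance of the species in each sample (needed by the pathway
#' carriage model, which regresses log pathway abundance on log species
#' abundance).
#'
#' @inheritParams gene_matrix
#' @param pathway_ids character vector of pathway identifiers.
#' @param species_abundance nonnegative numeric vector aligned to
#'   `sample_ids`.
#' @return An object of class `pathway_matrix`.
#' @export
pathway_matrix <- function(abundance, species_abundance,
                           species_name = "species",
                           pathway_ids = rownames(abundance),
                           sample_ids = colnames(abundance)) {
  gm <- gene_matrix(abundance, species_name, pathway_ids, sample_ids)
  species_abundance <- as.numeric(species_abundance)
  if (length(species_abundance) != length(gm$sample_ids))
    stop("species_abundance must align with sample_ids")
  if (anyNA(species_abundance) || any(species_abundance < 0))
    stop("species_abundance must be nonnegative")
  structure(list(species_name = gm$species_name,
                 pathway_ids = gm$gene_ids, sample_ids = gm$sample_ids,
                 abundance = gm$abundance,
                 species_abundance = setNames(species_abundance,
                                              gm$sample_ids)),
            class = "pathway_matrix")
}

#' @export
print.pathway_matrix <- function(x, ...) {
  cat(sprintf("<pathway_matrix> %s: %d pathways x %d samples\n",
              x$species_name, length(x$pathway_ids), length(x$sample_ids)))
  invisible(x)
}

#' Construct per-sample metadata (outcome + covariates)
#'
#' @param sample_ids character vector of unique sample identifiers.
#' @param outcome numeric vector: binary 0/1 or continuous, no missing values.
#' @param covariates data.frame of covariate columns (or NULL).
#' @param outcome_family `"bernoulli"`, `"gaussian"`, or `NULL` to auto-detect
#'   (bernoulli iff all outcome values are in \{0, 1\}).
#' @return An object of class `sample_metadata`.
#' @export
sample_metadata <- function(sample_ids, outcome, covariates = NULL,
                            outcome_family = NULL) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  outcome <- as.numeric(outcome)
  if (length(outcome) != length(sample_ids))
    stop("outcome length must match sample_ids")
  if (anyNA(outcome)) stop("outcome contains missing values")
  if (is.null(outcome_family)) {
    outcome_family <- if (all(outcome %in% c(0, 1))) "bernoulli" else "gaussian"
  }
  outcome_family <- match.arg(outcome_family, c("gaussian", "bernoulli"))
  if (outcome_family == "bernoulli" && !all(outcome %in% c(0, 1)))
    stop("bernoulli outcome must contain only 0 and 1")
  if (is.null(covariates)) {
    covariates <- data.frame(row.names = sample_ids)
  } else {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(sample_ids))
      stop("covariates must have one row per sample")
    rownames(covariates) <- sample_ids
  }
  structure(list(sample_ids = sample_ids, outcome = setNames(outcome, sample_ids),
                 covariates = covariates, outcome_family = outcome_family),
            class = "sample_metadata")
}

#' @export
print.sample_metadata <- function(x, ...) {
  cat(sprintf("<sample_metadata> %d samples, %s outcome, %d covariate(s)\n",
              length(x$sample_ids), x$outcome_family, ncol(x$covariates)))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Readers / writers
## ---------------------------------------------------------------------------

read_tsv_raw <- function(path) {
  # The first line is the header even when it starts with '#' (HUMAnN
  # writes e.g. "# Gene Family<TAB>sample1..."); later '#' lines are
  # comments and dropped. The first header cell is ignored.
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty table: ", path)
  keep <- c(TRUE, !startsWith(lines[-1], "#"))
  lines <- lines[keep]
  con <- textConnection(lines)
  on.exit(close(con))
  df <- read.delim(con, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("malformed header in ", path,
                         ": need a feature column plus >= 1 sample column")
  df
}

#' Read a (possibly species-stratified) abundance table
#'
#' Parses a HUMAnN-style TSV: header row of sample ids (first header cell
#' ignored), feature ids in the first column, optionally stratified as
#' `Species|Feature` (split at the first `|`). `#` comment lines are skipped.
#' Gzip-compressed files are accepted transparently.
#'
#' @param path file path.
#' @param stratified if TRUE, rows are partitioned by species prefix and
#'   unstratified rows (no `|`) are ignored; if FALSE the whole table becomes
#'   one matrix.
#' @param type `"gene"` or `"pathway"`; for `"pathway"`, per-species total
#'   abundance is taken from the column sums of that species' block unless a
#'   `species_abundance` named list is supplied.
#' @param species_abundance optional named list (species -> numeric vector
#'   aligned to samples) used when `type = "pathway"`.
#' @return A named list of [gene_matrix()] (or [pathway_matrix()]) objects,
#'   one per species; for `stratified = FALSE`, a list of length one named
#'   `"all"`.
#' @export
read_abundance_table <- function(path, stratified = TRUE, type = c("gene", "pathway"),
                                 species_abundance = NULL) {
  type <- match.arg(type)
  df <- read_tsv_raw(path)
  feats <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(mat) <- "double")
  if (anyNA(mat)) stop("non-numeric or missing abundance values in ", path)
  if (any(mat < 0)) stop("negative abundance values in ", path)
  if (anyDuplicated(feats)) stop("duplicate feature ids in ", path)
  samples <- colnames(df)[-1]
  build <- function(sub_feats, sub_mat, sp) {
    rownames(sub_mat) <- sub_feats
    colnames(sub_mat) <- samples
    if (type == "gene") {
      gene_matrix(sub_mat, species_name = sp)
    } else {
      sa <- if (!is.null(species_abundance)) species_abundance[[sp]]
            else colSums(sub_mat)
      pathway_matrix(sub_mat, sa, species_name = sp)
    }
  }
  if (!stratified) {
    return(list(all = build(feats, mat, "all")))
  }
  has_bar <- grepl("|", feats, fixed = TRUE)
  feats <- feats[has_bar]
  mat <- mat[has_bar, , drop = FALSE]
  if (!length(feats)) stop("no stratified (Species|Feature) rows in ", path)
  sp <- sub("\\|.*$", "", feats)
  id <- sub("^[^|]*\\|", "", feats)
  out <- lapply(split(seq_along(feats), sp), function(ix)
    build(id[ix], mat[ix, , drop = FALSE], sp[ix[1]]))
  out[unique(sp)]
}

#' Write a gene or pathway matrix as a (optionally stratified) TSV
#'
#' @param m a [gene_matrix()] or [pathway_matrix()].
#' @param path output file path.
#' @param stratified prefix feature ids with `species|` when TRUE.
#' @export
write_abundance_table <- function(m, path, stratified = TRUE) {
  ids <- if (inherits(m, "pathway_matrix")) m$pathway_ids else m$gene_ids
  feats <- if (stratified) paste0(m$species_name, "|", ids) else ids
  # %.17g guarantees bit-exact numeric round trips
  num <- apply(m$abundance, 2, function(v) sprintf("%.17g", v))
  if (is.null(dim(num))) num <- matrix(num, nrow = nrow(m$abundance))
  df <- data.frame(feature = feats, num, check.names = FALSE)
  names(df) <- c("# feature", m$sample_ids)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample metadata from a TSV
#'
#' @param path TSV with one row per sample.
#' @param outcome_col name of the outcome column.
#' @param covariate_cols character vector of covariate column names (may be
#'   empty).
#' @param sample_col name of the sample-id column (default first column).
#' @param outcome_family optional override of the auto-detected family.
#' @return A [sample_metadata()] object.
#' @export
read_metadata <- function(path, outcome_col, covariate_cols = character(),
                          sample_col = NULL, outcome_family = NULL) {
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (is.null(sample_col)) sample_col <- names(df)[1]
  for (cl in c(sample_col, outcome_col, covariate_cols))
    if (!cl %in% names(df)) stop("column not found in metadata: ", cl)
  if (anyNA(df[[outcome_col]])) stop("missing outcome values in ", path)
  sample_metadata(df[[sample_col]], df[[outcome_col]],
                  covariates = if (length(covariate_cols))
                    df[covariate_cols] else NULL,
                  outcome_family = outcome_family)
}

#' Read / write Newick trees
#'
#' Thin validating wrappers around the standard Newick parser: leaf names
#' must be unique and branch lengths nonnegative.
#'
#' @param path file path.
#' @return `read_newick` returns an [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("unparseable Newick: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("unparseable Newick file: ", path)
  validate_phylo(tr)
  tr
}

#' @rdname read_newick
#' @param tree a `phylo` object.
#' @export
write_newick <- function(tree, path) {
  validate_phylo(tree)
  ape::write.tree(tree, file = path)
  invisible(path)
}

validate_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf names in tree")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch length in tree")
  invisible(tree)
}

#' Align a gene/pathway matrix with metadata on their shared samples
#'
#' Samples present in only one of the two inputs are dropped with a warning;
#' the result uses the metadata's sample order restricted to the
#' intersection.
#'
#' @param m a [gene_matrix()] or [pathway_matrix()].
#' @param meta a [sample_metadata()].
#' @return list with elements `matrix` and `meta`, sample-aligned.
#' @export
align_samples <- function(m, meta) {
  keep <- intersect(meta$sample_ids, m$sample_ids)
  if (!length(keep)) stop("no samples shared between matrix and metadata")
  dropped <- setdiff(union(meta$sample_ids, m$sample_ids), keep)
  if (length(dropped))
    warning(sprintf("dropping %d sample(s) absent from one input: %s",
                    length(dropped),
                    paste(head(dropped, 5), collapse = ", ")))
  m2 <- subset_samples(m, keep)
  meta2 <- sample_metadata(keep, meta$outcome[keep],
                           covariates = if (ncol(meta$covariates))
                             meta$covariates[keep, , drop = FALSE] else NULL,
                           outcome_family = meta$outcome_family)
  list(matrix = m2, meta = meta2)
}

subset_samples <- function(m, keep) {
  if (inherits(m, "pathway_matrix")) {
    pathway_matrix(m$abundance[, keep, drop = FALSE],
                   m$species_abundance[keep],
                   species_name = m$species_name)
  } else {
    gene_matrix(m$abundance[, keep, drop = FALSE],
                species_name = m$species_name)
  }
}

subset_genes <- function(m, keep) {
  gene_matrix(m$abundance[keep, , drop = FALSE], species_name = m$species_name)
}
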