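## Associate binarized gene presence with an outcome: per-gene GLMs with
## Benjamini-Hochberg correction (default), or a joint sparse regression
## with a regularized horseshoe prior over all genes simultaneously.

#' Per-gene generalized linear models
#'
#' Fits `outcome ~ covariates + gene_presence` for each gene (identity link
#' for gaussian outcomes, logit link for bernoulli) and reports the Wald
#' test of the `gene_presence` coefficient. Genes with constant presence are
#' skipped with a warning; logistic fits with complete separation are
#' flagged (non-finite coefficient marker) and excluded from multiplicity
#' correction.
#'
#' @param presence a binarized [gene_matrix()].
#' @param meta a [sample_metadata()] covering the presence samples.
#' @return data.frame of class `gene_associations`: columns `species`,
#'   `gene`, `coefficient`, `std_error`, `p_value`, `q_value` (BH-adjusted
#'   over the finite p-values), `is_hit` (NA until [call_gene_hits()]).
#' @export
fit_gene_glms <- function(presence, meta) {
  al <- align_samples(presence, meta)
  m <- al$matrix; meta <- al$meta
  fam <- if (meta$outcome_family == "bernoulli") stats::binomial()
         else stats::gaussian()
  y <- meta$outcome
  covs <- meta$covariates
  base_df <- if (ncol(covs)) data.frame(y = y, covs) else data.frame(y = y)
  pres <- m$abundance
  const <- apply(pres, 1, function(v) length(unique(v)) == 1)
  if (any(const))
    warning(sum(const), " gene(s) with constant presence skipped")
  res <- lapply(which(!const), function(g) {
    df <- base_df
    df$gene_presence <- pres[g, ]
    fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = fam))
    cf <- summary(fit)$coefficients
    row <- cf["gene_presence", , drop = TRUE]
    est <- row[1]; se <- row[2]
    # complete separation: runaway estimate with huge standard error
    sep <- meta$outcome_family == "bernoulli" &&
      (abs(est) > 15 || se > 100 || !fit$converged)
    data.frame(gene = m$gene_ids[g],
               coefficient = if (sep) NA_real_ else unname(est),
               std_error = if (sep) NA_real_ else unname(se),
               p_value = if (sep) NA_real_ else unname(row[4]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(gene = character(), coefficient = numeric(),
                      std_error = numeric(), p_value = numeric())
  out$q_value <- NA_real_
  ok <- is.finite(out$p_value)
  out$q_value[ok] <- bh_adjust(out$p_value[ok])
  out <- cbind(species = m$species_name, out, stringsAsFactors = FALSE)
  out$is_hit <- NA
  class(out) <- c("gene_associations", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return q-values in the same order.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Call hits from gene associations
#'
#' GLM path: hit iff `q_value < q_threshold` (strict). Horseshoe path: hit
#' iff the posterior interval excludes 0 and the absolute posterior mean
#' exceeds the configured effect threshold (already recorded by
#' [fit_gene_horseshoe()]; the threshold arguments are ignored there).
#'
#' @param assocs a `gene_associations` data.frame.
#' @param q_threshold FDR threshold for the GLM path (default 0.05).
#' @return the input with `is_hit` populated.
#' @export
call_gene_hits <- function(assocs, q_threshold = 0.05) {
  if (!nrow(assocs)) return(assocs)
  if ("q_value" %in% names(assocs) && any(is.finite(assocs$q_value))) {
    assocs$is_hit <- is.finite(assocs$q_value) & assocs$q_value < q_threshold
  } else if (all(c("interval_low", "interval_high") %in% names(assocs))) {
    thr <- attr(assocs, "effect_threshold")
    if (is.null(thr)) thr <- 0.5
    assocs$is_hit <- (assocs$interval_low > 0 | assocs$interval_high < 0) &
      abs(assocs$coefficient) > thr
  }
  assocs
}

#' Regularized-horseshoe configuration
#'
#' @param p0 prior expected fraction of nonzero gene coefficients
#'   (default 0.01).
#' @param slab_scale,slab_df slab (bounded-coefficient) scale and degrees of
#'   freedom.
#' @param effect_threshold minimum absolute posterior mean (link scale) for
#'   a hit.
#' @param interval_level central posterior interval used for the
#'   excludes-zero criterion (default 0.99).
#' @export
horseshoe_config <- function(p0 = 0.01, slab_scale = 2.5, slab_df = 4,
                             effect_threshold = 0.5, interval_level = 0.99) {
  stopifnot(p0 > 0, p0 < 1, slab_scale > 0, slab_df > 0,
            effect_threshold > 0, interval_level > 0.5, interval_level < 1)
  as.list(environment())
}

#' Joint gene model with a regularized horseshoe prior
#'
#' `outcome ~ covariates + sum_g gamma_g presence_g` with the regularized
#' horseshoe on the gene coefficients: per-gene half-Cauchy local scales, a
#' half-Cauchy global scale whose reference value is set from `p0` so the
#' prior expected nonzero count is `p0 * G`, and a Student-t slab bounding
#' large coefficients. Genes with identical presence patterns are collapsed
#' to one representative before fitting (exact collinearity) and expanded
#' afterward with the shared coefficient, flagged in `collapsed_with`.
#'
#' @inheritParams fit_gene_glms
#' @param cfg a [horseshoe_config()].
#' @param settings a [sampler_settings()].
#' @return `gene_associations` data.frame with `coefficient` (posterior
#'   mean), `interval_low`/`interval_high`, `is_hit`, `collapsed_with`;
#'   attributes `fit` (sampler diagnostics) and `effect_threshold`.
#' @export
fit_gene_horseshoe <- function(presence, meta, cfg = horseshoe_config(),
                               settings = sampler_settings()) {
  al <- align_samples(presence, meta)
  m <- al$matrix; meta <- al$meta
  pres <- m$abundance                      # genes x samples, 0/1
  const <- apply(pres, 1, function(v) length(unique(v)) == 1)
  if (any(const))
    warning(sum(const), " gene(s) with constant presence skipped")
  pres <- pres[!const, , drop = FALSE]
  if (!nrow(pres)) stop("no non-constant genes to fit")
  # collapse identical presence patterns
  key <- apply(pres, 1, paste, collapse = "")
  rep_ix <- which(!duplicated(key))
  groups <- split(rownames(pres), key)[unique(key)]
  Z <- t(pres[rep_ix, , drop = FALSE])     # samples x unique genes
  G <- ncol(Z); n <- nrow(Z)
  Xm <- build_design(if (ncol(meta$covariates)) meta$covariates else NULL, n)
  y <- as.numeric(meta$outcome)
  fam <- if (meta$outcome_family == "bernoulli") 1L else 0L
  pseudo_sigma <- if (fam == 1L) 2 else sd(y)
  tau0 <- cfg$p0 / (1 - cfg$p0) * pseudo_sigma / sqrt(n)
  data <- list(y = y, X = Xm, Z = Z, family = fam, beta_sd = 5,
               tau0 = tau0, slab_scale = cfg$slab_scale,
               slab_df = cfg$slab_df)
  d <- ncol(Xm) + 2L * G + 2L + (fam == 0L)
  init_fun <- function() c(runif(ncol(Xm), -0.5, 0.5),  # beta
                           runif(G, -0.1, 0.1),          # z
                           runif(G, -1, 0),              # log lambda
                           log(tau0) + runif(1, -1, 0),  # log tau
                           log(cfg$slab_scale^2),        # log c2
                           if (fam == 0L) 0)
  fit <- run_nuts("horseshoe", data, init_fun, settings = settings)
  dr <- fit$draws
  pc <- ncol(Xm)
  zg <- dr[, pc + seq_len(G), drop = FALSE]
  lam2 <- exp(2 * dr[, pc + G + seq_len(G), drop = FALSE])
  tau2 <- exp(2 * dr[, pc + 2 * G + 1])
  c2 <- exp(dr[, pc + 2 * G + 2])
  t2 <- lam2 * tau2
  mscale <- sqrt(c2 * t2 / (c2 + t2))
  gamma <- zg * mscale                      # draws x G
  alpha <- (1 - cfg$interval_level) / 2
  qs <- apply(gamma, 2, quantile, probs = c(alpha, 1 - alpha))
  rep_genes <- rownames(pres)[rep_ix]
  out_rep <- data.frame(gene = rep_genes,
                        coefficient = colMeans(gamma),
                        std_error = apply(gamma, 2, sd),
                        interval_low = qs[1, ], interval_high = qs[2, ],
                        stringsAsFactors = FALSE)
  # expand collapsed duplicates with the shared coefficient
  out <- do.call(rbind, lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    row <- out_rep[i, , drop = FALSE]
    ex <- row[rep(1, length(g)), , drop = FALSE]
    ex$gene <- g
    ex$collapsed_with <- if (length(g) > 1) rep_genes[i] else NA_character_
    ex
  }))
  rownames(out) <- NULL
  out <- cbind(species = m$species_name, out, stringsAsFactors = FALSE)
  out$is_hit <- (out$interval_low > 0 | out$interval_high < 0) &
    abs(out$coefficient) > cfg$effect_threshold
  attr(out, "fit") <- fit[c("rhat", "divergences", "converged", "warnings")]
  attr(out, "effect_threshold") <- cfg$effect_threshold
  class(out) <- c("gene_associations", "data.frame")
  out
}
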