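## Synthetic-data generators emulating the statistical structure of
## strain-level metagenomic studies: species abundances (log-normal stand-in
## for a stool-like preset), skew-normal gene measurement noise, logistic
## zero-inflation, phylogenetically structured outcomes, and
## reverse-generated pathway profiles.

#' Draw from a skew-normal distribution
#'
#' Parameterized as (location, scale, shape); shape < 0 skews left. Uses the
#' standard construction from a correlated bivariate normal pair.
#'
#' @param n number of draws.
#' @param location,scale,shape skew-normal parameters.
#' @export
rskewnorm <- function(n, location = 0, scale = 1, shape = -1) {
  delta <- shape / sqrt(1 + shape^2)
  u0 <- abs(rnorm(n))
  u1 <- rnorm(n)
  location + scale * (delta * u0 + sqrt(1 - delta^2) * u1)
}

#' Configuration for the gene-profile simulator
#'
#' Defaults match the validation conditions of the gene model study: 200
#' cases and 200 controls, 1000 genes, risk genes shifting disease log-odds
#' by 1, 25% of subjects with poorly covered genes (average log gene
#' abundance reduced by 4), skew-normal(0, 1, -1) measurement noise, and
#' logistic zero-inflation centered on the per-gene median log abundance
#' with growth rate -1. Species natural-log abundance is drawn
#' Normal(`species_log_mu`, `species_log_sigma`) as a configurable log-normal
#' stand-in for a stool-like community preset.
#'
#' @param n_per_group subjects per outcome group (cases = controls).
#' @param n_genes genes in the simulated species.
#' @param n_risk_genes genes that causally raise disease log-odds.
#' @param risk_gene_logodds log-odds increment per carried risk gene.
#' @param species_effect_logodds log-odds increment per SD of species log
#'   abundance (0 or 1 in the validation study).
#' @param poor_coverage_fraction fraction of subjects with poorly covered
#'   genes.
#' @param poor_coverage_shift shift applied to all of a poor subject's log
#'   gene abundances.
#' @param carriage_prob per-subject per-gene carriage probability.
#' @param species_log_mu,species_log_sigma natural-log abundance parameters.
#' @param gene_slope slope of gene log abundance on species log abundance.
#' @param max_batches cap on rejection-sampling batches for the group quotas.
#' @export
gene_sim_config <- function(n_per_group = 200L, n_genes = 1000L,
                            n_risk_genes = 5L, risk_gene_logodds = 1,
                            species_effect_logodds = 0,
                            poor_coverage_fraction = 0.25,
                            poor_coverage_shift = -4,
                            carriage_prob = 0.5,
                            species_log_mu = 0, species_log_sigma = 2,
                            gene_slope = 1, max_batches = 50L) {
  stopifnot(n_genes >= n_risk_genes, poor_coverage_fraction >= 0,
            poor_coverage_fraction <= 1)
  as.list(environment())
}

#' Simulate a species' gene profile with a linked binary outcome
#'
#' Subjects are generated in batches until the case and control quotas are
#' both met. Each subject receives a species log abundance, a Bernoulli
#' carriage pattern over genes, and a disease state whose log-odds are
#' `intercept + risk_gene_logodds * (# carried risk genes) +
#' species_effect_logodds * standardized species log abundance` (intercept
#' set for ~50% baseline prevalence). Carried genes get log abundance
#' `gene_slope * species log abundance + skew-normal(0,1,-1)`; a random
#' fraction of subjects has all log abundances shifted down (poor coverage);
#' every observation is then zeroed with probability
#' `1 / (1 + exp(a - median_g))`, the logistic centered on the gene's median
#' observed log abundance with growth rate -1.
#'
#' @param cfg a [gene_sim_config()].
#' @param seed integer seed.
#' @return list: `genes` ([gene_matrix()]), `meta` ([sample_metadata()]),
#'   `truth` (list: `risk_genes`, `poor_samples`, `species_log_abundance`).
#' @export
simulate_gene_dataset <- function(cfg = gene_sim_config(), seed = 1L) {
  with_seed(seed, {
    G <- cfg$n_genes
    npg <- cfg$n_per_group
    risk <- seq_len(cfg$n_risk_genes)
    intercept <- -cfg$risk_gene_logodds * cfg$n_risk_genes * cfg$carriage_prob
    keep_carr <- NULL; keep_sla <- NULL; keep_y <- integer(0)
    need <- c(`0` = npg, `1` = npg)
    for (b in seq_len(cfg$max_batches)) {
      nb <- 2L * npg
      sla <- rnorm(nb, cfg$species_log_mu, cfg$species_log_sigma)
      carr <- matrix(rbinom(nb * G, 1L, cfg$carriage_prob), nrow = nb)
      eta <- intercept +
        cfg$risk_gene_logodds * rowSums(carr[, risk, drop = FALSE]) +
        cfg$species_effect_logodds *
          (sla - cfg$species_log_mu) / cfg$species_log_sigma
      y <- rbinom(nb, 1L, 1 / (1 + exp(-eta)))
      for (g in c(0L, 1L)) {
        ix <- which(y == g)
        take <- head(ix, need[as.character(g)])
        if (length(take)) {
          keep_carr <- rbind(keep_carr, carr[take, , drop = FALSE])
          keep_sla <- c(keep_sla, sla[take])
          keep_y <- c(keep_y, y[take])
          need[as.character(g)] <- need[as.character(g)] - length(take)
        }
      }
      if (all(need == 0)) break
    }
    if (any(need > 0)) stop("could not reach group quotas within max_batches")
    n <- length(keep_y)
    # log abundance for carried genes; NA encodes "not carried" (hard zero)
    la <- matrix(NA_real_, n, G)
    ci <- which(keep_carr == 1)
    la[ci] <- cfg$gene_slope * keep_sla[row(keep_carr)[ci]] +
      rskewnorm(length(ci), 0, 1, -1)
    poor <- sort(sample.int(n, round(cfg$poor_coverage_fraction * n)))
    la[poor, ] <- la[poor, ] + cfg$poor_coverage_shift
    med <- apply(la, 2, median, na.rm = TRUE)
    pzero <- 1 / (1 + exp(sweep(la, 2, med, "-")))
    zeroed <- matrix(runif(n * G), n, G) < pzero
    ab <- exp(la)
    ab[zeroed | is.na(la)] <- 0
    sample_ids <- sprintf("s%03d", seq_len(n))
    gm <- gene_matrix(t(ab), species_name = "sim_species",
                      gene_ids = sprintf("gene%04d", seq_len(G)),
                      sample_ids = sample_ids)
    meta <- sample_metadata(sample_ids, keep_y)
    list(genes = gm, meta = meta,
         truth = list(risk_genes = sprintf("gene%04d", risk),
                      poor_samples = sample_ids[poor],
                      species_log_abundance = setNames(keep_sla, sample_ids)))
  })
}

#' Configuration grid for the phylogenetic simulations
#'
#' Six evenly spaced values per axis: tips from 10 to 450 and both noise
#' scales from 0 to 2.09; the point with both noise scales zero is excluded,
#' leaving 210 grid points.
#'
#' @return data.frame with columns `n_tips`, `sigma_p`, `sigma_r`.
#' @export
phylo_sim_grid <- function() {
  g <- expand.grid(n_tips = round(seq(10, 450, length.out = 6)),
                   sigma_p = seq(0, 2.09, length.out = 6),
                   sigma_r = seq(0, 2.09, length.out = 6))
  g[!(g$sigma_p == 0 & g$sigma_r == 0), , drop = FALSE]
}

#' Simulate a phylogenetically structured outcome
#'
#' Generates a random phylogeny (random binary topology, uniform branch
#' lengths), derives the tree correlation matrix, and draws
#' `outcome = MVN(0, sigma_p^2 Omega) + MVN(0, sigma_r^2 I)`.
#'
#' @param n_tips number of tips (>= 4).
#' @param sigma_p phylogenetic noise scale.
#' @param sigma_r residual noise scale.
#' @param seed integer seed.
#' @return list: `tree` (`phylo`), `omega` ([tree_to_correlation()] result),
#'   `outcome` (named vector), `true_r2` = sigma_p^2 / (sigma_p^2 +
#'   sigma_r^2).
#' @export
simulate_phylo_dataset <- function(n_tips, sigma_p, sigma_r, seed = 1L) {
  stopifnot(n_tips >= 4)
  if (sigma_p == 0 && sigma_r == 0)
    stop("sigma_p and sigma_r cannot both be zero")
  with_seed(seed, {
    tree <- ape::rtree(n_tips)
    om <- tree_to_correlation(tree)
    L <- chol_psd(om$omega)
    n <- n_tips
    outcome <- sigma_p * as.vector(L %*% rnorm(n)) + sigma_r * rnorm(n)
    names(outcome) <- om$leaf_order
    list(tree = tree, omega = om, outcome = outcome,
         true_r2 = sigma_p^2 / (sigma_p^2 + sigma_r^2))
  })
}

#' Configuration for the pathway-profile simulator
#'
#' Defaults mirror the pathway-model validation: 30 pathways of which 3 have
#' a true group difference (`spiked_effect`, log10 units, varied between 0
#' and 1) with residual noise about the linear species-pathway relationship
#' held at 1.
#'
#' @param n_pathways,n_spiked,spiked_effect,residual_sd,n_samples see above.
#' @param species_log10_mu,species_log10_sigma log10 species-abundance
#'   stand-in parameters.
#' @export
pathway_sim_config <- function(n_pathways = 30L, n_spiked = 3L,
                               spiked_effect = 1, residual_sd = 1,
                               n_samples = 400L,
                               species_log10_mu = -2,
                               species_log10_sigma = 1) {
  stopifnot(n_spiked <= n_pathways)
  as.list(environment())
}

#' Simulate within-species pathway profiles by running the carriage model
#' generatively
#'
#' `log10 pathway abundance = intercept_p + 1 * log10 species abundance +
#' effect_p * group + Normal(0, residual_sd)`, with pathway intercepts drawn
#' Normal(0, 1) and `effect_p = spiked_effect` for the spiked pathways, 0
#' otherwise; abundances are exponentiated back to the linear scale.
#'
#' @param cfg a [pathway_sim_config()].
#' @param seed integer seed.
#' @return list: `pathways` ([pathway_matrix()]), `meta` ([sample_metadata()]
#'   with the binary group as outcome), `truth` (spiked pathway ids).
#' @export
simulate_pathway_dataset <- function(cfg = pathway_sim_config(), seed = 1L) {
  with_seed(seed, {
    n <- cfg$n_samples; P <- cfg$n_pathways
    x <- rnorm(n, cfg$species_log10_mu, cfg$species_log10_sigma)
    grp <- rbinom(n, 1L, 0.5)
    int_p <- rnorm(P, 0, 1)
    eff_p <- c(rep(cfg$spiked_effect, cfg$n_spiked),
               rep(0, P - cfg$n_spiked))
    ly <- outer(int_p, x, function(i, xx) i + xx) +
      outer(eff_p, grp) + matrix(rnorm(P * n, 0, cfg$residual_sd), P, n)
    sample_ids <- sprintf("s%03d", seq_len(n))
    pwy_ids <- sprintf("pwy%02d", seq_len(P))
    pm <- pathway_matrix(10^ly, species_abundance = 10^x,
                         species_name = "sim_species",
                         pathway_ids = pwy_ids, sample_ids = sample_ids)
    meta <- sample_metadata(sample_ids, grp)
    list(pathways = pm, meta = meta,
         truth = list(spiked_pathways = pwy_ids[eff_p != 0],
                      effects = setNames(eff_p, pwy_ids)))
  })
}

#' Binary classification metrics
#'
#' @param scores numeric scores (higher = more positive) or, if `calls`
#'   given, ignored for TPR/FPR/PPV.
#' @param truth logical/0-1 vector of true positives.
#' @param calls optional logical vector of positive calls; default
#'   `scores > 0.5`.
#' @return named list: `tpr`, `fpr`, `ppv`, `auc` (rank statistic; NA when a
#'   denominator class is empty).
#' @export
classification_metrics <- function(scores, truth, calls = NULL) {
  truth <- as.logical(truth)
  stopifnot(length(scores) == length(truth))
  if (is.null(calls)) calls <- scores > 0.5
  tp <- sum(calls & truth); fp <- sum(calls & !truth)
  fn <- sum(!calls & truth); tn <- sum(!calls & !truth)
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  fpr <- if (fp + tn > 0) fp / (fp + tn) else NA_real_
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  auc <- if (any(truth) && any(!truth)) {
    r <- rank(scores)
    (sum(r[truth]) - sum(truth) * (sum(truth) + 1) / 2) /
      (sum(truth) * sum(!truth))
  } else NA_real_
  list(tpr = tpr, fpr = fpr, ppv = ppv, auc = auc)
}
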