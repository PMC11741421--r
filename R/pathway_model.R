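## Within-species pathway carriage model: pathway abundance tracks species
## abundance on the log-log scale; strains that preferentially retain or
## lose a pathway in one phenotype group show up as a pathway-specific
## vertical shift. Hierarchical random effects share information across
## pathways while an aggressive Exponential(3) prior on the group-effect
## scale encodes that few pathways truly differ.

#' Prepare pathway-model input
#'
#' Takes base-10 logs of pathway and species abundances, discarding
#' observations where either is zero (the model works on log abundances),
#' and records the empirical mean `EM` of the retained log pathway
#' abundances (used to center the global-intercept prior). Pathways with
#' fewer than `min_obs` retained observations are dropped with a warning.
#'
#' @param pm a [pathway_matrix()].
#' @param meta a [sample_metadata()] whose (binary) outcome is the group.
#' @param min_obs minimum retained observations per pathway (default 3).
#' @return list of class `pathway_fit_input`: vectors `log10_pathway`,
#'   `log10_species`, `group`, `pathway` (factor), `sample_id`, scalar `EM`.
#' @export
prepare_pathway_input <- function(pm, meta, min_obs = 3L) {
  stopifnot(inherits(pm, "pathway_matrix"))
  al <- align_samples(pm, meta)
  pm <- al$matrix; meta <- al$meta
  if (!all(meta$outcome %in% c(0, 1))) stop("group must be binary 0/1")
  ab <- pm$abundance
  sa <- pm$species_abundance
  keep_s <- sa > 0
  long <- data.frame(
    pathway = rep(pm$pathway_ids, times = sum(keep_s)),
    sample_id = rep(pm$sample_ids[keep_s], each = length(pm$pathway_ids)),
    abundance = as.vector(ab[, keep_s, drop = FALSE]),
    species = rep(sa[keep_s], each = length(pm$pathway_ids)),
    group = rep(meta$outcome[keep_s], each = length(pm$pathway_ids)),
    stringsAsFactors = FALSE)
  long <- long[long$abundance > 0, , drop = FALSE]
  cnt <- table(long$pathway)
  low <- names(cnt)[cnt < min_obs]
  dropped <- c(low, setdiff(pm$pathway_ids, names(cnt)))
  if (length(dropped))
    warning("dropping ", length(dropped),
            " pathway(s) with < ", min_obs, " nonzero observations")
  long <- long[!long$pathway %in% low, , drop = FALSE]
  if (!nrow(long)) stop("all pathways dropped: no nonzero observations")
  pwy <- factor(long$pathway, levels = intersect(pm$pathway_ids,
                                                 unique(long$pathway)))
  structure(list(log10_pathway = log10(long$abundance),
                 log10_species = log10(long$species),
                 group = long$group, pathway = pwy,
                 sample_id = long$sample_id,
                 EM = mean(log10(long$abundance))),
            class = "pathway_fit_input")
}

#' Fit the pathway carriage random-effects model
#'
#' `log10(pwy_abd) ~ log10(species_abd) + (1 | pwy) + (0 + group | pwy) +
#' intercept`: a global intercept (prior `t(5, EM, 2.5)`), a global species
#' slope (prior `Normal(1, 1)`; consistent carriage means pathway abundance
#' rises one-for-one with species abundance on the log scale), pathway
#' random intercepts `Normal(0, sigma_int)` with `sigma_int ~
#' half-t(5, 0, 2.5)`, pathway group effects `Normal(0, sigma_effects)` with
#' the aggressive shrinkage prior `sigma_effects ~ Exponential(3)`
#' (independent of the intercepts), and residual scale `~
#' half-t(3, 0, 2.5)`. Sampled with the package's NUTS engine.
#'
#' @param inp a [prepare_pathway_input()] result.
#' @param settings a [sampler_settings()].
#' @return object of class `pathway_fit` with posterior draw matrices:
#'   `global_intercept`, `species_slope`, `pathway_intercepts`,
#'   `group_effects` (draws x pathways), `sigma_int`, `sigma_effects`,
#'   `residual_scale`, plus `rhat`, `divergences`, `converged`, `warnings`.
#' @export
fit_pathway_model <- function(inp, settings = sampler_settings()) {
  stopifnot(inherits(inp, "pathway_fit_input"))
  P <- nlevels(inp$pathway)
  if (P < 2) stop("need >= 2 pathways")
  if (length(unique(inp$group)) < 2) stop("both groups must be present")
  data <- list(y = inp$log10_pathway, x = inp$log10_species,
               g = as.numeric(inp$group),
               pidx = as.integer(inp$pathway) - 1L,
               P = as.integer(P), EM = inp$EM)
  d <- 2L + 2L * P + 3L
  init_fun <- function() c(inp$EM + runif(1, -0.5, 0.5), 1 + runif(1, -0.5, 0.5),
                           inp$EM + runif(P, -0.5, 0.5),   # pathway totals
                           runif(P, -0.5, 0.5), runif(3, -1, 0))
  fit <- run_nuts("pathway", data, init_fun, settings = settings)
  dr <- fit$draws
  lev <- levels(inp$pathway)
  s_int <- exp(dr[, 2 + 2 * P + 1])
  s_eff <- exp(dr[, 2 + 2 * P + 2])
  # sampled as pathway totals eta_p = alpha0 + intercept_p
  pathway_intercepts <- dr[, 2 + seq_len(P), drop = FALSE] - dr[, 1]
  group_effects <- dr[, 2 + P + seq_len(P), drop = FALSE] * s_eff
  colnames(pathway_intercepts) <- colnames(group_effects) <- lev
  structure(list(global_intercept = dr[, 1], species_slope = dr[, 2],
                 pathway_intercepts = pathway_intercepts,
                 group_effects = group_effects,
                 sigma_int = s_int, sigma_effects = s_eff,
                 residual_scale = exp(dr[, 2 + 2 * P + 3]),
                 rhat = fit$rhat, divergences = fit$divergences,
                 converged = fit$converged, warnings = fit$warnings,
                 pathway_ids = lev),
            class = "pathway_fit")
}

#' @export
print.pathway_fit <- function(x, ...) {
  cat(sprintf("<pathway_fit> %d pathways, %d draws; slope mean %.3f; max Rhat %.3f\n",
              length(x$pathway_ids), nrow(x$group_effects),
              mean(x$species_slope), max(x$rhat, na.rm = TRUE)))
  invisible(x)
}

#' Call differentially carried pathways
#'
#' A pathway is a hit iff all three criteria hold: (1) its central
#' `interval_level` posterior interval on the group effect excludes zero,
#' (2) the absolute posterior mean group effect exceeds
#' `effect_threshold` (0.25 log10 units, i.e. a 10^0.25 ~ 1.78-fold
#' change), and (3) the posterior mean species slope is positive.
#'
#' @param fit a [fit_pathway_model()] result.
#' @param interval_level central interval (default 0.98).
#' @param effect_threshold minimum absolute posterior mean on the log10
#'   scale (default 0.25).
#' @return data.frame: `pathway`, `effect` (posterior mean), `lower`,
#'   `upper`, `fold_change` (= 10^|effect|), `excludes_zero`,
#'   `exceeds_threshold`, `slope_positive`, `is_hit`.
#' @export
call_pathway_hits <- function(fit, interval_level = 0.98,
                              effect_threshold = 0.25) {
  stopifnot(inherits(fit, "pathway_fit"))
  a <- (1 - interval_level) / 2
  qs <- apply(fit$group_effects, 2, quantile, probs = c(a, 1 - a))
  eff <- colMeans(fit$group_effects)
  slope_pos <- mean(fit$species_slope) > 0
  out <- data.frame(pathway = fit$pathway_ids, effect = eff,
                    lower = qs[1, ], upper = qs[2, ],
                    fold_change = 10^abs(eff),
                    excludes_zero = qs[1, ] > 0 | qs[2, ] < 0,
                    exceeds_threshold = abs(eff) > effect_threshold,
                    slope_positive = slope_pos,
                    stringsAsFactors = FALSE)
  out$is_hit <- out$excludes_zero & out$exceeds_threshold & out$slope_positive
  rownames(out) <- NULL
  out
}
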