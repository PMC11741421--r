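# strainepi

Strain-level association models for shotgun metagenomics. Given
species-stratified gene-family or pathway profiles (HUMAnN-style TSVs),
per-sample metadata, and optionally per-species trees, `strainepi` asks
three complementary questions about the sub-species variation of each
species:

1. **Which individual genes does the outcome-associated strain carry?**
   Adaptive coverage filtering (k-means on per-sample gene-count and
   median-log-abundance statistics) selects the species–sample pairs with
   saturated gene repertoires, then per-gene GLMs
   `outcome ~ covariates + gene_presence` with Benjamini–Hochberg
   correction — or a joint regularized-horseshoe regression over all genes —
   call differentially carried genes.
2. **Does the species' phylogeny structure the outcome?** A Bayesian
   phylogenetic generalized linear mixed model
   `y = Xβ + u + ε`, `u ~ MVN(0, σ_P² Ω)`, `ε ~ Normal(0, σ_R²)`, with Ω the
   tree-derived correlation matrix and an optional Gamma(1, 2) penalty on
   σ_P/σ_R (86% prior mass below 1). Species are ranked by leave-one-out
   ELPD improvement over a phylogeny-free base model, computed with
   integrated importance sampling (leaf effects integrated out analytically
   before Pareto-smoothed weighting).
3. **Which pathways do outcome-associated strains retain or lose?** A
   hierarchical random-effects model
   `log10(pwy_abd) ~ log10(species_abd) + (1|pwy) + (0+group|pwy) + intercept`
   with an aggressive Exponential(3) shrinkage prior on the group-effect
   scale; hits require a 98% interval excluding zero, |effect| > 0.25
   (≥ 1.78-fold), and a positive species slope.

Posterior inference runs on the package's built-in No-U-Turn Hamiltonian
Monte Carlo engine (C++ via Rcpp/RcppArmadillo; 4 chains × 1000 warmup +
1000 draws by default, split-R̂ and divergence diagnostics attached to every
fit). A PERMANOVA comparator and simulation generators for all three data
types (log-normal species abundances, skew-normal gene noise, logistic
zero-inflation, phylogenetically structured outcomes, reverse-generated
pathway profiles) are included.

## Worked example

Simulate a gene-profile study (400 subjects, 1000 genes, 5 risk genes that
each raise disease log-odds by 1, 25% of subjects poorly covered), filter,
and test:

```r
library(strainepi)

sim <- simulate_gene_dataset(gene_sim_config(n_risk_genes = 5), seed = 1)
flt <- filter_pipeline(sim$genes, fraction = 0.005, seed = 1)
table(flt$labels$labels$label)
#> poorly_covered   well_covered
#>            177            223

assoc <- call_gene_hits(fit_gene_glms(flt$matrix, sim$meta), q_threshold = 0.05)
metrics <- classification_metrics(abs(assoc$coefficient),
                                  assoc$gene %in% sim$truth$risk_genes,
                                  calls = assoc$is_hit %in% TRUE)
round(unlist(metrics), 3)
#>   tpr   fpr   ppv   auc
#> 0.000 0.000    NA 0.962
```

The filter keeps 223 of 400 samples (the 100 planted poorly covered
subjects plus low-abundance subjects are dropped). Ranking genes by
|coefficient| places the 5 planted risk genes near the top (AUC 0.96) while
the strict Q < 0.05 rule calls no false positives — with modest power at
this effect size, the conservative trade-off the gene model is designed
for.

A phylogenetic fit on simulated lineage-structured data:

```r
sim <- simulate_phylo_dataset(n_tips = 100, sigma_p = 2.09, sigma_r = 0.418,
                              seed = 32)
cmp <- compare_models(sim$outcome, X = NULL, omega = sim$omega,
                      family = "gaussian",
                      settings = sampler_settings(chains = 2, warmup = 500,
                                                  draws = 500, seed = 13))
cmp
#> ELPD comparison: pglmm -141.84 vs base -192.33; diff 50.49 +/- 5.90 [positive call]
```

The phylogeny term improves leave-one-out predictive density by ~50 nats
(8.6 SE): a strong lineage–phenotype association, as planted
(true R² = 0.962).

## Command line

A thin launcher over the same functions is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "strainepi.R", package = "strainepi"))')" \
  filter --genes genefamilies.tsv --fraction 0.005 --seed 1 --out-dir out/
```

Subcommands: `simulate {genes,phylo,pathways}`, `filter`, `gene`, `tree`,
`pglmm`, `pathway`, `permanova`, `all`. Every run writes its result tables
plus a `run_manifest.json` recording the resolved options, seed, and any
warnings (including sampler non-convergence).

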