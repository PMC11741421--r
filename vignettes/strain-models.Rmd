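---
title: "Models for strain-level metagenomic association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models for strain-level metagenomic association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Species-level profiles hide most of the action in microbiome epidemiology:
strains of one species can differ by hundreds of gene families, whole
metabolic pathways, and deep phylogenetic splits, and those differences —
not the species' overall abundance — often carry the association with a host
phenotype. `strainepi` provides three complementary models for this setting,
an adaptive coverage filter that decides which species–sample pairs are
usable at all, and the simulation machinery to validate everything. This
vignette is the package's account of those methods: the models, their
priors, the tunable parameters, the numerical choices, and what the
simulations do and do not establish.

## Adaptive coverage filtering

Gene-level profiles are only informative when the species is sequenced
deeply enough that its typical gene repertoire saturates (collector's-curve
logic). For each species–sample pair we compute two statistics: the number
of genes with nonzero abundance, and the median natural-log abundance of
those nonzero observations. Samples split into two clouds in this plane —
saturated and unsaturated — and a k-means clustering with $k = 2$ labels
them `well_covered` / `poorly_covered`; the cluster whose centroid has the
larger sum of standardized coordinates is the well-covered one.

Numerical choices, made once:

* Both statistics are standardized to zero mean and unit variance before
  clustering. They live on incommensurate scales (a count against a log);
  without standardization the count would dominate the distance entirely.
* k-means uses a seeded deterministic multi-start (10 restarts, best
  within-cluster sum of squares), so labels are reproducible and invariant
  to sample order.
* The natural log is used for the median statistic. Any base gives the same
  clustering geometry after standardization.
* Samples with no nonzero genes never enter the clustering; they are labeled
  poorly covered directly. Ties between centroid coordinate sums are broken
  toward the cluster with the larger gene-count centroid, since breadth of
  coverage is the primary saturation signal.

The full filter runs prevalence → coverage → prevalence → binarization. The
prevalence rule removes genes observed in fewer than
$t = \lfloor 0.005\,N \rfloor$ samples or in more than $N - t$ (counts equal
to either bound are kept — "fewer than" and "more than" are read strictly).
At $N = 1262$ this gives bounds of 6 and 1256. The second prevalence pass
recomputes $t$ from the post-filter sample count. Near-absent genes carry no
information; near-universal genes are core genome, not strain variation.

## Per-gene models and the horseshoe alternative

After binarization, the default association model is one GLM per gene,
`outcome ~ covariates + gene_presence` (identity link for continuous
outcomes, logit for binary), with Wald p-values for the presence term and
Benjamini–Hochberg correction across the species' surviving genes; hits are
called at $Q < 0.05$ by default (strict inequality, configurable). BH is
applied per species because hit lists are reported and interpreted per
species. Genes with constant presence are skipped; logistic fits with
complete separation are flagged and excluded from the correction rather than
reported with meaningless standard errors.

The joint alternative places a regularized horseshoe prior on all gene
coefficients simultaneously: per-gene half-Cauchy local scales
$\lambda_g$, a global scale $\tau$ with half-Cauchy prior centered on
$\tau_0 = \frac{p_0}{1-p_0}\,\frac{\tilde\sigma}{\sqrt n}$, and a
Student-t slab (scale 2.5, 4 degrees of freedom) bounding large
coefficients. The default prior expectation is $p_0 = 1\%$ nonzero
coefficients. A gene is a hit when its central 99% posterior interval
excludes zero *and* its absolute posterior mean exceeds the effect threshold
(default 0.5 on the link scale — deliberately conservative, configurable).
Genes with exactly identical presence patterns are perfectly collinear;
they are collapsed to one representative before sampling and expanded
afterward with the shared coefficient, flagged in the output.

## Phylogenetic generalized linear mixed models

Whole-lineage effects that no single gene captures are modeled with a
PGLMM:

$$y = X\beta + u + \varepsilon,\qquad
  u \sim \mathrm{MVN}(0,\ \sigma_P^2\,\Omega),\qquad
  \varepsilon \sim \mathrm{Normal}(0,\ \sigma_R^2),$$

where $\Omega$ is the correlation matrix derived from the per-species tree:
the covariance of two leaves is their shared root-to-tip branch length,
standardized to unit diagonal. $\sigma_P$ ("phylogenetic noise") scales the
tree's contribution; for Gaussian outcomes the share
$R^2 = \sigma_P^2/(\sigma_P^2+\sigma_R^2)$ is the quantity of interest.
Binary outcomes use a logit link and have no residual scale.

Because neither noise scale is known a priori and the leaf-effect vector is
extremely flexible, the default fit is *regularized*: a
$\mathrm{Gamma}(1, 2)$ penalty on the ratio $\sigma_P/\sigma_R$, which
places $1 - e^{-2} \approx 86\%$ prior mass on ratios below 1 with density
concentrated toward 0. In simulation this dramatically reduces variance at
small $n$ at the cost of a small negative bias at large $n$. The remaining
priors are weak and exposed as configuration: $\beta \sim N(0, 5)$,
$\sigma_P, \sigma_R \sim$ half-Student-t(3, 0, 2.5). For the Bernoulli
family the ratio is undefined, so the regularizer is replaced by a tighter
half-Student-t(3, 0, 1) on $\sigma_P$.

Sampling uses the package's own No-U-Turn Hamiltonian Monte Carlo engine
(C++): dual-averaging step-size adaptation targeting acceptance 0.8,
windowed diagonal mass-matrix estimation, maximum tree depth 10, default
four chains of 1000 warmup + 1000 retained draws. The leaf effects use the
non-centered parameterization $u = \sigma_P L z$ with $L$ the Cholesky
factor of $\Omega$ (eigenvalue-clipped at zero plus a $10^{-8}$ diagonal
jitter when numerically indefinite). Any split-$\hat R > 1.01$ or divergent
transition attaches a prominent non-convergence warning to the fit and the
CLI manifest. Leaf-effect posteriors are retained rather than marginalized
out, so results can be juxtaposed against the tree.

### Model comparison by integrated leave-one-out ELPD

The PGLMM is compared against a base GLM with the same covariates but no
phylogeny term, by leave-one-out expected log pointwise predictive density.
The naive pointwise likelihood of a model with one free effect per
observation is ill-behaved under importance sampling, so the leaf effect is
integrated out analytically before weighting: under the tree prior,

$$u_i \mid u_{-i} \sim \mathrm{Normal}\!\left(u_i - \frac{(Qu)_i}{Q_{ii}},\
  \frac{\sigma_P^2}{Q_{ii}}\right),\qquad Q = \Omega^{-1}.$$

For Gaussian outcomes the integrated predictive is available in closed
form; for Bernoulli outcomes the one-dimensional integral is evaluated by
Gauss–Hermite quadrature (21 nodes; the rule is exact for polynomial
moments and the integrand is a logistic function of a Gaussian, for which
21 nodes are ample). The integrated likelihoods feed Pareto-smoothed
importance sampling (tail fitted by the Zhang–Stephens generalized-Pareto
estimator; $\hat k > 0.7$ triggers a per-sample warning). The base model is
scored by standard PSIS-LOO. A species is called positive when
`elpd_diff - 2 * se_diff > 0`; the multiplier is configurable, and the
2-SE rule is one consistent choice rather than a canonical one.

At $n \le 8$ the integrated-IS estimate agrees with brute-force
leave-one-out refitting within Monte-Carlo error; this equivalence is part
of the test suite.

## Pathway carriage model

Species-stratified pathway abundance tracks overall species abundance
almost mechanically; what carries strain information is a pathway sitting
*below* (or above) that line in one phenotype group — strains that lost or
retained it. The model, in random-effects formula notation:

```
log10(pwy_abd) ~ log10(species_abd) + (1 | pwy) + (0 + group | pwy) + intercept
```

with priors: pathway intercepts $\sim N(0, \sigma_{\mathrm{int}})$,
$\sigma_{\mathrm{int}} \sim$ half-t(5, 0, 2.5); group effects
$\sim N(0, \sigma_{\mathrm{eff}})$ independent of the intercepts, with the
deliberately aggressive shrinkage $\sigma_{\mathrm{eff}} \sim
\mathrm{Exponential}(3)$ (prior mass $1 - e^{-0.75} \approx 53\%$ below
0.25) encoding that few pathways truly differ; global intercept $\sim$
t(5, EM, 2.5) where EM is the empirical mean of the retained log10 pathway
abundances; species slope $\sim N(1, 1)$ (consistent carriage means the
log-log slope is near one); residual scale $\sim$ half-t(3, 0, 2.5). The
scale priors are half distributions truncated to the positives — the only
reading consistent with their role. Zeros are discarded before logging; a
censored-zero variant was deliberately omitted, as it adds substantial
computational cost without changing results in practice. Pathways with
fewer than three retained observations are dropped with a warning.

A pathway is a hit only if all three criteria hold: its 98% posterior
interval on the group effect excludes zero, the absolute posterior mean
exceeds 0.25 ($10^{0.25} \approx 1.78$-fold), and the posterior mean
species slope is positive (a negative slope means the global
species–pathway relationship itself is broken, and a "group shift" around a
broken relationship is uninterpretable).

Sampling note: the likelihood is parameterized in pathway-level totals
$\eta_p = \alpha_0 + \text{intercept}_p$ with hierarchical prior
$\eta_p \sim N(\alpha_0, \sigma_{\mathrm{int}})$ — the centered form,
appropriate because hundreds of observations identify each total directly,
and one that avoids the near-flat ridge a global-intercept-plus-deviations
split would create. The group effects are sampled *non-centered*
($\mathrm{eff} = \sigma_{\mathrm{eff}} z$): under the aggressive shrinkage
prior most sit near zero, exactly where the centered form funnels. Both
choices are pure reparameterizations (unit Jacobian) of the stated model.

## PERMANOVA comparator

The distance-based comparator used in the phylogenetic simulation study is
implemented from the Gower-centering construction:
$G = -\tfrac12 J (d \circ d) J$, $R^2 = \operatorname{tr}(HGH) /
\operatorname{tr}(G)$ with $H$ the hat matrix of the intercept + covariate
design, pseudo-F from the partition, and the p-value from permutations of
sample labels (residual permutation under the intercept-only reduced
model). Under the causal structure used in the simulations — phylogeny
*causes* the outcome — its $R^2$ systematically and dramatically
underestimates the generative variance share; this is a property of the
statistic, not a bug, and is asserted in the test suite. One canonical
variant is implemented; its agreement with `vegan::adonis2` is a
cross-check in the tests.

## What the simulations emulate — and what they do not

Three generators mirror the validation studies:

* **Gene profiles.** Species natural-log abundance per subject is drawn
  $N(0, 2)$ — a configurable log-normal stand-in for a stool-like community
  preset, the width chosen to span the realistic several-orders-of-magnitude
  range of per-species relative abundance. Each subject carries each gene
  with probability 0.5; disease log-odds are
  `intercept + 1 * (# carried risk genes) + species_effect * standardized
  species log abundance`, with the intercept set for ~50% baseline
  prevalence and subjects drawn until 200 cases and 200 controls (defaults).
  Carried-gene log abundance is the species log abundance plus
  skew-normal(0, 1, −1) noise; 25% of subjects have all log abundances
  shifted by −4 ("poorly covered"); every observation is zeroed with
  probability $1/(1 + e^{a - \mathrm{med}_g})$ — the logistic centered on
  the per-gene median with growth rate −1.
* **Phylogenies.** Random binary topologies with uniform branch lengths;
  `outcome = MVN(0, sigma_p^2 Omega) + MVN(0, sigma_r^2 I)`. The validation
  grid takes six evenly spaced values per axis over tips 10–450 and both
  noise scales 0–2.09, dropping the both-zero corner: 210 points.
* **Pathways.** The carriage model run generatively in reverse: 30
  pathways, 3 spiked with a group effect varied in [0, 1], residual noise
  held at 1, species log10 abundance drawn $N(-2, 1)$ (a typical stool
  relative-abundance range; the value is a package choice, stated here
  once).

These generators reproduce the statistical structure the models assume —
which is exactly why passing tests validate the *inference machinery*, not
the models' fit to real metagenomes. Real data add compositionality,
read-mapping ambiguity between close relatives, covariate-correlated
sequencing depth, and gene–gene linkage, none of which are simulated. The
test suite verifies calibration and recovery under the stated generative
conditions at desk scale: recovery runs use 5 replicates per condition and
reduced sampler settings (2 chains of a few hundred draws), pathway and
ELPD calibration use 10 replicates, and the coverage-filter accuracy check
uses 20 replicates — the package's chosen verification sizes, with the
asserted properties robust to the shorter runs.

## Known limitations

* One-at-a-time gene tests cannot distinguish a causal gene from the
  hundreds of genes private to an outcome-confounded subclade; the
  horseshoe model helps, but only external linkage information resolves it.
  Fitting a PGLMM on the gene-derived tree is the recommended diagnostic.
* The PGLMM accepts a single tree per species and no secondary covariance
  term (e.g. shared geography); offset support is limited to fixed-effect
  covariates.
* The pathway model assumes a binary group variable and a common species
  slope across pathways.
* Trees built by `build_tree()` are adaptive-PCA/neighbor-joining
  approximations from gene presence — fast and adequate for covariance
  construction, not substitutes for SNP-based phylogenetics. The eigenvalue
  rule keeps components up to and including the first eigenvalue below one
  tenth of the leading one (the inclusive reading; an exclusive variant is
  exposed as a flag). PCA centers but does not scale the presence columns,
  which already share the \{0,1\} scale.
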