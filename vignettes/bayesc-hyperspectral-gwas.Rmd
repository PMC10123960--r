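---
title: "Spike-and-slab whole-genome regression for multiphenotype GWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-and-slab whole-genome regression for multiphenotype GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Hyperspectral leaf reflectance (here 150 bands across 386–1021 nm, plus
arithmetic band combinations called spectral indices) is an inexpensive,
high-dimensional phenotype that correlates with pigments, nutrient status
and biomass. When a diversity panel of inbred lines is both genotyped and
imaged, each band and each index can be treated as a quantitative trait in
its own right: one can ask how heritable it is, how strongly it is
genetically correlated with manually measured growth traits (plant height,
stalk diameter, shoot dry mass), and which markers drive it. `specgwas`
implements that workflow for experiments with two contrasting managements
— with (B+) and without (B−) inoculation by plant growth-promoting
bacteria — where every model is fitted separately per management, since
inoculation can rewire the genetic architecture of early growth.

## Models

### Univariate BayesC

For plot-level phenotype $y_{kli}$ (replication $k$, block $l$ nested in
replication, genotype $i$):

$$y_{kli} = \mu + r_k + b_{l(k)} + \sum_{j=1}^m w_{ij}\,\alpha_j + \epsilon_{kli},$$

with dosage covariates $w_{ij} \in \{0,1,2\}$ and a spike-and-slab prior on
each marker effect: $\alpha_j = 0$ with probability $\pi$ and
$\alpha_j \sim N(0, \sigma^2_\alpha)$ otherwise. $\mu$, $r$, $b$ carry flat
priors; $\sigma^2_\alpha$ and $\sigma^2_\epsilon$ carry scaled
inverse-$\chi^2$ priors with $\nu = 4$ degrees of freedom. The prior scales
are set so that each prior variance mean equals `variance_partition`
(default one half) of the phenotypic variance; for the slab variance this
goes through the standard marker-variance partition
$(1-\pi)\sum_j 2p_j(1-p_j)\,E[\sigma^2_\alpha] = \tfrac12\mathrm{Var}(y)$,
since the mapping from marker variance to genetic variance is otherwise
underdetermined. $\pi$ is fixed (default 0.99), never estimated.

Each Gibbs sweep updates the fixed effects from their Gaussian full
conditionals, every marker's inclusion indicator (with the effect
integrated out) followed by its effect, and the two variances from their
scaled inverse-$\chi^2$ full conditionals, maintaining the residual vector
incrementally. Markers are visited in map order with a single RNG stream
seeded from the configuration.

Two summaries are derived per retained draw:

* the genomic variance $\sigma^2_g$ is the **empirical variance of
  $W\alpha$ across plots**, not the theoretical sum
  $\sum_j 2p_jq_j \sigma^2_\alpha$ — robust to LD and the common choice in
  whole-genome regression practice;
* genomic heritability $h^2_g = \sigma^2_g / (\sigma^2_g +
  \sigma^2_e/n_r)$ with $n_r$ the replication count (default 2), i.e. the
  heritability of a line mean.

The headline $h^2$ is the posterior mean of the per-draw ratio; the ratio
of posterior-mean variances is also reported
(`h2_from_post_means`) because either convention appears in the
literature. A marker's posterior inclusion probability (PIP) is the
fraction of retained (thinned, post-burn-in) draws with a nonzero effect.

### Bivariate BayesC

For a pair of traits the marker effect is reparameterized as
$\alpha_j = D_j\beta_j$ with $\mathrm{diag}(D_j) = \delta_j =
(\delta_{j1}, \delta_{j2})$ and $\beta_j \sim N(0, \Sigma_\alpha)$;
residual rows are $N(0, \Sigma_\epsilon)$. Both covariance matrices carry
inverse-Wishart priors $W^{-1}(S, \nu)$ with $\nu = 4$ and scale matrices
chosen so the prior mean $S/(\nu - \dim - 1)$ equals the configured
partition of each trait's phenotypic variance (zero prior covariance). All
four inclusion categories $(0,0), (0,1), (1,0), (1,1)$ have nonzero
probability; the default category prior is the product of independent
per-trait inclusion probabilities, which is the least-committal choice
when only per-trait sparsity levels are specified, and is fully
configurable. Per sweep the category is sampled with $\beta_j$ integrated
out under the active sub-block of $\Sigma_\alpha$; $\Sigma_\alpha$ is then
updated over markers with at least one active trait, the inactive
component filled in from its conditional prior.

The genomic correlation $r_g$ between the two traits is the posterior mean
of the **per-draw Pearson correlation of line-level genetic values**,
consistent with the empirical $\sigma^2_g$ convention above; the
correlation implied by $\Sigma_\alpha$ is also reported
(`rg_from_Sigma_alpha`). The two can differ: the $\Sigma_\alpha$ entry
describes per-marker effect covariance, the genetic-value correlation
describes the realized aggregate, which is what a breeder uses. Draws in
which either trait has zero genetic variance (possible under heavy
sparsity) are skipped and counted.

### Marker selection and annotation

Markers are selected by PIP with the inclusive rule `pip >= threshold`:
0.10 for manually measured traits, 0.50 (more conservative) for the 281
hyperspectral phenotypes, reflecting the different multiplicity of the two
phenotype families. Gene lookup takes all genes whose span intersects the
closed interval ±50 kbp around the marker (any-overlap rule; clipped at
position 1). PIP rather than window posterior probability is used
throughout because marker density is low and uneven in panels of this
kind.

## The synthetic-data generator

Real phenotypes and spectra of the motivating experiment are not publicly
deposited, so validation rests on a generator that emulates the
experiment's statistical structure with known ground truth:

* **Genotypes** — 360 lines × 13,826 SNPs on 10 chromosomes by default,
  founder allele frequency uniform on `maf_range`, and LD produced by
  block-copy-with-mutation: within a block of `ld_block_size` markers each
  allele is copied from the previous marker and resampled with probability
  `ld_flip_prob`. This gives controllable pairwise $r^2$ (geometrically
  decaying within blocks, zero across) — sufficient to exercise pruning,
  with no pretension to a realistic maize LD map or population structure.
* **Traits** — a sparse causal set (probability `1 - pi_sparsity`, or an
  exact `n_causal` for controlled experiments) with effects drawn jointly
  across traits from a multivariate normal with correlation `rg_target`,
  rescaled so the realized plot-level heritability equals `h2_target`
  exactly (defaults 0.61/0.60/0.30, the inoculated-management estimates
  for height, stalk diameter and dry mass). Replication and
  block-within-replication effects are drawn once per simulation and
  treated as fixed unknowns by the samplers. The B+ management shares
  genotypes and causal positions but redraws the effects of a configurable
  fraction of causal markers (default 0.8, since the motivating experiment
  found almost disjoint marker sets between managements); the distribution
  of inoculation response across lines is deliberately left as these two
  free parameters (`management_shift`, `management_resample_frac`) rather
  than asserting a biological model.
* **Spectra** — per-plot reflectance is a smooth leaf-like baseline plus
  sinusoidal band loadings times the plot's genetic values plus a
  low-order random Fourier noise series, clipped to $[0,1]$. The
  phase-shifted loadings make band–trait genetic correlations change sign
  along the spectrum, which is the qualitative feature the bivariate
  analysis must recover. Pixel-level cubes place a noisy rectangular
  "leaf" on constant background so masking can be tested against exact
  means.

A single master seed drives everything, with fixed offsets per stage
(+101 genotypes, +202 traits, +303 spectra, +404 synthetic annotation) so
stages are independently reproducible. What passing tests on these data do
**not** show: robustness to genotyping error, to non-Gaussian residuals,
to real LD decay, or to the camera's radiometric artifacts — none of which
the generator emulates.

## Numerical and design choices

* **Prior-scale mapping.** The phrase "prior mean equal to half the
  phenotypic variance" does not by itself fix the slab-variance scale; the
  marker-variance partition above is our documented assumption.
* **Validation chain lengths.** The default schedule is 60,000 iterations
  / 6,000 burn-in / thinning 60 (900 retained draws), the schedule used at
  analysis scale. Statistical-recovery checks in the test suite run
  shortened chains (30,000/3,000/27 univariate, 10,000/2,000/8 bivariate)
  on panels of 500 markers × 1,500 plots, and the end-to-end smoke run
  uses 6,000/600/6 on 300 lines × 1,000 markers — sizes at which the
  Monte-Carlo error is well below the tolerances being asserted.
* **Zero-variance markers** have undefined LD $r^2$; they are never pruned
  by correlation and are flagged in the QC report. Constant phenotypes are
  rejected by the samplers and skipped (with a log line) by the pipeline —
  a coarse band grid can collapse a normalized-difference index to a
  constant when both nominal wavelengths resolve to the same band.
* **Nearest-band resolution** breaks ties toward the lower wavelength and
  rejects targets more than one grid spacing outside the grid. Indices
  whose nominal wavelengths are unresolvable (e.g. SWIR-based NDNI on a
  VNIR camera) yield `NA` rather than an error, so a literature-faithful
  registry can be applied to any camera.
* **Index formulas** vary between sources, so the registry is data (JSON),
  each entry carrying its formula text and literature source. The index
  named "SD" is implemented as the sum of first-derivative reflectance
  over the red edge (626–795 nm) and stored as `SD_index` to avoid
  colliding with stalk diameter.
* **LD pruning** is exact greedy left-to-right within chromosome with the
  earlier-position marker winning — the unambiguous reading of an
  unparameterized pruning step, affordable at in-scope scales.
* **Imputation** is marker-mean dosage: after a 90% call-rate filter the
  residual missingness is small, and haplotype-based imputation is an
  external-tool concern out of scope here.
* **Covariance draws** that fail Cholesky are retried with escalating
  diagonal jitter and counted (`jitter_count`); persistent failure is an
  error, not a silent fallback.
* **Degenerate diagnostics.** Constant chains are flagged rather than
  given a numeric effective sample size; Geweke $|z| > 2$ flags a
  parameter for inspection.

## Limitations

Two traits per bivariate model (the full trait × band matrix is fitted
pairwise, as in the motivating study); $\pi$ and the category
probabilities are never estimated; no BayesA/B/LASSO variants; no
window-based association statistic; REML/GBLUP appears only as a
closed-form ridge oracle in tests. Under heavy sparsity with weak signal,
genomic-correlation estimates are attenuated toward zero relative to the
generative correlation — the per-draw genetic-value correlation can only
reflect markers the model currently includes — so near-threshold
correlation magnitudes should be read as lower bounds. Causal markers
whose drawn effects explain less than a few tenths of a percent of
phenotypic variance are statistically invisible at panel sizes of a few
hundred lines; power statements in the test suite are therefore statements
about detectable effects, and a Gaussian effect-size distribution places
mass near zero by construction.
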