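---
title: "Simulating and dissecting genome-microbiome-phenotype architectures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and dissecting genome-microbiome-phenotype architectures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holosim)
```

## The problem

Host genetics and microbiome composition both contribute to quantitative
phenotypes such as methane emission or feed efficiency in ruminants. Two
summary parameters are in play: heritability $h^2$, the fraction of
phenotypic variance explained by host SNPs, and microbiability $b^2$, the
fraction explained by microbial taxon abundances. Whether published
estimates of $b^2$ can be trusted, and how much the microbiome can add to
genomic prediction, depends on the causal architecture connecting genome
(G), microbiome (B) and phenotype (y) — which is unobserved.

`holosim` simulates data under six explicit causal scenarios and provides
the Bayesian machinery used to analyze them, so that estimation bias,
predictive accuracy and association-study power can be quantified under a
known ground truth:

* **Null** — neither G nor B affects y.
* **Genome** — only SNPs affect y ($b^2 = 0$).
* **Microbiome** — only abundances affect y ($h^2 = 0$).
* **Indirect** — G affects y only through genetically controlled
  abundances.
* **Joint** — G and B affect y independently ($h^2 = b^2 = r^2/2$).
* **Recursive** — G affects y directly *and* through genetically
  controlled abundances.

Here $r^2 = h^2 + b^2$ is the total signal; the default grids use
$r^2 = 0.5$ and $0.25$.

## The simulation model

The phenotype is additive in the causative features:

$$y_i = \sum_{j=1}^{N_{QTN}} \alpha_j z_{ij}
      + \sum_{k=1}^{N_{OTU}} \omega_k x_{ik} + \varepsilon_i,$$

where $z_{ij}$ is the genotype of individual $i$ at causative SNP $j$
(coded $-1/0/1$), and $x_{ik}$ is the log total-sum-scaled abundance of
causative taxon $k$. Since abundances enter on the log scale, $\omega_k$
acts multiplicatively on raw abundance. The SNP term is dropped in the
Microbiome/Indirect scenarios and the abundance term in the Genome
scenario. Effect magnitudes follow gamma laws — $|\alpha|, |\beta| \sim
\Gamma(0.2, 5)$ for SNP effects and $|\omega| \sim \Gamma(1.4, 3.8)$ for
abundance effects — with independent random signs (the laws are
positive-only; effects on a phenotype must be bidirectional, and nothing
downstream depends on the sign convention).

Genetically controlled abundances are themselves treated as complex traits:
$x_{ik} = \sum_j \beta_{jk} z_{ij} + \epsilon_i$, with a per-taxon
heritability $h_k^2$.

### Linking abundances to the genome without a parametric abundance model

Raw abundance tables are zero-inflated and highly leptokurtic, and no
parametric model reproduces all of their structure. Instead of sampling
abundances from a distribution conditional on genotypes, the package keeps
the observed (or generated) abundance matrix fixed and *rearranges rows*:
for a causative taxon $k$ with genetic value $\gamma_k = \sum_j \beta_{jk}
z_j$ and target correlation $\rho = h_k = \sqrt{h_k^2}$, `sortcor()` finds
a permutation of the abundance vector whose correlation with $\gamma_k$ is
approximately $\rho$, while the multiset of abundance values — hence every
marginal statistic — is exactly preserved. The construction sorts both
vectors, adds noise $e \sim N(0, S_y^2(1-\rho^2)/\rho^2)$ to the sorted
target to form a dummy variable, and reads the permutation off the ranks.
Accuracy improves with $n$ and needs no normality. Two limits need special
handling: $\rho = 0$ (the noise variance diverges; implemented as an
unconstrained shuffle) and $\rho = 1$ (exact co-sorting). Negative targets
are rejected: effect signs live in $\beta$ and $\omega$, not in the link.

Permuting a single taxon would break its covariance with every other
taxon. The package therefore clusters taxa (Ward D2 on Euclidean distances
between standardized log-abundance profiles, cut into $K = 500$ clusters by
default) and applies the *same* row permutation to the causative taxon's
entire cluster, which preserves within-cluster covariance exactly and
leaves all other clusters untouched. Profiles are standardized before the
distance computation so that squared distance is proportional to
$1 - r$ between taxa: clusters then collect correlated taxa rather than
taxa of similar mean abundance, which is what the co-permutation needs.
Causative taxa are drawn from distinct clusters. Tests verify that linking
a handful of clusters leaves the leading principal component of the
abundance matrix essentially unchanged.

### Variance targeting

Given the sampled effects, the genetic value $G_i$ and microbiome value
$M_i$ are standardized and scaled to $\mathrm{Var}(G) = h^2$,
$\mathrm{Var}(M) = b^2$ exactly; the residual is drawn as standard normal,
orthogonalized against $G$ and $M$, and scaled to variance $1 - r^2$. In
the Recursive scenario $G$ and $M$ are correlated through the genetically
controlled abundances; that cross-covariance is the biology being
simulated, so it is reported (`realized_gb_cov`), not removed, and the
exact decomposition is
$h^2 + b^2 + 2\,\mathrm{cov}(G, M) + (1 - r^2) = \mathrm{Var}(y)$.
This sum equals one to machine precision in every replicate, which the
test suite asserts.

### Threshold variant

To probe robustness to the multiplicative (log-linear) assumption,
`binarize_threshold()` generates phenotypes from 0/1 indicators of each
causative abundance exceeding its upper quartile (by default 25% of
observations above the threshold, ties broken by stable order), while the
analysis side still sees continuous log abundances — a deliberate
wrong-model stress test.

## The analysis models

All analyses use the linear model
$\mathbf{y} = \mathbf{Z}\mathbf{g} + \mathbf{W}\mathbf{b} + \mathbf{i} +
\mathbf{e}$ on standardized inputs, in two prior families (seven models in
total):

| tag | method | terms |
|-----|--------|-------|
| `Rgbx` | Bayesian RKHS (GBLUP) | G + B + G$\times$B |
| `Rgb`, `Rg`, `Rb` | Bayesian RKHS | G + B, G, B |
| `Cgb`, `Cg`, `Cb` | Bayes C | g + b, g, b |

**RKHS.** Random effects with covariances $\sigma_g^2 \mathbf{G}$,
$\sigma_b^2 \mathbf{B}$, $\sigma_i^2 (\mathbf{G} \circ \mathbf{B})$, where
$\mathbf{G} = \mathbf{Z}\mathbf{Z}'/p$ and $\mathbf{B} =
\mathbf{W}\mathbf{W}'/n_b$ are scaled by their feature counts so the mean
diagonal is about one, and $\circ$ is the Hadamard product (the analogue of
the additive-by-additive epistasis kernel). Each kernel is eigendecomposed
once and its effects are block-updated in the eigenbasis, where the
conditional posterior is diagonal — the whole sampler runs in a few
matrix-vector products per iteration. Variance components get
scaled-inverse-$\chi^2$ priors with $df = 5$ and scales whose prior mode
splits a prior $R^2 = 0.5$ equally across fitted components; the residual
gets the complementary scale. A `weakly_informative` mode ($df = 3$,
near-zero scale) mimics a REML-like estimator and is used for per-taxon
abundance heritabilities.

**Bayes C.** Spike-slab regression: each feature's effect is zero with
probability $1 - \pi$ or drawn from a common normal slab. The SNP block
and the taxon block keep separate $\pi$ and slab variances — pooling them
would confound exactly the $h^2/b^2$ split under study. The inclusion
prior is $\pi \sim \mathrm{Beta}(\pi_0 p_0, (1-\pi_0)p_0)$ with defaults
$\pi_0 = 0.001$, $p_0 = 5$ (a liberal alternative $\pi_0 = 0.01$,
$p_0 = 2$ is available). The slab scale is sized so that the expected
$\pi_0 p$ included features explain their share of the prior $R^2$. The
per-feature Gibbs loop is implemented in compiled code.

**Shared machinery.** At every kept iteration both samplers record
$\mathrm{Var}(\mathbf{u})/\mathrm{Var}(\mathbf{y})$ and
$\mathrm{Var}(\mathbf{v})/\mathrm{Var}(\mathbf{y})$, where $\mathbf{u} =
\mathbf{Z}\hat{\mathbf{g}}$ and $\mathbf{v} = \mathbf{W}\hat{\mathbf{b}}$
are the sampled genome and microbiome values — their posterior means are
the heritability and microbiability estimates. Bayes C additionally
records the absolute covariance share
$|\mathrm{cov}(\mathbf{u}, \mathbf{v})|/\mathrm{Var}(\mathbf{y})$
(a probe for genome-microbiome covariance) and per-feature inclusion
indicators. Held-out phenotypes are handled by data augmentation: they are
sampled each iteration, contribute no information, and their predictions
are the posterior mean of the linear predictor. Chain defaults are 50,000
iterations, 500 burn-in, thinning 5; all experiments in the tests and the
acceptance script use 5,000 iterations, which the traces show is ample at
these problem sizes (a stationarity test on the residual-variance trace is
part of the suite).

The fixed-variance RKHS posterior mean is validated against the direct
mixed-model (BLUP) solution, and the single-regressor Bayes C posterior
against the conjugate closed form.

## The synthetic data generator

Since the original livestock datasets cannot be redistributed, the
`fixtures` module generates inputs with their salient statistics:

* **Genotypes** — allele frequencies from a truncated Beta(0.5, 0.5)
  (U-shaped) spectrum; two latent Gaussian haplotype fields with AR(1)
  correlation 0.9 inside 10-SNP blocks, thresholded at the allele-frequency
  quantile: Hardy-Weinberg genotypes with local LD.
* **Abundances** — a latent Gaussian with common-factor correlation 0.6
  inside each of 100 planted taxon clusters, exponentiated to log-normal
  counts with heterogeneous per-taxon location and dispersion, then zeroed
  below per-taxon quantiles targeting 50% zero cells overall. Raw columns
  have median excess kurtosis well above 5; the log-TSS transform (a
  pseudo-count of 1 added to zero cells, division by the post-pseudo-count
  row total, then log) yields much less leptokurtic distributions — both
  asserted in tests.

The generator reproduces marginal shape, zero inflation, taxon correlation
blocks and LD; it does **not** model read-depth variation, phylogenetic
structure, or taxon-taxon interaction networks, so passing tests speak to
the statistical machinery, not to any particular real community. The
default scale — 300 individuals, 3,000 SNPs, 800 taxa — was chosen once as
large enough for the permutation algorithm and the samplers to operate in
their asymptotic regime while keeping a full scenario-by-model grid
runnable on a laptop; the causative counts ($N_{QTN} = 100$,
$N_{OTU} = 25$ by default) follow the standard grid. Two quantities the
study design leaves open are fixed as package defaults: each controlled
taxon gets 10 abundance QTNs, and per-taxon heritabilities follow
$\Gamma(2, 0.125)$ truncated to $(0.01, 0.9)$ (mean about 0.25), a
gamma-shaped law consistent with reported abundance-heritability
distributions.

## Worked example

```{r example, eval = FALSE}
spec <- fixture_spec(n = 300, p = 3000, k = 800)
set.seed(1)
g <- gen_genotypes(spec)
a <- tss_log_transform(gen_abundances(spec))
clusters <- cluster_taxa(a, K = 500)

cfg <- scenario_config("Recursive", r2 = 0.5)   # h2 = b2 = 0.25
sim <- simulate_dataset(cfg, g, a, clusters, seed = 2)
sim$realized_h2 + sim$realized_b2 + sim$realized_gb_cov + sim$realized_resid
#> [1] 1

inputs <- analysis_inputs(g, sim$abundances_linked)
mc <- mcmc_settings(5000, 500, 5)
fit_rkhs(sim$y, inputs$kernels, c("G", "B"), mcmc = mc)
fit_bayesc(sim$y, inputs$Z, inputs$W, mcmc = mc)

cv_accuracy(sim, inputs, "Cgb", mcmc = mc, seed = 3)$accuracy
mwas_power(sim)$power
```

## Numerical choices and edge cases

* Standardization uses the sample SD ($n-1$ denominator); hand-worked
  examples in the tests follow this convention.
* The pseudo-count is added to zero cells only (a flag switches to
  all-cell addition), and total-sum scaling divides by the
  post-pseudo-count row total.
* Ties in ranks and quantiles are broken by first occurrence (stable
  order) everywhere, so results are bit-reproducible under a fixed seed.
* Kernel diagonals receive a $10^{-8}$ jitter before eigendecomposition;
  eigenvalues below $10^{-8}$ of the maximum are dropped.
* A monomorphic QTN draw for an abundance (zero-variance genetic value) is
  resampled with a warning; monomorphic SNPs are dropped before
  standardization and get p-value 1 in association scans.
* Var(y) in all variance-share estimates is the variance of the observed
  (non-masked) phenotypes.

## Known limitations

* At the default desk scale ($n = 300$), Bayes C has limited power for
  highly polygenic architectures: with 250 causative taxa the per-feature
  signal falls below what the spike-slab prior can pick up, and the
  microbiability estimate collapses toward zero, whereas at larger $n$
  (and the correspondingly larger feature panels) the same sampler
  recovers — and overestimates — $b^2$. Conclusions about Bayes C bias at
  this scale are therefore conservative; RKHS estimates are robust across
  scales.
* The permutation link attains target correlations only approximately at
  small $n$ (the error decreases as $n^{-1/2}$-ish; the suite checks a
  0.05 bound at $n = 2000$).
* GWAS detectability of abundance QTNs is governed by the per-taxon QTN
  count: with the default of 10 QTNs per controlled abundance, individual
  QTN effects ($h_k^2/10$ each on average) are large enough to be
  individually detectable at these sample sizes; architectures with many
  more, weaker QTNs per abundance push detection toward chance level.
* Only biallelic SNPs and mean imputation are supported; no phasing, no
  rarefaction, no Bray-Curtis kernels, no structural-equation extensions.
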