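---
title: "Models and methods behind magicGP"
author: "magicGP authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind magicGP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`magicGP` implements genomic prediction (GP) for eight-way MAGIC
populations of doubled-haploid (DH) lines evaluated in multi-environment
yield trials. This vignette records the models, the assumptions behind
them, the tunable parameters and the numerical decisions, so that users
can judge what a given result does and does not establish.

# The MAGIC simulator

## Crossing design

The simulated population mirrors a standard eight-founder funnel with a
DH finish. Four "old" varieties are each crossed to one "modern" variety
(4 F1s); the half-diallel among the F1s yields six four-way sets; pairs of
founder-disjoint four-way sets are united so that each eight-way funnel
carries all eight founders exactly once (three such pairings exist, and
all are used). Instead of recursive selfing, one gamete of each eight-way
individual is doubled, so every line is fully homozygous and its genome is
a mosaic of founder segments with expected share 1/8 per founder. Lines
are spread as evenly as possible across funnels; how many DH lines real
programmes derive per funnel is generally not reported, so an even split
is the neutral choice.

## Meiosis

Crossovers per chromosome are Poisson with mean equal to the map length in
Morgans, placed uniformly on the cM scale. This is the Haldane model: no
interference, and a recombination fraction of `(1 - exp(-2d))/2` between
positions `d` Morgans apart. It is the simplest model consistent with a
cM map; real barley meiosis shows positive interference, which slightly
reduces double-crossover rates — immaterial for the relationship
structure GP models consume.

## Markers and founders

Markers are abstract biallelic loci on a barley-like map: 7 chromosomes,
~150 cM and ~600 Mb each by default. Founder haplotypes are drawn at a
per-marker allele frequency sampled from `mafRange` (default 0.1–0.5);
markers monomorphic across the eight founders are flagged and removed by
QC, emulating the "polymorphic SNPs" retained on a real array. Sequence
context, genotyping error and array ascertainment are *not* simulated;
missingness can be injected by the user before QC if needed.

## Traits and G×E

The effect of QTL `k` in environment `j` is `b0_k + b_jk`: a main effect
common to all environments plus an independent Gaussian deviation with
variance `gxeRatio` times the main-effect variance. Two environments with
deviation ratios `r1`, `r2` then have genetic correlation
`1/sqrt((1+r1)(1+r2))`: ratios near 0.8 reproduce the 0.4–0.6
correlations of repeated temperate trials, and a ratio of ~20 produces a
stress site nearly decorrelated from the rest. The default
nine-environment architecture (`defaultTraitArchitecture()`) uses the
heritability spectrum 0.12–0.81 with one such stress environment, the
realistic span for Mediterranean barley yield trials. Deviations are
independent across environments, so negative genetic correlations are not
generated — the same structural limitation the MDe model itself has, and
worth remembering when interpreting passing tests: they certify behaviour
under positively-correlated environments plus one near-zero-correlation
site, not under genuinely antagonistic G×E.

## Field trials

Each environment is a two-replicate alpha-lattice: every genotype appears
once per replicate, and blocks are filled by a seeded random permutation.
A formal alpha-design generator is unnecessary because the adjustment
model only consumes the replicate and block-within-replicate factors.
Plot yield adds replicate effects (SD 0.3 of the genetic SD), block
effects (SD 0.5), a days-to-heading (DH) covariate effect (default
−0.05 t/ha per day; DH itself is genotype-level, spread ~1 day around 210
as in winter 6-row founder sets, plus 0.3 days of plot noise) and
Gaussian residuals.

Residual variance is solved from the line-mean identity
`H2 = varG / (varG + varE / r)` with `r` the replicate count. One subtlety:
the DH covariate is heritable, so the adjustment model removes the genetic
variance collinear with it. The generator therefore calibrates `varE`
against the variance of the genetic values *residualized on the
covariate* — the genotypic variance the adjustment model actually
estimates — so recovered H2 is unbiased for the target. At H2 near 0.1
with 300 lines and two replicates the REML estimator itself has a
per-trial SD of roughly 0.08; single-trial H2 estimates at low
heritability are intrinsically noisy and only their average is a sharp
check.

# Adjusted means

`fitLatticeModel()` fits, per environment,
`y = mu + Rep + Block(Rep) + Gen + beta*DH + e` by REML (lme4), with
replicate fixed, block-within-replicate random, genotype random, and the
DH covariate fixed. Blocks are treated as random because that is standard
for alpha lattices and recovers inter-block information. Genotype BLUPs
(centred) are the GP phenotypes; per-environment adjusted means are then
standardized (mean 0, sample SD 1), so GP variance components are on an
interpretable scale where genetic plus residual variance is near 1.
Missing plots are simply dropped from the likelihood; genotypes observed
in fewer plots are shrunk harder.

# Kernels

Marker QC removes markers with more than 10% missing calls and
monomorphic markers, imputes remaining missing cells with the per-marker
mode (ties toward the lower dosage) and standardizes columns by sample
mean/SD. Mode imputation is a deliberate simplification: at the few
percent missingness of simulated panels it is accuracy-neutral, whereas
haplotype-based imputation would add a heavy dependency without changing
the relationship matrices appreciably.

The GBLUP kernel is `K = XX'/p` on standardized markers (mean diagonal
~1; the all-ones vector is a null direction because columns are centred,
handled by eigenvalue truncation in the samplers). The Gaussian kernel is
`K = exp(-h d^2)` on squared Euclidean distances scaled by their
off-diagonal mean, so `h` is comparable across panels.

## Bandwidth selection

For each candidate `h` in the default grid
{0.1, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 5}, the marginal likelihood of
`y = mu + u + e`, `u ~ N(0, s2u K(h))` is computed via the
eigendecomposition of `K(h)`, profiling `mu` and the residual variance
analytically and maximizing over a coarse grid of variance ratios. A mild
`Gamma(3, 1.5)` prior on `h` (mode ≈ 1.3) is added and the posterior-mode
candidate returned. The prior matters: with weak signals the profiled
evidence is flat to within a couple of log-units and drifts toward the
largest candidate, which makes the kernel nearly diagonal and predictions
poor; the prior resolves that indifference toward moderate bandwidths
while being overridden by any decisive likelihood difference.

# Whole-genome regression samplers

`fitWGR()` implements Gibbs samplers for three members of the Bayesian
alphabet, differing only in the prior on marker effects:

* **BayesA** — each marker has its own variance with a scaled-inverse-
  chi-square prior (marginally a scaled-t prior); no effect is exactly 0.
* **BayesB** — spike-and-slab: a point mass at zero with probability
  `1 - probIn` and a BayesA-type slab otherwise. `probIn` defaults to 0.5;
  the classical sparse convention (~0.05) is available as a parameter and
  is the better prior when most markers are truly null.
* **Bayesian LASSO** — double-exponential prior via the
  exponential-mixture augmentation, with a Gamma hyper-prior on the
  regularization parameter lambda^2.

Hyperparameters follow the usual variance-partition convention: with
assumed model R2 = 0.5 and df = 5, prior scales are set so the prior
modes of the genetic and residual variances match `R2 * var(y)` and
`(1 - R2) * var(y)`. Phenotypes are expected standardized; a warning is
emitted otherwise. Chains are reproducible bit-for-bit given the seed
because every draw uses R's RNG.

# Kernel GP models

All kernel models are sampled in the eigenbasis of their kernels:
`u = U a` with independent `a_k ~ N(0, s2 d_k)`, giving O(n_obs) updates
per eigen-coefficient and no n×n solves inside the chain. Eigenvalues
below 1e-8 of the maximum are dropped. Fixed effects (intercept and
environment effects, treatment-coded) have flat priors; variance
components are scaled-inverse-chi-square with df = 5 and scales
partitioning R2 = 0.5 equally among the genetic variance groups.

* **SE** — `y = 1mu + u + e`, `u ~ N(0, s2u K)`: GBLUP when `K = XX'/p`
  (a special case of RKHS regression — the package's equivalence test
  checks GEBVs against closed-form ridge BLUP), RKHS with the Gaussian
  kernel otherwise.
* **MM** — multi-environment main effect: one genetic effect per line
  shared by all environments; for balanced data equivalent to an SE fit
  on per-line environment means.
* **MDs** — adds an interaction with covariance
  `s2ue [Zu K Zu'] o [Ze Ze']` (Hadamard product). Internally this is
  realized as one independent kernel-distributed deviation per
  environment sharing a single variance — exactly the same covariance,
  without forming the N×N product.
* **MDe** — main effect plus an environment-specific deviation
  `uEj ~ N(0, s2uEj Kj)` per environment, each with its own variance (the
  block-diagonal covariance over environments). With Gaussian kernels,
  each environment may carry its own bandwidth, estimated on that
  environment's training data only.

Cells held out for cross-validation are excluded from the likelihood but
their lines keep GEBVs through the kernel, which is what CV1/CV2 score.
Because the interaction deviations are mutually independent given the
kernels, MDe implies non-negative covariance between environments; on
panels containing an antagonistic environment the single-variance MDs
structure often fits better — the models report their variance
components so this is visible (the discordant environment then takes the
largest `s2uEj`).

Run lengths: the `"test"` profile (5,000 iterations, 1,000 burn-in,
thin 5) is the package default for single fits; inside cross-validation
loops the test suite and acceptance script use 3,000/600/3 chains, which
we verified give predictive-ability summaries stable to well within their
partition-to-partition SD. The `"production"` profile (500,000/10,000/5)
is for analysis-grade runs. Convergence can be inspected via the
effective sample size and Geweke z reported per variance chain.

# Training-population optimization

All mixed-model criteria consume a kernel `K` and a variance ratio
`lambda = s2e/s2g`, defaulting to `(1 - h2)/h2` from a preliminary GBLUP
fit since the criteria are undefined without one. With training incidence
`Z`, intercept projection `M` and `B = (Z'MZ + lambda K^-1)^-1`, the
criteria over non-training contrasts `c_i` (line minus population mean)
are:

* **CDmean** (maximize): mean of `c'(K - lambda B)c / (c'Kc)`, in [0, 1];
* **PEV** (minimize): mean of `c'Bc` (residual-variance units);
* **rScore** (maximize): mean over candidates `j` of
  `sqrt(k_jT (K_TT + lambda I)^-1 k_Tj / k_jj)`, a kernel-block estimate
  of expected predictive correlation. The published estimator this name
  points to is derived differently; ours is the transparent
  expected-accuracy formula and is validated against direct evaluation.

`exchangeOptimize()` runs first-improvement single swaps from a seeded
random start until a full pass yields no improvement; trajectories are
monotone by construction. The entry-to-nearest-entry criterion maximizes
the mean modified-Rogers distance of each selected entry to its closest
selected neighbour (greedy max-min seeding plus swap refinement), with
forced inclusion for, e.g., founder parents. On near-singular MAGIC
kernels, `K` is inverted with an escalating ridge (1e-6) — the criteria
are insensitive to this regularization at the fourth decimal.

# Evaluation machinery

Predictive ability is always the Pearson correlation between GEBVs and
(standardized) adjusted means on held-out material. The TP-size sweep
repeats random TP/VP partitions (default 100) per size; LOO refits n
models of n−1 lines. For multi-environment data, CV1 masks all
environments of a sampled 10% of lines; CV2 masks 10% of observed cells
stratified by environment while guaranteeing each masked line stays
observed somewhere (the protocol for "sparse testing"; the exact masking
unit is a design choice — we mask stratified line-by-environment cells).
Model comparisons use two-sided Welch t-tests on per-partition
correlations. LD decay uses squared allelic correlations (DH genotype
columns are haplotypes), a chi-square(1) p-value on `n r^2` with pairs
above p = 0.001 discarded, and half-open 100-kb distance bins averaged
per chromosome and genome-wide (marker-pair weighted).

# Numerical choices and degenerate inputs

* PSD repair: kernels get diagonal jitter 1e-8, escalating tenfold to at
  most 1e-4, before failing.
* Eigenvalues below 1e-8 of the maximum are truncated in samplers.
* Mode-imputation ties break toward the lower dosage; marker QC keeps a
  marker at exactly 10% missingness.
* Zero-variance phenotype columns, empty marker panels after QC, masked
  environments with no observations, and duplicate plot keys raise
  immediate errors naming the offending unit.
* Variance draws are floored at 1e-10 to avoid degenerate conditionals;
  divergent (non-finite) chains abort with the iteration index.
* All stochastic functions take one integer seed and restore the caller's
  RNG state; fixed seed implies bit-identical populations, plot tables
  and chains.

# Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run at desk scale, chosen so the
statistical properties under test have comfortable margins: panels of
80–352 lines and 400–2,000 markers, 1,000-line populations for simulator
invariants, 8,000 gametes for recombination checks, 10–30 cross-validation
partitions, and the chain lengths above. The simulator's *conditions*
(8 founders, 352-line population norm, two-replicate lattices, the
0.12–0.81 heritability spectrum with one stress site) are fixed by the
study design it emulates, not by runtime.

# Known limitations

* No selfing-based MAGIC schedules, selection during population
  development, or segregation distortion; founder contributions are
  balanced by construction.
* Markers are abstract: no sequence, no genotyping error model, no array
  ascertainment; LD magnitudes depend on map density choices.
* Independent G×E deviations cannot generate negative genetic
  correlations between environments.
* Mode imputation is adequate only at low missingness.
* The bandwidth estimator explores a fixed grid; strongly multimodal
  evidence surfaces would need a finer grid.
* No dominance/epistasis kernels, pedigree matrices, spatial field-trend
  correction or multi-trait models.
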