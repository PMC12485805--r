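---
title: "The picsim generative model: estimation, simulation and diagnostics"
author: "picsim package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The picsim generative model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picsim)
```

# Overview

picsim simulates peak-by-cell paired-insertion count (PIC) matrices for
single-cell ATAC-seq. The model is deliberately small and interpretable:
every parameter is a distributional quantity a practitioner can estimate
from a real matrix, inspect, and perturb. Three layers build on each
other:

1. **Single cell type** (`simulateSingle()`): library sizes, peak means,
   Poisson counts, sparsity.
2. **Groups and batches** (`simulateGroups()`): multiplicative
   differential-accessibility (DA) factors per group, per-cell technical
   batch factors, and biological over-dispersion via a trended BCV.
3. **Population cohorts** (`simulatePopulation()`): per-individual
   baseline accessibility, genotype-driven caQTL effects, and
   condition-level DA, with mapper-ready pseudobulk export and a full
   ground-truth record.

`picEstimate()` and `estimatePopulation()` fit all parameters from data;
`compareReport()` quantifies how closely a simulation matches a
reference matrix.

# The single-sample model

For a matrix of `n` peaks by `m` cells:

* **Library size.** `L_j ~ logNormal(mu, sigma)` on the natural-log
  scale. `mu` and `sigma` are the moments of the log column totals
  (`estimateLibSize()`); cells with zero totals are dropped with a
  warning first.
* **Peak means.** `lambda_i` is drawn from a configurable family —
  Weibull by default (shape `eta`, scale `kappa`), with gamma, Pareto,
  lognormal and a lognormal–gamma mixture available. Estimation
  (`estimatePeakMeans()`) first scales every cell to the dataset's
  median total count (lower median, for determinism), takes per-peak
  means, drops all-zero peaks and fits the family by maximum likelihood
  (method-of-moments starts, log-likelihood tolerance 1e-8; the
  lognormal and Pareto MLEs are closed-form, the mixture uses a small
  EM). The *normalized* means `lambdaBar_i = lambda_i / sum(lambda)`
  are what the model consumes, so each cell's expected total equals its
  library size.
* **Counts.** `Y_ij ~ Poisson(lambdaBar_i * L_j)`, independent entries.
* **Sparsity.** Each cell has a target final zero fraction `pi_j`,
  estimated as the observed per-cell zero proportion. Simulation first
  produces structural Poisson zeros; if a cell's structural zero
  fraction `z0_j` is below its target, each nonzero entry is zeroed
  independently with probability `q_j = (pi_j - z0_j) / (1 - z0_j)`, so
  the expected final zero fraction is exactly `pi_j` and counts never
  increase. We define `pi` as the *target final* zero fraction (rather
  than a blind masking rate) because `pi` is estimated from realized
  zero proportions: this makes the estimate-simulate round trip a
  testable contract.

Two conventions in the sparsity layer deserve comment.

**Depth-rank pairing.** When simulating, per-cell sparsity targets are
paired with cells by depth rank: the deepest simulated cell receives the
smallest target. Sparsity and depth are strongly negatively coupled in
real scATAC-seq data (and in the estimated `pi_j` vector). Pairing
targets with cells at random would systematically *add* zeros — the
masking step can never remove any — which inflates realized sparsity
and deflates the re-simulated depth distribution. Rank pairing keeps the
marginal distribution of `pi` exactly and preserves the coupling.

**Identifiability and self-consistency.** The generative parameters are
only recoverable from a simulated matrix when the parameter set is
*self-consistent*: the peak-mean scale matches the library size
(`n * E[lambda] ~ exp(mu)`, so the stored `kappa` is on the same scale
as the observed peak means) and the sparsity targets sit at or just
above the structural zero rate. This is precisely the regime that
estimation from real data produces. If `pi` is set far above the
structural zero rate, masking removes most of the count mass and no
estimator can recover `mu` from the masked matrix; the package permits
such settings (they are useful for stress-testing downstream tools) but
the round-trip recovery tests, and any calibration claim, are stated for
the self-consistent regime. The test helper `selfConsistentParams()`
constructs such parameter sets.

# Groups, batches and biological variability

`simulateGroups()` extends the model:

* **Groups.** Cells are assigned i.i.d. to `nGroups` groups with
  probabilities `group.probs`. Per group, each peak is DA with
  probability `da.prob` (default 0.13, the typical fraction of
  differentially accessible peaks reported for scATAC-seq); DA factors
  are `exp(N(da.loc, da.scale))` (defaults 0.1, 0.4), inverted to their
  reciprocal for a `da.downProb` fraction (default 0.5) so that share of
  DA peaks loses accessibility. Non-DA peaks carry a factor of exactly
  1. The factor table is emitted as truth.
* **Batches.** Every cell `j` in batch `b` draws
  `omega_jb = exp(N(mu_b, sigma_b))` (defaults 0.1, 0.1 per batch,
  recycled). The factor is applied *jointly with the library size* to
  the cell's normalized means. This is a deliberate convention: DA
  factors act on relative peak means *before* per-cell normalization,
  while a cell-wide batch scalar would cancel exactly in that
  normalization, making batches unobservable; applying it to the
  effective depth keeps the written per-cell log-normal form and makes
  batch structure detectable in PC space. With one batch no factors are
  applied, so the single-batch model reduces exactly to the no-batch
  model.
* **BCV.** Adjusted means `lambda_ij` (normalized, scaled by depth) are
  perturbed by a biological coefficient of variation before Poisson
  sampling: each peak draws
  `BCV_i = (phi + 1 / sqrt(mean_i)) * sqrt(df0 / chisq_df0)` — a scaled
  inverse chi-squared draw around a trend that decreases with the peak
  mean, so highly accessible peaks are less variable — and each entry
  becomes `Gamma(shape = 1/BCV_i^2, scale = lambda_ij * BCV_i^2)`,
  preserving the expectation with CV `BCV_i`.

The common dispersion `phi` is estimated with `estimateDispersion()`,
which obtains a raw negative-binomial common dispersion from
`edgeR::estimateDisp()` and applies a fixed linear correction,
`phi = -0.3 + 0.15 * phiRaw`, clamped below at 1e-4 (the raw estimator
systematically over-estimates dispersion on synthetic count matrices;
the correction can cross zero, and a BCV must stay positive). `df0` is
taken from edgeR's prior degrees of freedom — the spread of per-peak
dispersions around the common trend — with a default of 8 when that
estimate is non-finite. One scale subtlety is inherited from the
lineage this model follows: the corrected `phi` is estimated on the
dispersion (BCV-squared) scale but enters the simulation trend on the
CV scale; the trend constant `1/sqrt(mean)` dominates for weak peaks
either way.

# Population cohorts and genetic effects

`estimatePopulation()` works on a peak-by-individual pseudobulk matrix:
per individual it fits the peak-mean family to that individual's nonzero
means (`eta_j`, `kappa_j`); across individuals it orders peaks by mean
accessibility, chunks them into consecutive bins of 50 (a trailing bin
with fewer than 3 peaks merges into its predecessor; all-constant bins
get a sentinel fit with a warning), computes each peak's coefficient of
variation and fits a gamma distribution per bin (`alpha_v`, `beta_v`).

`simulatePopulation()` then:

1. draws population means `lambda_i` from the pooled family fit,
   per-peak CVs from the matching bin, sets
   `sigma_i = CV_i * lambda_i * var.scale` and draws individual
   baselines `lambda_ij ~ N(lambda_i, sigma_i)` clamped at zero (clamp
   events are counted). Supplying empirical means/variances bypasses
   the sampling and uses them directly;
2. assigns caQTLs: `round(ca.peaks * nPeaks)` peaks chosen uniformly
   among peaks with at least one eligible SNP (folded MAF within
   `ca.mafRange`, default 0.05–0.5; distance from the peak midpoint at
   most `ca.window` bp, default 100 kb — midpoints are
   `floor((start+end)/2)` in 1-based coordinates). One eligible SNP per
   peak is chosen uniformly; effect magnitudes are
   `omega ~ Gamma(ca.shape, ca.rate)` (defaults 1.5, 3, giving a mean
   effect of 0.5 — `estimateCaqtlParams()` fits these from an empirical
   effect-size vector), negative with probability `ca.negProb`. The
   genotype multiplies the assigned peak's baseline by
   `1 + sign * omega * G/2` — dosage-linear with a half effect for
   heterozygotes — clamped at zero;
3. applies condition-level DA for cohorts beyond the reference, with
   its own log-normal factor parameters and down-regulated fraction;
4. simulates each individual's cells with the group/batch machinery,
   using that individual's baseline vector as peak means (group DA
   factors are shared across individuals; batches are assigned to
   individuals round-robin).

`aggregatePseudobulk()` scales cells to the median total count, averages
per individual and optionally rank-transforms each peak to a standard
normal (mean exactly 0, sd exactly 1 after re-standardisation — raw
rank-normal scores have sd noticeably below 1 at cohort sizes of ~100).
Cell normalization is the package's own median-total scaling throughout;
no pooled-factor normalization is involved, which keeps the step defined
on arbitrarily small and sparse matrices. `writePhenotypes()` and
`writeGroundTruth()` emit the inputs and truth tables a linear-mixed-
model caQTL scan needs; the mapping itself is out of scope.

No linkage disequilibrium is synthesized beyond what the input genotypes
carry; the HWE fixture generator draws SNPs independently.

# Diagnostics

`summarizeDataset()` computes the cell-level (library size, sparsity)
and peak-level (mean, variance, zero and nonzero proportion) summaries.
`compareDistributions()` sorts both inputs, reduces the longer one by
linear quantile interpolation when lengths differ, and reports
`MAD = median|d|`, `MAE = mean|d|`, `RMSE`, and `1 - Pearson` of the
sorted vectors ("MAD" here is the *median* absolute deviation, the
outlier-robust choice). All four are symmetric and ordering-invariant;
a zero-variance input makes the correlation term undefined and it is
reported missing with a warning. `compareReport()` applies the metric
quadruple to log-library size (natural-log by default), peak mean and
cell sparsity, and writes overlay and mean-versus-zeros plots.

# Reproducibility

Every simulation consumes one base `seed` through named RNG substreams
(one per sampling step, hashed from the step name), so reruns are
byte-identical and changing one dimension (say `nCells`) does not
perturb draws on other streams (say the peak means). Parameter objects
serialize to schema-versioned JSON (`writeParams()`/`readParams()`)
that round-trips to full double precision; a run is therefore
reproducible from its parameter file and seed alone. All dropped cells,
peaks and SNPs are counted and reported; nothing is filtered silently.

# Fixture scales and test sizes

The package's own test suite runs entirely on synthetic fixtures built
in code: single-sample recovery at 5,000 peaks by 1,000 cells, group and
batch structure at 2,000 peaks by 400–500 cells, and a cohort of 83
individuals at 100 cells each over 900 peaks with 3,000 chr22-like SNPs
(dense enough that every peak has eligible SNPs). These sizes were
chosen as the smallest at which the distributional checks have
comfortable statistical margins; the simulator itself scales far beyond
them. The genotype fixture (`generateGenotypeFixture()`) draws positions
uniformly, allele frequencies from Uniform(0.05, 0.5) and genotypes
under Hardy–Weinberg equilibrium; the default library-size location
`mu = 8.5` corresponds to a median of roughly 5,000 fragments per cell,
a typical depth for droplet scATAC-seq.

# What passing tests do and do not show

The fixtures emulate the model's own generative assumptions:
log-normal depth, a unimodal peak-mean law, Poisson sampling,
independence across entries, HWE genotypes without LD. Real data
violate several of these (zero inflation beyond Bernoulli masking,
batch-by-group interactions, LD structure, copy-number effects), so
passing the recovery and calibration suites demonstrates internal
consistency of the implementation — estimators recover the generative
truth, simulations reproduce what estimators describe — not that the
model captures every property of any particular real dataset. The
diagnostics module exists precisely to make that second judgement
against a user's own data.

# Known limitations

* Weibull/gamma scale parameters are only identifiable jointly with the
  depth scale (see self-consistency above).
* The lognormal–gamma mixture fit is an approximate EM (weighted
  method-of-moments M-step for the gamma component); it is adequate for
  initialization-quality fits but not for likelihood-ratio comparisons
  between families.
* Group-specific and condition-specific caQTLs share one effect-size
  law; effect sizes do not vary with peak accessibility.
* Baseline clamping at zero slightly deflates the realized
  inter-individual CV for peaks with large CV draws.
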