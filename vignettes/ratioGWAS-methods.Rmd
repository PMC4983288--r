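---
title: "Continuous-ratio GWAS for pooled samples: models and methods"
author: "ratioGWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous-ratio GWAS for pooled samples: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratioGWAS)
```

## The problem

SNP arrays report two hybridization intensities per marker, X and Y, one
per allele. For a single inbred individual the intensity ratio
X/(X + Y) clusters near 0, 0.5 or 1 and can be discretized into a
genotype call. Two situations break genotype calling: allopolyploid
genomes, where probes hybridize to several homoeologous loci at once,
and pooled (bulk) DNA from several plants of a heterogeneous accession,
where the "genotype" is a continuous allele frequency. ratioGWAS treats
the ratio itself as the genotype variable all the way through the
pipeline: quality control, population structure, kinship, association
testing, multiple-testing thresholds and linkage disequilibrium.

For a bulk of $T$ diploid plants the true marker state is an allele
frequency on the grid $\{0, \tfrac{1}{2T}, \dots, 1\}$; the observed
ratio is a noisy, slightly biased estimate of it. Everything downstream
is a statistical method for continuous covariates, so no information is
lost to premature discretization.

## Signal quality control

Stage order is fixed: (1) total intensity $R = X + Y$ masks individual
cells with $R < 0.25$ or $R > 2.5$ (strict inequalities — failed or
aberrant probe reactions); (2) markers with more than 25% missing cells
are removed; (3) markers with ratio variance below 0.001 (sample
variance, $n-1$ denominator) are removed as uninformative; (4) samples
whose observed ratios pile up in the intermediate band [0.2, 0.8]
(fraction above 0.5 by default) are flagged as genetically
heterogeneous — a quantitative surrogate for visual inspection of
per-sample ratio histograms; removal is opt-in; (5) remaining missing
cells are replaced by the per-marker mean, which preserves marker means
exactly and never touches observed cells. Heterogeneity is judged
before imputation because imputed values would dilute the band
statistic.

## Population structure

PCA standardizes every marker to zero mean and unit variance across
samples (correlation-matrix PCA, samples as observations) so
common and rare allele-frequency gradients contribute equally.
Component signs are fixed by making each component's
largest-magnitude loading positive. Ward clustering runs on pairwise
Euclidean distances between ratio profiles with the Ward.D2 criterion
(the textbook squared-Euclidean objective; the legacy `ward.D` dialect
is exposed and only rescales heights on data of this kind).

The two-level AMOVA partitions the squared-Euclidean distance matrix
into between-group, among-subgroup-within-group and within-subgroup
components by the standard sums-of-squares decomposition, with
unbalanced-design coefficients when sizes differ. Negative component
estimates are reported and flagged, never truncated. Permutation
p-values use the scheme appropriate to each statistic: whole subgroups
among groups for $\Phi_{CT}$, samples among subgroups within their
group for $\Phi_{SC}$, samples among all subgroups for $\Phi_{ST}$,
with $p = (\#\{perm \ge obs\} + 1)/(B + 1)$.

## Phenotype preparation

Quantitative field traits are reduced to one value per accession by the
additive fixed model `value ~ accession + environment`; the adjusted
mean is the model prediction averaged over environments, which equals
the raw accession mean exactly on balanced designs.

Chlorophyll-fluorescence frost assays yield plant-level Fv/Fm in
[0, 0.77], bimodal after freezing (damaged near 0, intact near 0.77).
Values strictly above a threshold (0.38 scale mid-point by default, 0.6
as a stricter cut) score 1; the 0/1 scores enter a binomial logistic
model with accession and experiment fixed effects, fitted on
accession-by-experiment totals (same likelihood as plant-level
Bernoulli). The frost tolerance score of an accession is the inverse
logit of its effect at the average experiment effect. Accessions with
all-tolerant or all-susceptible plants cause complete separation; their
scores are clamped to $[\varepsilon, 1-\varepsilon]$ with
$\varepsilon = 1/(2\,n_\text{plants})$ and flagged. Optimal and
sub-optimal hardening conditions can be scored separately or together.

## The mixed-model association scan

The kinship matrix comes from Euclidean distances between ratio
profiles: $K = -\tfrac12 C D^2 C$ (Gower double-centering), which for
Euclidean distances is the centered cross-product matrix and hence
positive semidefinite; it is scaled to mean diagonal 1 so the genetic
variance is identifiable. Kinship can be built from all markers or from
a subset of markers equally spaced in cM (e.g. 160, 302 or 520),
allocated to linkage groups proportionally to map length by
largest-remainder rounding; a spaced subset decorrelates the kinship
estimate from any single region.

The association model is
$y = \mu + x_j\beta_j + g + e$, with $g \sim N(0, \sigma_g^2 K)$ and
$e \sim N(0, \sigma_e^2 I)$, where $x_j$ is the marker-$j$ ratio
column. Variance components are estimated once by REML under the
no-marker null: after eigendecomposition of $K$ projected off the
covariate space, the REML log-likelihood is a one-dimensional function
of $\delta = \sigma_e^2/\sigma_g^2$, maximized over
$\log_{10}\delta \in [-10, 10]$ by a 100-point grid plus Brent
refinement (tolerance 1e-8). The wide base-10 box matters: at its upper
end the whitening distortion is $O(\lambda_{max}/\delta) \approx
10^{-9}$, so the no-genetic-variance limit reproduces ordinary least
squares to numerical precision rather than to $10^{-4}$.

Each marker is then tested by generalized least squares in the
whitened space with the null-anchored components held fixed (the
EMMAX-style single-fit approximation), a 1-df Wald F test with
denominator df $n - \mathrm{rank}$, and $-\log_{10} p$ capped at 300.
A per-marker full-REML scan (`gwas_full_reml()`) is kept as the exact
reference: it agrees with the fast scan to $\sim 10^{-3}$ on
$-\log_{10} p$ for the bulk of markers, but for the strongest
structure- or chance-aligned markers at small $n$ the per-marker REML
re-fit can collapse the residual genetic variance and report stronger
signal — an intrinsic property of exact-vs-P3D comparisons, quantified
in the test suite. Models `simple` (no correction) and `pcs`
(principal-component covariates, 10/15/20/40) are nested limits of the
same code path: identity kinship, vanishing $\sigma_g^2$, or zero
components all reproduce the simple model, and the tests assert those
identities.

## Multiple testing and diagnostics

The genome-wide threshold uses the effective number of independent
tests from the eigenvalues $\lambda_i$ of the marker correlation
matrix, $M_\text{eff} = \sum_i [\mathbb{1}(\lambda_i \ge 1) +
(\lambda_i - \lfloor\lambda_i\rfloor)]$, converted by the Sidak formula
$\alpha_p = 1 - (1-\alpha)^{1/M_\text{eff}}$. When markers outnumber
samples the spectrum comes from the dual $n \times n$ matrix
(identical nonzero eigenvalues, zero-padded). Because $f$ jumps at
integer $\lambda$, eigenvalues within $10^{-8}$ of an integer are
snapped to it — otherwise floating-point noise at exactly duplicated
markers lands on the wrong side of the jump.

QQ diagnostics pair sorted observed $-\log_{10} p$ with uniform order
statistics and report the median-based inflation factor
$\lambda_{GC}$. Finally, markers at or above the threshold pass an
outlier screen: the continuous analogue of a minor-allele-frequency
filter splits each significant marker's sorted ratios at the largest
gap and flags the marker when the smaller side holds fewer than 3
samples; flags annotate and never delete.

## Structure-corrected LD decay

Classical $r^2$ is the squared Pearson correlation of two ratio
columns; in a structured panel it mixes physical linkage with
stratification. The corrected $r^2_S$ whitens the columns by
$V^{-1/2}$ — $V$ a covariance matrix between individuals, typically
the kinship matrix — and projects out the intercept in the whitened
space before squaring the cosine. Singular $V$ (the double-centered
kinship has the intercept in its null space) is handled by a
pseudo-inverse square root on the positive eigenspace. With $V = I$
the module reduces bitwise to classical LD.

Within-linkage-group pairs are binned in 1-cM left-closed bins; the
per-bin 90th percentile (type-7 quantile, fixed for bit
reproducibility) is smoothed against bin midpoints. Bins with fewer
than 20 pairs are excluded from smoothing — sparse far bins make an
upper percentile erratic. The smoother is a penalized cubic regression
spline whose smoothness is selected by REML: on these short,
low-noise percentile series classical GCV runs to its search boundary
and returns an interpolant (df equal to the number of bins), which is
no smoothing at all; REML selection does not degenerate. GCV remains
available via `method = "gcv"`. Note that any faithful unconstrained
smoother retains upward wiggles of order $10^{-3}$ through the
far-distance sampling-noise plateau, so strict monotonicity of the
fitted curve is only guaranteed where the true decay slope dominates
that noise.

## The synthetic-data generator

No real dataset ships with the package, so every stage is validated on
synthetic studies with known truth. The generator emulates a
genebank-style panel of pooled accessions:

* **Structure** — ancestral allele frequencies uniform on
  [0.05, 0.95]; hierarchical Balding–Nichols (Beta) drift at three
  levels: group, subgroup, accession. The defaults (2 groups, 8
  subgroups, 131 accessions, drift 0.11 / 0.103 / 0.341) are calibrated
  in closed form so a two-level AMOVA of the generated panel partitions
  molecular variance approximately 22% between groups, 18% among
  subgroups and 60% within subgroups — the signature of a structured
  European cereal collection in which landraces and old varieties carry
  substantial individual drift. The accession level matters: without
  it, within-subgroup variance is only bulk-sampling noise and the
  panel is far more confounded than any real collection.
* **Bulks** — each accession draws $2 \times 10$ allele copies
  binomially, so true bulk frequencies sit exactly on the 1/20 grid.
* **Signals** — observed ratio
  $\mathrm{clip}(0.02 + 0.96f + N(0, 0.03), 0, 1)$; total intensity
  $R \sim \Gamma(9, \text{mean } 1.3)$, calibrated so ~1% of cells
  violate the [0.25, 2.5] bounds and the QC stage has real work.
* **LD** — optional latent Gaussian AR(1) coupling along each linkage
  group with correlation $e^{-d/L}$, which induces exponentially
  decaying $r^2$ while keeping marginals binomial (recombination
  genealogies are out of scope).
* **Phenotypes** — accession liability = planted QTL effects on true
  bulk frequencies + polygenic term ($\propto$ true kinship) +
  noise, with configured variance fractions; tolerance probability =
  inverse logit of scaled liability + experiment effect; plant
  survival Bernoulli; Fv/Fm from a two-component scaled-Beta mixture
  (tolerant high, susceptible low) bounded by 0.77; 5 experiments
  (3 optimal, 2 sub-optimal hardening) with 6 plants each, i.e. 30
  plants per accession; quantitative field traits from an additive
  accession + environment model.

What passing tests on these data do **not** show: real Infinium
normalization artifacts (the affine + Gaussian distortion is a
caricature), homoeologous cross-hybridization in allopolyploids beyond
its net effect on the ratio scale, LD from actual recombination
histories, and genotype-by-environment interaction (the phenotype
models are additive). Results on real data depend on those features.

## Problem sizes and numerical choices

The validation suite runs the mixed-model oracle comparison at
$n = 60, m = 300$; calibration and recovery studies at the panel scale
the package targets ($n = 130$–131, $m = 1000$–2000, 50–100 seeds);
permutation calibration with $10^4$ permutations at $n = 80$; AMOVA
permutation-null calibration with 200 replicates of 99 permutations.
These sizes were chosen as the smallest at which the properties under
test are statistically identifiable. All generators take explicit
seeds and restore the global RNG state.

Other fixed numerics: threshold comparisons are strict exactly as
printed ("more than", "<", ">"); the $-\log_{10} p$ cap is 300;
kinship eigen-repair adds a ridge only below $-10^{-10}$; the
heterogeneity band and threshold, QC bounds, and all generator knobs
are exposed in configuration with the defaults above.

## Known limitations

* The EMMAX-style single null fit under-reports the strongest signals
  relative to a per-marker REML re-fit at small $n$ (see the oracle
  comparison above); for final candidate lists at $n \lesssim 100$,
  re-checking top markers with `gwas_full_reml()` is cheap and
  recommended.
* The heterogeneity flag is a band statistic, not the original visual
  inspection; its default threshold is deliberately conservative and
  removal is opt-in.
* A QTL whose allele frequencies are strongly aligned with population
  structure is partially absorbed by the kinship term — detection
  power for such loci is intrinsically low under any
  structure-corrected model.
* Frost scores at the separation boundary depend on the clamping
  constant; comparing accessions whose scores are clamped is not
  meaningful beyond "all plants tolerant/susceptible".
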