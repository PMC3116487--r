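---
title: "Cluster-based ANOVA for multi-factorial MALDI-TOF profiling: models, defaults and design choices"
author: "profileANOVA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster-based ANOVA workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(profileANOVA)
```

# Scope

`profileANOVA` implements a complete biomarker-discovery chain for
multi-factorial MALDI-TOF profiling data: raw continuous spectra in, a
dendrogram fusing correlation with significance and a cross-validated
classification benchmark out. This vignette is the package's own account of
the underlying models, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the places where the
design was genuinely open and a choice had to be made.

# The data model

A profiling study is described by a `StudyDesign`: factor levels (genotype,
diet, sampling week) and, per genotype×diet×week cell, the number of
acquired spectra and of distinct biological samples. The emulated mouse
study (`mouseStudyDesign()`) has 36 cells totalling 1122 spectra from 155
samples; up to two sample preparations, each measured four times, give up to
eight technical replicates per sample. Two cells are empty (SJL/HF at weeks
3 and 4, a plasma-collection failure in young lean mice) — the design,
generator and ANOVA all tolerate `0/0` cells.

Spectra are `MassSpectrum` objects: a strictly increasing m/z axis, one
intensity per point, and a processing-stage tag that can only move forward
through `raw → logged → smoothed → baselined → aligned`, so a spectrum
cannot silently re-enter an earlier stage. Quantified data live in a
`PeakMatrix` (a `SummarizedExperiment`: peaks × profiles, with the sample
sheet as `colData` and an ordered log of applied transforms in
`metadata()`).

# Pre-processing

The chain per spectrum, with the defaults and their reasons:

* **Log transform**, `y → log(y + c₀)` with guard `c₀ = 1`. The guard keeps
  zero intensities representable (`log(1) = 0`); raw detector counts are
  large enough that the choice of guard is immaterial.
* **Median smoothing**, window 9 points. At the edges the window shrinks
  symmetrically; the interior is `stats::runmed`.
* **Tophat baseline correction**: subtraction of the morphological opening
  (erosion then dilation) with a flat structuring element of **151** index
  points. The width is a package choice: it must be much wider than peak
  widths (a few points) and narrower than baseline undulations (thousands of
  points); any value in that window behaves equivalently. The opening is
  computed by the van Herk–Gil–Werman running-extreme scheme, is idempotent,
  and guarantees `0 ≤ output ≤ input`.
* **CWT peak picking**: Mexican-hat wavelet over the integer scale ladder
  `scale.min … scale.max` (defaults 3 and 24), ridge lines tracked from
  coarse to fine with a gap tolerance of 3 scales. Ridges shorter than
  `length.min = 7` scales are discarded; the noise level is the 0.95
  quantile of the absolute finest-scale coefficients within ±500 points of
  the apex, and ridges with SNR < 3 are dropped. Apexes are reported at the
  finest linked scale. Reporting at the ladder's finest scale (rather than
  computing extra sub-`scale.min` scales) matters: after median smoothing a
  narrow peak's top is a plateau, and positions taken below scale 3 jitter
  by ±2 points, which would destroy exact shift recovery downstream.
* **Alignment**: reference peaks are picked from the pointwise mean of the
  baselined spectra; for each spectrum, every reference apex is matched to
  the nearest picked apex within ±30 index positions, and the spectrum's
  single integer shift is the mean signed distance rounded half away from
  zero. The shift is applied as a continuous translation of the intensity
  trace (edge positions filled with the boundary value), one pass, no
  multi-pass refinement. Alignment of the continuous trace (rather than of
  the apex list only) was chosen so that quantification windows always read
  the translated signal; both views are available.
* **Quantification**: per reference apex, the maximum intensity within ±4
  index positions. The maximum was preferred over area integration for
  robustness to residual one-to-two-point misalignment; at these peak
  widths the two estimators are monotonically related.
* **Variance stabilization**: the quantified matrix still shows a linear
  dependence of the replicate standard error on the mean — a multiplicative
  error component — so a second log is applied, `v → log(v + 0.1)`, with an
  optional cosmetic offset (default 0). `varianceDiagnostic()` exposes the
  (mean, SE) cloud per peak × replicate group with a least-squares slope and
  a lowess curve (span 2/3, the conventional default); on the package's
  multiplicative-noise simulation the slope falls from ≈ 0.25 to ≈ 0.
* **Replicate averaging**: technical replicates are not independent and
  would violate the ANOVA assumptions; each sample's columns are averaged
  arithmetically on the stabilized scale. The alternative of modelling
  replicates as random effects in a mixed model is deliberately out of
  scope — with this many biological replicates the two approaches give
  near-identical answers, and averaging keeps the downstream machinery
  exact.

# Nested-model ANOVA

All tests are model comparisons on residual sums of squares. For nested
least-squares fits with effective parameter counts `p₁ < p₂`,

$$F = \frac{(RSS_1 - RSS_2)/(p_2 - p_1)}{RSS_2/(n - p_2)}
      \sim F(p_2 - p_1,\; n - p_2).$$

Each main factor is tested by removing it from the full main-effects model
(`~ genotype + diet + week`); the interaction by adding `genotype:diet` to
the main-effects model. This Type-II-like strategy was chosen over
sequential (Type-I) sums of squares because the study is unbalanced and
sequential results would depend on term order. Week enters as a categorical
factor with four levels (`weekAsFactor = FALSE` switches to a linear trend);
the sampling times are too few and too unevenly spaced to assume linearity.

Effective parameter counts are design-matrix ranks after pivoting: a
genotype×diet combination absent from the data drops its interaction
column, and the affected peaks are flagged rather than failing. An
all-constant response yields p = 1 with a `degenerate` flag; an exactly
saturated larger model reports the p = 0 limit with a `saturated` flag.
`anovaAllPeaks()` shares the five QR decompositions across all peaks, so
2000 peaks at study scale test in well under a second, and a per-peak call
(`factorialAnova()`) is bit-identical to the corresponding table row.

One-way ANOVA is the same comparison with the group-means model and is
verified (to 10⁻¹⁰) against the pooled two-sided t-test at k = 2.
Bonferroni is the only multiple-testing procedure: the workflow's claims are
about per-peak significance surviving the most conservative correction, and
FDR-style procedures are out of scope.

# Redundancy: clustering with node p-values

Peptides of a common parent protein co-vary, so peak intensity profiles
(one peak's values across the sample-averaged profiles) are clustered with
average linkage (UPGMA) on the distance `1 − ρ`, Pearson's correlation,
computed on the stabilized sample-level matrix — the pipeline's natural
scale at that point. UPGMA was chosen as the standard reading of "average
linkage"; `stats::hclust` provides it, with deterministic (if internal)
tie-breaking, so identical inputs always give identical trees. Constant
profiles, whose correlation is undefined, are dropped with a warning before
clustering.

Every node carries the mean pairwise correlation of its member profiles
(1 for a leaf, by convention) and four factor-wise p-values. A node's
p-value is the factorial ANOVA of the pointwise mean of its members'
z-transformed profiles — z-transformation first, because profiles sit on
different absolute scales. Leaves reuse the per-peak ANOVA table row
verbatim (the same code path, hence exactly equal; this is also the F-test's
affine invariance at work, since a z-transformed profile is an affine image
of the original). The annotated tree exports as newick (internal nodes
labelled `N<k>`, ultrametric half-height branch lengths so that leaf-to-leaf
path lengths equal merge heights) plus a JSON side-table with `−log₁₀ p`
per factor and per-factor colour scales computed independently, so each
factor's annotation spans its own dynamic range — a factor with p-values
down to 10⁻⁹⁰ does not flatten the scale of one reaching 10⁻¹⁴.

# Feature selection and classification

Three strategies are benchmarked on the diet factor:

1. **ANOVA filter**: the n smallest diet p-values (ties broken by lower
   m/z).
2. **Cluster-representative ANOVA**: cut the tree at distance 0.3
   (correlation 0.7 — within the range of observed same-protein peptide
   correlations), rank the flat clusters by their cluster-level p-value,
   and take the minimum-p member peak from each of the top n clusters.
   Representatives are pairwise in different clusters by construction, so
   the selection respects redundancy at filter-method cost.
3. **Ant colony optimization** (wrapper): ants sample n-feature subsets with
   probability ∝ pheromone^α · heuristic^β, the heuristic being −log₁₀ of
   the peak's one-way ANOVA p-value. Fitness is the stratified internal CV
   error of the decision tree; after evaporation (rate 0.1) the
   iteration-best subset is reinforced by `0.1 · (1 − error)`, with
   pheromone clamped to [0.01, 5]. Defaults are 200 ants × 100 iterations;
   α = β = 1. Only the ant and iteration counts are externally prescribed —
   evaporation, bounds and iteration-best reinforcement are package choices
   fixed for reproducibility, and every run is bit-identical for a fixed
   seed. Subset fitness values are memoized, since ants frequently resample
   the same subset.

The classifier is a CART decision tree (Gini impurity, axis-aligned splits)
capped at depth 5 with at least 5 samples per leaf — conventional CART-family
settings chosen to limit overfitting at the ~155-sample scale; `rpart`
provides the implementation. Evaluation is stratified k-fold
cross-validation (default 10; folds are reduced with a warning if a class is
smaller) pooling out-of-fold predictions into one confusion matrix.
Feature-set significance is `p = (#{random error ≤ observed} + 1)/(n_random
+ 1)` over `n_random` (default 1000) uniformly drawn same-size sets, each
scored with the *same* folds — same-fold scoring removes fold noise from the
comparison, and the add-one form bounds p below by `1/(n_random + 1)` and
keeps it super-uniform under the null. Classification operates on
sample-averaged profiles, consistent with the ANOVA input.

# The synthetic-data generator

The generator is first-class, tested code; it emulates the structural
features of the study that the downstream stages are sensitive to:

* per-cell spectrum/sample bookkeeping, including empty cells and the
  preparation/replicate hierarchy;
* correlated peak families: per sample, each family draws a shared latent
  log-abundance mixed with per-peak noise so that the within-family
  correlation of log abundances equals the declared ρ (default 0.9);
  families are interleaved along the axis the way peptides of one protein
  scatter across the mass range;
* a multiplicative error model: biological log-noise (sd 0.5) shared by a
  sample's replicates, technical log-noise (sd 0.5) independent per
  spectrum — calibrated to raw-scale coefficients of variation of roughly
  50%, typical of MALDI profile intensities;
* Gaussian peaks in index space (sd 3 points; no peak-shape information is
  available to calibrate against, and the Mexican-hat picker assumes
  approximately Gaussian shapes);
* a slowly varying baseline (decaying exponential plus a non-negative
  low-frequency sinusoid with random phase) standing in for matrix chemical
  noise — plausible, not instrument-calibrated;
* per-spectrum integer axis drift, uniform on ±`shiftMax` (default 10),
  plus optional additive detector noise clamped at zero.

It does **not** emulate isotope envelopes, charge states, detector
saturation, or real m/z calibration physics (the axis is a linear map of
index to the 700–10,000 m/z range). Passing tests therefore demonstrate
that the algorithms recover the planted structure under a faithful noise
*model*, not that they are robust to every artefact of real spectra.
Defaults of 32,000 axis points mirror raw acquisitions; the test and
simulation default is 4,000 points to keep run times proportionate, with
peak density scaled accordingly. `simulateIntensityMatrix()` skips the
continuous-spectrum layer and draws quantified intensities directly from
the same abundance model — the appropriate level for statistical
simulations of the ANOVA, clustering and classification stages.

All randomness flows through a mandatory seed, the caller's RNG state is
saved and restored, and the ground truth (drifts, apexes, families, planted
effects, noise parameters, seed) round-trips through JSON unchanged.

# Numerical choices and degenerate inputs

* RSS comparisons use a relative tolerance of 10⁻⁹ to classify saturated
  and degenerate fits; vectorized RSS values are clamped at zero.
* Shift rounding is half away from zero, making ±x.5 symmetric.
* Apexes closer than 3 indices after ridge filtering are de-duplicated,
  keeping the stronger ridge.
* A spectrum matching no reference peak aligns with shift 0 and a
  `no_match` flag; constant profiles are excluded (clustering) or reported
  with p = 1 (nodes); empty peak sets, empty design cells and single-class
  labels raise informative errors rather than propagating `NA`s.
* Lowess in the variance diagnostic is evaluated on at most 2000
  evenly-spaced points of the (mean, SE) cloud, which leaves the fitted
  slope untouched and keeps the diagnostic linear-time.

# Simulation scales used by the tests and the acceptance script

The suite pins the study-scale statistical claims at sizes chosen to make
the checks sharp yet quick: type-I calibration on 2000 null peaks over the
155-sample design; drift recovery on 200 spectra of 4000 points with drifts
up to ±15; variance-diagnostic slopes on 10,000 replicate draws (25 peaks ×
2500 samples × 4 replicates); family recovery with 5 planted families of 4
peaks plus 20 singletons at study scale; and a classification benchmark
with planted diet-responsive families on the full 155-profile design, 200
random sets per permutation p-value. The ACO recovery checks use reduced
colonies (tens of ants, ~a dozen iterations), which already recover planted
pairs; the 200 × 100 default remains for analysis use.

# Known limitations

* The mean-spectrum reference is computed from the *drifted* spectra in the
  one-pass pipeline; large drifts smear the mean and can bias all reference
  apexes by a common offset. Coordinates remain internally consistent (the
  bias cancels in every comparison), but absolute apex indices may be offset
  by a few points — recoverable only with a drift-free reference batch.
* Anti-correlated peptide relationships (one protein's abundance suppressing
  another peptide) are outside the clustering model: `1 − ρ` places perfect
  anti-correlation at maximal distance by design.
* No TIC or quantile normalization is applied beyond the described
  transforms; spectra are assumed to share an acquisition protocol.
* The permutation p-value reuses one fold assignment for all feature sets;
  p-values are conditional on that assignment (they remain valid and
  super-uniform under the null, as the property tests check).
* Cluster confidence (bootstrap support) is not computed; node p-values
  quantify factor association, not topological stability.
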