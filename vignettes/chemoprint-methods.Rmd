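---
title: "Methods: fingerprint chemometrics and clustering in chemoprint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fingerprint chemometrics and clustering in chemoprint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`chemoprint` analyzes ambient mass-spectral chemical fingerprints for
species identification.  This vignette explains the models and
procedures, the parameters that matter, the numerical conventions, and
what the built-in simulator does and does not emulate.

## The data model

A **spectrum** is a pair of parallel vectors (m/z in u, intensity), in
profile (continuum) or centroid form, with polarity and a declared
acquisition range (default m/z 60–1000, a typical ambient TOF window).
Preprocessing follows the standard instrument chain:

1. **Centroiding** (`centroid_spectrum`): every local maximum above a
   relative-height threshold becomes one peak at the intensity-weighted
   mean m/z over its contiguous above-half-maximum region.  The FWHM
   region is used because TOF resolving power is conventionally quoted
   at FWHM; the weighted mean over that region is insensitive to
   baseline tails.
2. **Mass recalibration** (`fit_calibration`, `apply_calibration`): a
   least-squares polynomial (default degree 2) mapping measured to
   theoretical calibrant m/z, with each calibrant matched to its nearest
   peak within `match_tol_u` (default 0.05 u — deliberately generous,
   since matching happens *before* calibration).  Degree 2 absorbs the
   smooth residual drift of a TOF analyzer while staying monotone; the
   applied map is rejected if it would reorder peaks over the data
   range.  Calibrants such as PEG 600 give a ladder of known masses
   across the range; when calibration runs are interleaved between
   samples, each sample should use the model fitted from the nearest
   preceding calibrant acquisition.
3. **Averaging** (`average_spectra`): centroid peaks are pooled on a
   common half-open grid (`[lo, lo + w)`, anchored at the
   acquisition-range lower bound); the per-bin mean over spectra (absent
   peak = 0) is reported at the intensity-weighted mean m/z.  All
   binning in the package uses the same half-open, lower-anchored
   convention so bin membership is unambiguous and testable.
4. **Background subtraction** (`subtract_background`): per-bin
   `max(0, sample − background)`; emptied bins are dropped.  Either a
   blank acquisition or pre-sample scans can serve as background — the
   package supports both and asserts neither.
5. **Base-peak normalization** (`normalize_base_peak`): the most intense
   peak is scaled to 100 so samples are comparable as relative-abundance
   profiles regardless of absolute signal.

## Fingerprints and feature tables

Two analysis-ready representations are built from preprocessed spectra:

* The **fingerprint matrix** ("heat map", `build_fingerprint_matrix`):
  samples × m/z bins of relative abundance.  Within a bin the *maximum*
  intensity is taken (centroided data carry one chemotype ion per bin;
  summing would double-count split centroids).  Bins in which no sample
  reaches `min_rel_abundance_pct` (default 1%) are dropped.  The default
  bin width is **1 u** (unit-mass binning).  This is a deliberate
  choice: sample-to-sample mass error of a few ppm is ±0.002–0.005 u
  across m/z 400–1000, so millidalton-wide bins would place the same ion
  in different bins in different replicates and destroy the
  within-species correlation the clustering relies on.  Unit-mass bins
  keep replicate peaks aligned; millidalton selectivity belongs to the
  feature windows below.  At realistic spectral richness, thresholded
  unit-mass binning yields a few hundred retained variables over a
  60–1000 u range.
* The **feature table** (`extract_features`): for each target feature
  mass, the maximum peak intensity within ±`tolerance_u`.  The tolerance
  must lie in 0.001–0.05 u and windows of distinct targets must not
  overlap; the default 0.01 u sits mid-range of the 0.005–0.015 u
  windows customary for high-resolution TOF feature selection, and
  comfortably covers 5 ppm mass error below m/z 1000.

The fingerprint exports to the Cluster 3.0 tab-delimited dialect
(`UNIQID` header, bin centers to 4 decimals, samples as rows), which
`read_cluster_matrix` re-imports losslessly at that precision.  Samples
are the clustered items: dendrogram leaves are specimens.

## Supervised analysis

Features are standardized (zero mean, unit variance per variable)
before any discriminant fit, because relative abundances span orders of
magnitude; the standardization parameters are stored in the model and
re-derived inside every cross-validation fold, so the held-out sample
never influences the scaling it is judged against.

* **PCA** (`chemo_pca`): eigendecomposition of the correlation (default)
  or covariance matrix; scores are the (standardized) centered data on
  the eigenvector loadings; `variance_explained` is eigenvalue over
  eigenvalue sum.  Zero-variance variables are rejected by name in
  correlation mode rather than silently producing NaN.
* **KPCA** (`chemo_kpca`): eigendecomposition of the double-centered
  kernel matrix; scores are eigenvectors scaled by the square root of
  their eigenvalues; variance is reported against the centered-kernel
  trace.  Numerically negative eigenvalues are clipped at zero with a
  warning.  With a linear kernel on standardized data KPCA reproduces
  correlation-mode PCA scores up to column sign — a cross-check in the
  test suite.
* **LDA / KDA** (`discriminant`): Fisher directions maximizing
  between-class over within-class scatter, at most `k − 1` directions
  for `k` classes.  The within-class scatter carries a ridge `λI`
  (default `1e-3 · trace(scatter)/dim`), which is what makes the
  criterion well-posed when variables outnumber samples, as they
  typically do for spectral fingerprints.  KDA solves the identical
  criterion in the dual: the between/within scatter of kernel rows,
  ridge-regularized, yielding dual coefficients over the retained
  training samples.  The rbf bandwidth defaults to the median pairwise
  Euclidean distance of the standardized training features (the median
  heuristic).  Classification is by nearest class centroid (Euclidean)
  in discriminant space; exact ties go to the lexicographically
  smallest class label so results are deterministic.
* **LOOCV** (`loocv`): each sample held out in turn, everything —
  scaling, bandwidth, ridge, projection — refit on the remaining
  samples.  If removing a sample leaves its class with one member, that
  member is excluded from the fold's training set and the fold is
  predicted from the remaining classes' model, with a warning: a
  two-sample class can never predict itself perfectly under LOOCV and
  silently pretending otherwise would inflate accuracy.

Eigenproblems are solved by Cholesky whitening of the regularized
within-scatter followed by a symmetric eigendecomposition — numerically
stabler than forming `solve(Sw) %*% Sb` — and eigenvalues are clipped at
zero.  For KDA plots, the discriminant eigenvalue fractions are reported
and labeled as such (they are not principal-component variance
fractions, although instrument software often labels them that way).

Known limitation: an rbf-kernel discriminant projects a sample that is
far from *all* training points to near the origin of discriminant space
(its kernel row is almost zero), so extreme outliers can be assigned
arbitrarily.  This motivates both the linear-discriminant option and the
novelty flag below.

## Unsupervised analysis

Relatedness is inferred from the fingerprint matrix with the classic
gene-expression-clustering conventions:

* **Uncentered correlation** (`uncentered_correlation`):
  `r = Σxy / sqrt(Σx² Σy²)`, correlation about zero, not about the mean.
  For non-negative abundance rows this is the cosine similarity; it is
  invariant to positive rescaling, so overall signal level does not
  drive the tree.  Distance is `d = 1 − r`, range [0, 2].  Pearson and
  Euclidean metrics are available but never the default.
* **Single linkage** (`single_linkage`): iteratively merge the two
  clusters with the minimum pairwise member distance; heights are
  non-decreasing by construction (asserted in tests).  Ties break
  toward the smallest index pair, making the merge sequence
  deterministic and test-stable.  Leaf order is merge order — no
  display-side leaf-ordering optimization is attempted.
* **Newick export** (`to_newick`): branch lengths are parent–child
  height differences, so recovered node heights reproduce the merge
  heights; duplicate leaf labels are suffixed with a warning.
  `cophenetic_matrix` and `cut_dendrogram`/`cluster_purity` support
  downstream checks; purity at `k` clusters is the fraction of leaves
  in their cluster's majority class.

The matrix handed to clustering is the base-peak-normalized fingerprint
itself; no log transform is applied by default.  That is a configuration
choice, not a claim about best practice — a log transform would
de-emphasize dominant ions and can be applied by the user before
`distance_matrix`.

## The simulator

`make_species_profiles` builds `n` species over a common chemistry: a
shared compound pool (fraction `shared_fraction` of each profile, drawn
once) that every species expresses at species-specific mean abundances
offset by ±`separation` log10 units with random signs, plus private
compounds per species.  Neutral masses are uniform on 80–900 u and
observed as singly charged adducts (`M+H` in positive mode, `M+O2−` in
negative mode, the oxygen-attachment route by which nonpolar alkanes
are detected); mean log10 abundances are uniform on 3.5–5.

`simulate_spectrum` draws one acquisition: per compound a dropout
Bernoulli (`dropout_probability`), Gaussian mass error in ppm, and a
lognormal abundance.  The abundance spread is parameterized by the
**coefficient of variation of the linear-scale abundance**: the log10
standard deviation is `sqrt(log(1 + cv²))/log(10)` (≈0.043 for
`cv = 0.1`), i.e. a 10% shot-to-shot intensity spread at the default —
the "reproducible within-species abundances" regime that replicate
ambient acquisitions of a stable specimen show.  Parameterizing the
lognormal by a CV *of the abundance itself* keeps the noise magnitude
independent of where a compound's mean lies on the log scale.  Spurious
baseline peaks arrive as a Poisson count at uniform m/z.  Each spectrum
of a dataset gets its own RNG stream derived from the master seed and
its (species, replicate) indices, so adding or removing one replicate
never perturbs the others, and identical inputs are bit-reproducible.

Default study conditions (used throughout the tests): 5 species,
25 compounds each, `shared_fraction 0.5`, `separation 1.0`, `cv 0.1`,
5 replicates, 5 ppm mass error, 2% dropout.

What the simulator does **not** emulate: isotopologue envelopes (a
single optional satellite only), multiple charge states, ion
suppression and matrix effects, temperature-programmed volatility,
detector saturation, or correlated (chromatographic-style) noise.
Passing tests on simulated data therefore demonstrate the correctness
and statistical behavior of the *analysis chain* under controlled
chemotype structure — not instrument-level performance on real spectra.

## Workflow-level choices

* **Scan averaging before clustering.**  A raw single acquisition can
  lose its dominant ion to dropout; under a scale-invariant cosine-type
  distance that one sample then decorrelates from its conspecifics, and
  single linkage — which joins clusters through single close pairs — can
  misplace it.  Instrument workflows do not cluster single scans: a
  sample's spectrum is the average of many 1-per-second scans, in which
  compound dropout is vanishing.  The clustering tests therefore build
  each sample as the average of 5 simulated scans
  (`average_spectra`), which reproduces species-pure clades (purity 1.0
  at `k` = number of species); the classification path is
  window-based and robust to dropout, so it uses raw single
  acquisitions.
* **Novelty flag.**  `run_classification` flags a blind sample as a
  potential novel class when its nearest-centroid distance exceeds the
  95th percentile of the nearest-centroid distances that training
  samples attained *as held-out samples in their LOOCV folds*.
  Resubstitution distances would be far too small (discriminant
  projections overfit training points toward their centroids) and would
  flag everything.  This screen goes beyond what fingerprint
  classification software ordinarily reports and is labeled as such in
  the run report.
* **Synonym-merge experiment.**  Two labels drawn from one chemotype
  generator are mutually confusable: LOOCV among them sits near chance,
  and relabeling them as one species lifts overall LOOCV sharply.  The
  test uses 12 replicates per class: LOOCV's variance at
  small per-class counts is large (folds share all but one sample, so
  fold errors are highly correlated), and a dozen replicates is the
  smallest size at which the near-chance behavior of the synonym pair
  is stable across seeds.

## Problem sizes and runtime

The test suite and the acceptance script run on simulated datasets of
15–36 samples with 25–75 feature masses and up to 12-sample distance
matrices for the brute-force clustering comparisons; these sizes give
sub-minute suites while keeping every matrix well into the p ≫ n regime
the regularization is designed for.  All randomness is seeded; reported
quantities (LOOCV percent correct, purity, calibration residuals) are
computed at run time by the code under test.

## Known limitations

* Single linkage chains: it is the stated convention of the emulated
  workflow, not the most robust linkage; complete/average linkage are
  not currently offered.
* KDA with an rbf kernel degrades for samples far from the training
  set (see above); use LDA or inspect the novelty flag in that regime.
* The Cluster-dialect reader accepts only the subset of the format this
  package writes (no GWEIGHT/EWEIGHT columns).
* mzML support is read-only and MS1-only, via `mzR`.
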