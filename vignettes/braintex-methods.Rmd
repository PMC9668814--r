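---
title: "Methods: voxel-wise GLCM texture maps and explainable MLP classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel-wise GLCM texture maps and explainable MLP classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`braintex` implements a radiomics-texture analysis chain for registered 3D
brain volumes: per-image histogram equalization and gray-level quantization,
voxel-wise 3D gray-level co-occurrence matrix (GLCM) texture-feature maps, a
small tanh multilayer perceptron (MLP) evaluated in repeated nested
cross-validation with univariate feature selection, layer-wise relevance
propagation (LRP) heatmaps for the trained networks, and affinity-propagation
clustering of subjects' positive-relevance maps.  The motivating application
is discrimination of psychosis-spectrum groups (first-episode psychosis,
clinical high-risk with and without later transition, healthy controls) from
structural MRI, where texture is hypothesized to carry signal beyond and
above volumetric change.  Because no clinical volumes ship with the package,
a synthetic phantom-cohort generator with *texture-only* planted group
differences makes every stage testable end to end.

# Intensity normalization

Each volume is histogram-equalized before quantization.  The equalization
transform is a single monotone 256-entry lookup table per image, computed
from the cumulative distribution of the *foreground* (non-zero) voxels; it
is returned to the caller and can be dumped as CSV for audit.  Two design
choices are worth stating:

* **Foreground-only histograms.**  Brain volumes in template space are
  mostly background zeros; including them would let the background dominate
  the CDF and compress the brain's dynamic range into a few output levels.
  Whether the original analysis masked its histograms is not documented;
  masking is this package's documented assumption.
* **Output range `(0, 1]`.**  Equalized foreground intensities are mapped to
  `(level + 1)/256`, never 0, so the zero-voxel set is exactly invariant
  under equalization and quantization.  This "background preservation"
  property is asserted in the test suite.

Quantization then bins foreground intensities into `G` equal-width bins over
their observed min–max, producing integer levels `1..G` with background 0.
Because equalization has already flattened the histogram, equal-width binning
behaves like equal-frequency binning.  `G` must be even and in `[2, 256]`;
the default is `G = 16`, the value that maximized hold-out balanced accuracy
in the motivating study's exhaustive sweep (2–256 in steps of 2, 128
candidates, available via `sweep_bins()`; ties break toward fewer bins).

# GLCM texture-feature maps

For every voxel, a cube of edge 7 (cropped at volume boundaries) defines a
window.  Within the window, co-occurrence counts are accumulated over all
voxel pairs `(v, v + offset)` with *both* members foreground, over the 13
unique distance-1 3D directions, symmetrized, and normalized to a
probability matrix `p`.  Pairs with a background member are excluded — this
implements the "only cubes containing non-zero values" rule at pair
granularity, and windows with no valid pair yield 0 in every map.  Six
scalar features of `p` are mapped to the window centre:

* energy `= sum p^2`
* contrast `= sum (g1 - g2)^2 p`
* homogeneity `= sum p / (1 + |g1 - g2|)`
* entropy `= -sum p log2 p`
* sum entropy: entropy of the distribution of `g1 + g2`
* difference entropy: entropy of the distribution of `|g1 - g2|`

Design notes:

* **One pooled GLCM per window**, not one per direction.  The source
  analysis reports a single map per feature; pooling the 13 directions into
  one symmetrized matrix is rotation-robust and is the documented
  interpretation.  (Whether the original pooled directions or averaged
  per-direction features is unknowable from the text.)
* **Log base 2** for all entropies — a fixed bit-scale convention.
  `0 * log 0` is defined as 0.
* **Homogeneity** uses the inverse-difference form `1/(1 + |g1 - g2|)`, the
  commoner "homogeneity" in radiomics toolkits, rather than the
  inverse-difference-moment `1/(1 + (g1 - g2)^2)`.
* **Correctness is defined by a naive oracle.**  The sliding-window engine
  is compiled (Rcpp), but the test suite pins it, exactly at integer-count
  level and to 1e-12 after normalization, to a pure-R per-voxel, per-pair
  enumeration.
* Feature maps are smoothed with a Gaussian truncated to a 7×7×7 support.
  The support is stated by the source procedure; the sigma is not, and is
  fixed at 1.0 voxel here.  Smoothing uses separable convolution with
  local-mass renormalization (so constant maps are invariant at the
  boundary), and the background is re-zeroed afterwards.

# Classification

Each feature map type is analyzed independently — maps are never
concatenated.  The design matrix has one row per subject and one column per
foreground voxel.  The classifier chain per outer fold is:

1. **Inner cycle** (default 10 folds × 10 repetitions inside the outer
   training set): per inner split, columns are ranked by Welch two-sample
   *t* magnitude (ties by ascending column index; zero-variance columns get
   `t = 0` and rank last) and the top `k = 200` are selected; an MLP is fit
   per inner split (10 × 10 × 10 × 10 = 10,000 inner fits under the
   full-scale profile — the decomposition of that printed count is an
   interpretation, fixed here as outer reps × outer folds × inner reps ×
   inner folds).
2. **Consensus selection**: columns ordered by inner-selection vote count,
   then mean selection rank, then index, truncated to exactly `k`.
3. **Outer refit** on the full outer-training set with the consensus set
   (that the outer model is a refit rather than an inner ensemble is a
   documented choice).  Columns are z-scored with training-fold statistics
   (a conditioning choice for Levenberg–Marquardt; the source is silent).
4. **Hold-out evaluation** on the outer test fold only.  Sensitivity,
   specificity and balanced accuracy `= (sens + spec)/2` are computed per
   fold and aggregated so the identity holds exactly in aggregate.

The network is fixed at five hidden layers of two tanh units with a linear
output, trained full-batch by Levenberg–Marquardt on squared error with an
L2 penalty on connection weights (biases unpenalized).  Labels are coded
+1/−1 and thresholded at 0, with 0 assigned to the positive class.  The LM
damping schedule is the conventional one: start 1e-3, ×10 on rejected
steps, ÷10 on accepted ones, abort above 1e10; at most 1000 accepted epochs
(full-scale default).  The accepted-loss sequence is non-increasing by
construction and asserted in tests.  The L2 weight defaults to 0.01 and is
exposed in the configuration; the source states that L2 regularization was
used but not its strength.

**External validation.**  Stored outer models all score each external
subject (the clinical-high-risk-with-transition group in the motivating
design); a subject's call is the majority vote, ties to the positive class.

# Explanation and clustering

LRP redistributes the output score backwards through the network with the
epsilon rule: a unit's relevance is split over its inputs proportionally to
the signed contributions `z_ij = w_ij a_i`, with the stabilized denominator
`sum_i z_ij + b_j + eps * sign(.)`.  The bias share is absorbed (dropped),
which is the documented conservation leak; with zero biases the input
relevances sum to the output score within `1e-6 |score|` (asserted).  The
exact propagation variant used by the source study is in an appendix not
available here; the epsilon rule is its standard stand-in, with alpha-beta
rules out of scope.

Relevance is computed only for correctly classified hold-out subjects, and
a subject's heatmap is averaged across the outer models that held it out
and classified it correctly.  The positive part of the heatmap (PR) is
clipped, smoothed (default FWHM 10 mm, converted to voxels by
`sigma = FWHM / (2 sqrt(2 log 2)) / voxel`), and clustered.

Affinity propagation uses negative squared Euclidean distance between PR
vectors as similarity, the median off-diagonal similarity as preference (the
Frey–Dueck default favouring moderate cluster counts), damping 0.9, at most
1000 sweeps, convergence after 100 stable sweeps.  Cluster labels are
reindexed by descending cluster size (ties by ascending exemplar index), so
"cluster 1" is always the largest — matching the size-ranked color semantics
of the source figures.  On small instances the chosen exemplar set is
checked in tests against exhaustive enumeration of all exemplar subsets.

# The synthetic cohort

Phantoms are brain-shaped three-compartment volumes: an outer ellipsoid
(brain mask) with nested CSF-like (0.30), GM-like (0.55) and WM-like (0.80)
intensity bands, softened by a small Gaussian, plus spatially correlated
per-subject noise (white noise smoothed at sigma 1 voxel, rescaled to sd
0.05 on the compartment intensity scale).  Default group sizes mirror the
motivating study (FEP 77, CHR_NT 58, CHR_T 15, HC 44; 194 subjects);
desk-scale tests use 20 subjects/group on 24³ grids.  All randomness
derives from one master seed through a fixed counter scheme, so any subject
is reproducible in isolation.

The planted group difference is *texture-only*: the default `pair-shuffle`
effect partitions ROI voxels into 6³ blocks and, with probability equal to
the effect magnitude, permutes the intensities within a block.  A
permutation exactly preserves the ROI histogram — voxel count and mean
intensity cannot change — while local co-occurrence structure is disrupted
in proportion to the magnitude.  The block edge (6 voxels) and the default
ROI (an ellipsoid of radius one-sixth of the grid in the GM/WM bands) were
calibrated once, before the acceptance thresholds were evaluated, so that
magnitude 0.8 produces a strong planted signal (group-level Cohen's d well
above 1 on ROI-mean contrast) against the fixed noise level; they are part
of the stated world and not revisited.  Two further effect kinds exist:
`correlation-length-shift` (rank-remap onto a white-noise ordering; also a
permutation) and `checker-mix` (adds a zero-sum high-frequency component;
mean-preserving but not histogram-preserving).

What the generator does *not* emulate: scanner physics, bias fields,
preprocessing artifacts, anatomical variability, or realistic tissue
geometry.  A green signal-recovery test establishes that the pipeline can
detect co-occurrence differences planted under its own assumptions — it is
evidence of correct plumbing and statistical sanity, not of clinical
performance.  Conversely the zero-magnitude null cohort establishes that
the nested cross-validation does not leak (hold-out balanced accuracy stays
within 3 standard errors of chance).

# Test-scale profiles

Full-scale defaults (10×10 folds, 10+10 repetitions, k = 200, 1000 epochs,
194 subjects, 1 mm grids) are impractical for a test suite on one CPU.
Tests and the acceptance suite run a desk-scale profile: 24³ grids, 20
subjects/group, 3×3 folds with 2+2 repetitions, 60 epochs.  The
signal-recovery acceptance run keeps `k = 200` (the full-scale selection
size) rather than the desk default of 50, because selection size controls
how much spatial averaging the classifier can exploit and the acceptance
criterion is a statement about the full-scale configuration.  Both
classification acceptance runs use the difference-of-entropy map, the
dominant discriminative feature in the motivating analysis.

# Numerical and degenerate-input choices

* Constant-foreground volumes are rejected by `equalize()`/
  `quantize_volume()` ("degenerate histogram").
* GLCM windows with no valid pair produce `pair_count = 0`; features of such
  windows are `NA` at the scalar level and 0 in maps.
* `NA`-propagating metrics: if a confusion table lacks a class, its rate and
  the balanced accuracy are `NA` rather than silently 0.
* Ties: prediction score 0 is the positive class; feature-rank ties break by
  column index; cluster-size ties break by exemplar index; bin-sweep ties
  break toward fewer bins.
* The NIfTI-1 reader/writer is deliberately minimal (3D scalar volumes,
  little-endian write, gzip supported) because no NIfTI package is available
  in the supported dependency set; it is validated against `nibabel` in the
  test suite.

# Known limitations

* The sliding-window GLCM engine recomputes each window rather than updating
  incrementally; at full 1 mm brain resolution a production run takes
  minutes per subject, which is accepted because correctness is defined by
  the naive oracle and desk-scale grids dominate testing.
* LRP is implemented for dense tanh layers only.
* The bin sweep evaluates a user-supplied scorer; the two-stage visual
  inspection of the source procedure is out of scope.
* Affinity propagation can oscillate on pathological similarity matrices; in
  that case the best exemplar set seen is returned with `converged = FALSE`
  and a warning.  Exactly symmetric similarities (the generic case for
  distance-based input) make the message updates degenerate; following
  common practice, a deterministic fixed-seed perturbation at relative
  magnitude ~1e-14 is added before message passing (disable with
  `degeneracy_jitter = FALSE`).  Net similarities and assignments are
  always reported on the unperturbed matrix.
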