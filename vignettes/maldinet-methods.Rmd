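---
title: "maldinet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{maldinet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

MALDI mass spectrometry imaging (MSI) acquires a full mass spectrum at
every pixel of a tissue section. On a tissue microarray (TMA) carrying
cores from many patients, each core has a single diagnostic label, and
the question is whether the per-pixel spectra carry enough molecular
signal to recover that label — here, to distinguish salivary gland
carcinoma (SGC) subtypes from each other, from control tissue, and from
bare-matrix spots. `maldinet` implements the full workflow as reusable,
tested R functions: preprocessing, a 1-D convolutional classifier under
stratified cross-validation, DeepLift attribution to name the m/z
features behind each class decision, a duplicate-mass artifact filter,
a density-preserving 2-D embedding of the selected masses, and
core-level spatial reporting. Because no public TMA raw data accompany
the study design this package targets, a synthetic TMA generator with
planted ground truth is a first-class component: it is the substrate on
which every claim the test suite makes is actually computed.

## Data model

All stages share one equidistant mass axis (`binning_scheme`): bin *i*
covers the half-open interval `[lo + i*w, lo + (i+1)*w)` and is
represented by its center. Half-open lower-inclusive intervals remove
the double-counting ambiguity at bin edges. An `msi_dataset` holds a
dense pixels-by-bins intensity matrix, a pixel table (0-based grid
coordinates, core id, tissue flag) and a core table (core id, class
label). imzML 1.1 (continuous mode, external `.ibd` binary) is the
interchange format; a single-file RDS-based container (`.msid`) is
provided for fast local round trips, since XML-adjacent formats are
slow at hundreds of thousands of bins per pixel.

## Preprocessing

Four steps, in a fixed order:

1. **Re-binning** (`rebin`): every raw data point's intensity is added
   to the bin containing its m/z; out-of-range points are dropped.
   In-range total intensity is conserved to ~1e-9 relative.
2. **Off-tissue masking** (`mask_off_tissue`): pixels flagged as
   containing no tissue are removed, except in cores of the dedicated
   matrix-only class, which contain no tissue by design and constitute
   their own class.
3. **Matrix-peak correlation filter** (`matrix_filter`): the MALDI
   matrix (e.g. CHCA) contributes peaks in every pixel that carry no
   biology. The filter detects peaks as local maxima of the dataset-mean
   spectrum above a robust floor (median + 3·MAD of that spectrum — a
   deterministic, scale-free definition), takes as reference the most
   intense mean peak over the matrix-only pixels (falling back to the
   globally most intense peak when no matrix class exists; "pure
   matrix" is read as off-tissue signal), ranks all peaks by the
   Pearson correlation of their apex-bin intensity with the reference's
   across pixels, and zeroes ±0.02 Da around the best-correlated
   `n_filter` (default 500) peak positions in every pixel. Correlation
   is computed on pre-normalization intensities, where intensity
   co-variation is meaningful.
4. **Per-pixel min-max normalization** (`normalize_minmax`): each
   spectrum is mapped affinely onto [0, 1]. A constant spectrum maps to
   all zeros rather than NaN, keeping downstream tensors finite. No
   baseline removal and no global normalization are performed.

Normalization runs last so the classifier's [0, 1] input contract holds
regardless of what the filter zeroed.

## The classifier

A 1-D CNN: six blocks of [convolution → leaky ReLU → max-pool], then a
single fully connected layer producing one raw score per class
(`arch_config`, `build_model`, `train_cv`). Defaults: channels
8/16/32/64/128/128, kernel 9, pool 4, leaky slope 0.01 — sized for
desk-scale axes of roughly 4k–21k bins; all exposed in the
configuration. Convolutions are "valid" (no padding) and pooling drops
remainder positions; the architecture validator requires at least one
surviving position per block and names the offending block otherwise.
Training minimizes softmax cross-entropy with Adam at learning rate
0.001 for 30 epochs at batch size 64. Class imbalance (the default TMA
has 24 cores of one class and 3 of another) is deliberately not
reweighted — the protocol evaluates the plain pixel-level objective.

Spectra are zero-padded on the high-mass side to the smallest length
whose receptive field covers every real bin. Without padding, the
remainder positions dropped by each of the six max-pools compound into
a blind zone of roughly two thousand bins at the top of a 21,000-bin
axis — markers there would be classified around and never attributed.
Padding bins are zeros under the all-zero DeepLift reference, so they
carry exactly zero contribution.

Cross-validation is stratified at the pixel level: within each class,
pixels are shuffled (seeded) and dealt round-robin into k = 5 folds, so
per-class fold sizes differ by at most one. Pixel-level splitting lets
pixels of one core appear in both training and test folds; that is the
faithful protocol here (core-wise labels, per-pixel decisions), and the
core-level majority vote is reported separately. Every pixel is
predicted exactly once, by the model of the fold that held it out.
Per-class accuracy is computed per fold and averaged over folds.

The training loop is hand-written C++ (RcppArmadillo): im2col + GEMM
convolutions in float32 with all large buffers preallocated once per
fold and reused across batches, because per-batch allocation of
~100 MB im2col buffers costs more in page faults than the GEMMs
themselves on a single CPU. The leaky ReLU is monotone increasing, so
max-pooling is applied to the conv pre-activations and the activation
to the pooled values; the full-length activation tensor is never
materialized. Prediction and attribution run in float64. Determinism
is per-platform: fixing the seeds reproduces runs on one machine, but
BLAS and compiler differences may change low-order bits elsewhere.

## DeepLift

`deeplift_attribute` propagates multipliers from a target class score
back to the input, relative to a reference spectrum, and returns
per-bin contributions `m ⊙ (x − ref)`:

- linear and convolutional layers pass multipliers through their
  weights (bias terms cancel in deltas);
- leaky ReLU units use the rescale rule
  `m = (f(z) − f(z_ref)) / (z − z_ref)`, falling back to the pointwise
  derivative when `|z − z_ref| < 1e-7`;
- each max-pool routes its multiplier to the argmax position of the
  *actual* input, scaled by `(pool(x) − pool(ref)) / (z_a − z_ref_a)`,
  so the pooled output delta is carried exactly. Plain gradient-style
  routing (factor 1) would break summation-to-delta whenever input and
  reference select different window positions; the delta-ratio form
  keeps `Σ contributions = score(x) − score(ref)` exact up to float
  error, which the tests verify to 1e-4 relative on random networks.

The reference is the all-zero spectrum: after min-max normalization,
zero is the natural "no ion signal" state. Class-level attribution
averages the contribution vectors of all *correctly classified*
held-out pixels of a class, each attributed through its own fold's
model; restricting to correct pixels keeps confused spectra from
blurring the class profile. Whether attribution should run per pixel
and average, or once on a class-mean spectrum, is genuinely open; the
per-pixel mean is used because the classifier itself operates per
pixel. `top_k_masses` then reports the k = 10 *masses* of largest
strictly positive contribution per class, ties broken toward lower
mass. A mass is a positive local maximum of the contribution vector,
not a raw bin: a rendered peak spans several adjacent bins that all
score highly, and ranking raw bins would fill a top-10 list with
copies of its two or three strongest peaks. The apex bin is what
identifies the feature — the same granularity at which the duplicate
filter treats two masses within one bin width as identical.

## Duplicate filter and embedding

Masses appearing in more than one class's top-10 list (within one bin
width — the identity granularity of a binned pipeline) behave like
measurement artifacts rather than class markers; `dedup_filter` moves
them to an artifact list and keeps the class-unique masses.
`embed_densmap` reduces each pixel to its intensities at the unique
masses and embeds them in 2-D with densMAP — the density-preserving
extension of UMAP — supervised by the class labels. The projection is
delegated to the established `umap-learn` implementation (invoked
through the system Python, seeded, single-threaded, hence
deterministic); re-deriving UMAP internals would be out of proportion
to what this package contributes. Supervision strength
(`target_weight`, default 0.5) and the density term (`dens_lambda`,
default 2) are exposed. Tests assert label separation via silhouette
scores rather than exact coordinates. An interactive SVG/HTML export
colors points by class with per-core hover tooltips.

## Spatial reporting

`classification_map` renders held-out correctness per pixel
(green/red). `core_majority_vote` assigns each core its modal predicted
label — ties broken by higher mean class score, then class order, for
determinism — and reports the fraction of cores voted correctly; when
every core's own pixel accuracy exceeds 50%, the vote is guaranteed
correct, which is the amplification the tests assert. `ion_image` sums
intensities over all bins intersecting `mz ± window` (default 3 mDa)
and renders them with per-image maximum scaling; raw sums are exported
alongside so analyses never depend on rendering.

## The synthetic TMA generator

`generate_tma` emulates the statistical structure the analysis relies
on, with known ground truth:

- **Classes and cores.** Eight classes patterned on the study TMA:
  Acin 20, AdCy 24, Anos 8, Control 6, MuEp 16, SaDu 4, Sec 3 cores,
  plus 4 matrix-only cores. Cores are disks of 9 pixels on a shared
  grid, shuffled over grid positions.
- **Signal model.** Each tissue pixel is a sum of Gaussian peaks
  (constant width 0.02 Da) on the binned axis: 30 background peaks
  shared by all tissue classes, 5 private marker peaks per class with
  log-normal per-pixel heights (jitter σ = 0.3), a dominant matrix
  reference peak with log-normal amplitude, and a 500-peak matrix
  family (reference + 499 satellites constructed to have Pearson
  correlation 0.9 with the reference across pixels — sized so the
  default 500-peak filter can capture the family exactly), plus
  additive half-normal noise (σ = 0.02 relative to
  a marker height of 1). Off-tissue pixels (10% of each tissue core)
  and matrix-class pixels carry only matrix signal and noise. The
  reference peak is the most intense feature of the mean spectrum by
  construction, making the filter's reference identification
  deterministic.
- **Separation rule.** All planted positions are mutually separated by
  more than twice the filter window, so "filter removed a planted
  matrix peak" and "filter spared a planted marker" are unambiguous.
- **Ground truth.** Planted marker, background and matrix m/z lists
  are returned for recovery tests. The matrix-only class carries no
  markers (its cores contain no tissue); configurations without a
  matrix class plant markers for every class.
- **Label noise.** `plant_label_noise` regenerates a fraction of one
  core's pixels as marker-free tissue while keeping the core label,
  emulating a core whose healthy portion inherits the tumor label.

What the generator does *not* model: realistic peptide mass
distributions and isotope envelopes (a single optional +1 Da satellite
flag exists), adduct chemistry, resolution varying with m/z, spatial
intensity gradients within cores, and core-level batch effects.
Passing tests therefore demonstrate that the pipeline's machinery is
correct and recovers planted structure under MALDI-like noise — not
that any particular real-data accuracy is attainable.

Default problem sizes were chosen once for single-CPU experimentation:
the axis spans 590–800 Da at 10 mDa (21,000 bins — a desk-scale
stand-in for the 0.3 mDa axes of FT-ICR instruments), 85 cores × 9
pixels. Signal-to-noise defaults are stated as assumptions, chosen to
be MALDI-plausible, not estimates of any instrument.

## Numerical and degenerate-input choices

- Constant spectra normalize to zeros, never NaN.
- A dataset with zero pixel-to-pixel variance at the reference peak
  makes correlation undefined; `matrix_filter` raises an error rather
  than guessing.
- Rescale fallbacks (ε = 1e-7 on deltas) keep DeepLift finite; the
  only summation-to-delta leak is the measure-zero case where a pooled
  delta is nonzero while the routed position's delta vanishes.
- Fold assignment, generation, and label-noise planting consume
  isolated RNG streams (`withr::with_seed`), so pipeline stages can be
  re-run independently without disturbing each other.
- Max-pool ties resolve to the lowest index; vote ties resolve by mean
  score then class order.

## Known limitations

- The imzML reader targets continuous-mode files (and uniform-axis or
  explicitly re-binned processed files); vendor raw formats are out of
  scope.
- The CNN is CPU-only by design; the workflow is sized so the full
  default experiment (5 folds × 30 epochs) runs in minutes, not hours.
- Protein identification from discriminative masses is out of scope:
  a mass list is the product, not an identification.
- The embedding depends on a system Python with `umap-learn`; all
  other functionality is pure R/C++.
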