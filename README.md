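# maldinet

Deep-learning tumor subtyping for MALDI mass spectrometry imaging
(MSI) of tissue microarrays, in R.

MALDI imaging acquires a full mass spectrum at every ~50 µm pixel of a
tissue section. On a tissue microarray (TMA) holding cores from many
patients — here patterned on a salivary gland carcinoma (SGC) cohort
with six tumor subtypes, healthy control tissue and bare-matrix spots —
each core carries one diagnostic label, and the analysis asks whether
per-pixel spectra alone can recover it. `maldinet` is for MSI
bioinformaticians who want that workflow as ordinary, tested R
functions rather than vendor-GUI steps.

The pipeline:

1. **I/O** — imzML 1.1 (continuous mode) reader/writer, TSV core
   annotations and tissue masks, and a fast single-file container.
2. **Preprocessing** — re-binning onto an equidistant m/z axis
   (half-open bins), off-tissue pixel exclusion, removal of the
   `n = 500` peaks best correlated (Pearson, across pixels) with the
   strongest pure-matrix peak (±0.02 Da zeroed), and per-pixel min–max
   normalization to [0, 1]. No baseline removal, no global
   normalization.
3. **Classification** — a 1-D CNN, six blocks of
   [conv → leaky ReLU → max-pool] and a final fully connected layer,
   trained with Adam (lr 0.001, softmax cross-entropy) under
   stratified 5-fold cross-validation at the pixel level; every pixel
   is predicted once, held out. Forward/backward passes are
   hand-written RcppArmadillo (im2col + GEMM, float32 training,
   float64 inference) — no GPU, no Python for this part.
4. **Explanation** — DeepLift (rescale rule) contributions of every
   m/z bin to every class score, exact summation-to-delta:
   `Σᵢ Cᵢ = S_c(x) − S_c(x_ref)` with the all-zero reference; the
   top-10 positive masses per class; a duplicate filter that discards
   masses shared between classes (measurement artifacts) within one
   bin width.
5. **Embedding & reporting** — supervised densMAP (density-preserving
   UMAP, via the system's `umap-learn`) of the class-unique masses to
   2-D; green/red held-out classification maps; core-level majority
   votes; ion images at `mz ± 3 mDa`.
6. **Synthetic ground truth** — a TMA generator with planted
   class-marker peaks, matrix-correlated peak families, shared
   background peaks and off-tissue pixels, used by the test suite to
   verify marker recovery, filter precision and accuracy end to end.

## Worked example

A scaled-down experiment (4 classes, 19 cores, 590–620 Da at 10 mDa):

```r
library(maldinet)

cfg <- synthetic_config(
  scheme = binning_scheme(590, 620, 0.01),
  cores_per_class = c(AdCy = 6L, Acin = 6L, Control = 4L, Matrix = 3L),
  pixels_per_core = 9L, markers_per_class = 4L,
  n_matrix_peaks = 60L, seed = 1L)
sim  <- generate_tma(cfg)
prep <- preprocess_msi(sim$dataset, n_filter = 60L)

arch <- arch_config(n_conv_blocks = 4L, channels = c(8L, 16L, 32L, 64L),
                    kernel_size = 9L, pool_size = 4L,
                    n_classes = length(prep$dataset$class_order))
cv <- train_cv(prep$dataset, arch,
               train_config(epochs = 15L, batch_size = 32L, seed = 1L))
round(per_class_accuracy(cv$predictions), 1)
#>    Acin    AdCy Control  Matrix
#>     100     100     100     100
```

Per-class accuracy is the held-out percentage of correct pixel
predictions, fold-averaged. Majority voting then labels whole cores:

```r
core_majority_vote(cv$predictions, prep$dataset$cores)
#> <core_vote_result> 19 cores, 100.0% voted correctly
```

DeepLift names the masses behind each class decision. The four planted
AdCy markers sit at 598.0262, 601.1970, 607.1667 and 617.1401 Da, and
the top-4 attribution masses recover all of them to bin resolution:

```r
att  <- class_attribution(cv$models, prep$dataset, cv$predictions)
top_k_masses(att, k = 4L)$AdCy
#>   rank      mz     score
#> 1    1 607.155 0.8312198
#> 2    2 598.025 0.6407639
#> 3    3 601.195 0.6397974
#> 4    4 617.145 0.3644048

dedup_filter(top_k_masses(att, k = 4L))
#> <mass_list> 16 pooled entries: 16 class-unique, 0 duplicated (artifact) masses
```

`embed_densmap(prep$dataset, dedup_filter(...))` then projects the
pixels to 2-D on the class-unique masses, and
`ion_image(prep$dataset, 607.1667)` maps a single marker across the
grid.

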