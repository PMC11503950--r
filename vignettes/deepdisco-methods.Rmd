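---
title: "Methods: disconnectome surrogates, morphospace prediction, and the synthetic phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disconnectome surrogates, morphospace prediction, and the synthetic phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

A focal brain lesion does not only destroy the tissue it occupies: it
disconnects every white-matter pathway that passes through it. The
*disconnectome* formalizes this as a voxel map in [0, 1]: against a
population of N normative whole-brain tractograms, the value at a voxel is
the proportion of reference subjects for whom at least one streamline both
crosses the lesion and visits that voxel. Computing this directly requires
intersecting the lesion with every streamline of every subject — accurate
but slow, and it needs the full normative tractogram set at hand.

`deepdisco` implements both routes and the machinery to compare them:

1. **Oracle route** (`compute_disconnectome`): direct streamline
   intersection, the ground truth.
2. **Surrogate route** (`build_unet`, `train_model`,
   `predict_deep_disconnectome`): a dual-channel 3D U-Net trained to map a
   binary lesion mask straight to its disconnectome.
3. **Outcome prediction** (`fit_morphospace`, `localisation_map`,
   `pixelwise_correlation`, `extract_territories`, `fit_score_model`): a
   2D UMAP "morphospace" of disconnection profiles from which behavioural
   scores are predicted, runnable on either kind of disconnectome so the
   two routes can be compared end to end.
4. **A synthetic phantom** (`make_brain_mask`, `make_bundles`,
   `sample_subject_tractogram`, `make_lesion`, `make_scores`): generates
   the whole study — brain, bundles, normative subjects, lesions and
   behavioural scores with planted effect sizes — so every stage is
   testable with known ground truth and no imaging download.

# Geometry conventions

All volumes share a `grid_spec`: an isotropic voxel lattice. Geometry uses
continuous, 0-based voxel coordinates; a point `p` occupies voxel
`floor(p)` and voxel `i` has its centre at `i + 0.5`. The phantom affine is
the pure scaling `diag(voxel_size)`, which removes any world/voxel
ambiguity from the geometry tests. Indexing of flattened volumes is
column-major array order throughout, and that fixed order is also the
column order of vectorized disconnectomes.

## Streamline traversal

`voxels_traversed` resamples a polyline at equal arc-length steps of 0.1
voxel (plus the original vertices) and collects the voxels containing any
sample. This is an approximation to the exact 3D supercover of the curve;
the test suite bounds its error by comparing against a 10x finer sampling,
and the brute-force reference used in the oracle-equivalence tests
enumerates (subject, streamline, sample point) triples explicitly with
independent code. Streamline *generation* resamples at 0.5 voxel — coarse
enough to be cheap, fine enough that the 0.1-voxel traversal of the
resulting polyline is dense.

A deliberate choice: voxels inside the lesion itself may be marked
disconnected. Excluding them is a defensible alternative, but nothing in
the disconnectome definition requires it, so we do not.

## Binarization

`binarize_disconnectome` uses a *strict* threshold, 0.0001 by default. The
threshold exists to suppress the near-zero background that a sigmoid
network output produces; oracle values are quantized to k/N, so for any
cohort of at most 10,000 subjects the binarized oracle equals its support
exactly, while an exact-threshold value counts as background.

# The phantom

The brain is a filled ellipsoid inscribed in the grid with a safety
margin. White-matter anatomy is emulated by two bundle morphologies, in
alternation: *long* spines crossing the brain end to end (core pathways)
and *short peripheral arcs* hugging the surface, the stand-in for short
U-shaped association fibres — the structure reported as hardest for a
convolutional surrogate to capture. Each normative subject is the bundle
set re-jittered: every streamline is its spine plus a smooth Gaussian
offset whose per-point, per-coordinate marginal standard deviation is
exactly `jitter_sd` (offsets are drawn at the spine knots, interpolated
along arc length, and rescaled to undo the variance shrinkage of
interpolation — so the zero-noise limit is exactly the spine and the
Monte-Carlo mean absolute deviation is exactly `jitter_sd * sqrt(2/pi)`).

Default study conditions (chosen once, as plausible desk-scale stand-ins
for the real setting, and kept fixed): 16^3 grid at 2 mm, 6 bundles, 10
normative subjects, 16 streamlines per bundle per subject, jitter 0.75
voxel (1.5 mm — the order of real inter-subject tract-core variability),
lesion semi-axes uniform in 2–5 voxels (4–10 mm focal lesions). Lesions
are ellipsoidal blobs centred uniformly over brain voxels and clipped to
the brain.

Behavioural scores are planted: per patient and bundle, the disconnection
severity is the fraction of that bundle's streamlines (pooled over
subjects) crossing the lesion, and a score is a fixed linear combination
of severities plus Gaussian noise. With zero noise and one-hot weights a
score *is* the severity, which the tests assert; `max_score` is the
observed cohort maximum rounded up (floored at 1), giving the MAE%
normalization a defined denominator even for pure-noise null tests.

What the phantom does **not** emulate: real anatomy (no template space, no
atlas), diffusion signal, tracking errors, lesion segmentation noise, or
correlated test batteries. Passing tests therefore demonstrate that the
algorithms are implemented correctly and that the pipeline recovers known
planted structure at this scale — not that the surrogate generalizes to
clinical data.

# The network

The surrogate is a 3D U-Net with two input channels — the binary lesion
mask and a fixed template, the voxel-wise average of the training
disconnectomes, which anchors the output toward plausible disconnection
topography. Encoder: three blocks of two [3x3x3 convolution, batch
normalisation, LeakyReLU] layers, each block followed by 2x2x2 max-pooling
(stride 2) and dropout 0.5; filters double per block (16 to 64 at full
scale). Decoder: three blocks of [trilinear 2x upsampling, concatenation
with the matching encoder skip, one 3x3x3 convolution + batch
normalisation + plain ReLU] — the rectifier type differs between encoder
and decoder on purpose, following the architecture being reproduced.
A final 3x3x3 convolution with a sigmoid maps to (0, 1).

Training minimizes the sum of in-mask MSE and in-mask MAE (voxels outside
the brain mask contribute nothing to loss, evaluation or predictions),
with Adam (learning rate 3e-4, weight decay 1e-4 applied to convolution
weights), batch size 4, an 80/20 train/validation split (`floor` rule on
the training size), a 300-epoch cap and early stopping after 50 epochs
without validation improvement; the returned weights are those of the best
validation epoch. Everything — initialization (He-normal), shuffling,
dropout masks — draws from R's seeded RNG, and the kernels are
single-threaded C++, so two runs with the same configuration are
bit-identical.

Numerical choices worth recording:

* LeakyReLU negative slope 0.01 (the conventional default; not specified
  by the source architecture).
* Dropout is applied after pooling, reading the block order as written.
* Decoder channel widths mirror the encoder (64 -> 32 -> 16) after
  concatenation.
* Batch-norm uses batch statistics in training and running averages
  (momentum 0.1, eps 1e-5) in evaluation.
* The grid/width are configurable (`model_config`): the full-scale profile
  is 96^3 with base 16; the desk-scale profile used by the tests and the
  acceptance run is 16^3. For the fidelity experiment we use base
  6 (filters 6/12/24) rather than the minimal base 4: at the 60-epoch cap
  the narrowest net is still underfitting, and base 6 with 384 training
  pairs is the largest profile that keeps the full fidelity run within a
  routine desk budget (~13 minutes on one CPU). Width is the one deliberate departure from the
  smallest test profile, and it is still 2.7x narrower than full scale.
* Per-pair fidelity (`goodness_of_fit`) is the squared Pearson correlation
  over in-mask voxels — *not* 1 − SS_res/SS_tot; the two differ for biased
  predictors, and pairwise Pearson R² is the comparison statistic used
  throughout.
* The resize transform between a native grid and the cubic model grid uses
  nearest-neighbour for masks and trilinear for float maps, with
  half-voxel-centre alignment; the inverse is shape-exact always and
  value-exact for masks when the target is at least as large as the source
  on every axis (a strict downsample necessarily loses voxels).

# Morphospace outcome prediction

Reference disconnectomes (vectorized over in-mask voxels) are embedded in
2D with UMAP (defaults `n_neighbors = 15`, `min_dist = 0.1`, fixed seed,
single-threaded; hyperparameters are configuration keys since the source
work does not print them). New patients are transformed into the fitted
space without refitting. The package delegates the UMAP fit/transform to
`uwot`; everything around it is implemented here.

"Where a patient sits" becomes a *localisation-probability image*: a delta
at the containing pixel of a 64x64 raster spanning the reference bounding
box plus a 25% margin, convolved with an isotropic Gaussian (sigma 2
pixels) and renormalized to sum 1. The smoothing radius is what lets
nearby patients share probability mass, which is what makes pixel-wise
statistics across patients informative; raster resolution, margin and
sigma are all configuration keys. Coordinates outside the raster clamp to
the edge with a warning.

Per behavioural test: Pearson correlation between the patients'
localisation values and their scores at every pixel; pixels with |R|
strictly above 0.2 (medium effect size; both tails, since deficits may
correlate negatively — configurable to positive-only) form 8-connected
clusters; a cluster's informativeness is its summed |R|, the three most
informative clusters are kept (ties break by size, then lowest pixel
index). One pooled PCA runs over the patients x territory-pixel matrix
(column-centred), and an ordinary least-squares regression of the measured
scores on the first three component scores gives the prediction model.
Whether the original analysis pools one PCA over all suprathreshold pixels
or fits one per cluster is ambiguous; we implement the pooled variant (the
per-cluster alternative would change `fit_score_model` only).

Accuracy is reported as 1 − MAE%, where MAE% is the mean absolute error
divided by the maximum attainable score; R² is again squared Pearson
(predicted vs measured). For *calibration* we additionally carry the
sign-preserving statistic `sign(r)·r²`: the plain square of a correlation
is chance-positive by construction (for held-out size n its null mean is
about 1/(n−1), several Monte-Carlo standard errors above zero for any
permutation count), so a permutation-null check of "no information ⇒ no
performance" is only meaningful for a statistic whose chance level is
zero. `permutation_null_r2` therefore averages the signed statistic, and
returns the unsigned 95th percentile for signal-recovery comparisons.

Framework comparison uses the standard two-tailed paired t-test on the
per-test R² lists, average-Euclidean-distance profiles of the patient
coordinates in each morphospace, and a Bland–Altman summary of the paired
profiles (SD with the n−1 denominator; limits mean ± 2 SD; 95% CI of the
mean from the t distribution).

# The replication driver

`run_replication` chains the whole study at a configured scale: phantom
simulation → oracle disconnectomes → U-Net training → deep-disconnectome
prediction → the two prediction frameworks (conventional morphospace from
oracle maps, deep morphospace from predicted maps, identical patient
split) → comparison statistics, and writes a JSON report carrying every
headline number plus the full configuration. Stage seeds are fixed
offsets from the global seed, so the report is a pure function of the
configuration; the determinism test serializes two runs and compares the
bytes. The default profile (64 training pairs, 12 epochs, 60 patients, 6
tests) finishes in a few minutes on one CPU; the dedicated fidelity
experiment (`unet_fidelity_experiment`: 384 pairs, 60-epoch cap) is the
problem size used for the headline reconstruction-fidelity number.

# Known limitations

* The traversal set is sampling-based; a pathological polyline segment
  could graze a voxel for less than 0.1 voxel of arc length and be missed.
* Dense in-memory volumes only; at 96^3 with wide filters, training is a
  GPU-scale job that this pure-CPU implementation does not target.
* The phantom's score battery is linear in bundle severities; real
  neuropsychological batteries are correlated, censored and non-linear.
* `uwot`'s transform of far-out-of-distribution patients can land outside
  the reference cloud; such patients clamp to the raster edge.
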