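---
title: "Methods: CycleGAN harmonization of multi-site brain MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CycleGAN harmonization of multi-site brain MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mriharm)
```

## The problem

T1-weighted brain MR images pooled across scanners carry systematic,
non-biological intensity differences — field strength, vendor, and
acquisition parameters all shift the global brightness, the GM/WM
contrast, the spatial bias field and the noise level. These *site
effects* confound any downstream analysis that mixes sites: tissue
volumetry, image quality metrics, radiomics, and learned predictors such
as brain-age models. `mriharm` implements *harmonization*: an unpaired
image-to-image translation that moves every non-reference site's images
into the intensity domain of a chosen reference site while preserving
each subject's anatomy.

## The model

Harmonization is learned by a whole-volume 3D CycleGAN. Two generators
$G_{A\to B}$ and $G_{B\to A}$ translate between site domains; two
patchGAN discriminators $D_A$, $D_B$ score local realism. The training
loss is the least-squares adversarial loss plus an L1 cycle-consistency
penalty $\lambda\,(\lVert G_{B\to A}(G_{A\to B}(a)) - a\rVert_1 +
\lVert G_{A\to B}(G_{B\to A}(b)) - b\rVert_1)$, with $\lambda$ decaying
linearly from 200 to 100 over the run.

Architectural choices, all of which are tested properties rather than
conventions:

* **Strided convolutions only.** The U-net generator encoder is a stack
  of stride-2 $4^3$ convolutions; the decoder mirrors it with stride-2
  transposed convolutions and concatenating skip connections. There are
  no stride-1 refinement blocks and no resize convolutions.
* **Masked generation.** The input brain mask multiplies every generator
  output, so background voxels are exactly zero and nothing outside the
  brain can leak into the discriminators or the cycle loss.
* **Non-negative, unbounded output.** The final activation clamps
  negatives to zero and is linear above zero (instead of tanh), so the
  generator can emit intensities above the nominal input scale.
* **MAD instance normalization.** Instance normalization divides by the
  mean absolute deviation instead of the standard deviation:
  $y = (x - \bar x)/(\mathrm{mean}|x - \bar x| + \varepsilon)\cdot g + o$.
  The deviation is deliberately *not* rescaled by $\sqrt{\pi/2}$ to mimic
  an SD — the statistic is replaced, not approximated. $\varepsilon =
  10^{-5}$.
* **patchGAN receptive field 38.** The default discriminator stack
  (kernels 4/4/4 stride 2, then kernel 3 stride 1) sees $38^3$ input
  voxels per output unit, by the recurrence
  $RF_n = RF_{n-1} + (k_n - 1)\prod_{m<n} s_m$. `gradient_footprint()`
  confirms this empirically; because instance-norm statistics couple all
  spatial positions, the probe runs with normalization disabled (at
  frozen statistics normalization is a per-channel affine map and cannot
  widen the field).

The exact channel counts of the original architecture are not
recoverable, so channel schedules are configurable: `base_channels`
doubling per stage, capped at 8x. Skip connections concatenate (the
U-net convention) rather than add. Encoder activations are leaky (slope
0.2), decoder activations are plain rectifiers; both slopes are
configurable.

### Why the networks are implemented from first principles

The convolution stack, its backward passes and the optimizer are written
in this package (Rcpp im2col/col2im kernels, BLAS matrix products,
hand-derived gradients) because the normalization variant, the masked
generation rule, the output activation and the training protocol *are*
the method — they need to be controlled exactly, and every backward pass
is validated against central finite differences in the test suite.

## The training protocol

* **Identity pretraining.** A single generator is first trained to
  replicate its masked input with an L1 loss over all sites pooled; both
  CycleGAN generators start from those weights. This makes the cycle
  loss small from step 0 and biases the model toward anatomy-preserving
  mappings.
* **Cycle weight schedule.** $\lambda$ decays 200 to 100 linearly over
  the whole run (the schedule endpoint is not stated upstream; spanning
  the full run is this package's choice, and both endpoints are
  configurable).
* **History buffer.** Each discriminator trains against a 50-image
  history of generated volumes under the classic store-or-swap rule:
  below capacity the offer is stored and shown; at capacity the offer is
  shown with probability 1/2, otherwise a uniformly drawn stored image
  is shown and replaced by the offer.
* **Batch composition.** Generators use batch size 1. Each
  discriminator update sees 8 images: 4 real, 2 newly generated, 2 from
  the history. Before the buffer holds 2 images the shortfall is filled
  with additional new fakes — a documented cold-start fallback.
* **Optimizer.** Adam with $\beta = (0.5, 0.999)$ for all networks. The
  upstream learning schedule is not published; the classic CycleGAN
  value is $2\times10^{-4}$ over ~10^5 steps. At this package's desk
  scale (a few hundred batch-1 steps) that schedule barely moves the
  generators, so the default `training_config()` learning rate is
  higher; the end-to-end tests state the value they use. No identity
  loss term is used during adversarial training (replication is handled
  by pretraining).
* **Determinism.** Every stochastic choice in a run (sampling, buffer
  coin flips, initialization) flows from one seeded RNG; identical
  seeds reproduce identical weights bit for bit on fixed hardware.
* **Precision.** All computation is double precision. A mixed-precision
  mode is not provided: R has no half/single-precision numeric type, so
  `training_config(mixed_precision = TRUE)` is rejected rather than
  silently ignored.

### Age-balanced sampling

When two sites differ in age structure, a site translator can learn to
"correct" age effects. The sampler assigns one shared per-decade-bin
probability $q(b) \propto \min(n_A(b), n_B(b))$, zero for bins empty in
either site, uniform-with-replacement within bins. Both sites are then
sampled from the *same* age distribution at every step (exactly, by
construction), and the min rule maximizes use of the limiting site per
bin, avoiding undersampling of the smallest populations. The upstream
probability-assignment algorithm is unpublished; the min rule is this
package's reimplementation of its stated objective.

## Preprocessing in scope

Upstream skull-stripping, bias-field correction and affine registration
are external. In scope: median normalization (brain median to 500 — less
outlier-sensitive than max normalization), zero-padding/cropping to a
cube (default 192, tests use 48) centered on the brain bounding box with
ties toward the lower index, refusing to drop brain voxels; and brain
intensity histograms over 100 bins from 0 to 900. Out-of-range voxels
are ignored, not clipped into the edge bins — the upstream convention is
unstated, the ignored count is reported, and the bounds are
configurable.

## The phantom simulator

Real multi-site cohorts cannot ship with a package; the simulator
generates what the method needs to be exercised end to end:

* **Anatomy.** Nested deformed ellipsoids — WM core, GM shell, CSF rim —
  with a smooth per-subject radial perturbation field. Cheap,
  mask-consistent, and with genuine curved GM/WM boundaries so partial
  volume and smoothness metrics have nontrivial ground truth.
* **Partial volumes** by smoothing hard labels with a small Gaussian
  (sigma 0.7 voxels; 0 keeps hard labels), renormalized to sum to 1
  inside the mask and 0 outside.
* **Aging.** The GM volume fraction follows a linear atrophy line,
  `atrophy_line(age) = 0.48 - 0.0015 * age`, with GM loss converted to
  CSF and WM held at 0.35; intensities are age-independent, so age acts
  only through anatomy — the biological covariate harmonization must
  preserve. The intercept and slope sit in the range volumetric studies
  report for adult cohorts, and are configurable.
* **Site effects**, in a fixed documented order: per-tissue contrast
  multipliers (weighted by partial volumes) -> rescale brain intensities
  to [0,1] by the brain max -> gamma -> rescale back -> smooth unit-mean
  multiplicative bias field -> global scale -> additive Gaussian noise
  inside the mask. Background stays exactly zero, identity stages are
  skipped (so the identity configuration is bit-exact), and with zero
  noise the whole map is invertible given the configuration
  (`invert_site_effect()`, round-trip within 1e-6 relative).
* **Traveling subjects.** Paired cohorts sharing anatomy and differing
  only in site effect and noise realization, mirroring participants
  scanned at two sites.

What the simulator does *not* emulate: cortical folding, lesions,
k-space/acquisition physics, registration error. Tests passing on
phantoms therefore demonstrate that the machinery is correct and that
the training dynamics behave, not that harmonization quality transfers
to any particular real dataset; the default site-effect presets are
illustrative, not calibrated to real scanners.

## The evaluation suite

Per image: GM/WM/CSF volume fractions (normalized by intracranial
volume); cjv; EFC (normalized so a constant image scores 1); per-tissue
SNR $\mu/(\sigma\sqrt{n/(n-1)})$; wm2max (WM median over brain P95,
linear-interpolation percentiles); rPVE per tissue; and a
first-difference FWHM estimate (geometric mean over axes). Tissue
statistics are partial-volume-weighted by default, with a 0.5-threshold
mode for parity with hard segmentations; which convention the upstream
analysis used is unknowable, so both are provided. For the FWHM
estimator, axes whose first differences exhaust the intensity variance
(white noise) are floored at a sub-voxel smoothness rather than
discarded — discarding would randomly invalidate unsmoothed images.

Radiomics: 18 first-order features per region (GM, WM; 36 total),
pinned in `radiomic_feature_names()` — the standard first-order set
minus the standard deviation, which the common reference tool disables
by default as redundant with variance. Entropy and uniformity use
fixed-bin-width discretization (width 25, on the median-500 scale).
PCA projection standard-scales features and reports the top-2 axes with
variance explained.

Between sites: Euclidean distance between site-averaged histograms; the
multisite heterogeneity index (the sum over the 100 bins of the
across-site sample SD of mean counts, n-1 denominator). For traveling
pairs: 3D SSIM with a fixed intensity range of 1000, a uniform $7^3$
window, sample-covariance normalization, after cropping both volumes to
their joint nonzero bounding box (background-slice removal); the
implementation matches an independent reference implementation to 1e-6
on a frozen fixture. Brain-age error statistics (MAE, MPAD, TMD) are
provided as pure definitions; the CNN age predictor itself is out of
scope.

A simple fallback segmentation (k-means over brain intensities with
deterministic quantile initialization, clusters ordered CSF < GM < WM)
stands in when no tissue maps accompany a volume; it is a stand-in for a
proper segmenter, not a replacement.

## Numerical choices and degenerate inputs

* Median of an even count uses the midpoint-of-two convention;
  percentiles interpolate linearly (the R type-7 default) — documented
  because `wm2max` depends on it.
* `normalize_median` refuses all-zero brains; `pad_crop` refuses to crop
  brain voxels; undefined metrics (equal GM/WM means for cjv, zero
  within-tissue SD for SNR) raise errors, which `iqm_set()` converts to
  `NA` so one degenerate metric does not void a report row.
* Histograms are half-open `[lo, hi)` per bin with the last bin closed.
* Weight initialization is N(0, 0.02); normalization gains start at 1,
  offsets at 0.
* `sub-seeds` for cohorts and runs are drawn from one master seed and
  kept below 2^31.

## Scale of the shipped experiments

The package's tests and examples run at desk scale on one CPU: phantoms
of 48^3 voxels (192^3 in production use), cohorts of 8-20 subjects per
site, identity pretraining of ~400 steps (learning rate 1e-3) and ~300
adversarial steps. Unit tests exercise a 2-stage, base-8 generator; the
end-to-end demonstrations use a 3-stage, base-8 generator with a
base-4-to-8 discriminator and generator/discriminator learning rates of
2e-3 / 1e-3 — at a few hundred steps the deeper generator is what it
takes to express the nonlinear gamma/contrast remapping between the
site presets, and the conventional 2e-4 schedule (tuned for runs three
orders of magnitude longer) barely moves the networks. These sizes and
rates are the package's chosen demonstration conditions; the same code
paths scale to full-size volumes by changing the configuration. At this
scale a full two-site experiment (simulate, pretrain, train, harmonize,
evaluate) completes in about ten minutes.

## Known limitations

* Batch-1 CycleGAN training at a few hundred steps is enough to
  demonstrate direction and machinery on phantoms, not to saturate
  harmonization quality.
* The reference-site asymmetry (reference images are never modified at
  inference) means harmonization quality is only as good as the
  A-to-reference generator; no symmetric averaging is attempted.
* No second-order radiomics, no hypothesis testing, no human radiologic
  scoring, no 2D/2.5D baselines.
* Checkpoints serialize with R's native format; they are runtime
  artifacts, not exchange files.
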