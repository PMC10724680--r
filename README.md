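# mriharm

Inter-site harmonization of 3D T1-weighted brain MRI with a
whole-volume cycle-consistent adversarial network, for neuroimaging
studies that pool scans from several scanners. Images acquired on
different hardware or with different protocols carry systematic,
non-biological intensity differences (global brightness, GM/WM
contrast, bias fields, noise) that confound pooled analyses; `mriharm`
learns an unpaired image-to-image translation that moves every
non-reference site's volumes into the intensity domain of a reference
site while preserving subject anatomy.

The model is a 3D CycleGAN: U-net generators built from stride-2
`4x4x4` convolutions only, patchGAN discriminators with a `38^3`
receptive field, instance normalization that divides by the **mean
absolute deviation** rather than the SD, generation **masked** by the
input brain mask, and a final activation that clamps negatives and is
linear above zero. Training uses identity pretraining, a cycle weight
decaying linearly 200 -> 100, a 50-image history buffer for the
discriminators, and 4-real / 2-new-fake / 2-history-fake discriminator
batches at generator batch size 1. The losses are least-squares
adversarial plus L1 cycle consistency:

    L = E[(D_B(G_AB(a)) - 1)^2] + E[(D_A(G_BA(b)) - 1)^2]
        + lambda(step) * ( |G_BA(G_AB(a)) - a|_1 + |G_AB(G_BA(b)) - b|_1 )

Because no external brain-MRI dataset can ship with a package, a
synthetic phantom simulator provides the study material: nested
deformed-ellipsoid anatomy (WM/GM/CSF), a linear age-dependent GM
atrophy line, parameterized site effects (contrast, gamma, bias field,
scale, noise), and paired traveling-subject cohorts. An evaluation
suite measures site effects before and after harmonization: brain
intensity histograms (100 bins, 0-900), tissue volume fractions,
MRIQC-style image quality metrics (cjv, EFC, SNR, wm2max, rPVE, FWHM),
36 first-order radiomic features with PCA, a multisite heterogeneity
index, 3D SSIM for traveling pairs, and brain-age error statistics
(MAE / MPAD / TMD).

The conv stack, backward passes and optimizer are implemented in the
package (Rcpp kernels + BLAS); every backward pass is verified against
finite differences in the test suite. See
`vignettes/harmonization-methods.Rmd` for the model, its assumptions
and all numerical choices.

## Worked example

A complete two-site experiment at desk scale (48^3 phantoms, reduced
channel widths — production use swaps in 192^3 and wider nets):

```r
library(mriharm)

cfgs  <- preset_site_configs()              # two illustrative scanners
seeds <- 1:6

norm <- function(co) { co$phantoms <- lapply(co$phantoms, function(ph) {
  ph$volume <- pad_crop(normalize_median(ph$volume), 48L); ph }); co }

coA <- norm(generate_cohort(20, 20, 80, cfgs$siteA, 48, seeds[1], "siteA"))
coB <- norm(generate_cohort(20, 20, 80, cfgs$siteB, 48, seeds[2], "siteB"))

gen0 <- build_generator(generator_spec(depth = 3, base_channels = 8))
pre  <- pretrain_identity(gen0,
          lapply(c(coA$phantoms, coB$phantoms), `[[`, "volume"),
          steps = 400, learning_rate = 1e-3, seed = seeds[4])

fit <- train_cyclegan(coA, coB,
         training_config(total_steps = 300, seed = seeds[6],
                         learning_rate = 2e-3, disc_learning_rate = 1e-3),
         gen_spec  = generator_spec(depth = 3, base_channels = 8),
         disc_spec = discriminator_spec(layers = list(c(4,2,8), c(4,2,16),
                                                      c(4,2,32), c(3,1,1))),
         init_gen = pre$gen)

histB  <- average_histograms(lapply(coB$phantoms, \(p) brain_histogram(p$volume)))
histA  <- average_histograms(lapply(coA$phantoms, \(p) brain_histogram(p$volume)))
harmA  <- lapply(coA$phantoms, \(p) harmonize_volume(fit$G_AB, p$volume))
histAh <- average_histograms(lapply(harmA, brain_histogram))

histogram_distance(histA,  histB)   # site distance before harmonization
histogram_distance(histAh, histB)   # ... and after
```

This configuration prints a pre-harmonization site-averaged histogram
distance of `3738.194` dropping to `1550.15` after harmonization (41%
of the original distance), and on eight traveling-subject pairs the
mean SSIM against the true site-B version rises from `0.8963` without
harmonization to `0.9456` with it. The end-to-end blocks in
`tests/testthat/test-acceptance.R` run the same experiment (under their
own derived seeds) and additionally check that the GM-fraction-age
correlation survives harmonization.

The same pipeline is scriptable from a shell via `inst/cli/mriharm.R`
(`simulate`, `preprocess`, `train`, `harmonize`, `evaluate`
subcommands), writing NIfTI cohorts, CSV metrics/loss traces and JSON
manifests with checksums.

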