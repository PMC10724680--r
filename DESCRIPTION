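Package: mriharm
Title: Inter-Site Harmonization of 3D Brain MRI with Cycle-Consistent
    Adversarial Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for removing scanner- and site-related intensity
    variability from pooled T1-weighted brain MRI studies. Implements a
    whole-volume 3D CycleGAN (U-net generators built from strided
    convolutions only, patchGAN discriminators, mean-absolute-deviation
    instance normalization, masked generation, a non-negative final
    activation), the training protocol (identity pretraining, linearly
    decaying cycle-consistency weight, generated-image history buffer,
    mixed real/fake discriminator batches, age-balanced sampling), a
    synthetic multi-site brain phantom simulator with parameterized site
    effects and traveling-subject pairs, and a site-effect evaluation
    suite (brain intensity histograms, tissue volume fractions,
    MRIQC-style image quality metrics, first-order radiomics with PCA,
    3D SSIM, brain-age error statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
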