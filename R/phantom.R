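# Synthetic multi-site brain phantom simulator.
#
# Phantoms are nested deformed ellipsoids — a WM core, a GM shell and a CSF
# rim — with smooth per-subject radial perturbations, an age-dependent
# linear decline of the GM volume fraction (GM-to-CSF conversion; intensity
# means are age-independent), and partial volumes obtained by smoothing the
# hard tissue labels with a small Gaussian. Site effects compose per-tissue
# contrast change, gamma distortion, a smooth multiplicative bias field,
# global intensity scaling and additive noise, all confined to the brain
# mask.

#' Site-effect configuration
#'
#' Parameterizes a simulated scanner/site effect. The identity
#' configuration leaves any volume bit-for-bit unchanged.
#'
#' @param scale global multiplicative intensity factor (> 0).
#' @param gamma exponent applied to brain intensities rescaled to `[0, 1]`
#'   by the brain maximum (> 0).
#' @param bias_amplitude peak fractional deviation of the smooth
#'   multiplicative bias field (>= 0).
#' @param bias_smoothness correlation length of the bias field in voxels
#'   (> 0).
#' @param noise_sd additive Gaussian noise SD inside the mask, intensity
#'   units (>= 0).
#' @param contrast per-tissue mean multipliers, order (CSF, GM, WM).
#' @return an object of class `site_effect_config`.
#' @export
site_effect_config <- function(scale = 1, gamma = 1, bias_amplitude = 0,
                               bias_smoothness = 8, noise_sd = 0,
                               contrast = c(1, 1, 1)) {
  if (!is.numeric(scale) || scale <= 0) stop("scale must be > 0")
  if (!is.numeric(gamma) || gamma <= 0) stop("gamma must be > 0")
  if (bias_amplitude < 0) stop("bias_amplitude must be >= 0")
  if (bias_smoothness <= 0) stop("bias_smoothness must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(contrast) != 3L || any(contrast <= 0))
    stop("contrast must be three positive factors (CSF, GM, WM)")
  structure(list(scale = scale, gamma = gamma,
                 bias_amplitude = bias_amplitude,
                 bias_smoothness = bias_smoothness, noise_sd = noise_sd,
                 contrast = as.numeric(contrast)),
            class = "site_effect_config")
}

is_identity_config <- function(cfg) {
  cfg$scale == 1 && cfg$gamma == 1 && cfg$bias_amplitude == 0 &&
    cfg$noise_sd == 0 && all(cfg$contrast == 1)
}

#' Illustrative site-effect presets
#'
#' Two contrasting scanner profiles used by the demos and the end-to-end
#' tests: `siteA` is a near-neutral scanner with mild noise; `siteB` is
#' brighter, with higher GM/WM contrast, a stronger bias field and more
#' noise. These are illustrative, not calibrated to any real scanner.
#'
#' @return named list of [site_effect_config()] objects.
#' @export
preset_site_configs <- function() {
  list(
    siteA = site_effect_config(scale = 1.0, gamma = 1.0,
                               bias_amplitude = 0.05, bias_smoothness = 10,
                               noise_sd = 10, contrast = c(1, 1, 1)),
    siteB = site_effect_config(scale = 1.25, gamma = 1.3,
                               bias_amplitude = 0.10, bias_smoothness = 8,
                               noise_sd = 14, contrast = c(0.9, 1.05, 1.1))
  )
}

#' Read/write site-effect configs as flat key-value files
#' @param cfg a [site_effect_config()].
#' @param path file path.
#' @return `read_site_effect_config` returns a [site_effect_config()].
#' @export
write_site_effect_config <- function(cfg, path) {
  write_flat_config(unclass(cfg), path)
}

#' @rdname write_site_effect_config
#' @export
read_site_effect_config <- function(path) {
  x <- read_flat_config(path)
  do.call(site_effect_config, x)
}

# Default anatomical and atrophy parameters of the simulator. The GM
# fraction follows gm0 - atrophy_slope * age; WM is age-constant and CSF
# absorbs the GM loss. Intensity means sit on the median-500 scale.
phantom_defaults <- function() {
  list(wm_frac = 0.35, gm0 = 0.48, atrophy_slope = 0.0015,
       tissue_means = c(csf = 150, gm = 400, wm = 600),
       intensity_jitter = 0.03, frac_jitter_sd = 0.005,
       shape_amplitude = 0.04, pv_sigma = 0.7,
       radius_frac = c(0.88, 0.84, 0.80))
}

#' Closed-form atrophy line of the simulator
#'
#' The expected GM volume fraction at a given age under the generator's
#' defaults (before per-subject jitter): a constant linear fall throughout
#' adulthood.
#'
#' @param age years.
#' @param gm0 GM fraction extrapolated to age 0.
#' @param atrophy_slope GM fraction lost per year.
#' @return expected GM fraction.
#' @export
atrophy_line <- function(age, gm0 = phantom_defaults()$gm0,
                         atrophy_slope = phantom_defaults()$atrophy_slope) {
  gm0 - atrophy_slope * age
}

#' Generate a synthetic brain phantom
#'
#' @param age subject age in years (0 < age < 120).
#' @param size grid edge in voxels (>= 32; smaller grids cannot host the
#'   three nested tissue shells).
#' @param seed integer; the phantom is a pure function of
#'   `(age, size, seed)` and the override parameters.
#' @param spacing voxel spacing in mm.
#' @param pv_sigma Gaussian width (voxels) used to soften hard tissue
#'   labels into partial-volume maps; `0` keeps hard labels.
#' @param params overrides for the simulator defaults (see
#'   `mriharm:::phantom_defaults`).
#' @return an object of class `phantom` with fields `volume` (a
#'   [volume()]), `segmentation` (class `tissue_segmentation`: partial
#'   volume arrays `csf`, `gm`, `wm`), `age`, `subject_id`, `seed`.
#' @export
generate_phantom <- function(age, size, seed, spacing = c(1, 1, 1),
                             pv_sigma = phantom_defaults()$pv_sigma,
                             params = list()) {
  if (!is.numeric(age) || age <= 0 || age >= 120)
    stop("age must be in (0, 120)")
  if (size < 32L)
    stop("size too small to host three nested tissue shells (need >= 32)")
  pd <- utils::modifyList(phantom_defaults(), params)
  pd$pv_sigma <- pv_sigma
  size <- as.integer(size)

  draws <- with_seed(seed, {
    list(frac_jitter = stats::rnorm(1, 0, pd$frac_jitter_sd),
         mu = pd$tissue_means * exp(stats::rnorm(3, 0, pd$intensity_jitter)),
         noise = array(stats::rnorm(size^3), dim = rep(size, 3)))
  })
  shape <- gaussian_smooth3(draws$noise, size / 10)
  shape <- shape / max(abs(shape)) * pd$shape_amplitude

  gm_frac <- pd$gm0 - pd$atrophy_slope * age + draws$frac_jitter
  wm_frac <- pd$wm_frac
  if (gm_frac <= 0.05 || gm_frac + wm_frac >= 0.98)
    stop("atrophy parameters give a degenerate tissue composition")
  r_wm <- wm_frac^(1 / 3)
  r_gm <- (wm_frac + gm_frac)^(1 / 3)

  ctr <- (size + 1) / 2
  ax <- (seq_len(size) - ctr)
  R <- pd$radius_frac * size / 2
  rho2 <- outer(outer((ax / R[1])^2, (ax / R[2])^2, `+`), (ax / R[3])^2, `+`)
  u <- sqrt(rho2) * (1 + shape)

  mask <- array(as.numeric(u <= 1), dim = rep(size, 3))
  lab_wm <- array(as.numeric(u <= r_wm), dim = rep(size, 3))
  lab_gm <- array(as.numeric(u > r_wm & u <= r_gm), dim = rep(size, 3))
  lab_csf <- mask - lab_wm - lab_gm

  if (pd$pv_sigma > 0) {
    pv <- lapply(list(csf = lab_csf, gm = lab_gm, wm = lab_wm),
                 gaussian_smooth3, sigma = pd$pv_sigma)
    tot <- pv$csf + pv$gm + pv$wm
    tot[tot == 0] <- 1
    pv <- lapply(pv, function(a) a * mask / tot)
  } else {
    pv <- list(csf = lab_csf, gm = lab_gm, wm = lab_wm)
  }

  intens <- pv$csf * draws$mu[["csf"]] + pv$gm * draws$mu[["gm"]] +
    pv$wm * draws$mu[["wm"]]
  seg <- structure(pv, class = "tissue_segmentation")
  structure(list(volume = volume(intens, mask = mask, spacing = spacing),
                 segmentation = seg, age = age,
                 subject_id = sprintf("sub-%010d", as.integer(seed)),
                 seed = seed),
            class = "phantom")
}

#' Tissue volume of a segmentation (bookkeeping helper)
#' @param seg a `tissue_segmentation`.
#' @return named vector of summed partial volumes (voxel counts).
#' @export
segmentation_volumes <- function(seg) {
  vapply(seg[c("gm", "wm", "csf")], sum, numeric(1))
}

#' Apply a simulated site effect to a volume
#'
#' Transform order (fixed): per-tissue contrast multipliers weighted by the
#' partial volumes; rescale brain intensities to `[0, 1]` by the brain
#' maximum; gamma; rescale back; multiplicative unit-mean smooth bias
#' field; global scale; additive Gaussian noise inside the mask. Background
#' voxels stay exactly zero, and identity stages are skipped so the
#' identity configuration returns the input unchanged.
#'
#' @param vol a [volume()] with a nonempty mask.
#' @param seg aligned `tissue_segmentation` partial-volume maps.
#' @param cfg a [site_effect_config()].
#' @param seed seed for the noise realization.
#' @param bias_seed seed for the bias field (defaults to `seed`; fix it
#'   across a cohort to model a scanner-specific field).
#' @return a [volume()].
#' @export
apply_site_effect <- function(vol, seg, cfg, seed, bias_seed = seed) {
  stopifnot(inherits(cfg, "site_effect_config"))
  if (is.null(vol$mask) || !any(vol$mask > 0))
    stop("apply_site_effect requires a nonempty brain mask")
  m <- vol$mask > 0
  v <- vol$data

  if (!all(cfg$contrast == 1)) {
    w <- seg$csf * cfg$contrast[1] + seg$gm * cfg$contrast[2] +
      seg$wm * cfg$contrast[3]
    v[m] <- v[m] * w[m]
  }
  if (cfg$gamma != 1) {
    bmax <- max(v[m])
    if (bmax > 0) v[m] <- bmax * (v[m] / bmax)^cfg$gamma
  }
  if (cfg$bias_amplitude > 0) {
    f <- bias_field(dim(v), cfg$bias_smoothness, cfg$bias_amplitude,
                    bias_seed, m)
    v[m] <- v[m] * f[m]
  }
  if (cfg$scale != 1) v[m] <- v[m] * cfg$scale
  if (cfg$noise_sd > 0) {
    nz <- with_seed(seed, stats::rnorm(sum(m), 0, cfg$noise_sd))
    v[m] <- v[m] + nz
  }
  v[!m] <- 0
  volume(v, mask = vol$mask, spacing = vol$spacing, affine = vol$affine)
}

# Smooth multiplicative field: seeded low-frequency Gaussian random field,
# peak fractional deviation = amplitude, normalized to unit mean over mask.
bias_field <- function(dims, smoothness, amplitude, seed, mask) {
  g <- with_seed(seed, array(stats::rnorm(prod(dims)), dim = dims))
  g <- gaussian_smooth3(g, smoothness)
  g <- g / max(abs(g[mask]))
  f <- 1 + amplitude * g
  f / mean(f[mask])
}

#' Invert a noiseless site effect
#'
#' For configurations with `noise_sd = 0` the site-effect map is a monotone
#' intensity transform composed with strictly positive fields, hence
#' invertible on brain voxels given the configuration and the bias seed.
#'
#' @inheritParams apply_site_effect
#' @param bias_seed the bias seed used when the effect was applied.
#' @return a [volume()] recovering the pre-site-effect input (up to noise).
#' @export
invert_site_effect <- function(vol, seg, cfg, bias_seed) {
  m <- vol$mask > 0
  v <- vol$data
  if (cfg$scale != 1) v[m] <- v[m] / cfg$scale
  if (cfg$bias_amplitude > 0) {
    f <- bias_field(dim(v), cfg$bias_smoothness, cfg$bias_amplitude,
                    bias_seed, m)
    v[m] <- v[m] / f[m]
  }
  if (cfg$gamma != 1) {
    bmax <- max(v[m])
    if (bmax > 0) v[m] <- bmax * (v[m] / bmax)^(1 / cfg$gamma)
  }
  if (!all(cfg$contrast == 1)) {
    w <- seg$csf * cfg$contrast[1] + seg$gm * cfg$contrast[2] +
      seg$wm * cfg$contrast[3]
    v[m] <- v[m] / w[m]
  }
  v[!m] <- 0
  volume(v, mask = vol$mask, spacing = vol$spacing, affine = vol$affine)
}

#' Generate a single-site cohort of phantoms
#'
#' Ages are drawn uniformly on `[age_low, age_high]` (or from a supplied
#' sampler); each phantom keeps its pre-site-effect ground truth under
#' `$truth` for later supervised checks. The bias field realization is
#' shared across the cohort (a scanner property); noise is per subject.
#'
#' @param n cohort size (>= 1).
#' @param age_low,age_high age range in years.
#' @param cfg a [site_effect_config()].
#' @param size grid edge in voxels.
#' @param seed master seed; the whole cohort is reproducible from it.
#' @param site_label site name recorded in the cohort.
#' @param age_sampler optional `function(n)` drawing ages.
#' @param ... passed to [generate_phantom()].
#' @return an object of class `cohort`: a list with `phantoms` (each a
#'   `phantom` whose `volume` is the observed post-site-effect image, plus
#'   `$truth`), `site_label` and `ages`.
#' @export
generate_cohort <- function(n, age_low = 20, age_high = 80, cfg, size, seed,
                            site_label = "site", age_sampler = NULL, ...) {
  stopifnot(n >= 1, age_low < age_high)
  draws <- with_seed(seed, {
    ages <- if (is.null(age_sampler)) stats::runif(n, age_low, age_high)
            else age_sampler(n)
    list(ages = ages,
         sub_seeds = sample.int(.Machine$integer.max - 1L, n),
         noise_seeds = sample.int(.Machine$integer.max - 1L, n),
         bias_seed = sample.int(.Machine$integer.max - 1L, 1L))
  })
  phantoms <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- generate_phantom(draws$ages[i], size, draws$sub_seeds[i], ...)
    obs <- apply_site_effect(ph$volume, ph$segmentation, cfg,
                             seed = draws$noise_seeds[i],
                             bias_seed = draws$bias_seed)
    ph$truth <- ph$volume
    ph$volume <- obs
    phantoms[[i]] <- ph
  }
  structure(list(phantoms = phantoms, site_label = site_label,
                 ages = draws$ages), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> site ", x$site_label, ", n = ", length(x$phantoms),
      ", ages ", round(min(x$ages), 1), "-", round(max(x$ages), 1),
      " y\n", sep = "")
  invisible(x)
}

#' Generate paired traveling-subject cohorts
#'
#' The i-th subjects of the two returned cohorts share the same underlying
#' phantom (same anatomy, same age) and differ only by site effect and
#' noise realization — the synthetic analogue of participants scanned at
#' two sites.
#'
#' @param n number of traveling subjects.
#' @param cfgA,cfgB site-effect configurations of the two sites.
#' @param size grid edge in voxels.
#' @param seed master seed.
#' @param age_low,age_high age range in years.
#' @param ... passed to [generate_phantom()].
#' @return list with cohorts `A` and `B`.
#' @export
generate_traveling_cohort <- function(n, cfgA, cfgB, size, seed,
                                      age_low = 20, age_high = 80, ...) {
  stopifnot(n >= 1)
  draws <- with_seed(seed, {
    list(ages = stats::runif(n, age_low, age_high),
         sub_seeds = sample.int(.Machine$integer.max - 1L, n),
         noiseA = sample.int(.Machine$integer.max - 1L, n),
         noiseB = sample.int(.Machine$integer.max - 1L, n),
         biasA = sample.int(.Machine$integer.max - 1L, 1L),
         biasB = sample.int(.Machine$integer.max - 1L, 1L))
  })
  phA <- vector("list", n)
  phB <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- generate_phantom(draws$ages[i], size, draws$sub_seeds[i], ...)
    mk <- function(cfg, nseed, bseed) {
      out <- ph
      out$truth <- ph$volume
      out$volume <- apply_site_effect(ph$volume, ph$segmentation, cfg,
                                      seed = nseed, bias_seed = bseed)
      out
    }
    phA[[i]] <- mk(cfgA, draws$noiseA[i], draws$biasA)
    phB[[i]] <- mk(cfgB, draws$noiseB[i], draws$biasB)
  }
  list(A = structure(list(phantoms = phA, site_label = "siteA",
                          ages = draws$ages), class = "cohort"),
       B = structure(list(phantoms = phB, site_label = "siteB",
                          ages = draws$ages), class = "cohort"))
}

#' Write / read a cohort as NIfTI files plus a subject table
#'
#' Each subject contributes the observed volume, its mask, the three
#' partial-volume maps and (optionally) the pre-site-effect ground truth;
#' a `subjects.csv` sidecar records `subject_id`, `age` and `site_label`.
#'
#' @param cohort a `cohort`.
#' @param dir output directory (created if missing).
#' @param truth also write the pre-site-effect volumes.
#' @return `dir`, invisibly; `read_cohort` returns a `cohort`.
#' @export
write_cohort <- function(cohort, dir, truth = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$phantoms, function(ph) {
    base <- file.path(dir, ph$subject_id)
    write_volume(ph$volume, paste0(base, ".nii.gz"))
    for (t in c("gm", "wm", "csf"))
      write_volume(volume(ph$segmentation[[t]], spacing = ph$volume$spacing),
                   paste0(base, "_pv_", t, ".nii.gz"))
    if (truth && !is.null(ph$truth))
      write_volume(ph$truth, paste0(base, "_truth.nii.gz"))
    data.frame(subject_id = ph$subject_id, age = ph$age,
               site_label = cohort$site_label, seed = ph$seed)
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  tab <- utils::read.csv(file.path(dir, "subjects.csv"),
                         stringsAsFactors = FALSE)
  phantoms <- lapply(seq_len(nrow(tab)), function(i) {
    base <- file.path(dir, tab$subject_id[i])
    vol <- read_volume(paste0(base, ".nii.gz"))
    seg <- lapply(c(csf = "csf", gm = "gm", wm = "wm"), function(t) {
      p <- paste0(base, "_pv_", t, ".nii.gz")
      if (file.exists(p)) read_volume(p)$data else NULL
    })
    seg <- structure(seg, class = "tissue_segmentation")
    tpath <- paste0(base, "_truth.nii.gz")
    structure(list(volume = vol, segmentation = seg, age = tab$age[i],
                   subject_id = tab$subject_id[i],
                   seed = if ("seed" %in% names(tab)) tab$seed[i] else NA,
                   truth = if (file.exists(tpath)) read_volume(tpath)),
              class = "phantom")
  })
  structure(list(phantoms = phantoms, site_label = tab$site_label[1],
                 ages = tab$age), class = "cohort")
}
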