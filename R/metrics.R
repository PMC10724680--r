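# Site-effect evaluation suite: tissue volume fractions, MRIQC-style image
# quality metrics, first-order radiomics with PCA, histogram distances and
# the multisite heterogeneity index, 3D SSIM for traveling pairs, and
# brain-age error statistics.

# Partial-volume-weighted moments within a tissue. mode = "hard" thresholds
# the map at 0.5 for parity with hard segmentations.
tissue_stats <- function(vol, seg, tissue, mode = c("pv", "hard")) {
  mode <- match.arg(mode)
  w <- seg[[tissue]]
  if (mode == "hard") w <- as.numeric(w >= 0.5)
  sw <- sum(w)
  if (sw == 0) stop("tissue region '", tissue, "' is empty")
  v <- vol$data
  mu <- sum(w * v) / sw
  sigma <- sqrt(sum(w * (v - mu)^2) / sw)
  list(mean = mu, sd = sigma, n = sw)
}

#' Tissue volume fractions
#'
#' GM, WM and CSF volumes normalized by the total intracranial volume
#' (the summed partial volumes of the three tissues).
#'
#' @param seg a `tissue_segmentation` (fields `gm`, `wm`, `csf`).
#' @return named numeric vector `(icv_gm, icv_wm, icv_csf)`, summing to 1.
#' @export
tissue_volume_fractions <- function(seg) {
  s <- c(icv_gm = sum(seg$gm), icv_wm = sum(seg$wm), icv_csf = sum(seg$csf))
  tot <- sum(s)
  if (tot <= 0) stop("degenerate input: all partial-volume maps are zero")
  s / tot
}

#' Coefficient of joint variation of GM and WM
#'
#' `(sd_WM + sd_GM) / |mean_WM - mean_GM|` with partial-volume-weighted
#' means and SDs. Lower values indicate better GM/WM separability; the
#' metric is invariant to global intensity rescaling.
#'
#' @param vol a [volume()].
#' @param seg aligned `tissue_segmentation`.
#' @param mode `"pv"` (partial-volume weights) or `"hard"` (threshold 0.5).
#' @return scalar.
#' @export
cjv <- function(vol, seg, mode = "pv") {
  g <- tissue_stats(vol, seg, "gm", mode)
  w <- tissue_stats(vol, seg, "wm", mode)
  if (w$mean == g$mean) stop("undefined metric: equal GM and WM means")
  (w$sd + g$sd) / abs(w$mean - g$mean)
}

#' Entropy focus criterion
#'
#' Shannon entropy of voxel intensities normalized by the maximum-entropy
#' value for the grid, so the result lies in `[0, 1]`: with
#' `x_max = sqrt(sum(x^2))`, `E = -sum((x/x_max) * ln(x/x_max))`, divided
#' by `sqrt(N) * ln(sqrt(N))`. A constant image scores 1, a single bright
#' voxel 0; ghosting and blur move real images upward.
#'
#' @param vol a [volume()] (all grid voxels enter the sum).
#' @return scalar in `[0, 1]`.
#' @export
efc <- function(vol) {
  x <- abs(as.numeric(vol$data))
  n <- length(x)
  xmax <- sqrt(sum(x^2))
  if (xmax == 0) stop("degenerate input: all-zero image")
  r <- x / xmax
  e <- -sum(r[r > 0] * log(r[r > 0]))
  emax <- sqrt(n) * log(sqrt(n))
  e / emax
}

#' Within-tissue signal-to-noise ratio
#'
#' `mean / (sd * sqrt(n / (n - 1)))` with partial-volume-weighted mean and
#' SD inside the tissue (`n` = summed weights).
#'
#' @inheritParams cjv
#' @param tissue one of `"gm"`, `"wm"`, `"csf"`.
#' @return scalar; errors when the within-tissue SD is zero.
#' @export
snr_tissue <- function(vol, seg, tissue, mode = "pv") {
  st <- tissue_stats(vol, seg, tissue, mode)
  if (st$sd == 0) stop("undefined metric: zero within-tissue SD")
  st$mean / (st$sd * sqrt(st$n / (st$n - 1)))
}

weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1]]
}

#' WM-median to brain-P95 ratio
#'
#' Ratio between the WM median intensity and the 95th percentile of the
#' full brain intensity distribution (linear-interpolation percentile).
#'
#' @inheritParams cjv
#' @return scalar.
#' @export
wm2max <- function(vol, seg, mode = "pv") {
  w <- seg$wm
  if (mode == "hard") w <- as.numeric(w >= 0.5)
  if (sum(w) == 0) stop("degenerate input: empty WM region")
  med <- weighted_median(vol$data[w > 0], w[w > 0])
  p95 <- stats::quantile(brain_values(vol), 0.95, names = FALSE, type = 7)
  med / p95
}

#' Residual partial volume effect
#'
#' `100 * sum(f(p)) / sum(p)` over the tissue's partial-volume map, with
#' `f(p) = p` for `0 < p <= 0.5`, `1 - p` for `0.5 < p < 1`, and 0 for
#' exact 0/1: the share of the tissue volume carried by ambiguous voxels.
#'
#' @param seg a `tissue_segmentation`.
#' @param tissue one of `"gm"`, `"wm"`, `"csf"`.
#' @return percentage in `[0, 100]`.
#' @export
rpve <- function(seg, tissue) {
  p <- as.numeric(seg[[tissue]])
  tot <- sum(p)
  if (tot == 0) stop("degenerate input: all-zero partial-volume map")
  f <- numeric(length(p))
  lowr <- p > 0 & p <= 0.5
  uppr <- p > 0.5 & p < 1
  f[lowr] <- p[lowr]
  f[uppr] <- 1 - p[uppr]
  100 * sum(f) / tot
}

#' Image smoothness (FWHM) estimate
#'
#' Classic first-difference smoothness estimator. Per axis, with `s2` the
#' brain-voxel intensity variance and `sd2` the variance of first
#' differences between neighboring in-mask voxels along that axis:
#' `FWHM_axis = spacing * sqrt(-2 log(2) / log(1 - sd2 / (2 * s2)))`.
#' For unsmoothed (or anti-correlated) noise the log argument falls to or
#' below zero, meaning smoothness below one voxel: such axes are floored at
#' a small positive argument rather than discarded, so white noise yields a
#' sub-voxel estimate. Axes that are degenerate (zero variance, argument
#' >= 1, or too few in-mask pairs) are excluded with a warning; the result
#' is the geometric mean of the valid axes.
#'
#' @param vol a [volume()] with a mask spanning at least 2 voxels per axis.
#' @return FWHM in mm.
#' @export
fwhm_estimate <- function(vol) {
  m <- vol$mask > 0
  v <- vol$data
  s2 <- stats::var(v[m])
  per_axis <- vapply(1:3, function(ax) {
    d <- dim(v)
    n <- d[ax]
    if (n < 2L) return(NA_real_)
    i1 <- lapply(d, seq_len); i1[[ax]] <- seq_len(n - 1L)
    i2 <- lapply(d, seq_len); i2[[ax]] <- seq_len(n - 1L) + 1L
    a <- do.call(`[`, c(list(v), i1))
    b <- do.call(`[`, c(list(v), i2))
    ok <- do.call(`[`, c(list(m), i1)) & do.call(`[`, c(list(m), i2))
    if (sum(ok) < 2L) return(NA_real_)
    sd2 <- stats::var((b - a)[ok])
    arg <- 1 - sd2 / (2 * s2)
    if (!is.finite(arg) || arg >= 1) return(NA_real_)
    arg <- max(arg, 1e-3)          # sub-voxel smoothness floor
    vol$spacing[ax] * sqrt(-2 * log(2) / log(arg))
  }, numeric(1))
  bad <- is.na(per_axis)
  if (any(bad))
    warning("FWHM undefined along axis ", paste(which(bad), collapse = ", "))
  if (sum(!bad) < 2L)
    stop("undefined metric: fewer than 2 valid axes for FWHM")
  exp(mean(log(per_axis[!bad])))
}

#' Pinned first-order radiomic feature list
#' @return character vector of the 18 feature names, in order.
#' @export
radiomic_feature_names <- function() {
  c("energy", "total_energy", "entropy", "minimum", "p10", "p90",
    "maximum", "mean", "median", "iqr", "range", "mad", "rmad", "rms",
    "skewness", "kurtosis", "variance", "uniformity")
}

#' First-order radiomic features of a region
#'
#' The standard first-order set over the intensities of a region of
#' interest; entropy and uniformity use fixed-bin-width discretization
#' (default width 25, bin edges aligned to multiples of the width).
#' Skewness (`m3/m2^1.5`) and kurtosis (`m4/m2^2`, normal = 3) use
#' population moments and are reported as 0 for constant regions.
#'
#' @param vol a [volume()].
#' @param region_mask logical/0-1 array selecting the region.
#' @param bin_width discretization width for entropy/uniformity.
#' @return named numeric vector of the 18 features in
#'   [radiomic_feature_names()] order.
#' @export
first_order_radiomics <- function(vol, region_mask, bin_width = 25) {
  x <- vol$data[region_mask > 0]
  if (!length(x)) stop("degenerate input: empty region")
  vox_vol <- prod(vol$spacing)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  q <- stats::quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  sub <- x[x >= q[1] & x <= q[4]]
  edges <- seq(floor(min(x) / bin_width) * bin_width,
               max(x) + bin_width, by = bin_width)
  p <- tabulate(findInterval(x, edges), nbins = length(edges) - 1L)
  p <- p[p > 0] / length(x)
  c(energy = sum(x^2),
    total_energy = vox_vol * sum(x^2),
    entropy = -sum(p * log2(p)),
    minimum = min(x),
    p10 = q[1], p90 = q[4],
    maximum = max(x),
    mean = mu,
    median = stats::median(x),
    iqr = q[3] - q[2],
    range = max(x) - min(x),
    mad = mean(abs(x - mu)),
    rmad = if (length(sub)) mean(abs(sub - mean(sub))) else 0,
    rms = sqrt(mean(x^2)),
    skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    variance = m2,
    uniformity = sum(p^2))
}

#' 36-feature radiomic profile (GM + WM)
#'
#' The 18 first-order features over the GM region followed by the same 18
#' over WM (regions thresholded at partial volume >= 0.5), names prefixed
#' `gm_` / `wm_`.
#'
#' @inheritParams first_order_radiomics
#' @param seg a `tissue_segmentation`.
#' @return named numeric vector of length 36.
#' @export
radiomic_profile <- function(vol, seg, bin_width = 25) {
  g <- first_order_radiomics(vol, seg$gm >= 0.5, bin_width)
  w <- first_order_radiomics(vol, seg$wm >= 0.5, bin_width)
  stats::setNames(c(g, w), c(paste0("gm_", names(g)), paste0("wm_", names(w))))
}

#' PCA projection of radiomic feature matrices
#'
#' Standard-scales every feature column (constant columns are dropped with
#' a warning) and projects onto the top two principal axes.
#'
#' @param features numeric matrix, one row per image, one column per
#'   feature (>= 3 rows).
#' @return list with `coords` (n x 2 matrix) and `variance_explained`
#'   (length-2 vector, fractions of the retained variance).
#' @export
pca_project <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 3L) stop("pca_project needs at least 3 samples")
  sds <- apply(features, 2L, stats::sd)
  keep <- sds > 0
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " constant feature column(s)")
    features <- features[, keep, drop = FALSE]
  }
  z <- scale(features)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(2L, ncol(pc$x))
  coords <- pc$x[, seq_len(k), drop = FALSE]
  if (k < 2L) coords <- cbind(coords, 0)
  list(coords = coords, variance_explained = c(ve, 0)[1:2])
}

cumsum_axis <- function(a, ax) {
  d <- dim(a)
  perm <- c(ax, setdiff(1:3, ax))
  m <- matrix(aperm(a, perm), nrow = d[ax])
  m <- apply(m, 2L, cumsum)
  aperm(array(m, dim = d[perm]), order(perm))
}

# Valid-window box sums via an integral volume (inclusion-exclusion).
box_sum_valid <- function(a, w) {
  d <- dim(a)
  s <- cumsum_axis(cumsum_axis(cumsum_axis(a, 1L), 2L), 3L)
  pad <- array(0, dim = d + 1L)
  pad[-1, -1, -1] <- s
  n <- d - w + 1L
  hi <- lapply(1:3, function(ax) seq_len(n[ax]) + w)
  lo <- lapply(1:3, function(ax) seq_len(n[ax]))
  pad[hi[[1]], hi[[2]], hi[[3]]] - pad[lo[[1]], hi[[2]], hi[[3]]] -
    pad[hi[[1]], lo[[2]], hi[[3]]] - pad[hi[[1]], hi[[2]], lo[[3]]] +
    pad[lo[[1]], lo[[2]], hi[[3]]] + pad[lo[[1]], hi[[2]], lo[[3]]] +
    pad[hi[[1]], lo[[2]], lo[[3]]] - pad[lo[[1]], lo[[2]], lo[[3]]]
}

#' Structural similarity of two volumes
#'
#' Mean local SSIM over all fully interior windows (uniform `window^3`
#' kernel), with constants `C1 = (0.01 * data_range)^2` and
#' `C2 = (0.03 * data_range)^2` and sample-covariance normalization
#' `N/(N-1)`. Before comparison both volumes are cropped to their joint
#' nonzero bounding box per axis, removing background slices.
#'
#' @param a,b [volume()]s or 3D arrays with identical dimensions.
#' @param data_range fixed intensity range (default 1000).
#' @param window cubic window edge (odd).
#' @param crop_background crop to the joint nonzero bounding box first.
#' @return scalar SSIM.
#' @export
ssim3d <- function(a, b, data_range = 1000, window = 7L,
                   crop_background = TRUE) {
  av <- if (inherits(a, "volume")) a$data else a
  bv <- if (inherits(b, "volume")) b$data else b
  if (!identical(dim(av), dim(bv))) stop("volumes have mismatched dimensions")
  if (crop_background) {
    nz <- (av != 0) | (bv != 0)
    if (!any(nz)) stop("both volumes are identically zero")
    idx <- which(nz, arr.ind = TRUE)
    rng <- lapply(1:3, function(ax) seq(min(idx[, ax]), max(idx[, ax])))
    av <- av[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    bv <- bv[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  }
  if (any(dim(av) < window))
    stop("volume smaller than the SSIM window after background removal")
  nw <- window^3
  ux <- box_sum_valid(av, window) / nw
  uy <- box_sum_valid(bv, window) / nw
  uxx <- box_sum_valid(av * av, window) / nw
  uyy <- box_sum_valid(bv * bv, window) / nw
  uxy <- box_sum_valid(av * bv, window) / nw
  cn <- nw / (nw - 1)
  vx <- cn * (uxx - ux * ux)
  vy <- cn * (uyy - uy * uy)
  cxy <- cn * (uxy - ux * uy)
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  s <- ((2 * ux * uy + c1) * (2 * cxy + c2)) /
    ((ux^2 + uy^2 + c1) * (vx + vy + c2))
  mean(s)
}

#' Euclidean distance between histograms
#'
#' L2 norm of the difference between the count vectors of two histograms
#' sharing edges.
#'
#' @param h1,h2 `histogram_summary` objects.
#' @return scalar distance.
#' @export
histogram_distance <- function(h1, h2) {
  if (!isTRUE(all.equal(h1$edges, h2$edges)))
    stop("histograms have mismatched edges")
  sqrt(sum((h1$counts - h2$counts)^2))
}

#' Multisite heterogeneity index
#'
#' Sum over histogram bins of the across-site sample standard deviation
#' (n - 1 denominator) of the per-site mean voxel counts. Zero when all
#' site-averaged histograms coincide.
#'
#' @param site_hists list of `histogram_summary`, one averaged histogram
#'   per site (>= 2 sites, shared edges).
#' @return scalar index.
#' @export
heterogeneity_index <- function(site_hists) {
  if (length(site_hists) < 2L) stop("heterogeneity index needs >= 2 sites")
  e1 <- site_hists[[1]]$edges
  for (h in site_hists)
    if (!isTRUE(all.equal(h$edges, e1)))
      stop("histograms have mismatched edges")
  cm <- vapply(site_hists, function(h) h$counts,
               numeric(length(site_hists[[1]]$counts)))
  sum(apply(cm, 1L, stats::sd))
}

#' Brain-age error statistics
#'
#' `mae` = mean absolute prediction error; `mpad` = mean predicted age
#' difference (average predicted minus real age); `tmd` = training mean
#' deviation, the mean age of the training set minus that of the test set
#' (a regression-to-the-mean diagnostic). All in years.
#'
#' @param pred,true equal-length vectors of predicted and real ages.
#' @param train_mean,test_mean mean ages of the training and test sets.
#' @return object of class `age_error_stats` with fields `mae`, `mpad`,
#'   `tmd`.
#' @export
age_error_stats <- function(pred, true, train_mean = NA_real_,
                            test_mean = NA_real_) {
  if (length(pred) != length(true) || !length(pred))
    stop("pred and true must be equal-length nonempty vectors")
  structure(list(mae = mean(abs(pred - true)),
                 mpad = mean(pred - true),
                 tmd = train_mean - test_mean),
            class = "age_error_stats")
}

#' Full IQM vector for one volume
#'
#' The Table-style metric set: three tissue volume fractions plus eleven
#' image quality metrics (cjv, efc, snr per tissue, wm2max, rpve per
#' tissue, fwhm). Metrics that are undefined on the input (e.g. SNR of a
#' noiseless tissue) are reported as `NA` rather than failing the set.
#'
#' @inheritParams cjv
#' @return named list of class `iqm_set` (14 entries).
#' @export
iqm_set <- function(vol, seg, mode = "pv") {
  safe <- function(expr) tryCatch(suppressWarnings(expr),
                                  error = function(e) NA_real_)
  fr <- tissue_volume_fractions(seg)
  structure(list(
    icv_gm = fr[["icv_gm"]], icv_wm = fr[["icv_wm"]],
    icv_csf = fr[["icv_csf"]],
    cjv = safe(cjv(vol, seg, mode)),
    efc = safe(efc(vol)),
    snr_gm = safe(snr_tissue(vol, seg, "gm", mode)),
    snr_wm = safe(snr_tissue(vol, seg, "wm", mode)),
    snr_csf = safe(snr_tissue(vol, seg, "csf", mode)),
    wm2max = safe(wm2max(vol, seg, mode)),
    rpve_gm = safe(rpve(seg, "gm")), rpve_wm = safe(rpve(seg, "wm")),
    rpve_csf = safe(rpve(seg, "csf")),
    fwhm = safe(fwhm_estimate(vol))), class = "iqm_set")
}

#' Simple 3-class fallback segmentation
#'
#' K-means on the brain intensities with deterministic quantile
#' initialization (0.15/0.5/0.85); clusters ordered by center are labelled
#' CSF < GM < WM. A stand-in when no proper tissue segmentation is
#' available.
#'
#' @param vol a [volume()] with a nonempty mask.
#' @return a hard-label `tissue_segmentation`.
#' @export
fallback_segment <- function(vol) {
  bv <- brain_values(vol)
  ctr <- stats::quantile(bv, c(0.15, 0.5, 0.85), names = FALSE, type = 7)
  if (any(duplicated(ctr))) ctr <- ctr + c(-1e-6, 0, 1e-6) * max(abs(ctr), 1)
  km <- stats::kmeans(bv, centers = matrix(ctr, ncol = 1))
  ord <- order(km$centers)
  lab <- match(km$cluster, ord)          # 1 = CSF, 2 = GM, 3 = WM
  mk <- function(l) {
    a <- array(0, dim = dim(vol$data))
    a[vol$mask > 0] <- as.numeric(lab == l)
    a
  }
  structure(list(csf = mk(1L), gm = mk(2L), wm = mk(3L)),
            class = "tissue_segmentation")
}

#' GM-volume / age correlation
#'
#' Plain linear (Pearson) correlation between GM volume fractions and ages
#' — the aging pattern a harmonization procedure must conserve.
#'
#' @param gm_fractions numeric vector of GM volume fractions.
#' @param ages numeric vector of ages (years).
#' @return correlation coefficient.
#' @export
gm_age_correlation <- function(gm_fractions, ages) {
  stats::cor(gm_fractions, ages)
}
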