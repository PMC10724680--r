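test_that("tissue volume fractions normalize by intracranial volume", {
  seg <- structure(list(
    csf = array(c(rep(1, 25), rep(0, 75)), dim = c(100, 1, 1)),
    gm = array(c(rep(0, 25), rep(1, 25), rep(0, 50)), dim = c(100, 1, 1)),
    wm = array(c(rep(0, 50), rep(1, 50)), dim = c(100, 1, 1))),
    class = "tissue_segmentation")
  fr <- tissue_volume_fractions(seg)
  expect_equal(unname(fr), c(0.25, 0.50, 0.25))
  expect_equal(sum(fr), 1)

  ph <- generate_phantom(60, 32, 13)
  fr2 <- tissue_volume_fractions(ph$segmentation)
  expect_equal(sum(fr2), 1)
})

test_that("cjv matches its closed form and is scale invariant", {
  tt <- toy_two_tissue(10, mu_gm = 300, mu_wm = 600, sd_gm = 30, sd_wm = 30,
                       seed = 7)
  v <- tt$vol; seg <- tt$seg
  gm_sd <- sqrt(mean((v$data[seg$gm == 1] - mean(v$data[seg$gm == 1]))^2))
  wm_sd <- sqrt(mean((v$data[seg$wm == 1] - mean(v$data[seg$wm == 1]))^2))
  mu_d <- abs(mean(v$data[seg$wm == 1]) - mean(v$data[seg$gm == 1]))
  expect_equal(cjv(v, seg), (gm_sd + wm_sd) / mu_d)
  expect_equal(cjv(v, seg), 60 / 300, tolerance = 0.15)   # population values

  v2 <- volume(v$data * 3.7, mask = v$mask)
  expect_equal(cjv(v2, seg), cjv(v, seg), tolerance = 1e-12)

  # noiseless hard-label tissues give cjv = 0
  tt0 <- toy_two_tissue(10, sd_gm = 0, sd_wm = 0)
  expect_equal(cjv(tt0$vol, tt0$seg), 0)
})

test_that("efc hits its closed-form anchors and the brute-force oracle", {
  const <- volume(array(7, dim = rep(6, 3)), mask = array(1, dim = rep(6, 3)))
  expect_equal(efc(const), 1, tolerance = 1e-12)

  single <- array(0, dim = rep(6, 3)); single[3, 3, 3] <- 5
  expect_equal(efc(volume(single)), 0)

  set.seed(8)
  r <- array(runif(6^3), dim = rep(6, 3))
  x <- as.numeric(r); xmax <- sqrt(sum(x^2))
  brute <- -sum((x / xmax) * log(x / xmax)) /
    (sqrt(length(x)) * log(sqrt(length(x))))
  expect_equal(efc(volume(r)), brute, tolerance = 1e-9)
})

test_that("snr follows mu/(sd*sqrt(n/(n-1))) and scales as expected", {
  set.seed(9)
  tt <- toy_two_tissue(16, mu_gm = 500, mu_wm = 500, sd_gm = 50, sd_wm = 50,
                       seed = 9)
  s <- snr_tissue(tt$vol, tt$seg, "gm")
  expect_equal(s, 10, tolerance = 0.05)
  # invariant to global rescale
  v2 <- volume(tt$vol$data * 2, mask = tt$vol$mask)
  expect_equal(snr_tissue(v2, tt$seg, "gm"), s, tolerance = 1e-12)
  # doubling the noise halves snr (same seed: same standardized residuals)
  tt2 <- toy_two_tissue(16, mu_gm = 500, mu_wm = 500, sd_gm = 100,
                        sd_wm = 100, seed = 9)
  expect_equal(snr_tissue(tt2$vol, tt2$seg, "gm") * 2, s, tolerance = 0.02)

  tt0 <- toy_two_tissue(8, sd_gm = 0, sd_wm = 0)
  expect_error(snr_tissue(tt0$vol, tt0$seg, "gm"), "zero")
})

test_that("wm2max relates the WM median to the brain P95", {
  tt <- toy_two_tissue(10, mu_gm = 300, mu_wm = 600)
  v <- tt$vol
  p95 <- quantile(v$data[v$mask > 0], 0.95, names = FALSE)
  expect_equal(wm2max(v, tt$seg), 600 / p95)

  unif <- toy_volume(10, fill = 123)
  seg1 <- structure(list(csf = array(0, dim = rep(10, 3)),
                         gm = array(0, dim = rep(10, 3)), wm = unif$mask),
                    class = "tissue_segmentation")
  expect_equal(wm2max(unif, seg1), 1)
  v3 <- volume(v$data * 5, mask = v$mask)
  expect_equal(wm2max(v3, tt$seg), wm2max(v, tt$seg), tolerance = 1e-12)
})

test_that("rpve counts ambiguous partial volumes per the piecewise rule", {
  bin <- structure(list(csf = array(0, dim = c(5, 5, 4)),
                        gm = array(rep(c(0, 1), 50), dim = c(5, 5, 4)),
                        wm = array(0, dim = c(5, 5, 4))),
                   class = "tissue_segmentation")
  expect_equal(rpve(bin, "gm"), 0)

  p <- array(0, dim = c(120, 1, 1))
  p[1:80] <- 1; p[81:120] <- 0.5
  seg <- structure(list(csf = p * 0, gm = p, wm = p * 0),
                   class = "tissue_segmentation")
  expect_equal(rpve(seg, "gm"), 100 * 20 / 100)   # hand sum

  ph <- generate_phantom(40, 32, 3)
  for (t in c("gm", "wm", "csf")) {
    r <- rpve(ph$segmentation, t)
    expect_gte(r, 0); expect_lte(r, 100)
  }
})

test_that("fwhm estimator recovers known smoothness and respects units", {
  set.seed(10)
  n <- 40L
  wn <- array(rnorm(n^3), dim = rep(n, 3))
  mask <- array(1, dim = rep(n, 3))
  # independent separable Gaussian smoothing built from first principles
  sm_sigma <- 1.7
  kern <- dnorm(seq(-6, 6), sd = sm_sigma); kern <- kern / sum(kern)
  smooth1 <- function(a, ax) {
    d <- dim(a); perm <- c(ax, setdiff(1:3, ax))
    m <- matrix(aperm(a, perm), nrow = d[ax])
    ms <- apply(m, 2, function(col)
      stats::filter(c(rev(col[1:6]), col, rev(col[(d[ax]-5):d[ax]])),
                    kern)[7:(6 + d[ax])])
    aperm(array(ms, dim = d[perm]), order(perm))
  }
  sm <- smooth1(smooth1(smooth1(wn, 1), 2), 3)
  true_fwhm <- 2 * sqrt(2 * log(2)) * sm_sigma      # ~4.0 voxels
  est <- fwhm_estimate(volume(sm, mask = mask))
  expect_rel_equal(est, true_fwhm, 0.10)

  # unsmoothed white noise: below 1.5 voxel widths
  est0 <- fwhm_estimate(volume(wn, mask = mask))
  expect_lt(est0, 1.5)

  # linear in voxel spacing
  est2 <- fwhm_estimate(volume(sm, mask = mask, spacing = c(2, 2, 2)))
  expect_equal(est2, 2 * est, tolerance = 1e-9)
})

test_that("first-order radiomics match hand computation and pin 36 features", {
  vals <- c(1, 2, 2, 3)
  v <- volume(array(c(vals, rep(0, 4)), dim = c(8, 1, 1)))
  mask <- array(c(rep(1, 4), rep(0, 4)), dim = c(8, 1, 1))
  f <- first_order_radiomics(v, mask, bin_width = 1)
  expect_equal(unname(f["mean"]), 2)
  expect_equal(unname(f["median"]), 2)
  expect_equal(unname(f["range"]), 2)
  expect_equal(unname(f["minimum"]), 1)
  expect_equal(unname(f["maximum"]), 3)
  expect_equal(unname(f["energy"]), 1 + 4 + 4 + 9)
  expect_equal(unname(f["rms"]), sqrt(18 / 4))
  expect_equal(unname(f["variance"]), mean((vals - 2)^2))
  expect_equal(unname(f["mad"]), mean(abs(vals - 2)))
  expect_equal(unname(f["uniformity"]), 0.25^2 + 0.5^2 + 0.25^2)
  expect_equal(unname(f["entropy"]), -sum(c(.25, .5, .25) * log2(c(.25, .5, .25))))
  expect_equal(unname(f["skewness"]), 0)

  # constant region: variance 0, entropy 0, uniformity 1
  fc <- first_order_radiomics(toy_volume(8, fill = 42),
                              toy_volume(8, fill = 42)$mask)
  expect_equal(unname(fc["variance"]), 0)
  expect_equal(unname(fc["entropy"]), 0)
  expect_equal(unname(fc["uniformity"]), 1)

  ph <- generate_phantom(55, 32, 17)
  prof <- radiomic_profile(ph$volume, ph$segmentation)
  expect_length(prof, 36)
  expect_identical(names(prof),
                   c(paste0("gm_", radiomic_feature_names()),
                     paste0("wm_", radiomic_feature_names())))
})

test_that("pca projection matches an eigendecomposition oracle", {
  set.seed(11)
  X <- matrix(rnorm(30 * 6), 30, 6)
  X[, 3] <- X[, 1] * 2 + rnorm(30, 0, 0.1)
  res <- pca_project(X)
  ve <- res$variance_explained
  expect_gte(ve[1], ve[2]); expect_gte(ve[2], 0); expect_lte(sum(ve), 1)

  # independent oracle: eigen of the correlation covariance
  Z <- scale(X)
  eg <- eigen(stats::cov(Z))
  ve_or <- eg$values / sum(eg$values)
  expect_equal(ve, ve_or[1:2], tolerance = 1e-9)
  proj_or <- Z %*% eg$vectors[, 1:2]
  # match up to per-axis sign
  for (k in 1:2) {
    agree <- min(max(abs(res$coords[, k] - proj_or[, k])),
                 max(abs(res$coords[, k] + proj_or[, k])))
    expect_lt(agree, 1e-6)
  }

  # rank-1 data: first axis explains all retained variance
  r1 <- outer(rnorm(10), c(1, 2, 3)) + 5
  res1 <- suppressWarnings(pca_project(r1))
  expect_equal(res1$variance_explained[1], 1, tolerance = 1e-9)

  expect_error(pca_project(X[1:2, ]), "3 samples")
})

test_that("ssim3d matches closed forms and the frozen cross-implementation oracle", {
  ph <- normalize_median(generate_phantom(50, 32, 19)$volume)
  expect_equal(ssim3d(ph, ph), 1)

  # constant 0 vs constant 1000 without cropping: C1/(10^6 + C1)
  z <- array(0, dim = rep(10, 3)); o <- array(1000, dim = rep(10, 3))
  expect_equal(ssim3d(z, o, crop_background = FALSE),
               100 / (1e6 + 100), tolerance = 1e-12)

  # frozen oracle computed with an independent reference implementation
  # (uniform 7^3 window, range 1000, sample-covariance normalization)
  set.seed(42)
  a <- array(runif(20^3, 0, 1000), dim = c(20, 20, 20))
  b <- a + array(rnorm(20^3, 0, 60), dim = c(20, 20, 20))
  b[b < 0] <- 0
  expect_equal(ssim3d(a, b, data_range = 1000), 0.9796812743,
               tolerance = 1e-6)

  expect_error(ssim3d(z, array(0, dim = rep(8, 3))), "mismatch")
})

test_that("histogram distance is the L2 metric on counts", {
  e <- seq(0, 10, length.out = 11)
  h0 <- histogram_summary(c(1, rep(0, 9)), e)
  h1 <- histogram_summary(c(0, 1, rep(0, 8)), e)
  expect_equal(histogram_distance(h0, h0), 0)
  expect_equal(histogram_distance(h0, h1), sqrt(2))
  set.seed(12)
  hs <- lapply(1:3, function(i) histogram_summary(runif(10, 0, 5), e))
  expect_equal(histogram_distance(hs[[1]], hs[[2]]),
               histogram_distance(hs[[2]], hs[[1]]))
  expect_lte(histogram_distance(hs[[1]], hs[[3]]),
             histogram_distance(hs[[1]], hs[[2]]) +
               histogram_distance(hs[[2]], hs[[3]]) + 1e-12)
})

test_that("heterogeneity index sums across-site SDs of bin counts", {
  e <- seq(0, 900, length.out = 101)
  h <- histogram_summary(rep(10, 100), e)
  expect_equal(heterogeneity_index(list(h, h, h)), 0)

  h2 <- histogram_summary(c(20, rep(10, 99)), e)
  expect_equal(heterogeneity_index(list(h, h2)), 10 / sqrt(2))
  expect_equal(heterogeneity_index(list(h2, h)),
               heterogeneity_index(list(h, h2)))
  expect_error(heterogeneity_index(list(h)), "2 sites")

  # replacing every site by the grand mean sends the index to zero
  set.seed(13)
  hs <- lapply(1:4, function(i) histogram_summary(runif(100, 0, 50), e))
  gi <- heterogeneity_index(hs)
  gm <- average_histograms(hs)
  expect_gt(gi, 0)
  expect_equal(heterogeneity_index(list(gm, gm, gm, gm)), 0)
})

test_that("age error statistics follow their definitions", {
  st <- age_error_stats(c(30, 40), c(35, 35), train_mean = 50,
                        test_mean = 40)
  expect_equal(st$mae, 5)
  expect_equal(st$mpad, 0)
  expect_equal(st$tmd, 10)

  set.seed(14)
  for (i in 1:20) {
    pred <- runif(15, 20, 80); true <- runif(15, 20, 80)
    s <- age_error_stats(pred, true)
    expect_gte(s$mae, abs(s$mpad))
  }
  expect_error(age_error_stats(1:3, 1:2), "equal-length")
})

test_that("the full IQM set on a phantom is coherent", {
  ph <- generate_phantom(45, 32, 23)
  nv <- normalize_median(ph$volume)
  iq <- iqm_set(nv, ph$segmentation)
  expect_named(iq, c("icv_gm", "icv_wm", "icv_csf", "cjv", "efc", "snr_gm",
                     "snr_wm", "snr_csf", "wm2max", "rpve_gm", "rpve_wm",
                     "rpve_csf", "fwhm"))
  expect_equal(iq$icv_gm + iq$icv_wm + iq$icv_csf, 1)
  expect_true(iq$efc >= 0 && iq$efc <= 1)

  # hard-label noiseless phantom: closed forms
  hard <- generate_phantom(45, 32, 23, pv_sigma = 0)
  expect_equal(cjv(hard$volume, hard$segmentation), 0, tolerance = 1e-12)
  expect_equal(rpve(hard$segmentation, "gm"), 0)
  expect_equal(unname(tissue_volume_fractions(hard$segmentation)["icv_gm"]),
               sum(hard$segmentation$gm) /
                 sum(hard$volume$mask))
})

test_that("fallback segmentation is deterministic and ordered", {
  ph <- generate_phantom(50, 32, 29)
  nv <- normalize_median(apply_site_effect(ph$volume, ph$segmentation,
                                           preset_site_configs()$siteA,
                                           seed = 3))
  s1 <- fallback_segment(nv)
  s2 <- fallback_segment(nv)
  expect_identical(s1, s2)
  mu <- vapply(c("csf", "gm", "wm"), function(t) mean(nv$data[s1[[t]] > 0]),
               numeric(1))
  expect_true(mu["csf"] < mu["gm"] && mu["gm"] < mu["wm"])
  # agrees broadly with the generative labels
  agree <- sum(s1$gm * (ph$segmentation$gm > 0.5)) / sum(s1$gm)
  expect_gt(agree, 0.6)
})
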