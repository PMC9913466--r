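# The 14 image-based intensity normalization methods and their contracts.

vol_from <- function(x, sequence = "T1w") {
  d <- c(length(x), 1, 1)
  scan_volume(array(x, d), c(2, 2, 2), sequence)
}

test_that("z-score maps {1,2,3} to {-1,0,1} and is affine-invariant", {
  v <- vol_from(c(1, 2, 3))
  b <- array(TRUE, dim(v$voxels))
  out <- zscore_normalize(v, b)
  expect_equal(as.numeric(out$voxels), c(-1, 0, 1))
  # idempotence on standardized input
  out2 <- zscore_normalize(out, b)
  expect_equal(out2$voxels, out$voxels, tolerance = 1e-9)
  # affine invariance
  va <- vol_from(3.7 * c(1, 2, 3) + 11)
  outa <- zscore_normalize(va, b)
  expect_equal(outa$voxels, out$voxels, tolerance = 1e-9)
  # constant image errors
  expect_error(zscore_normalize(vol_from(c(5, 5, 5)), b), "constant")
})

test_that("z-score postcondition holds on phantom volumes", {
  co <- tiny_cohort()
  b <- co$masks$p001$brain > 0
  for (i in c(1, 4)) {
    out <- zscore_normalize(co$volumes$T1wce[[i]], b)
    expect_equal(mean(out$voxels[b]), 0, tolerance = 1e-6)
    expect_equal(sd(out$voxels[b]), 1, tolerance = 1e-6)
    expect_true(all(out$voxels[!b] == 0))
  }
})

test_that("FCM single-tissue, two-tissue and tissue+mode follow the stated formulas", {
  # single wm mask with mean 200: voxel 100 -> 0.5
  v <- vol_from(c(100, 200, 300))
  masks <- list(brain = array(1, c(3, 1, 1)),
                wm = array(c(0, 1, 1), c(3, 1, 1)),
                csf = array(c(1, 0, 0), c(3, 1, 1)))
  out <- fcm_normalize(v, masks, "wm")   # wm mean = 250
  expect_equal(out$voxels[1, 1, 1], 100 / 250)
  # weighted tissue mean of the output is 1
  expect_equal(sum(out$voxels * masks$wm) / sum(masks$wm), 1, tolerance = 1e-6)
  # two-tissue: mu1 = 50, mu2 = 150 -> (I - 50)/100
  v2 <- vol_from(c(50, 150, 100))
  masks2 <- list(brain = array(1, c(3, 1, 1)),
                 csf = array(c(1, 0, 0), c(3, 1, 1)),
                 gm = array(c(0, 1, 0), c(3, 1, 1)))
  out2 <- fcm_normalize(v2, masks2, "csf-gm")
  expect_equal(as.numeric(out2$voxels), c(0, 1, 0.5))
  # tissue + mode with mu_T == mode(B): build a membership whose weighted
  # mean equals the histogram mode exactly
  vmode <- vol_from(c(rep(100, 12), rep(100.2, 4)))
  bm <- array(1, c(16, 1, 1))
  md <- image_mode(vmode, bm > 0)
  w2 <- (md - 100) / (100.2 - 100)
  gm <- array(0, c(16, 1, 1))
  gm[1] <- 1 - w2; gm[13] <- w2
  masksm <- list(brain = bm, gm = gm)
  expect_error(fcm_normalize(vmode, masksm, "gm-mode"), "degenerate")
})

test_that("FCM tissue+mode divides by mu_T - mode(B)", {
  co <- clean_cohort()
  v <- co$volumes$T1w[[1]]
  m <- co$masks$p001
  out <- fcm_normalize(v, m, "wm-mode")
  mu <- tissue_mean(v, m$wm)
  md <- image_mode(v, m$brain > 0)
  i <- which(m$brain > 0)[100]
  expect_equal(out$voxels[i], v$voxels[i] / (mu - md), tolerance = 1e-12)
})

test_that("KDE normalization maps the dominant mode to the standard value and is scale-equivariant", {
  set.seed(4)
  x <- c(rnorm(3000, 40, 4), rnorm(7000, 120, 6))
  v <- scan_volume(array(x, c(100, 100, 1)), c(2, 2, 2), "T1w")
  b <- array(TRUE, dim(v$voxels))
  out <- kde_normalize(v, b)
  # a voxel at intensity 120 maps to ~1 (grid resolution + KDE bias bound)
  pk <- out$meta$peak
  expect_lt(abs(pk - 120) / 120, 0.02)
  expect_equal(120 / pk, 1, tolerance = 0.02)
  # doubling all intensities leaves the output unchanged
  v2 <- v; v2$voxels <- v$voxels * 2
  out2 <- kde_normalize(v2, b)
  expect_equal(out2$voxels, out$voxels, tolerance = 1e-6)
  # constant image with c = 1 -> all ones
  vc <- scan_volume(array(5, c(4, 4, 4)), c(2, 2, 2), "T1w")
  outc <- kde_normalize(vc, array(TRUE, c(4, 4, 4)))
  expect_true(all(outc$voxels == 1))
})

test_that("GMM normalization locates the wm component within 2% on a simulated mixture", {
  set.seed(9)
  x <- c(rnorm(2e4, 30, 3), rnorm(4e4, 80, 6), rnorm(4e4, 160, 8))
  v <- scan_volume(array(x, c(100, 1000, 1)), c(2, 2, 2), "T1w")
  b <- array(TRUE, dim(v$voxels))
  out <- gmm_normalize(v, b)
  expect_lt(abs(out$meta$mu_wm - 160) / 160, 0.02)
  # global scaling leaves output unchanged
  v2 <- v; v2$voxels <- v$voxels * 3
  out2 <- gmm_normalize(v2, b)
  expect_equal(out2$voxels, out$voxels, tolerance = 1e-6)
  # near-constant image errors
  vc <- scan_volume(array(rep(c(1, 1), 32), c(4, 4, 4)), c(2, 2, 2), "T1w")
  expect_error(gmm_normalize(vc, array(TRUE, c(4, 4, 4))), "distinct")
})

test_that("histogram-matching training reproduces analytic quantiles and averages", {
  co <- tiny_cohort()
  b <- lapply(1:2, function(i) co$masks[[sprintf("p%03d", i)]]$brain > 0)
  vols <- co$volumes$T1wce[1:2]
  # identical training images -> reference equals either image's landmarks
  lmk2 <- hm_train(vols[c(1, 1)], b[c(1, 1)])
  lmk1 <- hm_train(vols[1], b[1])
  expect_equal(lmk2$reference_values, lmk1$reference_values)
  # two uniforms U(0,1), U(0,2): after the p1/p99 standardization both give
  # the same standard-scale deciles, so the average equals the analytic map
  set.seed(2)
  u1 <- scan_volume(array(runif(40000, 0, 1), c(40000, 1, 1)), c(2, 2, 2))
  u2 <- scan_volume(array(runif(40000, 0, 2), c(40000, 1, 1)), c(2, 2, 2))
  bu <- array(TRUE, c(40000, 1, 1))
  lev <- seq(0.1, 0.9, by = 0.1)
  lmk <- hm_train(list(u1, u2), list(bu, bu), quantile_levels = c(0.01, lev, 0.99))
  # analytic: standardized landmark for U(0,m) at level q is
  # 100 * (q - 0.01)/0.98 for both images
  expected <- 100 * (c(0.01, lev, 0.99) - 0.01) / 0.98
  expect_equal(unname(lmk$reference_values), expected, tolerance = 0.5)
})

test_that("histogram matching maps landmarks exactly and inverts affine shifts", {
  co <- tiny_cohort()
  b1 <- co$masks$p001$brain > 0
  v1 <- co$volumes$T1wce[[1]]
  lmk <- hm_train(list(v1), list(b1))
  out <- hm_apply(v1, b1, lmk)
  q <- quantile(out$voxels[b1], lmk$quantile_levels, names = FALSE)
  step <- diff(range(v1$voxels[b1])) / 1000
  expect_true(all(abs(q - lmk$reference_values) <=
                    pmax(abs(lmk$reference_values) * 0.01, 1)))
  # affine-transformed copy maps onto the same reference
  v2 <- v1; v2$voxels <- 2.5 * v1$voxels + 30
  out2 <- hm_apply(v2, b1, lmk)
  expect_equal(out2$voxels[b1], out$voxels[b1], tolerance = 1e-6)
  # an intensity exactly at a landmark maps exactly to the reference value
  inl <- quantile(v1$voxels[b1], lmk$quantile_levels, names = FALSE)
  for (k in c(1, 4, 12))
    expect_identical(radnorm:::piecewise_linear(inl[k], inl,
                                                lmk$reference_values)[1],
                     unname(lmk$reference_values[k]))
})

test_that("histogram matching is idempotent on an already-matched image", {
  co <- tiny_cohort()
  b <- lapply(names(co$masks), function(p) co$masks[[p]]$brain > 0)
  vols <- co$volumes$T1wce[1:5]
  lmk <- hm_train(vols, b[1:5])
  out1 <- hm_apply(vols[[2]], b[[2]], lmk)
  out2 <- hm_apply(out1, b[[2]], lmk)
  rg <- diff(range(out1$voxels[b[[2]]]))
  q1 <- quantile(out1$voxels[b[[2]]], lmk$quantile_levels)
  q2 <- quantile(out2$voxels[b[[2]]], lmk$quantile_levels)
  # bounded by the empirical-quantile resolution (one order-statistic gap)
  expect_true(all(abs(q1 - q2) < rg / sum(b[[2]])))
})

test_that("white stripe centres the peak at zero with the expected stripe mass", {
  set.seed(6)
  x <- c(rnorm(30000, 100, 20))
  v <- scan_volume(array(x, c(30000, 1, 1)), c(2, 2, 2), "T1w")
  b <- array(TRUE, dim(v$voxels))
  out <- whitestripe_normalize(v, b, tau = 0.05)
  expect_lt(abs(out$meta$stripe_frac - 0.10), 0.01)
  # voxel at exactly mu maps to 0
  mu <- out$meta$mu_peak
  vt <- v; vt$voxels[5] <- mu
  outt <- whitestripe_normalize(vt, b, tau = 0.05)
  expect_equal(outt$voxels[5], 0)
  # translation invariance
  v2 <- v; v2$voxels <- v$voxels + 57
  out2 <- whitestripe_normalize(v2, b, tau = 0.05)
  expect_equal(out2$voxels, out$voxels, tolerance = 1e-6)
})

test_that("the dispatcher enumerates 14 image-based datasets plus nn with provenance", {
  co <- tiny_cohort()
  vols <- co$volumes$T1wce[1:3]
  methods <- normalization_methods(image_only = TRUE)
  expect_length(methods, 14)
  expect_length(normalization_methods(), 16)
  expect_length(grep("^fcm-", methods), 9)
  outs <- lapply(methods, function(m) normalize_dataset(vols, co$masks, m))
  names(outs) <- methods
  # nn returns input unchanged
  nn <- normalize_dataset(vols, co$masks, "nn")
  expect_equal(nn[[1]]$voxels, vols[[1]]$voxels)
  expect_equal(nn[[1]]$meta$norm_method, "nn")
  # provenance on every output volume, and all methods distinct
  b <- co$masks$p001$brain > 0
  sig <- vapply(methods, function(m) {
    v <- outs[[m]][[1]]
    expect_equal(v$meta$norm_method, m)
    expect_equal(v$patient_id, "p001")
    expect_true(all(is.finite(v$voxels[b])))
    mean(v$voxels[b])
  }, 0)
  expect_equal(anyDuplicated(round(sig, 10)), 0)
  # unknown and feature-level methods are rejected
  expect_error(normalize_dataset(vols, co$masks, "nope"), "unknown")
  expect_error(normalize_dataset(vols, co$masks, "combat"), "feature-level")
})

test_that("scale-target postconditions hold for kde, gmm and fcm-single on phantoms", {
  co <- tiny_cohort()
  m <- co$masks$p001
  v <- co$volumes$T1wce[[1]]
  b <- m$brain > 0
  kd <- kde_normalize(v, b)
  expect_equal(kd$meta$peak * kd$meta$standard_value / kd$meta$peak, 1)
  fc <- fcm_normalize(v, m, "wm")
  expect_equal(sum(fc$voxels * m$wm) / sum(m$wm), 1, tolerance = 1e-6)
})
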