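# Radiomics extraction: resampling, derived images, discretization, and
# the feature classes with their reference counts.

test_that("resampling is the identity on the target grid and preserves polynomials", {
  v <- scan_volume(array(rnorm(16^3), c(16, 16, 16)), c(2, 2, 2))
  out <- resample_volume(v, spacing_mm = c(2, 2, 2))
  expect_identical(out$vol$voxels, v$voxels)
  # constant survives interpolation
  vc <- scan_volume(array(5, c(10, 10, 10)), c(1, 1, 1))
  oc <- resample_volume(vc, spacing_mm = c(2, 2, 2))
  expect_equal(max(abs(oc$vol$voxels - 5)), 0, tolerance = 1e-9)
  # linear ramp preserved by cubic splines
  d <- c(12, 12, 12)
  ramp <- array(0, d)
  for (i in seq_len(d[1])) ramp[i, , ] <- 3 * i
  vr <- scan_volume(ramp, c(1, 1, 1))
  or <- resample_volume(vr, spacing_mm = c(0.5, 0.5, 0.5))
  i2 <- seq_len(dim(or$vol$voxels)[1])
  expect_equal(or$vol$voxels[, 1, 1], 3 * (1 + (i2 - 1) * 0.5),
               tolerance = 1e-6)
  # masks go through linear interpolation + 0.5 threshold
  roi <- array(FALSE, d); roi[4:8, 4:8, 4:8] <- TRUE
  om <- resample_volume(vr, list(roi = roi), c(0.5, 0.5, 0.5))
  expect_true(sum(om$masks$roi) > sum(roi) * 6)
})

test_that("derive_images yields the 12 tagged images with filter identities", {
  v <- scan_volume(array(rnorm(12^3), c(12, 12, 12)), c(2, 2, 2))
  imgs <- derive_images(v)
  expect_length(imgs, 12)
  expect_equal(names(imgs)[1], "original")
  expect_length(grep("^wavelet-", names(imgs)), 8)
  expect_setequal(grep("^log-", names(imgs), value = TRUE),
                  c("log-2", "log-3", "log-4"))
  # constant image: LoG vanishes, HHH vanishes, LLL is constant x gain
  vc <- scan_volume(array(4, c(12, 12, 12)), c(2, 2, 2))
  ic <- derive_images(vc)
  expect_equal(max(abs(ic[["log-3"]])), 0, tolerance = 1e-9)
  expect_equal(max(abs(ic[["wavelet-HHH"]])), 0, tolerance = 1e-9)
  gain <- sum(radnorm:::coif1_filters()$lo)^3
  expect_equal(unique(round(as.numeric(ic[["wavelet-LLL"]]), 9)), round(4 * gain, 9))
  # requesting a subset computes only that subset
  sub <- derive_images(v, images = c("original", "log-2"))
  expect_setequal(names(sub), c("original", "log-2"))
})

test_that("bin-count discretization labels as specified", {
  x <- array(0, c(32, 1, 1))
  x[] <- 0:31
  roi <- array(TRUE, c(32, 1, 1))
  lab <- discretize_roi(x, roi, 32)
  expect_equal(as.numeric(lab), 1:32)
  expect_equal(tabulate(lab), rep(1L, 32))
  # bin count 1 puts everything in bin 1... except max clamps; use 2 values
  lab1 <- discretize_roi(x, roi, 1)
  expect_true(all(lab1[roi] == 1))
  # affine intensity transform leaves labels unchanged
  lab2 <- discretize_roi(2.3 * x + 7, roi, 32)
  expect_identical(lab, lab2)
  expect_error(discretize_roi(array(1, c(4, 1, 1)), array(TRUE, c(4, 1, 1)), 8),
               "constant")
})

test_that("first-order features match hand computations and count 19", {
  f <- first_order_features(c(1, 2, 3, 4), c(1L, 2L, 3L, 4L), voxel_volume_mm3 = 2)
  expect_length(f, 19)
  expect_equal(unname(f["Mean"]), 2.5)
  expect_equal(unname(f["Variance"]), 1.25)   # population denominator
  expect_equal(unname(f["Range"]), 3)
  expect_equal(unname(f["Energy"]), 1 + 4 + 9 + 16)
  expect_equal(unname(f["TotalEnergy"]), 2 * 30)
  expect_equal(unname(f["Entropy"]), 2)       # 4 equal bins -> log2(4)
  expect_equal(unname(f["Uniformity"]), 0.25)
  expect_equal(unname(f["RootMeanSquared"]), sqrt(30 / 4))
  # constant ROI
  fc <- first_order_features(rep(7, 10), rep(1L, 10))
  expect_equal(unname(fc[c("Mean", "Median", "Minimum", "Maximum")]),
               rep(7, 4))
  expect_equal(unname(fc[c("Variance", "Entropy", "Skewness", "Kurtosis")]),
               rep(0, 4))
  expect_equal(unname(fc["Uniformity"]), 1)
})

test_that("shape features reproduce analytic solids", {
  # digital ball, radius 10 voxels
  d <- c(27, 27, 27); ctr <- c(14, 14, 14)
  ball <- array(FALSE, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1]))
    ball[i, j, k] <- sum((c(i, j, k) - ctr)^2) <= 100
  sh <- shape_features(ball, c(1, 1, 1))
  expect_length(sh, 16)
  expect_true(sh["Sphericity"] >= 0.95 && sh["Sphericity"] <= 1.0)
  expect_lt(abs(sh["MeshVolume"] - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.05)
  expect_equal(unname(sh["VoxelVolume"]), sum(ball))
  # spacing scaling: volume x8, surface x4
  sh2 <- shape_features(ball, c(2, 2, 2))
  expect_equal(unname(sh2["MeshVolume"] / sh["MeshVolume"]), 8, tolerance = 1e-6)
  expect_equal(unname(sh2["SurfaceArea"] / sh["SurfaceArea"]), 4, tolerance = 1e-6)
  # axis-aligned box: axis lengths proportional to the edges
  box <- array(FALSE, c(24, 18, 12))
  box[3:22, 3:14, 3:8] <- TRUE     # 20 x 12 x 6 voxels
  shb <- shape_features(box, c(1, 1, 1))
  expect_equal(unname(shb["MajorAxisLength"] / shb["MinorAxisLength"]),
               20 / 12, tolerance = 0.05)
  expect_equal(unname(shb["MinorAxisLength"] / shb["LeastAxisLength"]),
               12 / 6, tolerance = 0.05)
  expect_equal(unname(shb["Elongation"]), 12 / 20, tolerance = 0.03)
  expect_equal(unname(shb["Flatness"]), 6 / 20, tolerance = 0.03)
})

test_that("texture classes have the reference feature counts", {
  cc <- feature_class_counts()
  expect_equal(unname(cc[c("firstorder", "shape", "glcm", "glrlm", "glszm",
                           "ngtdm", "gldm")]),
               c(19L, 16L, 24L, 16L, 16L, 5L, 14L))
  set.seed(1)
  lab <- array(sample(1:4, 5^3, replace = TRUE), c(5, 5, 5))
  tx <- texture_features(lab, 4L)
  expect_length(tx, 75)
  cls <- table(sub("\\..*", "", names(tx)))
  expect_equal(unname(cls[c("glcm", "glrlm", "glszm", "ngtdm", "gldm")]),
               c(24L, 16L, 16L, 5L, 14L), ignore_attr = TRUE)
  expect_true(all(is.finite(tx)))
})

test_that("GLCM counts match brute-force pair enumeration on random grids", {
  for (s in 1:5) {
    set.seed(s)
    lab <- array(sample(0:3, 4^3, replace = TRUE), c(4, 4, 4))
    storage.mode(lab) <- "integer"
    if (length(unique(lab[lab > 0])) < 2) next
    P_fast <- radnorm:::glcm_counts(lab, 3L)
    P_slow <- glcm_oracle(lab, 3L)
    expect_equal(unname(P_fast), unname(P_slow))
  }
})

test_that("checkerboard attains maximal GLCM contrast among 2-level images", {
  d <- c(4, 4, 4)
  idx <- arrayInd(seq_len(prod(d)), d)
  cb <- array(1L + (rowSums(idx) %% 2L), d)
  con_cb <- glcm_features(radnorm:::glcm_counts(cb, 2L))["Contrast"]
  set.seed(2)
  for (r in 1:10) {
    rnd <- array(sample(1:2, prod(d), replace = TRUE), d)
    storage.mode(rnd) <- "integer"
    if (length(unique(as.integer(rnd))) < 2) next
    con_r <- glcm_features(radnorm:::glcm_counts(rnd, 2L))["Contrast"]
    expect_lte(con_r, con_cb + 1e-12)
  }
})

test_that("two-voxel ROI GLCM follows the single-pair hand computation", {
  lab <- array(0L, c(3, 1, 1))
  lab[1:2] <- c(1L, 2L)
  P <- radnorm:::glcm_counts(lab, 2L)
  # one pair, symmetric: p(1,2) = p(2,1) = 0.5
  expect_equal(unname(P / sum(P)), matrix(c(0, 0.5, 0.5, 0), 2))
  f <- glcm_features(P)
  expect_equal(unname(f["JointEntropy"]), 1)      # -2 * 0.5 log2 0.5
  expect_equal(unname(f["Contrast"]), 1)
  expect_equal(unname(f["MaximumProbability"]), 0.5)
})

test_that("run, zone and dependence matrices follow hand-checkable patterns", {
  # a single run of 4 equal voxels along x
  lab <- array(0L, c(6, 3, 3))
  lab[2:5, 2, 2] <- 3L
  R <- radnorm:::glrlm_counts(lab, 3L)
  expect_equal(R[3, 4], 1)                  # one run of length 4 along x
  expect_equal(sum(R[3, 1] > 0), 1)         # off-axis directions: length-1 runs
  S <- radnorm:::glszm_counts(lab, 3L)
  expect_equal(sum(S), 1)                   # a single 26-connected zone
  expect_equal(S[3, 4], 1)                  # of size 4
  G <- radnorm:::gldm_counts(lab, 3L, 0L)
  expect_equal(sum(G), 4)                   # every ROI voxel counted once
  # interior voxels have 2 same-level neighbours -> dependence column 3
  expect_equal(G[3, 3], 2)
  expect_equal(G[3, 2], 2)                  # run ends have 1 neighbour
  N <- radnorm:::ngtdm_counts(lab, 3L)
  expect_equal(N[3, 1], 4)                  # n_3 = 4 voxels
  expect_equal(N[3, 2], 0)                  # all neighbours equal the level
})

test_that("direction-averaged texture features are stable under 90-degree rotation", {
  co <- tiny_cohort()
  v <- co$volumes$T1wce[[1]]
  roi <- co$masks$p001$roi > 0
  lab <- discretize_roi(v, roi, 16)
  rot <- aperm(lab, c(2, 1, 3))[dim(lab)[2]:1, , ]   # 90 deg about z
  storage.mode(rot) <- "integer"
  f1 <- texture_features(lab, 16L)
  f2 <- texture_features(rot, 16L)
  rel <- abs(f2 - f1) / pmax(abs(f1), 1e-12)
  expect_lt(max(rel), 0.01)
})

test_that("the feature table has the documented composition and metadata", {
  co <- tiny_cohort()
  cfgx <- extraction_config(bin_counts = 32)
  ft <- build_feature_table(co$volumes$T1wce[1:2], co$masks, cfgx,
                            method_id = "nn")
  # 16 shape + 94 intensity features x 12 derived images = 1144 per bin count
  expect_equal(ncol(ft) - 1, 1144)
  meta <- attr(ft, "metadata")
  expect_equal(sum(meta$class == "shape"), 16)
  expect_equal(sum(meta$class == "firstorder"), 19 * 12)
  expect_equal(sum(meta$class == "glcm"), 24 * 12)
  expect_true(all(meta$method == "nn"))
  expect_true(all(meta$sequence == "T1wce"))
  expect_false(anyDuplicated(meta$column) > 0)
  # identical volumes give identical rows
  ft2 <- build_feature_table(co$volumes$T1wce[c(1, 1)], co$masks, cfgx,
                             method_id = "nn")
  expect_equal(as.numeric(ft2[1, -1]), as.numeric(ft2[2, -1]))
  # five bin counts produce five feature sets per intensity feature
  cfg5 <- extraction_config(images = "original")
  ft5 <- build_feature_table(co$volumes$T1wce[1], co$masks, cfg5,
                             method_id = "nn")
  m5 <- attr(ft5, "metadata")
  expect_equal(sort(unique(m5$bins[m5$class != "shape"])),
               c(8, 16, 32, 64, 128))
  expect_equal(sum(m5$name == "Mean"), 5)
})
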