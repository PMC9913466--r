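# Synthetic multi-scanner phantom cohort generator.

test_that("identical config and seed reproduce the cohort bit for bit", {
  cfg <- cohort_config(n_patients = 20, sequences = "T1w",
                       grid_shape = c(32, 32, 32), seed = 9)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth, b$truth)
  expect_identical(a$volumes$T1w[[5]]$voxels, b$volumes$T1w[[5]]$voxels)
  expect_identical(a$masks$p003, b$masks$p003)
})

test_that("without scanner effects, healthy tissue is identical across patients and contrast orderings hold", {
  co <- clean_cohort()
  m <- co$masks$p001
  healthy <- (m$wm > 0)
  v1 <- co$volumes$T1w[[1]]$voxels[healthy]
  v2 <- co$volumes$T1w[[7]]$voxels[healthy]
  expect_equal(v1, v2)
  means <- function(sq, i = 1) {
    v <- co$volumes[[sq]][[i]]$voxels
    c(csf = mean(v[m$csf > 0]), gm = mean(v[m$gm > 0]),
      wm = mean(v[m$wm > 0]))
  }
  t1 <- means("T1w"); expect_true(t1["wm"] > t1["gm"] && t1["gm"] > t1["csf"])
  t1c <- means("T1wce"); expect_true(t1c["wm"] > t1c["gm"] && t1c["gm"] > t1c["csf"])
  t2 <- means("T2w"); expect_true(t2["csf"] > t2["gm"] && t2["gm"] > t2["wm"])
  fl <- means("FLAIR"); expect_true(fl["gm"] > fl["wm"] && fl["wm"] > fl["csf"])
})

test_that("T1wce tumour rim is enhanced relative to core", {
  co <- clean_cohort()
  g <- co$geometry
  v <- co$volumes$T1wce[[3]]$voxels
  expect_gt(mean(v[g$roi_rim]), mean(v[g$roi_core]) + 100)
})

test_that("scanner effect is the stated affine/bias/noise composition", {
  co <- clean_cohort()
  v <- co$volumes$T1w[[1]]
  id <- apply_scanner_effect(v, gain = 1, offset = 0, bias_amplitude = 0,
                             noise_sd = 0, seed = 1)
  expect_equal(id$voxels, v$voxels)
  m <- co$masks$p001$brain > 0
  g2 <- apply_scanner_effect(v, gain = 2, offset = 0, bias_amplitude = 0,
                             noise_sd = 0, seed = 1)
  expect_equal(mean(g2$voxels[m]), 2 * mean(v$voxels[m]), tolerance = 1e-12)
  # determinism of noise and bias
  n1 <- apply_scanner_effect(v, 1.2, 5, 0.2, 8, seed = 77)
  n2 <- apply_scanner_effect(v, 1.2, 5, 0.2, 8, seed = 77)
  expect_identical(n1$voxels, n2$voxels)
})

test_that("batch gain differences separate raw ROI means almost perfectly", {
  co <- clean_cohort()
  roi <- co$masks$p001$roi > 0
  half <- seq_len(10)
  roi_mean <- vapply(seq_len(20), function(i) {
    g <- if (i %in% half) 1 else 3
    v <- apply_scanner_effect(co$volumes$T1w[[i]], gain = g, offset = 0,
                              bias_amplitude = 0, noise_sd = 5,
                              seed = 1000 + i)
    mean(v$voxels[roi])
  }, 0)
  lab <- as.integer(!(seq_len(20) %in% half))
  # rank-based AUC of the two-group separation
  r <- rank(roi_mean)
  auc <- (sum(r[lab == 1]) - sum(lab) * (sum(lab) + 1) / 2) /
    (sum(lab) * sum(lab == 0))
  expect_gt(auc, 0.95)
})

test_that("batch effects at default magnitudes are ANOVA-visible on raw ROI means", {
  co <- tiny_cohort()
  roi <- co$masks$p001$roi > 0
  roi_mean <- vapply(co$volumes$T1wce, function(v) mean(v$voxels[roi]), 0)
  p <- summary(stats::aov(roi_mean ~ co$clinical$batch_id))[[1]][1, "Pr(>F)"]
  expect_lt(p, 0.01)
})

test_that("survival simulation honours censoring settings and recovers the planted hazard", {
  cfg <- cohort_config(n_patients = 500, censoring_rate = 0, seed = 5)
  a <- rnorm(500)
  age <- rnorm(500, 55, 10)
  grade <- sample(c("III", "IV"), 500, replace = TRUE)
  cfg$effect_size_beta_a <- 1
  s0 <- simulate_survival(a, age, grade, cfg, seed = 2)
  expect_true(all(s0$event == 1L))
  fit <- survival::coxph(survival::Surv(s0$os_days, s0$event) ~ a)
  expect_lt(abs(coef(fit)[1] - 1), 0.15)
  # censoring calibration
  cfg$censoring_rate <- 0.3
  s3 <- simulate_survival(a, age, grade, cfg, seed = 2)
  expect_lt(abs(mean(1 - s3$event) - 0.3), 0.07)
})

test_that("ROI variance increases with the latent aggressiveness", {
  rhos <- vapply(c(11, 12, 13), function(s) {
    co <- generate_cohort(cohort_config(
      n_patients = 40, sequences = "FLAIR", grid_shape = c(32, 32, 32),
      batch_gain_sd = 0, batch_offset_sd = 0, bias_field_amplitude = 0,
      noise_sd = 5, seed = s))
    roi <- co$masks$p001$roi > 0
    v <- vapply(co$volumes$FLAIR, function(x) var(x$voxels[roi]), 0)
    cor(v, co$truth$latent_a, method = "spearman")
  }, 0)
  expect_gt(mean(rhos), 0.5)
})

test_that("ROI too large for the white-matter shell is rejected", {
  expect_error(phantom_geometry(c(32, 32, 32), c(2, 2, 2),
                                roi_radius_mm = 40), "ROI")
})

test_that("cohort round-trips through NIfTI and CSV", {
  co <- tiny_cohort()
  dir <- tempfile("cohort")
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "p001_T1wce.nii.gz")))
  v <- read_volume_nifti(file.path(dir, "p001_T1wce.nii.gz"),
                         sequence = "T1wce", patient_id = "p001")
  expect_equal(v$voxels, co$volumes$T1wce[[1]]$voxels, tolerance = 1e-6)
  cl <- read.csv(file.path(dir, "clinical.csv"))
  expect_equal(nrow(cl), 20)
  expect_false("latent_a" %in% names(cl))
  unlink(dir, recursive = TRUE)
})
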