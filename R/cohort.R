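# Synthetic multi-scanner brain-phantom cohort with planted prognostic
# tumour texture and simulated overall survival. Stands in for multi-scanner
# glioma cohorts whose images are not publicly available: the phantom has
# known tissue geometry, a tumour whose texture encodes a latent
# aggressiveness variable, scanner batch effects, and survival drawn from a
# proportional-hazards model on that variable plus age and grade.

#' Configuration for a synthetic phantom cohort
#'
#' @param n_patients number of patients (>= 20)
#' @param n_batches number of scanner batches (>= 2)
#' @param sequences subset of c("T1w","T1wce","T2w","FLAIR")
#' @param grid_shape voxel grid, default 64^3
#' @param spacing_mm voxel spacing in mm, default 2 mm isotropic
#' @param effect_size_beta_a log-hazard per unit latent aggressiveness
#' @param beta_age log-hazard per year of age (centred)
#' @param grade_effect log-hazard offset for grade IV vs III
#' @param censoring_rate target fraction censored, in [0, 1)
#' @param batch_gain_sd sd of log multiplicative scanner gain
#' @param batch_offset_sd sd of additive scanner offset (intensity units)
#' @param bias_field_amplitude relative amplitude of the smooth polynomial
#'   bias field (0 disables)
#' @param noise_sd sd of additive Gaussian scanner noise (intensity units)
#' @param roi_radius_mm tumour sphere radius in mm
#' @param seed master integer seed
#' @return object of class `cohort_config`
#' @export
cohort_config <- function(n_patients = 120, n_batches = 4,
                          sequences = c("T1w", "T1wce", "T2w", "FLAIR"),
                          grid_shape = c(64, 64, 64), spacing_mm = c(2, 2, 2),
                          effect_size_beta_a = 0.8, beta_age = 0.02,
                          grade_effect = 0.5, censoring_rate = 0.3,
                          batch_gain_sd = 0.3, batch_offset_sd = 20,
                          bias_field_amplitude = 0.15, noise_sd = 10,
                          roi_radius_mm = 9, seed = 1L) {
  stopifnot(n_patients >= 20, n_batches >= 2,
            all(sequences %in% c("T1w", "T1wce", "T2w", "FLAIR")),
            length(grid_shape) == 3, all(grid_shape >= 24),
            all(spacing_mm > 0), censoring_rate >= 0, censoring_rate < 1,
            batch_gain_sd >= 0, batch_offset_sd >= 0,
            bias_field_amplitude >= 0, noise_sd >= 0)
  structure(list(n_patients = as.integer(n_patients),
                 n_batches = as.integer(n_batches),
                 sequences = sequences, grid_shape = as.integer(grid_shape),
                 spacing_mm = as.numeric(spacing_mm),
                 effect_size_beta_a = effect_size_beta_a, beta_age = beta_age,
                 grade_effect = grade_effect, censoring_rate = censoring_rate,
                 batch_gain_sd = batch_gain_sd, batch_offset_sd = batch_offset_sd,
                 bias_field_amplitude = bias_field_amplitude,
                 noise_sd = noise_sd, roi_radius_mm = roi_radius_mm,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Healthy-tissue mean intensities (arbitrary units) per sequence, encoding
# the clinical contrast orderings: T1w/T1wce wm > gm > csf; T2w csf > gm >
# wm; FLAIR gm > wm > csf (csf attenuated). Tumour sits in white matter.
tissue_intensity_table <- function(sequence) {
  switch(sequence,
    T1w   = c(csf = 120, gm = 320, wm = 450, tumor = 280, rim = 280),
    T1wce = c(csf = 120, gm = 320, wm = 450, tumor = 280, rim = 560),
    T2w   = c(csf = 500, gm = 300, wm = 200, tumor = 380, rim = 380),
    FLAIR = c(csf = 80,  gm = 340, wm = 280, tumor = 400, rim = 400),
    stop("unknown sequence: ", sequence))
}

# Normalised ellipsoidal radius field on the voxel grid.
ellipsoid_r <- function(d, centre, semi_axes) {
  x <- (seq_len(d[1]) - centre[1]) / semi_axes[1]
  y <- (seq_len(d[2]) - centre[2]) / semi_axes[2]
  z <- (seq_len(d[3]) - centre[3]) / semi_axes[3]
  sqrt(outer(outer(x^2, y^2, `+`), z^2, `+`))
}

#' Build the phantom tissue geometry for one grid
#'
#' Nested ellipsoids: a thin peripheral csf rim, a gm ribbon, a wm
#' interior, and a central csf ventricle; a spherical tumour ROI (core +
#' rim) is embedded in white matter.
#'
#' @param grid_shape voxel triple
#' @param spacing_mm spacing triple
#' @param roi_radius_mm tumour radius in mm
#' @return list of binary/membership arrays: brain, csf, gm, wm, roi,
#'   roi_core, roi_rim (all on the grid)
#' @export
phantom_geometry <- function(grid_shape = c(64, 64, 64), spacing_mm = c(2, 2, 2),
                             roi_radius_mm = 9) {
  d <- grid_shape
  centre <- (d + 1) / 2
  semi <- 0.42 * d * c(1.05, 0.92, 1.0)
  r <- ellipsoid_r(d, centre, semi)
  brain <- r <= 1
  csf_rim <- brain & r > 0.92
  gm <- brain & r <= 0.92 & r > 0.75
  wm <- brain & r <= 0.75
  # central ventricle (csf)
  vr <- ellipsoid_r(d, centre, 0.16 * d)
  vent <- vr <= 1
  wm <- wm & !vent
  csf <- csf_rim | (vent & brain)
  # tumour: sphere centred in the wm shell, offset along +x
  roi_r_vox <- roi_radius_mm / spacing_mm
  tc <- centre + c(0.40 * semi[1], 0, 0)
  tr <- ellipsoid_r(d, tc, roi_r_vox)
  roi <- tr <= 1
  if (sum(roi) < 64)
    stop("phantom_geometry: ROI smaller than 64 voxels; increase roi_radius_mm")
  if (any(roi & !(wm | vent)))
    if (mean(roi & !wm) > 0.02)
      stop("phantom_geometry: ROI does not fit inside white matter")
  roi_core <- tr <= 0.6
  roi_rim <- roi & !roi_core
  list(brain = brain, csf = csf & !roi, gm = gm & !roi, wm = wm & !roi,
       roi = roi, roi_core = roi_core, roi_rim = roi_rim)
}

# Gaussian random field on the ROI bounding box: white noise smoothed with
# a Gaussian kernel of sd `ell` voxels, rescaled to unit variance on the ROI.
roi_texture_field <- function(roi, ell, seed) {
  idx <- which(roi, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - 4L, 1L)
  hi <- pmin(apply(idx, 2, max) + 4L, dim(roi))
  dd <- hi - lo + 1L
  wn <- with_seed(seed, array(rnorm(prod(dd)), dd))
  sm <- gauss_smooth(wn, rep(ell, 3))
  box_roi <- roi[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  v <- sm[box_roi]
  sm <- (sm - mean(v)) / max(sd(v), 1e-12)
  field <- array(0, dim(roi))
  field[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sm
  field[!roi] <- 0
  field
}

#' Apply a multiplicative/additive scanner effect to a volume
#'
#' `output = bias_field * (gain * I + offset) + noise`, with a smooth
#' low-order polynomial bias field and additive Gaussian noise, emulating
#' the scanner-dependent arbitrary units of MR intensities. Deterministic
#' given `seed`.
#'
#' @param vol a `scan_volume`
#' @param gain multiplicative gain (> 0)
#' @param offset additive offset
#' @param bias_amplitude relative bias-field amplitude (0 disables)
#' @param noise_sd additive Gaussian noise sd (0 disables)
#' @param seed integer seed for bias coefficients and noise
#' @return a `scan_volume`
#' @export
apply_scanner_effect <- function(vol, gain = 1, offset = 0,
                                 bias_amplitude = 0, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(vol, "scan_volume"), gain > 0)
  d <- dim(vol$voxels)
  out <- gain * vol$voxels + offset
  if (bias_amplitude > 0) {
    cf <- with_seed(seed, runif(9, -1, 1))
    x <- seq(-1, 1, length.out = d[1])
    y <- seq(-1, 1, length.out = d[2])
    z <- seq(-1, 1, length.out = d[3])
    px <- cf[1] * x + cf[4] * x^2
    py <- cf[2] * y + cf[5] * y^2
    pz <- cf[3] * z + cf[6] * z^2
    pol <- outer(outer(px, py, `+`), pz, `+`) +
      cf[7] * outer(outer(x, y), rep(1, d[3])) +
      cf[8] * outer(outer(x, rep(1, d[2])), z) +
      cf[9] * outer(outer(rep(1, d[1]), y), z)
    pol <- pol / max(abs(pol), 1e-12)
    out <- (1 + bias_amplitude * pol) * out
  }
  if (noise_sd > 0)
    out <- out + with_seed(derive_seed(seed, 1L), array(rnorm(prod(d), 0, noise_sd), d))
  scan_volume(out, vol$spacing_mm, vol$sequence, vol$patient_id, vol$batch_id,
              meta = c(vol$meta, list(scanner_gain = gain, scanner_offset = offset)))
}

#' Simulate survival times from a proportional-hazards model
#'
#' Exponential event times with rate
#' `lambda0 * exp(beta_a * a + beta_age * (age - mean(age)) + grade_effect * 1[grade IV])`
#' and independent uniform censoring on `[0, c_max]`, with `c_max` calibrated
#' by bisection so the realised censoring fraction matches the target.
#'
#' @param latent_a numeric vector of latent aggressiveness values
#' @param age numeric vector of ages (years)
#' @param grade character vector, "III" or "IV"
#' @param config a `cohort_config` (betas, censoring rate)
#' @param seed integer seed
#' @param lambda0 baseline hazard per day (default gives ~300-day median
#'   survival at covariate zero)
#' @return data.frame with os_days and event
#' @export
simulate_survival <- function(latent_a, age, grade, config, seed = 1L,
                              lambda0 = log(2) / 300) {
  n <- length(latent_a)
  lp <- config$effect_size_beta_a * latent_a +
    config$beta_age * (age - mean(age)) +
    config$grade_effect * as.numeric(grade == "IV")
  tt <- with_seed(seed, rexp(n, rate = lambda0 * exp(lp)))
  tt <- pmax(tt, 1)
  if (config$censoring_rate <= 0)
    return(data.frame(os_days = tt, event = 1L))
  u <- with_seed(derive_seed(seed, 1L), runif(n))
  cens_frac <- function(cmax) mean(u * cmax < tt)   # decreasing in cmax
  lo <- 1; hi <- max(tt) * 4
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (cens_frac(mid) > config$censoring_rate) lo <- mid else hi <- mid
  }
  cmax <- (lo + hi) / 2
  cens <- u * cmax
  data.frame(os_days = pmax(pmin(tt, cens), 1),
             event = as.integer(tt <= cens))
}

#' Generate a complete synthetic multi-scanner cohort
#'
#' Produces per-sequence phantom volumes with scanner batch effects, the
#' shared tissue/ROI mask set, a clinical table, and the hidden ground truth
#' (latent aggressiveness and true hazard coefficients) kept separate from
#' the clinical table so analyses cannot accidentally use it.
#'
#' The tumour texture is a Gaussian random field whose amplitude and
#' correlation length are affine in the patient's latent aggressiveness, so
#' ROI intensity variance and spatial correlation increase monotonically
#' with the prognostic variable; on T1wce the tumour rim is
#' contrast-enhanced.
#'
#' @param config a `cohort_config`
#' @return list with elements `volumes` (named list per sequence of lists of
#'   `scan_volume`), `masks` (per-patient list: brain, csf, gm, wm, roi),
#'   `clinical` (data.frame), `truth` (data.frame with latent_a and betas)
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  geom <- phantom_geometry(config$grid_shape, config$spacing_mm,
                           config$roi_radius_mm)
  pid <- sprintf("p%03d", seq_len(n))
  batch_levels <- sprintf("b%02d", seq_len(config$n_batches))
  # covariates drawn to roughly match typical HGG cohorts (61% male,
  # grade IV majority)
  demo <- with_seed(derive_seed(config$seed, 2L), {
    age <- pmin(pmax(rnorm(n, 55, 12), 18), 85)
    gender <- ifelse(runif(n) < 0.61, "M", "F")
    grade <- ifelse(runif(n) < 0.64, "IV", "III")
    batch <- batch_levels[rep_len(seq_len(config$n_batches), n)][sample.int(n)]
    list(age = age, gender = gender, grade = grade, batch = batch)
  })
  latent_a <- with_seed(derive_seed(config$seed, 3L), rnorm(n))
  surv <- simulate_survival(latent_a, demo$age, demo$grade, config,
                            seed = derive_seed(config$seed, 4L))
  clinical <- data.frame(patient_id = pid, os_days = surv$os_days,
                         event = surv$event, age = demo$age,
                         gender = demo$gender, grade = demo$grade,
                         batch_id = demo$batch, stringsAsFactors = FALSE)
  truth <- data.frame(patient_id = pid, latent_a = latent_a,
                      beta_a = config$effect_size_beta_a,
                      beta_age = config$beta_age,
                      grade_effect = config$grade_effect,
                      stringsAsFactors = FALSE)
  # per-batch scanner parameters
  bp <- with_seed(derive_seed(config$seed, 5L), list(
    gain = exp(rnorm(config$n_batches, 0, config$batch_gain_sd)),
    offset = rnorm(config$n_batches, 0, config$batch_offset_sd)))
  names(bp$gain) <- names(bp$offset) <- batch_levels

  # texture parameters affine in latent aggressiveness
  amp <- pmax(40 + 15 * latent_a, 2)
  ell <- pmax(1.5 + 0.3 * latent_a, 0.5)

  masks <- list()
  volumes <- stats::setNames(vector("list", length(config$sequences)),
                             config$sequences)
  for (s in config$sequences) volumes[[s]] <- vector("list", n)

  for (i in seq_len(n)) {
    tex <- roi_texture_field(geom$roi, ell[i],
                             derive_seed(config$seed, 100L + i))
    masks[[pid[i]]] <- list(brain = geom$brain, csf = geom$csf * 1,
                            gm = geom$gm * 1, wm = geom$wm * 1,
                            roi = geom$roi)
    for (si in seq_along(config$sequences)) {
      s <- config$sequences[si]
      ti <- tissue_intensity_table(s)
      img <- array(0, config$grid_shape)
      img[geom$csf] <- ti["csf"]
      img[geom$gm] <- ti["gm"]
      img[geom$wm] <- ti["wm"]
      img[geom$roi_core] <- ti["tumor"]
      img[geom$roi_rim] <- ti["rim"]
      img <- img + amp[i] * tex
      vol <- scan_volume(img, config$spacing_mm, s, pid[i], demo$batch[i])
      b <- demo$batch[i]
      volumes[[s]][[i]] <- apply_scanner_effect(
        vol, gain = bp$gain[[b]], offset = bp$offset[[b]],
        bias_amplitude = config$bias_field_amplitude,
        noise_sd = config$noise_sd,
        seed = derive_seed(config$seed, 1000L + i * 8L + si))
    }
  }
  list(volumes = volumes, masks = masks, clinical = clinical, truth = truth,
       geometry = geom, config = config,
       batch_params = data.frame(batch_id = batch_levels, gain = bp$gain,
                                 offset = bp$offset, row.names = NULL))
}

#' Write a cohort to disk (NIfTI volumes + CSV tables)
#'
#' @param cohort result of [generate_cohort()]
#' @param dir output directory (created if needed)
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in names(cohort$volumes))
    for (v in cohort$volumes[[s]])
      write_volume_nifti(v, file.path(dir, sprintf("%s_%s.nii.gz", v$patient_id, s)))
  for (p in names(cohort$masks)) {
    m <- cohort$masks[[p]]
    write_volume_nifti(m$brain * 1, file.path(dir, sprintf("%s_brain.nii.gz", p)),
                       cohort$config$spacing_mm)
    write_volume_nifti(m$roi * 1, file.path(dir, sprintf("%s_roi.nii.gz", p)),
                       cohort$config$spacing_mm)
  }
  write.csv(cohort$clinical, file.path(dir, "clinical.csv"), row.names = FALSE)
  write.csv(cohort$truth, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  invisible(dir)
}
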