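# Image-based MR intensity normalization. Fourteen variants behind one
# dispatcher: z-score, nine fuzzy-c-means tissue-mask combinations, kernel
# density estimation, Gaussian mixture, Nyul-Udupa histogram matching, and
# white stripe. Feature-level ComBat lives in combat.R; "nn" is the
# no-normalization reference. All statistics are computed strictly inside
# the brain mask; background voxels are set to 0 after normalization.

#' The normalization method identifiers
#'
#' 14 image-based methods, feature-based ComBat, and the no-normalization
#' reference "nn" (16 identifiers in total; 15 normalized datasets + nn).
#' @param image_only if TRUE, return only the 14 image-based methods
#' @return character vector of method ids
#' @export
normalization_methods <- function(image_only = FALSE) {
  img <- c("zscore", "fcm-csf", "fcm-gm", "fcm-wm", "fcm-csf-gm", "fcm-wm-csf",
           "fcm-wm-gm", "fcm-csf-mode", "fcm-wm-mode", "fcm-gm-mode",
           "kde", "gmm", "hm", "ws")
  if (image_only) img else c(img, "combat", "nn")
}

finish_norm <- function(vol, out, brain, method, extra = list()) {
  out[!brain] <- 0
  if (any(!is.finite(out[brain])))
    stop(method, ": non-finite values produced inside brain mask")
  scan_volume(out, vol$spacing_mm, vol$sequence, vol$patient_id, vol$batch_id,
              meta = c(vol$meta, list(norm_method = method), extra))
}

#' Z-score intensity normalization
#'
#' Subtracts the brain-mask mean and divides by the brain-mask sample
#' standard deviation (denominator |B| - 1), so the output brain voxels
#' have mean 0 and sd 1.
#'
#' @param vol a `scan_volume`
#' @param brain logical brain mask
#' @return normalized `scan_volume`
#' @export
zscore_normalize <- function(vol, brain) {
  x <- vol$voxels[brain]
  stopifnot(length(x) >= 2)
  mu <- mean(x); sg <- sd(x)
  if (sg == 0) stop("zscore_normalize: constant image inside brain")
  finish_norm(vol, (vol$voxels - mu) / sg, brain, "zscore",
              list(mu = mu, sigma = sg))
}

#' Fuzzy-c-means tissue-mask normalization (nine variants)
#'
#' Single-tissue (`csf`, `gm`, `wm`): divide by the membership-weighted
#' tissue mean, `I / mu_T`. Two-tissue (`csf-gm`, `wm-csf`, `wm-gm`):
#' `(I - a) / (b - a)` with `a = min(mu_1, mu_2)`, `b = max(mu_1, mu_2)`,
#' mapping the two tissue means to 0 and 1. Tissue + mode (`csf-mode`,
#' `wm-mode`, `gm-mode`): `I / (mu_T - mode(B))`.
#'
#' @param vol a `scan_volume`
#' @param masks list with `brain` plus the needed membership arrays
#'   (`csf`, `gm`, `wm`)
#' @param combo one of "csf","gm","wm","csf-gm","wm-csf","wm-gm",
#'   "csf-mode","wm-mode","gm-mode"
#' @return normalized `scan_volume`
#' @export
fcm_normalize <- function(vol, masks, combo) {
  brain <- masks$brain > 0
  parts <- strsplit(combo, "-", fixed = TRUE)[[1]]
  rng <- diff(range(vol$voxels[brain]))
  if (length(parts) == 1) {
    mu <- tissue_mean(vol, masks[[parts[1]]])
    if (abs(mu) < 1e-12) stop("fcm_normalize: zero tissue mean")
    out <- vol$voxels / mu
  } else if (parts[2] == "mode") {
    mu <- tissue_mean(vol, masks[[parts[1]]])
    md <- image_mode(vol, brain)
    dif <- mu - md
    if (abs(dif) < 1e-8 * max(rng, 1))
      stop("fcm_normalize: degenerate denominator mu_T - mode(B) ~ 0")
    out <- vol$voxels / dif
  } else {
    mu1 <- tissue_mean(vol, masks[[parts[1]]])
    mu2 <- tissue_mean(vol, masks[[parts[2]]])
    a <- min(mu1, mu2); b <- max(mu1, mu2)
    if (b - a < 1e-8 * max(rng, 1)) stop("fcm_normalize: a = b, degenerate")
    out <- (vol$voxels - a) / (b - a)
  }
  finish_norm(vol, out, brain, paste0("fcm-", combo))
}

# Locate the "white matter" histogram peak of the brain intensities.
# Gaussian KDE (Silverman bandwidth) on a 1000-point grid; candidate modes
# are local maxima with density >= 20% of the global maximum; the sequence
# rule picks among them: T1w/T1wce the highest-intensity mode, T2w the
# lowest, FLAIR the middle one.
kde_peak <- function(x, sequence, n_grid = 1000) {
  de <- stats::density(x, bw = "nrd0", n = n_grid)
  y <- de$y
  is_max <- c(FALSE, diff(sign(diff(y))) < 0, FALSE)
  # plateau / boundary guard: also accept global max if no interior mode
  cand <- which(is_max & y >= 0.2 * max(y))
  if (length(cand) == 0) cand <- which.max(y)
  xs <- de$x[cand][order(de$x[cand])]
  k <- length(xs)
  pick <- switch(sequence,
                 T1w = , T1wce = xs[k],
                 T2w = xs[1],
                 FLAIR = xs[ceiling(k / 2)],
                 stop("unknown sequence: ", sequence))
  pick
}

#' Kernel-density-estimation normalization
#'
#' Finds the white-matter peak of the smoothed brain-intensity histogram
#' (Gaussian KDE, Silverman bandwidth, 1000-point grid) and rescales the
#' image so the peak maps to the standard value `c`:
#' `I_norm = c * I / pi`.
#'
#' @param vol a `scan_volume`
#' @param brain logical brain mask
#' @param standard_value the positive constant `c` the peak is mapped to
#' @return normalized `scan_volume`
#' @export
kde_normalize <- function(vol, brain, standard_value = 1.0) {
  x <- vol$voxels[brain]
  if (sd(x) == 0) {
    # degenerate but well-defined: the single value is the peak
    pk <- x[1]
  } else pk <- kde_peak(x, vol$sequence)
  if (abs(pk) < 1e-12) stop("kde_normalize: peak at zero intensity")
  finish_norm(vol, standard_value * vol$voxels / pk, brain, "kde",
              list(peak = pk, standard_value = standard_value))
}

#' Gaussian-mixture-model normalization
#'
#' Fits a three-component univariate Gaussian mixture to the brain-mask
#' intensities (EM, deterministic hierarchical initialisation) and divides
#' by the white-matter component mean so it maps to the standard value.
#' The white-matter component follows the sequence contrast rule
#' (T1w/T1wce highest mean, T2w lowest, FLAIR middle).
#'
#' @param vol a `scan_volume`
#' @param brain logical brain mask
#' @param standard_value target value of the wm component mean
#' @param max_points voxel subsample cap for the EM fit (deterministic)
#' @return normalized `scan_volume`
#' @export
gmm_normalize <- function(vol, brain, standard_value = 1.0, max_points = 20000) {
  x <- vol$voxels[brain]
  if (length(unique(round(x, 10))) < 3)
    stop("gmm_normalize: fewer than 3 distinct intensity levels")
  if (length(x) > max_points)
    x <- with_seed(97L, sample(x, max_points))
  fit <- tryCatch(
    Mclust(x, G = 3, modelNames = "V", verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit) || is.null(fit$parameters))
    stop("gmm_normalize: EM failed to fit a 3-component mixture")
  mu <- sort(fit$parameters$mean)
  k <- length(mu)
  wm <- switch(vol$sequence,
               T1w = , T1wce = mu[k], T2w = mu[1], FLAIR = mu[ceiling(k / 2)],
               stop("unknown sequence: ", vol$sequence))
  if (abs(wm) < 1e-12) stop("gmm_normalize: wm component mean at zero")
  finish_norm(vol, standard_value * vol$voxels / wm, brain, "gmm",
              list(mu_wm = wm, component_means = mu))
}

#' Train Nyul-Udupa histogram-matching landmarks
#'
#' Each training image is affinely rescaled to the standard range anchored
#' at its 1st/99th percentiles; landmark intensities at the quantile levels
#' are then averaged across images to give the reference standard scale.
#'
#' @param volumes list of `scan_volume`
#' @param brains list of logical brain masks (same order)
#' @param quantile_levels ordered quantile levels in (0,1); default deciles
#'   plus the 1st and 99th percentiles
#' @param standard_range numeric length-2, default c(0, 100)
#' @return object of class `hm_landmarks`: quantile levels and reference
#'   values (strictly increasing)
#' @export
hm_train <- function(volumes, brains,
                     quantile_levels = c(0.01, seq(0.1, 0.9, by = 0.1), 0.99),
                     standard_range = c(0, 100)) {
  stopifnot(length(volumes) >= 1, length(volumes) == length(brains),
            !is.unsorted(quantile_levels, strictly = TRUE))
  lm <- sapply(seq_along(volumes), function(i) {
    x <- volumes[[i]]$voxels[brains[[i]]]
    p <- quantile(x, c(0.01, 0.99), names = FALSE)
    if (p[2] <= p[1]) stop("hm_train: degenerate intensity range in image ", i)
    q <- quantile(x, quantile_levels, names = FALSE)
    standard_range[1] + (q - p[1]) / (p[2] - p[1]) * diff(standard_range)
  })
  ref <- rowMeans(as.matrix(lm))
  if (is.unsorted(ref, strictly = TRUE))
    stop("hm_train: averaged landmarks not strictly increasing")
  structure(list(quantile_levels = quantile_levels, reference_values = ref,
                 standard_range = standard_range, n_train = length(volumes)),
            class = "hm_landmarks")
}

#' Apply histogram-matching normalization
#'
#' Piecewise-linear intensity map sending the input image's landmark
#' intensities (at the trained quantile levels) to the reference values,
#' with linear extrapolation beyond the extreme landmarks.
#'
#' @param vol a `scan_volume`
#' @param brain logical brain mask
#' @param landmarks an `hm_landmarks` object from [hm_train()]
#' @return normalized `scan_volume`
#' @export
hm_apply <- function(vol, brain, landmarks) {
  stopifnot(inherits(landmarks, "hm_landmarks"))
  x <- vol$voxels[brain]
  inl <- quantile(x, landmarks$quantile_levels, names = FALSE)
  if (is.unsorted(inl, strictly = TRUE)) {
    # collapse exact duplicates from discrete images; fail if fully constant
    keep <- c(TRUE, diff(inl) > 0)
    if (sum(keep) < 2) stop("hm_apply: input landmarks not increasing (constant image)")
    inl_u <- inl[keep]; ref_u <- landmarks$reference_values[keep]
  } else {
    inl_u <- inl; ref_u <- landmarks$reference_values
  }
  out <- piecewise_linear(vol$voxels, inl_u, ref_u)
  finish_norm(vol, out, brain, "hm", list(input_landmarks = inl))
}

# piecewise-linear map with linear extrapolation from the end segments
piecewise_linear <- function(v, xk, yk) {
  n <- length(xk)
  i <- findInterval(v, xk, all.inside = TRUE)
  x0 <- xk[i]; x1 <- xk[i + 1]; y0 <- yk[i]; y1 <- yk[i + 1]
  y0 + (v - x0) * (y1 - y0) / (x1 - x0)
}

#' White-stripe intensity normalization
#'
#' Locates the largest (sequence-appropriate) peak `mu` of the smoothed
#' brain-intensity histogram; the white stripe is the voxel set whose
#' empirical-CDF values lie within `tau` of F(mu); the image is shifted by
#' `mu` and scaled by the stripe's sample standard deviation:
#' `I_norm = (I - mu) / sigma_ws`. Voxels at intensity `mu` map to 0.
#'
#' @param vol a `scan_volume`
#' @param brain logical brain mask
#' @param tau CDF half-width, default 0.05 (a 10% stripe)
#' @return normalized `scan_volume`
#' @export
whitestripe_normalize <- function(vol, brain, tau = 0.05) {
  stopifnot(tau > 0, tau < 0.5)
  x <- vol$voxels[brain]
  if (sd(x) == 0) stop("whitestripe_normalize: constant image inside brain")
  mu <- kde_peak(x, vol$sequence)
  Fn <- stats::ecdf(x)
  fmu <- Fn(mu)
  lo <- quantile(x, max(fmu - tau, 0), names = FALSE)
  hi <- quantile(x, min(fmu + tau, 1), names = FALSE)
  stripe <- x[x > lo & x < hi]
  if (length(stripe) < 10) stop("whitestripe_normalize: stripe has < 10 voxels")
  sg <- sd(stripe)
  if (sg == 0) stop("whitestripe_normalize: zero stripe variance")
  finish_norm(vol, (vol$voxels - mu) / sg, brain, "ws",
              list(mu_peak = mu, sigma_ws = sg, tau = tau,
                   stripe_frac = length(stripe) / length(x)))
}

#' Normalize a per-sequence set of volumes with one method
#'
#' Dispatcher over the image-based methods. `hm` first trains the reference
#' landmarks on the whole set (per sequence); `nn` returns the input
#' unchanged apart from provenance. ComBat is feature-level and handled
#' downstream, so it is rejected here.
#'
#' @param volumes list of `scan_volume` (one sequence)
#' @param masks named per-patient list; each element has `brain` and, for
#'   mask-based methods, `csf`/`gm`/`wm` membership arrays
#' @param method a method id from [normalization_methods()]
#' @param ... passed to the individual normalizers
#' @return list of normalized `scan_volume` with method provenance
#' @export
normalize_dataset <- function(volumes, masks, method, ...) {
  if (!method %in% normalization_methods())
    stop("unknown normalization method: ", method)
  if (method == "combat")
    stop("combat is feature-level; apply combat_fit_apply() to feature tables")
  get_masks <- function(v) masks[[v$patient_id]]
  if (method == "nn") {
    return(lapply(volumes, function(v) {
      v$meta$norm_method <- "nn"; v
    }))
  }
  if (method == "hm") {
    brains <- lapply(volumes, function(v) get_masks(v)$brain > 0)
    lmk <- hm_train(volumes, brains, ...)
    return(lapply(seq_along(volumes), function(i)
      hm_apply(volumes[[i]], brains[[i]], lmk)))
  }
  lapply(volumes, function(v) {
    m <- get_masks(v)
    brain <- m$brain > 0
    if (method == "zscore") zscore_normalize(v, brain)
    else if (startsWith(method, "fcm-"))
      fcm_normalize(v, m, sub("^fcm-", "", method))
    else if (method == "kde") kde_normalize(v, brain, ...)
    else if (method == "gmm") gmm_normalize(v, brain, ...)
    else if (method == "ws") whitestripe_normalize(v, brain, ...)
    else stop("unhandled method: ", method)
  })
}
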