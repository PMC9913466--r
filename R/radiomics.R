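# ROI-restricted IBSI-style radiomics: resampling, derived images
# (undecimated coif1 wavelet sub-bands, Laplacian of Gaussian), bin-count
# discretization, and the feature classes with their reference counts:
# 19 first-order, 16 3D shape, 24 GLCM, 16 GLRLM, 16 GLSZM, 5 NGTDM,
# 14 GLDM. Intensity features are computed on each derived image at each
# bin count; shape is computed once from the (non-derived) ROI mask.

#' Radiomics extraction configuration
#'
#' @param bin_counts strictly increasing vector of 5 bin counts; the
#'   default doubling ladder 8,16,32,64,128 brackets the commonly shown 32
#' @param log_sigmas_mm Laplacian-of-Gaussian scales in mm
#' @param resample_spacing_mm target isotropic spacing in mm
#' @param images which derived images to use: "all" or a subset of the
#'   tags from [derive_images()] (scaled-down runs use fewer)
#' @param include_shape compute the 16 shape features (they are constant
#'   across patients when every phantom shares one ROI geometry, so
#'   scaled-down runs may skip them)
#' @return object of class `extraction_config`
#' @export
extraction_config <- function(bin_counts = c(8, 16, 32, 64, 128),
                              log_sigmas_mm = c(2, 3, 4),
                              resample_spacing_mm = c(2, 2, 2),
                              images = "all", include_shape = TRUE) {
  stopifnot(!is.unsorted(bin_counts, strictly = TRUE), all(bin_counts >= 1),
            all(log_sigmas_mm > 0), all(resample_spacing_mm > 0))
  structure(list(bin_counts = as.integer(bin_counts),
                 log_sigmas_mm = log_sigmas_mm,
                 resample_spacing_mm = resample_spacing_mm,
                 images = images, include_shape = isTRUE(include_shape),
                 glcm_distance = 1L, wavelet_levels = 1L),
            class = "extraction_config")
}

#' Reference feature counts per class
#' @return named integer vector
#' @export
feature_class_counts <- function() {
  c(firstorder = 19L, shape = 16L, glcm = 24L, glrlm = 16L, glszm = 16L,
    ngtdm = 5L, gldm = 14L)
}

# ---------------------------------------------------------------- resampling

interp_axis <- function(a, old_x, new_x, axis, method = "spline") {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = d[axis])
  out <- apply(m, 2, function(col) {
    if (method == "spline") stats::spline(old_x, col, xout = new_x,
                                          method = "fmm")$y
    else stats::approx(old_x, col, xout = new_x, rule = 2)$y
  })
  out <- array(out, c(length(new_x), d[perm[2]], d[perm[3]]))
  aperm(out, order(perm))
}

#' Resample a volume (and masks) to a target spacing
#'
#' Image interpolated with cubic splines, masks with linear interpolation
#' followed by thresholding at 0.5. A volume already on the target grid is
#' returned unchanged.
#'
#' @param vol a `scan_volume`
#' @param masks optional named list of mask arrays (binary or membership)
#' @param spacing_mm target spacing, default 2 mm isotropic
#' @return list with `vol` (resampled `scan_volume`) and `masks`
#' @export
resample_volume <- function(vol, masks = NULL, spacing_mm = c(2, 2, 2)) {
  stopifnot(all(spacing_mm > 0))
  if (isTRUE(all.equal(vol$spacing_mm, as.numeric(spacing_mm))))
    return(list(vol = vol, masks = masks))
  d <- dim(vol$voxels)
  a <- vol$voxels
  rmask <- masks
  for (ax in 1:3) {
    old_x <- (seq_len(dim(a)[ax]) - 1) * vol$spacing_mm[ax]
    extent <- (d[ax] - 1) * vol$spacing_mm[ax]
    n_new <- max(2L, floor(extent / spacing_mm[ax]) + 1L)
    new_x <- (seq_len(n_new) - 1) * spacing_mm[ax]
    a <- interp_axis(a, old_x, new_x, ax, "spline")
    if (!is.null(rmask))
      rmask <- lapply(rmask, function(m) {
        interp_axis(m * 1, old_x, new_x, ax, "linear")
      })
  }
  if (!is.null(rmask)) {
    rmask <- lapply(rmask, function(m) m >= 0.5)
    if (!is.null(rmask$roi) && sum(rmask$roi) == 0)
      stop("resample_volume: ROI vanished after resampling")
  }
  out <- scan_volume(a, spacing_mm, vol$sequence, vol$patient_id,
                     vol$batch_id, vol$meta)
  list(vol = out, masks = rmask)
}

# ------------------------------------------------------------ derived images

# coiflet-1 decomposition filters (low/high pass)
coif1_filters <- function() {
  lo <- c(-0.015655728135465, -0.072732619512854, 0.384864846864203,
          0.852572020212255, 0.337897662457809, -0.072732619512854)
  n <- length(lo)
  hi <- (-1)^(0:(n - 1)) * rev(lo)
  list(lo = lo, hi = hi)
}

#' Derived images for radiomics extraction
#'
#' Returns 12 tagged images: the original, the 8 single-level undecimated
#' 3D wavelet sub-bands (coiflet-1; every low/high-pass combination across
#' the three axes, dimensions preserved), and Laplacian-of-Gaussian images
#' at the configured scales (sigma in mm, applied in physical units).
#'
#' @param vol a `scan_volume`
#' @param log_sigmas_mm LoG scales in mm
#' @param images "all" or a subset of tags; unrequested filter banks are
#'   not computed
#' @return named list of 3D arrays, tags `original`, `wavelet-LLL` ...
#'   `wavelet-HHH`, `log-2` ...
#' @export
derive_images <- function(vol, log_sigmas_mm = c(2, 3, 4), images = "all") {
  a <- vol$voxels
  if (any(dim(a) < 6))
    stop("derive_images: volume smaller than the wavelet filter support")
  all_imgs <- identical(images, "all")
  want <- function(tag) all_imgs || tag %in% images
  out <- list()
  if (want("original")) out$original <- a
  wv <- paste0("wavelet-", c("LLL", "LLH", "LHL", "LHH",
                             "HLL", "HLH", "HHL", "HHH"))
  if (all_imgs || any(wv %in% images)) {
    f <- coif1_filters()
    # separable cascade: axis 1, then 2, then 3
    lvl1 <- list(L = conv_axis(a, f$lo, 1), H = conv_axis(a, f$hi, 1))
    lvl2 <- list()
    for (n1 in names(lvl1)) {
      lvl2[[paste0(n1, "L")]] <- conv_axis(lvl1[[n1]], f$lo, 2)
      lvl2[[paste0(n1, "H")]] <- conv_axis(lvl1[[n1]], f$hi, 2)
    }
    for (n2 in names(lvl2)) {
      for (n3 in c("L", "H")) {
        tag <- paste0("wavelet-", n2, n3)
        if (want(tag))
          out[[tag]] <- conv_axis(lvl2[[n2]],
                                  if (n3 == "L") f$lo else f$hi, 3)
      }
    }
    out <- out[c(intersect("original", names(out)), intersect(wv, names(out)))]
  }
  for (s in log_sigmas_mm) {
    tag <- sprintf("log-%g", s)
    if (!want(tag)) next
    sm <- gauss_smooth(a, s / vol$spacing_mm)
    lap <- array(0, dim(a))
    for (ax in 1:3)
      lap <- lap + conv_axis(sm, c(1, -2, 1) / vol$spacing_mm[ax]^2, ax)
    out[[tag]] <- lap
  }
  out
}

# ------------------------------------------------------------- discretization

#' Bin-count discretization of ROI intensities
#'
#' Equal-width bins spanning the ROI intensity range:
#' `label = floor((I - min) / width) + 1` with the maximum clamped to
#' `bin_count`. Labels are 0 outside the ROI.
#'
#' @param vol a `scan_volume` or 3D array
#' @param roi logical ROI mask
#' @param bin_count number of gray levels
#' @return integer array of labels (0 outside ROI, 1..bin_count inside)
#' @export
discretize_roi <- function(vol, roi, bin_count) {
  a <- if (inherits(vol, "scan_volume")) vol$voxels else vol
  stopifnot(sum(roi) > 0, bin_count >= 1)
  x <- a[roi]
  rg <- range(x)
  if (rg[1] == rg[2]) stop("discretize_roi: constant ROI (degenerate range)")
  w <- (rg[2] - rg[1]) / bin_count
  lab <- array(0L, dim(a))
  lab[roi] <- pmin(as.integer(floor((x - rg[1]) / w)) + 1L, as.integer(bin_count))
  lab
}

# ------------------------------------------------------------- first order

#' First-order intensity statistics (19 features)
#'
#' Computed from the raw ROI intensities plus the discretized labels
#' (entropy and uniformity are histogram-based). Population denominators
#' (n) are used for variance-type features.
#'
#' @param x numeric vector of ROI intensities
#' @param labels integer vector of discretized ROI labels (same length)
#' @param voxel_volume_mm3 physical voxel volume, for total energy
#' @return named numeric vector of length 19
#' @export
first_order_features <- function(x, labels = rep(1L, length(x)),
                                 voxel_volume_mm3 = 1) {
  n <- length(x)
  stopifnot(n > 0, length(labels) == n)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  p <- tabulate(labels)
  p <- p[p > 0] / n
  q <- quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
  rob <- x[x >= q[1] & x <= q[5]]
  c(Energy = sum(x^2),
    TotalEnergy = voxel_volume_mm3 * sum(x^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(x),
    P10 = q[1],
    P90 = q[5],
    Maximum = max(x),
    Mean = mu,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(rob - mean(rob))),
    RootMeanSquared = sqrt(mean(x^2)),
    StandardDeviation = sqrt(m2),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2))
}

# ------------------------------------------------------------------- shape

# marching-tetrahedra iso-surface (level 0.5) of a scalar field; returns
# total triangle area and enclosed volume (divergence theorem, outward
# orientation). Field must be 0 on the array border.
mt_mesh_measures <- function(field, spacing) {
  d <- dim(field)
  corner_off <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                      c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  tets <- rbind(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
                c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))
  iso <- 0.5
  # corner value arrays for each cube
  nc <- d - 1L
  cube_vals <- lapply(seq_len(8), function(ci) {
    o <- corner_off[ci, ]
    field[(1 + o[1]):(nc[1] + o[1]), (1 + o[2]):(nc[2] + o[2]),
          (1 + o[3]):(nc[3] + o[3])]
  })
  inside_any <- Reduce(`|`, lapply(cube_vals, function(v) v > iso))
  inside_all <- Reduce(`&`, lapply(cube_vals, function(v) v > iso))
  mixed <- which(inside_any & !inside_all)
  area <- 0; vol6 <- 0
  if (length(mixed) == 0) return(list(area = 0, volume = 0))
  mi <- arrayInd(mixed, nc)
  vals8 <- sapply(cube_vals, function(v) v[mixed])   # nmix x 8
  if (length(mixed) == 1) vals8 <- matrix(vals8, nrow = 1)
  cross3 <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                             u[3] * v[1] - u[1] * v[3],
                             u[1] * v[2] - u[2] * v[1])
  for (ci in seq_along(mixed)) {
    base <- (mi[ci, ] - 1)
    fv <- vals8[ci, ]
    for (t in 1:6) {
      vidx <- tets[t, ]
      f4 <- fv[vidx]
      ins <- f4 > iso
      nin <- sum(ins)
      if (nin == 0 || nin == 4) next
      P4 <- (corner_off[vidx, , drop = FALSE] +
               matrix(base, 4, 3, byrow = TRUE)) *
        matrix(spacing, 4, 3, byrow = TRUE)
      mp <- function(a, b) {
        tt <- (iso - f4[a]) / (f4[b] - f4[a])
        P4[a, ] + tt * (P4[b, ] - P4[a, ])
      }
      tris <- list()
      if (nin == 1) {
        A <- which(ins); O <- which(!ins)
        tris[[1]] <- rbind(mp(A, O[1]), mp(A, O[2]), mp(A, O[3]))
        ref_out <- colMeans(P4[O, , drop = FALSE]) - P4[A, ]
      } else if (nin == 3) {
        D <- which(!ins); I <- which(ins)
        tris[[1]] <- rbind(mp(D, I[1]), mp(D, I[2]), mp(D, I[3]))
        ref_out <- P4[D, ] - colMeans(P4[I, , drop = FALSE])
      } else {
        I <- which(ins); O <- which(!ins)
        v1 <- mp(I[1], O[1]); v2 <- mp(I[1], O[2])
        v3 <- mp(I[2], O[2]); v4 <- mp(I[2], O[1])
        tris[[1]] <- rbind(v1, v2, v3)
        tris[[2]] <- rbind(v1, v3, v4)
        ref_out <- colMeans(P4[O, , drop = FALSE]) -
          colMeans(P4[I, , drop = FALSE])
      }
      for (tr in tris) {
        nvec <- cross3(tr[2, ] - tr[1, ], tr[3, ] - tr[1, ])
        if (sum(nvec * ref_out) < 0) {
          tr <- tr[c(1, 3, 2), ]
          nvec <- -nvec
        }
        a2 <- sqrt(sum(nvec^2))
        if (a2 == 0) next
        area <- area + 0.5 * a2
        vol6 <- vol6 + sum(tr[1, ] * cross3(tr[2, ], tr[3, ]))
      }
    }
  }
  list(area = area, volume = abs(vol6) / 6)
}

max_pair_dist <- function(P) {
  if (nrow(P) < 2) return(0)
  # max distance over pairs; chunked cross-distances to bound memory
  best <- 0
  n <- nrow(P)
  step <- 512L
  for (s in seq(1, n, by = step)) {
    e <- min(s + step - 1L, n)
    d2 <- outer(rowSums(P[s:e, , drop = FALSE]^2), rowSums(P^2), `+`) -
      2 * P[s:e, , drop = FALSE] %*% t(P)
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}

#' 3D shape features of an ROI mask (16 features)
#'
#' Mesh volume and surface area come from a marching-tetrahedra iso-surface
#' of the lightly smoothed binary mask; axis lengths from a principal
#' component analysis of the voxel-centre coordinates; maximum diameters
#' from boundary-voxel pair distances. Feature names follow the common
#' radiomics reference nomenclature.
#'
#' @param roi logical 3D ROI mask
#' @param spacing_mm voxel spacing in mm
#' @return named numeric vector of length 16
#' @export
shape_features <- function(roi, spacing_mm = c(2, 2, 2)) {
  nv <- sum(roi)
  stopifnot(nv >= 1)
  vox_vol <- prod(spacing_mm)
  idx <- which(roi, arr.ind = TRUE)
  P <- (idx - 1) * matrix(spacing_mm, nrow(idx), 3, byrow = TRUE)
  if (nv < 4) {
    warning("shape_features: degenerate ROI; voxel-based fallback")
    V <- nv * vox_vol
    A <- 2 * nv * (spacing_mm[1] * spacing_mm[2] + spacing_mm[1] * spacing_mm[3] +
                     spacing_mm[2] * spacing_mm[3])
    lam <- rep(max(var(as.numeric(P[, 1])), 1e-12), 3)
  } else {
    # crop + zero pad so the iso-surface closes
    lo <- pmax(apply(idx, 2, min) - 2L, 1L)
    hi <- pmin(apply(idx, 2, max) + 2L, dim(roi))
    box <- (roi[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]) * 1
    dpad <- dim(box) + 2L
    fld <- array(0, dpad)
    fld[2:(dpad[1] - 1), 2:(dpad[2] - 1), 2:(dpad[3] - 1)] <- box
    # smoothing radius chosen so an analytic sphere's volume and area are
    # reproduced to a few percent (staircase artifact suppression)
    fld <- gauss_smooth(fld, 0.8)
    mm <- mt_mesh_measures(fld, spacing_mm)
    V <- mm$volume; A <- mm$area
    if (V <= 0 || A <= 0) { V <- nv * vox_vol; A <- 6 * nv * vox_vol^(2 / 3) }
    lam <- sort(eigen(stats::cov(P) * (nv - 1) / nv,
                      symmetric = TRUE)$values, decreasing = TRUE)
    lam <- pmax(lam, 1e-12)
  }
  sph <- (36 * pi * V^2)^(1 / 3) / A
  # boundary voxels (6-connectivity) for diameters
  bnd <- roi & !(arr_shift(roi, c(1, 0, 0)) %in% TRUE &
                   arr_shift(roi, c(-1, 0, 0)) %in% TRUE &
                   arr_shift(roi, c(0, 1, 0)) %in% TRUE &
                   arr_shift(roi, c(0, -1, 0)) %in% TRUE &
                   arr_shift(roi, c(0, 0, 1)) %in% TRUE &
                   arr_shift(roi, c(0, 0, -1)) %in% TRUE)
  dim(bnd) <- dim(roi)
  bidx <- which(bnd, arr.ind = TRUE)
  if (nrow(bidx) == 0) bidx <- idx
  BP <- (bidx - 1) * matrix(spacing_mm, nrow(bidx), 3, byrow = TRUE)
  d3 <- max_pair_dist(BP)
  plane_max <- function(keep_cols, slice_col) {
    m <- 0
    for (s in unique(bidx[, slice_col])) {
      sel <- bidx[, slice_col] == s
      m <- max(m, max_pair_dist(BP[sel, keep_cols, drop = FALSE]))
    }
    m
  }
  d2_slice <- plane_max(c(1, 2), 3)   # axial: x-y per z slice
  d2_col <- plane_max(c(1, 3), 2)     # coronal: x-z per y
  d2_row <- plane_max(c(2, 3), 1)     # sagittal: y-z per x
  c(MeshVolume = V,
    VoxelVolume = nv * vox_vol,
    SurfaceArea = A,
    SurfaceVolumeRatio = A / V,
    Sphericity = sph,
    Compactness2 = 36 * pi * V^2 / A^3,
    SphericalDisproportion = 1 / sph,
    Maximum3DDiameter = d3,
    Maximum2DDiameterSlice = d2_slice,
    Maximum2DDiameterColumn = d2_col,
    Maximum2DDiameterRow = d2_row,
    MajorAxisLength = 4 * sqrt(lam[1]),
    MinorAxisLength = 4 * sqrt(lam[2]),
    LeastAxisLength = 4 * sqrt(lam[3]),
    Elongation = sqrt(lam[2] / lam[1]),
    Flatness = sqrt(lam[3] / lam[1]))
}

# ------------------------------------------------------------------ texture

safe_log2 <- function(p) ifelse(p > 0, log2(p), 0)

#' GLCM features (24) from a symmetric co-occurrence count matrix
#' @param P count matrix from [glcm_counts()] (directions merged)
#' @return named numeric vector of length 24
#' @export
glcm_features <- function(P) {
  p <- P / sum(P)
  ng <- nrow(p)
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)
  ux <- sum(i * p); uy <- sum(j * p)
  sigx <- sqrt(sum((i - ux)^2 * p)); sigy <- sqrt(sum((j - uy)^2 * p))
  k_d <- abs(row(p) - col(p))
  pd <- sapply(0:(ng - 1), function(k) sum(p[k_d == k]))
  k_s <- row(p) + col(p)
  ps <- sapply(2:(2 * ng), function(k) sum(p[k_s == k]))
  da <- sum((0:(ng - 1)) * pd)
  HX <- -sum(px * safe_log2(px)); HY <- -sum(py * safe_log2(py))
  HXY <- -sum(p * safe_log2(p))
  pxy <- outer(px, py)
  HXY1 <- -sum(p * safe_log2(pxy))
  HXY2 <- -sum(pxy * safe_log2(pxy))
  imc1 <- if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (HXY2 - HXY)), 0))
  # MCC: second-largest eigenvalue of Q
  keep <- px > 0
  mcc <- 1
  if (sum(keep) >= 2) {
    pk <- p[keep, keep, drop = FALSE]
    pxk <- px[keep]; pyk <- py[keep]
    Q <- matrix(0, nrow(pk), nrow(pk))
    for (kk in seq_len(ncol(pk)))
      Q <- Q + outer(pk[, kk] / pxk, pk[, kk]) / pyk[kk]
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- sqrt(pmax(ev[2], 0))
  }
  c(Autocorrelation = sum(i * j * p),
    JointAverage = ux,
    ClusterProminence = sum((i + j - ux - uy)^4 * p),
    ClusterShade = sum((i + j - ux - uy)^3 * p),
    ClusterTendency = sum((i + j - ux - uy)^2 * p),
    Contrast = sum((i - j)^2 * p),
    Correlation = if (sigx > 0 && sigy > 0)
      (sum(i * j * p) - ux * uy) / (sigx * sigy) else 1,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pd * safe_log2(pd)),
    DifferenceVariance = sum(((0:(ng - 1)) - da)^2 * pd),
    JointEnergy = sum(p^2),
    JointEntropy = HXY,
    Imc1 = imc1,
    Imc2 = imc2,
    Idm = sum(p / (1 + (i - j)^2)),
    Idmn = sum(p / (1 + ((i - j) / ng)^2)),
    Id = sum(p / (1 + abs(i - j))),
    Idn = sum(p / (1 + abs(i - j) / ng)),
    InverseVariance = sum(p[i != j] / (i[i != j] - j[i != j])^2),
    MaximumProbability = max(p),
    SumAverage = sum((2:(2 * ng)) * ps),
    SumEntropy = -sum(ps * safe_log2(ps)),
    SumSquares = sum((i - ux)^2 * p),
    MCC = mcc)
}

#' GLRLM features (16) from a run-length count matrix
#' @param R count matrix (gray level x run length), directions merged
#' @param np number of ROI voxels
#' @return named numeric vector of length 16
#' @export
glrlm_features <- function(R, np) {
  nr <- sum(R)
  p <- R / nr
  i <- row(R); l <- col(R)
  mu_i <- sum(i * p); mu_l <- sum(l * p)
  c(ShortRunEmphasis = sum(R / l^2) / nr,
    LongRunEmphasis = sum(R * l^2) / nr,
    GrayLevelNonUniformity = sum(rowSums(R)^2) / nr,
    GrayLevelNonUniformityNormalized = sum(rowSums(R)^2) / nr^2,
    RunLengthNonUniformity = sum(colSums(R)^2) / nr,
    RunLengthNonUniformityNormalized = sum(colSums(R)^2) / nr^2,
    RunPercentage = nr / (np * 13),
    GrayLevelVariance = sum((i - mu_i)^2 * p),
    RunVariance = sum((l - mu_l)^2 * p),
    RunEntropy = -sum(p * safe_log2(p)),
    LowGrayLevelRunEmphasis = sum(R / i^2) / nr,
    HighGrayLevelRunEmphasis = sum(R * i^2) / nr,
    ShortRunLowGrayLevelEmphasis = sum(R / (i^2 * l^2)) / nr,
    ShortRunHighGrayLevelEmphasis = sum(R * i^2 / l^2) / nr,
    LongRunLowGrayLevelEmphasis = sum(R * l^2 / i^2) / nr,
    LongRunHighGrayLevelEmphasis = sum(R * i^2 * l^2) / nr)
}

#' GLSZM features (16) from a size-zone count matrix
#' @param S count matrix (gray level x zone size)
#' @param np number of ROI voxels
#' @return named numeric vector of length 16
#' @export
glszm_features <- function(S, np) {
  nz <- sum(S)
  p <- S / nz
  i <- row(S); s <- col(S)
  mu_i <- sum(i * p); mu_s <- sum(s * p)
  c(SmallAreaEmphasis = sum(S / s^2) / nz,
    LargeAreaEmphasis = sum(S * s^2) / nz,
    GrayLevelNonUniformity = sum(rowSums(S)^2) / nz,
    GrayLevelNonUniformityNormalized = sum(rowSums(S)^2) / nz^2,
    SizeZoneNonUniformity = sum(colSums(S)^2) / nz,
    SizeZoneNonUniformityNormalized = sum(colSums(S)^2) / nz^2,
    ZonePercentage = nz / np,
    GrayLevelVariance = sum((i - mu_i)^2 * p),
    ZoneVariance = sum((s - mu_s)^2 * p),
    ZoneEntropy = -sum(p * safe_log2(p)),
    LowGrayLevelZoneEmphasis = sum(S / i^2) / nz,
    HighGrayLevelZoneEmphasis = sum(S * i^2) / nz,
    SmallAreaLowGrayLevelEmphasis = sum(S / (i^2 * s^2)) / nz,
    SmallAreaHighGrayLevelEmphasis = sum(S * i^2 / s^2) / nz,
    LargeAreaLowGrayLevelEmphasis = sum(S * s^2 / i^2) / nz,
    LargeAreaHighGrayLevelEmphasis = sum(S * i^2 * s^2) / nz)
}

#' NGTDM features (5)
#' @param M two-column matrix from [ngtdm_counts()]: per-level voxel count
#'   n_i and summed absolute deviation s_i
#' @param np number of ROI voxels
#' @return named numeric vector of length 5
#' @export
ngtdm_features <- function(M, np) {
  n_i <- M[, 1]; s_i <- M[, 2]
  p_i <- n_i / np
  lev <- seq_len(nrow(M))
  act <- p_i > 0
  ngp <- sum(act)
  coars_den <- sum(p_i * s_i)
  coarseness <- if (coars_den > 0) 1 / coars_den else 1e6
  if (ngp > 1) {
    ii <- lev[act]
    pp <- p_i[act]
    dif2 <- outer(ii, ii, function(a, b) (a - b)^2)
    contrast <- sum(outer(pp, pp) * dif2) / (ngp * (ngp - 1)) * sum(s_i) / np
    bus_den <- sum(abs(outer(ii * pp, ii * pp, `-`)))
    busyness <- if (bus_den > 0) coars_den / bus_den else 0
    ps <- pp * s_i[act]
    num <- abs(outer(ii, ii, `-`)) * outer(ps, ps, `+`)
    den <- outer(pp, pp, `+`)
    complexity <- sum(num / den) / np
    strength_num <- sum(outer(pp, pp, `+`) * dif2)
    strength <- if (sum(s_i) > 0) strength_num / sum(s_i) else 0
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  c(Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
    Complexity = complexity, Strength = strength)
}

#' GLDM features (14)
#' @param P count matrix from [gldm_counts()] (gray level x dependence)
#' @param np number of ROI voxels
#' @return named numeric vector of length 14
#' @export
gldm_features <- function(P, np) {
  nz <- sum(P)
  p <- P / nz
  i <- row(P); j <- col(P)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  c(SmallDependenceEmphasis = sum(P / j^2) / nz,
    LargeDependenceEmphasis = sum(P * j^2) / nz,
    GrayLevelNonUniformity = sum(rowSums(P)^2) / nz,
    DependenceNonUniformity = sum(colSums(P)^2) / nz,
    DependenceNonUniformityNormalized = sum(colSums(P)^2) / nz^2,
    GrayLevelVariance = sum((i - mu_i)^2 * p),
    DependenceVariance = sum((j - mu_j)^2 * p),
    DependenceEntropy = -sum(p * safe_log2(p)),
    LowGrayLevelEmphasis = sum(P / i^2) / nz,
    HighGrayLevelEmphasis = sum(P * i^2) / nz,
    SmallDependenceLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / nz,
    SmallDependenceHighGrayLevelEmphasis = sum(P * i^2 / j^2) / nz,
    LargeDependenceLowGrayLevelEmphasis = sum(P * j^2 / i^2) / nz,
    LargeDependenceHighGrayLevelEmphasis = sum(P * i^2 * j^2) / nz)
}

#' All texture features (75 in 5 classes) from discretized ROI labels
#'
#' @param labels integer 3D array, 0 outside ROI, 1..ng inside
#' @param ng number of gray levels
#' @return named numeric vector: `glcm.*` (24), `glrlm.*` (16),
#'   `glszm.*` (16), `ngtdm.*` (5), `gldm.*` (14)
#' @export
texture_features <- function(labels, ng) {
  if (length(unique(labels[labels > 0])) < 2)
    stop("texture_features: single gray level in ROI")
  np <- sum(labels > 0)
  storage.mode(labels) <- "integer"
  g1 <- glcm_features(glcm_counts(labels, ng))
  g2 <- glrlm_features(glrlm_counts(labels, ng), np)
  g3 <- glszm_features(glszm_counts(labels, ng), np)
  g4 <- ngtdm_features(ngtdm_counts(labels, ng), np)
  g5 <- gldm_features(gldm_counts(labels, ng, 0L), np)
  c(setNames(g1, paste0("glcm.", names(g1))),
    setNames(g2, paste0("glrlm.", names(g2))),
    setNames(g3, paste0("glszm.", names(g3))),
    setNames(g4, paste0("ngtdm.", names(g4))),
    setNames(g5, paste0("gldm.", names(g5))))
}

# -------------------------------------------------------------- feature table

#' Extract the full feature vector for one patient volume
#'
#' Shape (from the non-derived ROI mask, once) plus, for every derived
#' image and bin count, 19 first-order and 75 texture features; intensities
#' are re-discretized per derived image.
#'
#' @param vol normalized `scan_volume`
#' @param roi logical ROI mask
#' @param config an `extraction_config`
#' @return named numeric vector; names `image|class|name|bins` (shape uses
#'   `mask|shape|name|0`)
#' @export
extract_patient_features <- function(vol, roi, config = extraction_config()) {
  rs <- resample_volume(vol, list(roi = roi), config$resample_spacing_mm)
  vol <- rs$vol; roi <- rs$masks$roi
  if (sum(roi) == 0) stop("extract_patient_features: empty ROI")
  imgs <- derive_images(vol, config$log_sigmas_mm, config$images)
  vox_vol <- prod(vol$spacing_mm)
  out <- numeric(0)
  if (config$include_shape %||% TRUE) {
    sh <- shape_features(roi, vol$spacing_mm)
    out <- setNames(sh, sprintf("mask|shape|%s|0", names(sh)))
  }
  for (tag in names(imgs)) {
    a <- imgs[[tag]]
    x <- a[roi]
    for (bc in config$bin_counts) {
      lab <- discretize_roi(a, roi, bc)
      fo <- first_order_features(x, lab[roi], vox_vol)
      tx <- texture_features(lab, bc)
      cls <- sub("\\..*$", "", names(tx))
      nm <- sub("^[a-z]+\\.", "", names(tx))
      out <- c(out,
               setNames(fo, sprintf("%s|firstorder|%s|%d", tag, names(fo), bc)),
               setNames(tx, sprintf("%s|%s|%s|%d", tag, cls, nm, bc)))
    }
  }
  if (any(!is.finite(out)))
    stop("extract_patient_features: non-finite feature for patient ",
         vol$patient_id)
  out
}

#' Build the patients-by-features table for one normalized dataset
#'
#' @param volumes list of normalized `scan_volume` (one sequence, one
#'   method)
#' @param masks named per-patient mask list (needs `roi`)
#' @param config an `extraction_config`
#' @param method_id normalization method id recorded in column metadata
#' @return data.frame, rows = patients (patient_id column first), feature
#'   columns named `method|sequence|image|class|name|bins`; attribute
#'   `metadata` holds the parsed per-column metadata
#' @export
build_feature_table <- function(volumes, masks, config = extraction_config(),
                                method_id = NULL) {
  stopifnot(length(volumes) >= 1)
  if (is.null(method_id))
    method_id <- volumes[[1]]$meta$norm_method %||% "nn"
  seqn <- volumes[[1]]$sequence
  rows <- lapply(volumes, function(v) {
    f <- tryCatch(extract_patient_features(v, masks[[v$patient_id]]$roi > 0,
                                           config),
                  error = function(e)
                    stop("feature extraction failed for patient ",
                         v$patient_id, ": ", conditionMessage(e)))
    f
  })
  feat <- do.call(rbind, rows)
  colnames(feat) <- sprintf("%s|%s|%s", method_id, seqn, colnames(feat))
  meta <- parse_feature_names(colnames(feat))
  # per-class count contract (first-order/texture per image+bin; shape once)
  cc <- feature_class_counts()
  n_img_bins <- length(unique(paste(meta$image, meta$bins)[meta$class != "shape"]))
  if (config$include_shape %||% TRUE)
    stopifnot(sum(meta$class == "shape") == cc["shape"])
  for (cl in c("firstorder", "glcm", "glrlm", "glszm", "ngtdm", "gldm"))
    stopifnot(sum(meta$class == cl) == cc[cl] * n_img_bins)
  df <- data.frame(patient_id = vapply(volumes, function(v) v$patient_id, ""),
                   feat, check.names = FALSE, stringsAsFactors = FALSE)
  attr(df, "metadata") <- meta
  attr(df, "extraction_config") <- config
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse structured feature column ids
#' @param x character vector `method|sequence|image|class|name|bins`
#' @return data.frame with one row per column id
#' @export
parse_feature_names <- function(x) {
  parts <- strsplit(x, "|", fixed = TRUE)
  stopifnot(all(lengths(parts) == 6))
  data.frame(column = x,
             method = vapply(parts, `[`, "", 1),
             sequence = vapply(parts, `[`, "", 2),
             image = vapply(parts, `[`, "", 3),
             class = vapply(parts, `[`, "", 4),
             name = vapply(parts, `[`, "", 5),
             bins = as.integer(vapply(parts, `[`, "", 6)),
             stringsAsFactors = FALSE)
}
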