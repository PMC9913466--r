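# Fuzzy tissue segmentation and brain-mask intensity mode: the inputs the
# tissue-mask normalization variants need. Fuzzy c-means clustering of the
# brain-mask intensities yields csf/gm/wm membership maps; cluster-to-tissue
# assignment follows the sequence's contrast ordering.

#' Fuzzy c-means tissue segmentation of a brain volume
#'
#' Clusters brain-mask intensities into three fuzzy classes (fuzzifier
#' m = 2) and assigns clusters to csf/gm/wm by mean-intensity ordering
#' appropriate to the sequence: T1w/T1wce ascending = csf, gm, wm; T2w
#' ascending = wm, gm, csf; FLAIR ascending = csf, wm, gm.
#'
#' Initial centres are placed at fixed intensity quantiles, making the
#' estimate deterministic.
#'
#' @param vol a `scan_volume`
#' @param brain logical 3D brain mask
#' @param n_classes number of tissue classes (3)
#' @param max_iter,tol c-means iteration controls
#' @return list of membership arrays `csf`, `gm`, `wm` (in [0,1], summing to
#'   1 inside the brain, 0 outside) plus `centers` (named cluster means)
#' @export
segment_tissues <- function(vol, brain, n_classes = 3, max_iter = 300,
                            tol = 1e-5) {
  stopifnot(inherits(vol, "scan_volume"), any(brain))
  x <- vol$voxels[brain]
  if (length(unique(round(x, 10))) < n_classes)
    stop("segment_tissues: fewer than ", n_classes, " distinct intensity levels")
  if (sd(x) == 0) stop("segment_tissues: constant image inside brain")
  init <- matrix(quantile(x, probs = seq(0.15, 0.85, length.out = n_classes)),
                 ncol = 1)
  fit <- e1071::cmeans(matrix(x, ncol = 1), centers = init, m = 2,
                       iter.max = max_iter, method = "cmeans",
                       control = list(reltol = tol))
  ord <- order(fit$centers[, 1])
  asc <- switch(vol$sequence,
                T1w = , T1wce = c("csf", "gm", "wm"),
                T2w = c("wm", "gm", "csf"),
                FLAIR = c("csf", "wm", "gm"),
                stop("unknown sequence: ", vol$sequence))
  out <- list()
  for (k in seq_len(n_classes)) {
    m <- array(0, dim(vol$voxels))
    m[brain] <- fit$membership[, ord[k]]
    out[[asc[k]]] <- m
  }
  out$centers <- setNames(fit$centers[ord, 1], asc)
  out[c("csf", "gm", "wm", "centers")]
}

#' Most common intensity value (mode) inside the brain mask
#'
#' Histogram mode over 256 equal-width bins spanning the observed brain
#' intensity range; the mode is the centre of the tallest bin (leftmost on
#' ties). A constant image returns its value.
#'
#' @param vol a `scan_volume` (or 3D array)
#' @param brain logical 3D brain mask
#' @param n_bins histogram bin count (256)
#' @return scalar mode intensity
#' @export
image_mode <- function(vol, brain, n_bins = 256) {
  x <- if (inherits(vol, "scan_volume")) vol$voxels[brain] else vol[brain]
  stopifnot(length(x) > 0)
  rg <- range(x)
  if (rg[1] == rg[2]) return(rg[1])
  br <- seq(rg[1], rg[2], length.out = n_bins + 1)
  cnt <- tabulate(pmin(findInterval(x, br, rightmost.closed = TRUE), n_bins),
                  nbins = n_bins)
  k <- which.max(cnt)          # which.max returns the leftmost maximum
  (br[k] + br[k + 1]) / 2
}

#' Membership-weighted tissue mean
#'
#' `mu_T = sum(w * I) / sum(w)` over the volume, for a fuzzy membership map
#' `w`; reduces to the plain mask mean for a hard mask.
#'
#' @param vol `scan_volume` or array
#' @param membership membership array in [0,1]
#' @return scalar mean
#' @export
tissue_mean <- function(vol, membership) {
  v <- if (inherits(vol, "scan_volume")) vol$voxels else vol
  w <- as.numeric(membership)
  sw <- sum(w)
  if (sw <= 0) stop("tissue_mean: empty membership")
  sum(v * membership) / sw
}
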