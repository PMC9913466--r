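#' @useDynLib radnorm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats density ecdf sd var quantile median mad rnorm runif rbinom
#'   rexp aggregate coef cor predict glm poisson setNames complete.cases
#' @importFrom mclust Mclust mclustBIC
#' @importFrom utils head tail write.csv read.csv
NULL

#' Derive a reproducible sub-seed from a master seed
#'
#' A fixed counter scheme so that cohorts are extensible without reshuffling:
#' each (master seed, counter) pair maps to a distinct 31-bit seed.
#'
#' @param seed master integer seed
#' @param counter non-negative integer stream index
#' @return an integer seed in [0, 2^31 - 1]
#' @export
derive_seed <- function(seed, counter) {
  # affine hash mod a Mersenne prime; keeps results < 2^31 (R integers)
  p <- 2147483647
  as.integer((as.numeric(seed) %% p * 48271 + as.numeric(counter) * 16807 + 1) %% p)
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores .Random.seed so library code never disturbs the
#' caller's RNG stream.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @keywords internal
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Construct a scan volume
#'
#' Container for one 3D MR acquisition: voxel intensities in arbitrary
#' units plus spacing and identifying metadata.
#'
#' @param voxels 3D numeric array
#' @param spacing_mm positive length-3 numeric, voxel size in mm
#' @param sequence one of "T1w", "T1wce", "T2w", "FLAIR"
#' @param patient_id identifier string
#' @param batch_id scanner batch identifier
#' @param meta optional named list of provenance entries
#' @return an object of class `scan_volume`
#' @export
scan_volume <- function(voxels, spacing_mm = c(2, 2, 2), sequence = "T1w",
                        patient_id = "p1", batch_id = "b1", meta = list()) {
  stopifnot(length(dim(voxels)) == 3, all(spacing_mm > 0), length(spacing_mm) == 3)
  if (!all(is.finite(voxels))) stop("scan_volume: voxels must be finite")
  structure(list(voxels = voxels, spacing_mm = as.numeric(spacing_mm),
                 sequence = sequence, patient_id = patient_id,
                 batch_id = batch_id, meta = meta),
            class = "scan_volume")
}

#' @export
print.scan_volume <- function(x, ...) {
  cat(sprintf("<scan_volume %s/%s batch=%s dims=%s spacing=%s mm>\n",
              x$patient_id, x$sequence, x$batch_id,
              paste(dim(x$voxels), collapse = "x"),
              paste(x$spacing_mm, collapse = "x")))
  invisible(x)
}

#' Shift a 3D array by an integer offset, padding with NA
#'
#' `arr_shift(a, c(1,0,0))[i,j,k] == a[i-1,j,k]`; voxels shifted in from
#' outside the array are NA. Used by the texture-matrix and filtering code.
#' @param a 3D array
#' @param off integer length-3 offset
#' @keywords internal
arr_shift <- function(a, off) {
  d <- dim(a)
  out <- array(NA_real_, d)
  src <- lapply(1:3, function(k) {
    i <- seq_len(d[k]) - off[k]
    i[i < 1 | i > d[k]] <- NA
    i
  })
  ok <- lapply(src, function(i) which(!is.na(i)))
  out[ok[[1]], ok[[2]], ok[[3]]] <-
    a[src[[1]][ok[[1]]], src[[2]][ok[[2]]], src[[3]][ok[[3]]]]
  out
}

#' Separable 1D convolution of a 3D array along one axis
#'
#' Symmetric (half-sample mirror) boundary extension; kernel centred at
#' `origin` (1-based index into `kern`).
#' @keywords internal
conv_axis <- function(a, kern, axis, origin = (length(kern) + 1) %/% 2) {
  d <- dim(a)
  n <- d[axis]
  out <- array(0, d)
  for (t in seq_along(kern)) {
    off <- t - origin
    idx <- seq_len(n) + off
    # mirror extension
    idx <- ifelse(idx < 1, 1 - idx, idx)
    idx <- ifelse(idx > n, 2 * n + 1 - idx, idx)
    idx <- pmin(pmax(idx, 1), n)
    sl <- switch(axis,
                 a[idx, , , drop = FALSE],
                 a[, idx, , drop = FALSE],
                 a[, , idx, drop = FALSE])
    out <- out + kern[t] * sl
  }
  out
}

#' Gaussian smoothing of a 3D array, sigma in voxels per axis
#' @keywords internal
gauss_smooth <- function(a, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k <- k / sum(k)
    a <- conv_axis(a, k, ax, origin = r + 1L)
  }
  a
}

#' Write a scan volume (or plain mask array) to NIfTI-1
#' @param vol a `scan_volume` or 3D array
#' @param path output path, typically ending in .nii.gz
#' @param spacing_mm spacing when `vol` is a bare array
#' @export
write_volume_nifti <- function(vol, path, spacing_mm = c(2, 2, 2)) {
  if (inherits(vol, "scan_volume")) {
    arr <- vol$voxels; spacing_mm <- vol$spacing_mm
  } else arr <- vol
  img <- RNifti::asNifti(arr, pixdim = spacing_mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 file into a scan volume
#' @inheritParams scan_volume
#' @param path file path
#' @export
read_volume_nifti <- function(path, sequence = "T1w", patient_id = "p1",
                              batch_id = "b1") {
  img <- RNifti::readNifti(path)
  scan_volume(array(as.numeric(img), dim = dim(img)),
              spacing_mm = RNifti::pixdim(img)[1:3],
              sequence = sequence, patient_id = patient_id, batch_id = batch_id)
}
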