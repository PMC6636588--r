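## Low-level 3D volume helpers: separable convolution along array axes,
## Gaussian and box kernels. Volumes are plain 3D numeric arrays; physical
## units enter only through the voxel size (mm, isotropic).

#' @keywords internal
stop_if_not_vol3d <- function(x, name = deparse(substitute(x))) {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop(sprintf("'%s' must be a 3D array", name), call. = FALSE)
  invisible(x)
}

## Band matrix applying 1D kernel `k` (odd length, centred) along an axis of
## length n with zero padding; conv by matrix multiplication keeps the whole
## operation in BLAS.
conv_band_matrix <- function(n, k) {
  r <- (length(k) - 1L) %/% 2L
  M <- matrix(0, n, n)
  for (d in -r:r) {
    idx <- seq_len(n)
    src <- idx + d
    ok <- src >= 1L & src <= n
    M[cbind(idx[ok], src[ok])] <- M[cbind(idx[ok], src[ok])] + k[d + r + 1L]
  }
  M
}

## Separable convolution of a 3D array with per-axis 1D kernels (zero padded).
conv_separable <- function(vol, k1, k2 = k1, k3 = k1) {
  d <- dim(vol)
  M1 <- conv_band_matrix(d[1L], k1)
  M2 <- conv_band_matrix(d[2L], k2)
  M3 <- conv_band_matrix(d[3L], k3)
  ## axis 1
  x <- M1 %*% matrix(vol, d[1L], d[2L] * d[3L])
  dim(x) <- d
  ## axis 2
  x <- aperm(x, c(2L, 1L, 3L))
  x <- M2 %*% matrix(x, d[2L], d[1L] * d[3L])
  dim(x) <- d[c(2L, 1L, 3L)]
  x <- aperm(x, c(2L, 1L, 3L))
  ## axis 3
  x <- aperm(x, c(3L, 1L, 2L))
  x <- M3 %*% matrix(x, d[3L], d[1L] * d[2L])
  dim(x) <- d[c(3L, 1L, 2L)]
  aperm(x, c(2L, 3L, 1L))
}

gaussian_kernel_1d <- function(sigma_vox, radius = NULL) {
  if (sigma_vox <= 0) return(1)
  if (is.null(radius)) radius <- max(1L, ceiling(3 * sigma_vox))
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

#' Gaussian smoothing of a 3D map
#'
#' Smooths a volume with an isotropic Gaussian kernel specified by its full
#' width at half maximum in millimetres (\code{sigma = fwhm / (2*sqrt(2*log(2)))},
#' converted to voxels by the voxel size). With a mask, smoothing is
#' renormalized by the smoothed mask so that zeros outside the brain do not
#' dilute values at the brain edge; output is zero outside the mask.
#' \code{fwhm_mm = 0} returns the input unchanged.
#'
#' @param map 3D numeric array.
#' @param fwhm_mm kernel full width at half maximum, mm; must be >= 0.
#' @param voxel_size_mm isotropic voxel edge length, mm.
#' @param mask optional logical/0-1 3D array; smoothing is confined to it.
#' @return 3D numeric array of the same dimensions.
#' @export
smooth_map <- function(map, fwhm_mm, voxel_size_mm, mask = NULL) {
  stop_if_not_vol3d(map)
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || is.na(fwhm_mm) || fwhm_mm < 0)
    stop("'fwhm_mm' must be a single non-negative number", call. = FALSE)
  if (fwhm_mm == 0) return(map)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  k <- gaussian_kernel_1d(sigma_vox)
  if (is.null(mask)) return(conv_separable(map, k))
  m <- array(as.numeric(mask != 0), dim(map))
  if (any(dim(m) != dim(map))) stop("mask dimensions do not match map", call. = FALSE)
  num <- conv_separable(map * m, k)
  den <- conv_separable(m, k)
  out <- array(0, dim(map))
  inside <- m > 0 & den > 0
  out[inside] <- num[inside] / den[inside]
  out
}

## Count of set voxels in the cubic neighborhood of each voxel: separable
## convolution with all-ones kernels, zero-padded (used by the junction map).
box_count <- function(mask, kernel_size) {
  k <- rep(1, kernel_size)
  conv_separable(array(as.numeric(mask != 0), dim(mask)), k)
}

## Linear voxel index <-> (i,j,k) coordinates
vox_index <- function(ijk, d) {
  (ijk[, 1L]) + (ijk[, 2L] - 1L) * d[1L] + (ijk[, 3L] - 1L) * d[1L] * d[2L]
}

vox_coords <- function(idx, d) {
  idx0 <- idx - 1L
  i <- idx0 %% d[1L]
  j <- (idx0 %/% d[1L]) %% d[2L]
  k <- idx0 %/% (d[1L] * d[2L])
  cbind(i + 1L, j + 1L, k + 1L)
}
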