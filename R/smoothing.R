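# Truncated-Gaussian smoothing of 3D maps, implemented as separable 1D
# convolutions.  Zero padding at the grid boundary with optional
# renormalization by the local kernel mass, so constant images are invariant
# up to machine precision everywhere including edges.

#' Truncated 1D Gaussian kernel
#'
#' @param sigma Standard deviation in voxels.
#' @param support Odd kernel edge length (voxels).
#' @return Numeric vector of length `support`, normalized to unit sum.
#' @export
gaussian_kernel_1d <- function(sigma, support) {
  if (support < 1 || support %% 2 == 0) stop("support must be a positive odd integer")
  if (sigma <= 0) stop("sigma must be positive")
  h <- (support - 1) / 2
  k <- exp(-((-h:h)^2) / (2 * sigma^2))
  k / sum(k)
}

convolve_axis <- function(img, k, axis) {
  m <- length(k)
  h <- (m - 1) / 2
  d <- dim(img)
  pad <- d
  pad[axis] <- d[axis] + 2 * h
  padded <- array(0, dim = pad)
  idx <- lapply(seq_len(3), function(a) seq_len(d[a]))
  idx[[axis]] <- idx[[axis]] + h
  padded[idx[[1]], idx[[2]], idx[[3]]] <- img
  out <- array(0, dim = d)
  for (j in seq_len(m)) {
    sl <- lapply(seq_len(3), function(a) seq_len(d[a]))
    sl[[axis]] <- sl[[axis]] + (j - 1)
    out <- out + k[j] * padded[sl[[1]], sl[[2]], sl[[3]]]
  }
  out
}

#' Smooth a 3D map with a truncated Gaussian kernel
#'
#' Separable Gaussian convolution truncated to a finite cubic support.
#' With `renormalize = TRUE` the result is divided by the smoothed
#' indicator of the grid, so a constant image stays constant at the
#' boundary.  When `mask` is given, voxels outside it are re-zeroed after
#' smoothing (background preservation for brain maps).
#'
#' @param img 3D numeric array.
#' @param sigma Gaussian standard deviation in voxels.
#' @param support Odd cubic support edge in voxels (default covers +-3 sigma).
#' @param mask Optional logical/0-1 array; outside voxels are set to 0 after
#'   smoothing.
#' @param renormalize Divide by the smoothed all-ones image (default TRUE).
#' @return Smoothed 3D array.
#' @export
smooth_3d <- function(img, sigma, support = NULL, mask = NULL, renormalize = TRUE) {
  if (length(dim(img)) != 3L) stop("img must be a 3D array")
  if (is.null(support)) support <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  if (any(support > dim(img))) stop("kernel support exceeds the grid")
  k <- gaussian_kernel_1d(sigma, support)
  out <- convolve_axis(convolve_axis(convolve_axis(img, k, 1L), k, 2L), k, 3L)
  if (renormalize) {
    ones <- array(1, dim = dim(img))
    w <- convolve_axis(convolve_axis(convolve_axis(ones, k, 1L), k, 2L), k, 3L)
    out <- out / w
  }
  if (!is.null(mask)) out[!(mask > 0)] <- 0
  out
}

#' Convert a FWHM in mm to a Gaussian sigma in voxels
#'
#' @param fwhm_mm Full width at half maximum in millimetres.
#' @param voxel_size_mm Isotropic voxel edge in millimetres.
#' @return Sigma in voxel units (`fwhm / (2 sqrt(2 log 2)) / voxel`).
#' @export
fwhm_to_sigma <- function(fwhm_mm, voxel_size_mm = 1) {
  fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
}
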