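# Shared 3D image utilities: FFT Gaussian smoothing, clamped shifts, finite
# differences, robust noise estimation, local windows.

# FFT of a centred sampled Gaussian handled analytically: the transform of a
# Gaussian is a Gaussian, so smoothing is three separable multiplications in
# the frequency domain (circular boundary).
gauss_freq_1d <- function(n, sigma_vox) {
  k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[1:n]
  if (n == 1) k <- 0
  f <- k / n
  exp(-2 * pi^2 * sigma_vox^2 * f^2)
}

#' Gaussian smoothing of a 3D volume
#'
#' Anisotropic Gaussian filter implemented in the frequency domain
#' (circular boundary conditions).
#'
#' @param vol 3D array.
#' @param sigma_vox per-axis standard deviation in voxels `(z, y, x)`.
#' @return smoothed 3D array.
#' @export
gauss_smooth <- function(vol, sigma_vox) {
  d <- dim(vol)
  G <- outer(outer(gauss_freq_1d(d[1], sigma_vox[1]),
                   gauss_freq_1d(d[2], sigma_vox[2])),
             gauss_freq_1d(d[3], sigma_vox[3]))
  dim(G) <- d
  Re(fft(fft(vol) * G, inverse = TRUE)) / prod(d)
}

# result[i] = a[i + by] along `axis`, clamped at the edges
ax_shift <- function(a, by, axis) {
  d <- dim(a)
  idx <- pmin(pmax(seq_len(d[axis]) + by, 1L), d[axis])
  args <- list(a, 1:d[1], 1:d[2], 1:d[3])
  args[[axis + 1]] <- idx
  args$drop <- FALSE
  do.call(`[`, args)
}

# second derivatives (physical units: per um^2) of a volume
hessian_components <- function(a, voxel_size_um) {
  v <- voxel_size_um
  d2 <- function(ax) (ax_shift(a, 1, ax) - 2 * a + ax_shift(a, -1, ax)) / v[ax]^2
  dcross <- function(ax1, ax2) {
    (ax_shift(ax_shift(a, 1, ax1), 1, ax2) - ax_shift(ax_shift(a, 1, ax1), -1, ax2) -
     ax_shift(ax_shift(a, -1, ax1), 1, ax2) + ax_shift(ax_shift(a, -1, ax1), -1, ax2)) /
      (4 * v[ax1] * v[ax2])
  }
  list(zz = d2(1), yy = d2(2), xx = d2(3),
       zy = dcross(1, 2), zx = dcross(1, 3), yx = dcross(2, 3))
}

#' Robust image noise estimate
#'
#' Standard deviation of the additive noise, estimated as the median absolute
#' deviation of first spatial differences divided by `sqrt(2)` (the difference
#' of two independent noise samples has variance `2 * sd^2`).
#'
#' @param vol 3D array.
#' @return scalar noise sd.
#' @export
estimate_noise_sd <- function(vol) {
  d <- as.vector(ax_shift(vol, 1, 3) - vol)
  mad(d, center = 0) / sqrt(2)
}

# integer voxel window around a um position; returns index ranges (clipped)
voxel_window <- function(center_um, half_um, voxel_size_um, dims) {
  lo <- pmax(1L, floor((center_um - half_um) / voxel_size_um) + 1L)
  hi <- pmin(dims, ceiling((center_um + half_um) / voxel_size_um) + 1L)
  if (any(lo > hi)) return(NULL)
  list(lo = as.integer(lo), hi = as.integer(hi))
}

# array index grid (n x 3 matrix, 1-based) for a window
window_grid <- function(w) {
  as.matrix(expand.grid(z = w$lo[1]:w$hi[1], y = w$lo[2]:w$hi[2],
                        x = w$lo[3]:w$hi[3]))
}

# linear indices of an index matrix into an array of dims d
lin_index <- function(idx, d) {
  (idx[, 3] - 1) * d[1] * d[2] + (idx[, 2] - 1) * d[1] + idx[, 1]
}

# inverse of lin_index
unlin_index <- function(lin, d) {
  lin0 <- lin - 1
  z <- lin0 %% d[1]
  y <- (lin0 %/% d[1]) %% d[2]
  x <- lin0 %/% (d[1] * d[2])
  cbind(z = z + 1, y = y + 1, x = x + 1)
}
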