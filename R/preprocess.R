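# Optional restoration / motion compensation ahead of detection. All of it is
# opt-in via the preprocess config section; the default pipeline runs raw.

hann <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

# circular FFT convolution of a volume with a centred kernel
fft_convolve <- function(vol, kern_full) {
  d <- dim(vol)
  Re(fft(fft(vol) * fft(kern_full), inverse = TRUE)) / prod(d)
}

# embed a (small) PSF into a full-size array centred at the origin voxel
embed_psf <- function(psf, dims) {
  kd <- dim(psf)
  if (any(kd > dims)) abort("psf larger than the volume")
  full <- array(0, dims)
  ctr <- (kd + 1) %/% 2
  for (z in 1:kd[1]) for (y in 1:kd[2]) for (x in 1:kd[3]) {
    zi <- ((z - ctr[1]) %% dims[1]) + 1
    yi <- ((y - ctr[2]) %% dims[2]) + 1
    xi <- ((x - ctr[3]) %% dims[3]) + 1
    full[zi, yi, xi] <- psf[z, y, x]
  }
  full
}

#' Richardson--Lucy deconvolution
#'
#' Multiplicative EM iterations for Poisson deblurring. Output is
#' non-negative and conserves total intensity to within about a percent.
#'
#' @param vol 3D intensity volume.
#' @param psf 3D non-negative kernel summing to ~1 (a delta kernel returns
#'   the input unchanged).
#' @param iterations number of RL updates, `>= 1`.
#' @return deconvolved 3D array.
#' @export
deconvolve <- function(vol, psf, iterations = 10) {
  stopifnot(iterations >= 1)
  if (any(psf < 0)) abort("psf must be non-negative")
  s <- sum(psf)
  if (s <= 0) abort("psf must not be all zero")
  psf <- psf / s
  dims <- dim(vol)
  K <- embed_psf(psf, dims)
  Kf <- fft(K)
  Kf_conj <- Conj(Kf)
  est <- pmax(vol, 1e-12)
  for (i in seq_len(iterations)) {
    conv <- Re(fft(fft(est) * Kf, inverse = TRUE)) / prod(dims)
    conv[conv < 1e-12] <- 1e-12
    ratio <- vol / conv
    corr <- Re(fft(fft(ratio) * Kf_conj, inverse = TRUE)) / prod(dims)
    est <- est * corr
    est[est < 0] <- 0
  }
  est
}

#' Rigid translation registration by phase correlation
#'
#' Finds the integer voxel shift maximising the normalised cross-power
#' spectrum, optionally refined to subvoxel precision by a quadratic fit
#' around the peak. A low peak correlation flags unreliable registration
#' (e.g. pure noise inputs).
#'
#' @param reference,moving 3D volumes of identical shape.
#' @param subvoxel refine the integer shift by a local quadratic fit?
#' @return list: `shift` (z, y, x voxels such that shifting `moving` by it
#'   aligns it to `reference`), `registered` volume (integer part of the
#'   shift applied), `score` (phase-correlation peak between 0 and 1), `reliable`.
#' @export
rigid_register <- function(reference, moving, subvoxel = TRUE) {
  if (length(reference) == 0 || length(moving) == 0) abort("empty volume")
  stopifnot(all(dim(reference) == dim(moving)))
  d <- dim(reference)
  Fa <- fft(reference); Fb <- fft(moving)
  R <- Fa * Conj(Fb)
  mag <- Mod(R); mag[mag < 1e-12] <- 1e-12
  pc <- Re(fft(R / mag, inverse = TRUE)) / prod(d)
  peak <- which.max(pc)
  ix <- unlin_index(peak, d)[1, ] - 1
  shift <- ifelse(ix > d / 2, ix - d, ix)
  score <- max(pc)
  if (subvoxel) {
    frac <- numeric(3)
    for (ax in 1:3) {
      if (d[ax] < 3) next
      at <- function(off) {
        j <- ix; j[ax] <- (j[ax] + off) %% d[ax]
        pc[matrix(j + 1, 1)]
      }
      y0 <- at(-1); y1 <- at(0); y2 <- at(1)
      den <- (y0 - 2 * y1 + y2)
      if (abs(den) > 1e-12) frac[ax] <- 0.5 * (y0 - y2) / den
      frac[ax] <- max(min(frac[ax], 0.5), -0.5)
    }
    shift <- shift + frac
  }
  int_shift <- round(shift)
  reg <- moving
  for (ax in 1:3) if (int_shift[ax] != 0)
    reg <- ax_shift(reg, -int_shift[ax], ax)
  list(shift = shift, registered = reg, score = score,
       reliable = score >= 0.05)
}

#' Piecewise-constant motion flow field
#'
#' Block-matching flow between consecutive volumes: each block's displacement
#' is estimated by local phase correlation, giving a coarse grid of 3D
#' vectors (um) that downstream linking uses to offset transition costs.
#' Queried positions are interpolated trilinearly from the block grid.
#'
#' @param vol_t,vol_t1 3D volumes of identical shape.
#' @param block_size_vox block edge length in voxels (>= 4).
#' @param voxel_size_um voxel size (um).
#' @return a `flow_field`: block centres (um), displacement vectors (um),
#'   block size.
#' @export
estimate_motion_flow <- function(vol_t, vol_t1, block_size_vox = 16,
                                 voxel_size_um = c(1, 1, 1)) {
  d <- dim(vol_t)
  stopifnot(all(dim(vol_t1) == d))
  if (any(block_size_vox > d)) abort("block larger than the volume")
  if (block_size_vox < 4) abort("block_size_vox must be >= 4")
  nb <- pmax(1L, d %/% block_size_vox)
  centers <- list(); vecs <- list()
  k <- 0L
  for (bz in seq_len(nb[1])) for (by in seq_len(nb[2])) for (bx in seq_len(nb[3])) {
    lo <- (c(bz, by, bx) - 1L) * block_size_vox + 1L
    hi <- pmin(d, lo + block_size_vox - 1L)
    if (bz == nb[1]) hi[1] <- d[1]
    if (by == nb[2]) hi[2] <- d[2]
    if (bx == nb[3]) hi[3] <- d[3]
    # a Hann window suppresses the crop-boundary artefacts that otherwise
    # anchor a spurious zero-shift correlation peak
    windowed <- function(block) {
      bd <- dim(block)
      w3 <- outer(outer(hann(bd[1]), hann(bd[2])), hann(bd[3]))
      dim(w3) <- bd
      (block - mean(block)) * w3
    }
    A <- vol_t[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    B <- vol_t1[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    r <- rigid_register(windowed(B), windowed(A), subvoxel = FALSE)
    s0 <- round(r$shift)
    shift <- r$shift
    # iterate on a re-cropped target to remove the crop bias of large shifts
    for (pass in 1:3) {
      lo2 <- lo + s0; hi2 <- hi + s0
      if (any(lo2 < 1) || any(hi2 > d)) break
      B2 <- vol_t1[lo2[1]:hi2[1], lo2[2]:hi2[2], lo2[3]:hi2[3], drop = FALSE]
      r2 <- rigid_register(windowed(B2), windowed(A), subvoxel = TRUE)
      shift <- s0 + r2$shift
      if (all(round(r2$shift) == 0)) break
      s0 <- s0 + round(r2$shift)
    }
    k <- k + 1L
    centers[[k]] <- ((lo + hi) / 2 - 1) * voxel_size_um
    vecs[[k]] <- shift * voxel_size_um
  }
  structure(list(centers = do.call(rbind, centers),
                 vectors = do.call(rbind, vecs),
                 block_size_vox = block_size_vox,
                 nb = nb, voxel_size_um = voxel_size_um,
                 dims = d),
            class = "flow_field")
}

#' Query a flow field at an arbitrary position
#'
#' Trilinear interpolation of the block grid (nearest block outside the
#' grid).
#'
#' @param flow a `flow_field` (or a per-frame list of them).
#' @param t frame index (used when `flow` is a list; otherwise ignored).
#' @param pos_um position (z, y, x) in um.
#' @return displacement vector (um).
#' @export
flow_at <- function(flow, t, pos_um) {
  if (is.null(flow)) return(c(0, 0, 0))
  if (!inherits(flow, "flow_field") && is.list(flow)) {
    flow <- flow[[t + 1]]
    if (is.null(flow)) return(c(0, 0, 0))
  }
  ctr <- flow$centers
  # inverse-distance weighting over the 8 nearest block centres:
  # piecewise-trilinear in effect for a regular grid
  d2 <- colSums((t(ctr) - pos_um)^2)
  o <- order(d2)[seq_len(min(8, nrow(ctr)))]
  w <- 1 / pmax(d2[o], 1e-6)
  as.numeric(colSums(flow$vectors[o, , drop = FALSE] * w) / sum(w))
}
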