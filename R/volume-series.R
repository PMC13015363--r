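#' 4D intensity series with physical calibration
#'
#' A `volume_series` holds one 3D intensity volume per time frame together with
#' the physical calibration needed for metric computations: voxel size in
#' micrometres (z, y, x order) and the frame interval in seconds. All
#' geometric quantities in the package (centroids, gating radii, velocities)
#' are expressed in micrometres; the voxel at array index `(1, 1, 1)` has its
#' centre at physical coordinate `(0, 0, 0)`.
#'
#' @param frames list of 3D numeric arrays, all of identical dimension,
#'   ordered `(z, y, x)`. Intensities must be non-negative.
#' @param voxel_size_um numeric length-3, voxel extent in um as `(z, y, x)`;
#'   all components must be positive.
#' @param frame_interval_s positive scalar, seconds between frames.
#' @param time_origin_hpf optional scalar, developmental-time offset of frame 0
#'   in hours post fertilization (metadata only).
#'
#' @return An object of class `volume_series`.
#' @export
volume_series <- function(frames, voxel_size_um, frame_interval_s = 60,
                          time_origin_hpf = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1)
  dims <- lapply(frames, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    abort("every frame must be a 3D array (z, y, x)")
  d0 <- dims[[1]]
  if (!all(vapply(dims, function(d) all(d == d0), TRUE)))
    abort("all frames must share the same (z, y, x) shape")
  if (length(voxel_size_um) != 3 || any(!is.finite(voxel_size_um)) ||
      any(voxel_size_um <= 0))
    abort("voxel_size_um must be three positive numbers (z, y, x)")
  if (!is.finite(frame_interval_s) || frame_interval_s <= 0)
    abort("frame_interval_s must be positive")
  if (any(vapply(frames, function(a) any(a < 0), TRUE)))
    abort("intensities must be non-negative")
  structure(
    list(frames = frames,
         voxel_size_um = as.numeric(voxel_size_um),
         frame_interval_s = as.numeric(frame_interval_s),
         time_origin_hpf = time_origin_hpf),
    class = "volume_series")
}

#' Number of frames in a series
#' @param x a `volume_series` or `label_series`
#' @return integer frame count
#' @export
n_frames <- function(x) length(x$frames)

#' Extract the 3D volume at a frame
#' @param x a `volume_series` or `label_series`
#' @param t 0-based frame index
#' @return 3D array
#' @export
frame_volume <- function(x, t) {
  stopifnot(t >= 0, t < n_frames(x))
  x$frames[[t + 1]]
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<volume_series> %d frames of %dx%dx%d (z,y,x) voxels\n",
              n_frames(x), d[1], d[2], d[3]))
  cat(sprintf("  voxel size (um): %.3g x %.3g x %.3g; frame interval: %gs\n",
              x$voxel_size_um[1], x$voxel_size_um[2], x$voxel_size_um[3],
              x$frame_interval_s))
  invisible(x)
}

#' Per-frame integer label volumes (instance segmentation)
#'
#' Label 0 is background; labels within a frame are unique positive integers.
#' Calibration mirrors [volume_series()].
#'
#' @param frames list of 3D integer arrays `(z, y, x)`.
#' @inheritParams volume_series
#' @return An object of class `label_series`.
#' @export
label_series <- function(frames, voxel_size_um, frame_interval_s = 60) {
  stopifnot(is.list(frames), length(frames) >= 1)
  d0 <- dim(frames[[1]])
  for (f in frames) {
    if (length(dim(f)) != 3 || !all(dim(f) == d0))
      abort("all label frames must share one 3D shape")
    if (any(f < 0)) abort("labels must be non-negative integers")
  }
  frames <- lapply(frames, function(f) { storage.mode(f) <- "integer"; f })
  structure(
    list(frames = frames,
         voxel_size_um = as.numeric(voxel_size_um),
         frame_interval_s = as.numeric(frame_interval_s)),
    class = "label_series")
}

#' @export
print.label_series <- function(x, ...) {
  d <- dim(x$frames[[1]])
  nl <- vapply(x$frames, function(f) length(setdiff(unique(as.vector(f)), 0L)), 1L)
  cat(sprintf("<label_series> %d frames of %dx%dx%d; %d--%d labels/frame\n",
              n_frames(x), d[1], d[2], d[3], min(nl), max(nl)))
  invisible(x)
}

#' Labels present in one frame
#' @param labels a `label_series`
#' @param t 0-based frame
#' @return sorted integer vector of positive labels
#' @export
frame_labels <- function(labels, t) {
  sort(setdiff(unique(as.vector(frame_volume(labels, t))), 0L))
}

# physical um coordinates (z,y,x) of voxel array indices (1-based)
voxel_to_um <- function(idx, voxel_size_um) {
  sweep(idx - 1, 2, voxel_size_um, `*`)
}

um_to_voxel <- function(um, voxel_size_um) {
  round(um / voxel_size_um) + 1
}
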