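# Shared fixtures, all generated in code.

# circular roll of a 3D array (ground truth for registration tests)
roll_array <- function(a, by) {
  d <- dim(a)
  idx <- lapply(1:3, function(ax) ((seq_len(d[ax]) - 1 - by[ax]) %% d[ax]) + 1)
  a[idx[[1]], idx[[2]], idx[[3]]]
}

# a volume with isotropic Gaussian blobs at given centres (1-based voxel um)
blob_volume <- function(dims, centers, sigma = 2.2, peak = 90, background = 10,
                        noise_sd = 0, seed = 1) {
  g <- as.matrix(expand.grid(z = 1:dims[1], y = 1:dims[2], x = 1:dims[3]))
  vol <- array(background, dims)
  for (i in seq_len(nrow(centers))) {
    q <- (g[, 1] - centers[i, 1])^2 + (g[, 2] - centers[i, 2])^2 +
      (g[, 3] - centers[i, 3])^2
    vol <- vol + array(peak * exp(-q / (2 * sigma^2)), dims)
  }
  if (noise_sd > 0) {
    set.seed(seed)
    vol <- pmax(vol + array(rnorm(prod(dims), 0, noise_sd), dims), 0)
  }
  vol
}

# well-separated blob centres
separated_centers <- function(n, dims, min_sep = 10, margin = 6, seed = 1) {
  set.seed(seed)
  out <- NULL
  tries <- 0
  while (is.null(out) || nrow(out) < n) {
    cand <- c(runif(1, margin, dims[1] - margin),
              runif(1, margin, dims[2] - margin),
              runif(1, margin, dims[3] - margin))
    if (is.null(out) ||
        min(sqrt(colSums((t(out) - cand)^2))) >= min_sep)
      out <- rbind(out, cand)
    tries <- tries + 1
    if (tries > 5000) break
  }
  out
}

# small, fast synthetic scene for unit tests
small_scene_params <- function(seed = 1, ...) {
  base <- list(
    n_cells_initial = 25L, n_frames = 12L,
    domain_um = c(24, 80, 80), voxel_size_um = c(2, 1, 1),
    shell_center_um = c(-40, 40, 40), shell_radius_um = 52,
    division_prob = 0, seed = seed)
  args <- utils::modifyList(base, list(...))
  do.call(sim_params, args)
}

# random detection tables for linking tests
random_detections <- function(seed, max_per_frame = 5, n_frames = 3) {
  set.seed(seed)
  det <- do.call(rbind, lapply(seq_len(n_frames) - 1L, function(t) {
    n <- sample(seq_len(max_per_frame), 1)
    tibble::tibble(id = 0L, frame = t, z = runif(n, 0, 10),
                   y = runif(n, 0, 20), x = runif(n, 0, 20),
                   volume_um3 = runif(n, 60, 140), n_voxels = 100L,
                   mean_intensity = 50, z_score = runif(n, 3, 12),
                   scale_um = 3)
  }))
  det$id <- seq_len(nrow(det))
  det
}

# hand-built toy forest from a frame-by-track position array
toy_forest <- function(tracks) {
  # tracks: list of tibbles with frame, z, y, x, optional parent_track/at
  rows <- list(); nid <- 0L
  firsts <- integer(length(tracks)); lasts <- integer(length(tracks))
  for (k in seq_along(tracks)) {
    tt <- tracks[[k]]
    ids <- nid + seq_len(nrow(tt)); nid <- nid + nrow(tt)
    firsts[k] <- ids[1]; lasts[k] <- ids[length(ids)]
    rows[[k]] <- tibble::tibble(
      id = ids, frame = tt$frame, z = tt$z, y = tt$y, x = tt$x,
      volume_um3 = 100, parent_id = c(NA_integer_, ids[-length(ids)]),
      track_id = k, interpolated = FALSE)
  }
  nodes <- dplyr::bind_rows(rows)
  for (k in seq_along(tracks)) {
    pt <- attr(tracks[[k]], "parent_track")
    if (!is.null(pt))
      nodes$parent_id[match(firsts[k], nodes$id)] <- lasts[pt]
  }
  lineage_forest(nodes)
}

straight_track <- function(frames, y, x = NULL, z = 10) {
  x <- x %||% (10 + frames)
  tibble::tibble(frame = frames, z = z, y = y, x = x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
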