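#' Multiscale principal-curvature blob score
#'
#' Scores every voxel for "bright blob"-ness from the eigenvalues of the
#' Hessian of the Gaussian-smoothed image: at the centre of a bright nucleus
#' all three principal curvatures are negative, so the score is the product
#' `max(0, -lambda_i)` over the three eigenvalues and is zero wherever any
#' curvature is non-negative (background, edges, dark blobs). Each scale's
#' Hessian is computed in physical (um) units and scale-normalised by
#' `sigma^2`; the returned score is the pointwise maximum over scales.
#'
#' @param vol 3D intensity array `(z, y, x)`.
#' @param scales_um detection scales in micrometres (roughly nucleus radii).
#' @param voxel_size_um voxel size `(z, y, x)` in um.
#' @param return_scale if `TRUE`, also return the scale achieving the maximum.
#' @return 3D score array (non-negative), or a list `(score, scale)` when
#'   `return_scale` is `TRUE`.
#' @export
principal_curvature_score <- function(vol, scales_um, voxel_size_um,
                                      return_scale = FALSE) {
  stopifnot(length(scales_um) >= 1)
  d <- dim(vol)
  best <- array(0, d)
  best_scale <- array(scales_um[1], d)
  for (s in scales_um) {
    sig_vox <- s / voxel_size_um
    if (any(sig_vox < 1)) {
      warn(sprintf("scale %.3g um is below one voxel on some axis; clamped", s))
      sig_vox <- pmax(sig_vox, 1)
    }
    sm <- gauss_smooth(vol, sig_vox)
    H <- hessian_components(sm, voxel_size_um)
    sc <- s^2
    score <- .blob_score_sym3(as.vector(H$zz) * sc, as.vector(H$yy) * sc,
                              as.vector(H$xx) * sc, as.vector(H$zy) * sc,
                              as.vector(H$zx) * sc, as.vector(H$yx) * sc)
    dim(score) <- d
    upd <- score > best
    best[upd] <- score[upd]
    best_scale[upd] <- s
  }
  if (return_scale) list(score = best, scale = best_scale) else best
}

#' Region significance against its surrounding shell
#'
#' Contrast-to-noise z-score of a candidate region: difference between the
#' mean interior and mean shell intensity, in units of the standard error
#' implied by the (robust, global) noise sd.
#'
#' @param vol 3D intensity array.
#' @param interior,shell integer vectors of linear voxel indices (disjoint).
#' @param noise_sd positive noise standard deviation, e.g. from
#'   [estimate_noise_sd()].
#' @return scalar z-score.
#' @export
region_significance <- function(vol, interior, shell, noise_sd) {
  if (length(interior) < 1) abort("empty interior")
  if (length(shell) < 1) abort("empty shell: region has no usable neighborhood")
  if (noise_sd <= 0) abort("noise_sd must be positive")
  if (length(intersect(interior, shell)) > 0) abort("interior and shell overlap")
  (mean(vol[interior]) - mean(vol[shell])) /
    (noise_sd * sqrt(1 / length(interior) + 1 / length(shell)))
}

# linear indices of voxels within an um-radius band [r0, r1] of a um center
ball_indices <- function(center_um, r0, r1, voxel_size_um, dims) {
  w <- voxel_window(center_um, rep(r1, 3), voxel_size_um, dims)
  if (is.null(w)) return(integer(0))
  g <- window_grid(w)
  p <- voxel_to_um(g, voxel_size_um)
  d2 <- (p[, 1] - center_um[1])^2 + (p[, 2] - center_um[2])^2 +
    (p[, 3] - center_um[3])^2
  keep <- d2 >= r0^2 & d2 <= r1^2
  lin_index(g[keep, , drop = FALSE], dims)
}

#' Seed detection from a blob-score volume
#'
#' Finds local maxima of the score, suppresses duplicates within one scale
#' radius, and keeps maxima whose interior is significantly brighter than its
#' surrounding shell (`z >= z_thr`). Each seed carries the scale of maximal
#' response, a small core voxel set (hard foreground for the min-cut) and its
#' interior/shell significance.
#'
#' @param score 3D score array or the list returned by
#'   [principal_curvature_score()] with `return_scale = TRUE`.
#' @param vol the intensity volume the score came from.
#' @param z_thr significance threshold (z-score units), `> 0`.
#' @param voxel_size_um voxel size in um.
#' @return a list of seeds; each has `center_um`, `center_vox`, `scale_um`,
#'   `score`, `z`, `core` (linear indices) and `interior`.
#' @export
detect_seeds <- function(score, vol, z_thr, voxel_size_um) {
  stopifnot(z_thr > 0)
  if (is.list(score)) { scale_map <- score$scale; score <- score$score }
  else scale_map <- array(NA_real_, dim(score))
  d <- dim(score)
  # 26-neighborhood local maxima with positive score
  is_max <- score > 0
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    nb <- ax_shift(ax_shift(ax_shift(score, dz, 1), dy, 2), dx, 3)
    is_max <- is_max & (score >= nb)
    if (!any(is_max)) break
  }
  cand <- which(is_max)
  if (length(cand) == 0) return(list())
  cand <- cand[order(score[cand], decreasing = TRUE)]
  pos <- voxel_to_um(unlin_index(cand, d), voxel_size_um)
  scl <- scale_map[cand]
  scl[is.na(scl)] <- max(voxel_size_um) * 2
  # greedy non-maximum suppression within one scale radius
  keep <- logical(length(cand))
  taken_pos <- NULL
  taken_scl <- numeric(0)
  for (i in seq_along(cand)) {
    if (is.null(taken_pos)) ok <- TRUE
    else {
      dd <- sqrt(colSums((t(taken_pos) - pos[i, ])^2))
      ok <- all(dd > pmax(taken_scl, scl[i]))
    }
    if (ok) {
      keep[i] <- TRUE
      taken_pos <- rbind(taken_pos, pos[i, ])
      taken_scl <- c(taken_scl, scl[i])
    }
  }
  cand <- cand[keep]; pos <- pos[keep, , drop = FALSE]; scl <- scl[keep]
  noise_sd <- max(estimate_noise_sd(vol), 1e-12)
  seeds <- list()
  for (i in seq_along(cand)) {
    s <- scl[i]
    # a physical floor on the test region keeps the interior mean from being
    # dominated by the (selected) peak voxels at small scales
    r_int <- max(0.9 * s, 2.5)
    interior <- ball_indices(pos[i, ], 0, r_int, voxel_size_um, d)
    shell <- ball_indices(pos[i, ], 1.44 * r_int, 2.1 * r_int, voxel_size_um, d)
    shell <- setdiff(shell, interior)
    if (length(shell) == 0) { # region near the border: take what is available
      shell <- setdiff(ball_indices(pos[i, ], 1.2 * r_int, 2.9 * r_int,
                                    voxel_size_um, d),
                       interior)
      if (length(shell) == 0)
        abort("seed region has no surrounding shell (volume too small)")
    }
    z <- region_significance(vol, interior, shell, noise_sd)
    if (!is.finite(z) || z < z_thr) next
    core <- ball_indices(pos[i, ], 0, max(0.5 * s, 1.01 * min(voxel_size_um)),
                         voxel_size_um, d)
    seeds[[length(seeds) + 1]] <- list(
      center_um = pos[i, ], center_vox = unlin_index(cand[i], d)[1, ],
      scale_um = s, score = score[cand[i]], z = z,
      core = core, interior = interior)
  }
  seeds
}

# single-linkage grouping of seeds by center distance
group_seeds <- function(seeds) {
  n <- length(seeds)
  if (n == 1) return(list(1L))
  pos <- t(vapply(seeds, function(s) s$center_um, numeric(3)))
  scl <- vapply(seeds, function(s) s$scale_um, 1)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (sqrt(sum((pos[i, ] - pos[j, ])^2)) <= 2 * (scl[i] + scl[j])) {
      parent[find(i)] <- find(j)
    }
  }
  split(seq_len(n), vapply(seq_len(n), find, 1L))
}

#' Seeded min-cut boundary refinement
#'
#' Turns detected seeds into a voxel-level instance segmentation. Seeds are
#' grouped spatially; within each group's dilated bounding box a voxel graph
#' is built with neighbour capacities `exp(-(dI)^2 / (2 sigma_g^2))` and
#' terminal capacities from foreground/background intensity log-likelihood
#' ratios. One binary min-cut is solved per seed against background plus the
#' other seeds' cores (hard constraints); voxels claimed by several seeds go
#' to the seed with the nearer centre.
#'
#' @param vol 3D intensity array.
#' @param seeds list of seeds from [detect_seeds()].
#' @param voxel_size_um voxel size in um.
#' @param gradient_sigma intensity scale of the boundary term; `NULL` =
#'   `(foreground - background) / 4` estimated from the data.
#' @param labels optional integer label to assign per seed (defaults `1..n`).
#' @return integer label array of `dim(vol)`.
#' @export
refine_boundaries_mincut <- function(vol, seeds, voxel_size_um,
                                     gradient_sigma = NULL, labels = NULL) {
  stopifnot(length(seeds) >= 1)
  d <- dim(vol)
  out <- array(0L, d)
  if (is.null(labels)) labels <- seq_along(seeds)
  mu_b <- median(vol)
  groups <- group_seeds(seeds)
  for (grp in groups) {
    gs <- seeds[grp]
    claims <- vector("list", length(gs))
    pos <- t(vapply(gs, function(s) s$center_um, numeric(3)))
    pad <- 2.2 * max(vapply(gs, function(s) s$scale_um, 1))
    w <- voxel_window(c(apply(pos, 2, min)), 0, voxel_size_um, d)
    lo <- floor((apply(pos, 2, min) - pad) / voxel_size_um) + 1
    hi <- ceiling((apply(pos, 2, max) + pad) / voxel_size_um) + 1
    lo <- pmax(1, lo); hi <- pmin(d, hi)
    w <- list(lo = as.integer(lo), hi = as.integer(hi))
    sub <- vol[w$lo[1]:w$hi[1], w$lo[2]:w$hi[2], w$lo[3]:w$hi[3], drop = FALSE]
    sd3 <- dim(sub)
    nvox <- prod(sd3)
    # map group-frame linear indices into subvolume linear indices
    to_sub <- function(lin) {
      ix <- unlin_index(lin, d)
      ok <- ix[, 1] >= w$lo[1] & ix[, 1] <= w$hi[1] &
        ix[, 2] >= w$lo[2] & ix[, 2] <= w$hi[2] &
        ix[, 3] >= w$lo[3] & ix[, 3] <= w$hi[3]
      ix <- sweep(ix[ok, , drop = FALSE], 2, w$lo - 1L, `-`)
      lin_index(ix, sd3)
    }
    mu_f <- mean(unlist(lapply(gs, function(s) vol[s$interior])))
    sig_n <- max(estimate_noise_sd(sub), 1e-6)
    sg <- gradient_sigma %||% max((mu_f - mu_b) / 4, sig_n, 1e-6)
    s_lik <- max((mu_f - mu_b) / 4, sig_n)
    I <- as.vector(sub)
    llr <- (mu_f - mu_b) * (2 * I - mu_f - mu_b) / (2 * s_lik^2)
    llr <- pmin(pmax(llr, -25), 25)
    cap_src <- pmax(llr, 0)
    cap_snk <- pmax(-llr, 0)
    # 6-neighbour edges within subvolume
    edges <- NULL; wts <- NULL
    for (ax in 1:3) {
      idx <- window_grid(list(lo = c(1L, 1L, 1L), hi = sd3))
      keep <- idx[, ax] < sd3[ax]
      a <- lin_index(idx[keep, , drop = FALSE], sd3)
      idx2 <- idx[keep, , drop = FALSE]; idx2[, ax] <- idx2[, ax] + 1L
      b <- lin_index(idx2, sd3)
      wab <- 2 * exp(-((I[a] - I[b])^2) / (2 * sg^2)) + 1e-4
      edges <- rbind(edges, cbind(a, b))
      wts <- c(wts, wab)
    }
    border <- which({
      ix <- unlin_index(seq_len(nvox), sd3)
      ix[, 1] == 1 | ix[, 1] == sd3[1] | ix[, 2] == 1 | ix[, 2] == sd3[2] |
        ix[, 3] == 1 | ix[, 3] == sd3[3]
    })
    HARD <- 1e5
    for (si in seq_along(gs)) {
      core <- to_sub(gs[[si]]$core)
      if (length(core) == 0) next
      other_core <- unlist(lapply(gs[-si], function(s) to_sub(s$core)))
      cs <- cap_src; ck <- cap_snk
      cs[core] <- HARD; ck[core] <- 0
      if (length(other_core)) { ck[other_core] <- HARD; cs[other_core] <- 0 }
      ck[border] <- pmax(ck[border], HARD)
      S <- nvox + 1L; T <- nvox + 2L
      nz_s <- which(cs > 0); nz_k <- which(ck > 0)
      ed <- rbind(edges,
                  cbind(rep(S, length(nz_s)), nz_s),
                  cbind(nz_k, rep(T, length(nz_k))))
      cap <- c(wts, cs[nz_s], ck[nz_k])
      g <- igraph::graph_from_edgelist(ed, directed = FALSE)
      if (igraph::vcount(g) < T) g <- igraph::add_vertices(g, T - igraph::vcount(g))
      fl <- igraph::max_flow(g, source = S, target = T, capacity = cap)
      part <- fl$partition1
      src_side <- setdiff(as.integer(part[part <= nvox]), other_core)
      if (!(length(src_side))) src_side <- core
      claims[[si]] <- src_side
    }
    # resolve contested voxels by nearer seed centre
    claimed <- unlist(claims)
    dup <- unique(claimed[duplicated(claimed)])
    if (length(dup)) {
      pos_dup <- voxel_to_um(sweep(unlin_index(dup, sd3), 2, -(w$lo - 1L), `-`) - 0,
                             voxel_size_um)
      # recompute positions in frame coordinates
      ixf <- sweep(unlin_index(dup, sd3), 2, w$lo - 1L, `+`)
      pos_dup <- voxel_to_um(ixf, voxel_size_um)
      nearest <- apply(pos_dup, 1, function(p) {
        which.min(colSums((t(pos) - p)^2))
      })
      for (si in seq_along(gs)) {
        lose <- dup[nearest != si]
        claims[[si]] <- setdiff(claims[[si]], lose)
      }
    }
    for (si in seq_along(gs)) {
      if (length(claims[[si]]) == 0) next # zero-mass seed dropped
      ixf <- sweep(unlin_index(claims[[si]], sd3), 2, w$lo - 1L, `+`)
      linf <- lin_index(ixf, d)
      free <- out[linf] == 0L
      out[linf[free]] <- labels[grp[si]]
      # the seed's own core always keeps its label
      out[gs[[si]]$core] <- labels[grp[si]]
    }
  }
  out
}

#' Detect nuclei in one frame
#'
#' Composition of blob scoring, significance-tested seed detection, and
#' seeded min-cut refinement, followed by volume gating. Deterministic for a
#' fixed input.
#'
#' @param vol 3D intensity array.
#' @param config a [pipeline_config()].
#' @param voxel_size_um voxel size in um.
#' @param id_offset detections get ids `id_offset + 1, ...`.
#' @param frame 0-based frame index stored in the output.
#' @return list with `detections` (tibble: id, frame, z, y, x, volume_um3,
#'   n_voxels, mean_intensity, z_score, scale_um) and `labels` (integer array,
#'   values = detection ids).
#' @export
detect_frame <- function(vol, config, voxel_size_um, id_offset = 0L, frame = 0L) {
  sc <- principal_curvature_score(vol, config$detect$scales_um, voxel_size_um,
                                  return_scale = TRUE)
  seeds <- detect_seeds(sc, vol, config$detect$z_threshold, voxel_size_um)
  if (length(seeds) == 0) {
    return(list(detections = empty_detections(), labels = array(0L, dim(vol))))
  }
  lab <- refine_boundaries_mincut(vol, seeds, voxel_size_um,
                                  gradient_sigma = config$detect$gradient_sigma,
                                  labels = seq_along(seeds) + id_offset)
  det <- measure_labels(lab, vol, voxel_size_um, frame = frame)
  det$scale_um <- vapply(seeds, function(s) s$scale_um, 1)[match(det$id - id_offset,
                                                                 seq_along(seeds))]
  det$z_score <- vapply(seeds, function(s) s$z, 1)[match(det$id - id_offset,
                                                         seq_along(seeds))]
  keep <- det$volume_um3 >= config$detect$min_volume_um3 &
    det$volume_um3 <= config$detect$max_volume_um3
  drop_ids <- det$id[!keep]
  if (length(drop_ids)) lab[lab %in% drop_ids] <- 0L
  list(detections = det[keep, , drop = FALSE], labels = lab)
}

empty_detections <- function() {
  tibble(id = integer(), frame = integer(), z = numeric(), y = numeric(),
         x = numeric(), volume_um3 = numeric(), n_voxels = integer(),
         mean_intensity = numeric(), z_score = numeric(), scale_um = numeric())
}

# centroid / volume / intensity statistics for every positive label in a frame
measure_labels <- function(lab, vol, voxel_size_um, frame = 0L) {
  pos <- which(lab > 0L)
  if (length(pos) == 0) return(empty_detections())
  d <- dim(lab)
  ids <- lab[pos]
  ix <- unlin_index(pos, d)
  um <- voxel_to_um(ix, voxel_size_um)
  inten <- if (is.null(vol)) rep(NA_real_, length(pos)) else vol[pos]
  agg <- rowsum(cbind(um, inten, 1), ids)
  uid <- as.integer(rownames(agg))
  nv <- agg[, 5]
  tibble(id = uid, frame = as.integer(frame),
         z = agg[, 1] / nv, y = agg[, 2] / nv, x = agg[, 3] / nv,
         volume_um3 = nv * prod(voxel_size_um), n_voxels = as.integer(nv),
         mean_intensity = agg[, 4] / nv,
         z_score = NA_real_, scale_um = (3 * nv * prod(voxel_size_um) /
                                           (4 * pi))^(1 / 3))
}

#' Detect nuclei across a whole series
#'
#' @param series a [volume_series()].
#' @param config a [pipeline_config()].
#' @return list of `detections` tibble over all frames and a [label_series()].
#' @export
detect_series <- function(series, config) {
  dets <- list(); labs <- list(); off <- 0L
  for (t in seq_len(n_frames(series)) - 1L) {
    r <- detect_frame(frame_volume(series, t), config, series$voxel_size_um,
                      id_offset = off, frame = t)
    dets[[t + 1]] <- r$detections
    labs[[t + 1]] <- r$labels
    if (nrow(r$detections)) off <- max(r$detections$id)
  }
  list(detections = bind_rows(dets),
       labels = label_series(labs, series$voxel_size_um, series$frame_interval_s))
}

#' Build a detection table from an existing label series
#'
#' For precomputed or ground-truth segmentations. Labels are made globally
#' unique across frames (CTC-style label volumes reuse track labels per
#' frame); the returned table carries the original per-frame label in
#' `label_in_frame`. If intensity is supplied, a cheap contrast z-score
#' against the global background is attached; otherwise detections are
#' treated as fully confident.
#'
#' @param labels a [label_series()].
#' @param series optional matching [volume_series()].
#' @return list `(detections, labels)` where `labels` has values equal to the
#'   global detection ids.
#' @export
detections_from_labels <- function(labels, series = NULL) {
  vs <- labels$voxel_size_um
  out_lab <- vector("list", n_frames(labels))
  dets <- vector("list", n_frames(labels))
  off <- 0L
  for (t in seq_len(n_frames(labels)) - 1L) {
    lab <- frame_volume(labels, t)
    vol <- if (is.null(series)) NULL else frame_volume(series, t)
    ids <- sort(setdiff(unique(as.vector(lab)), 0L))
    if (length(ids) == 0) {
      out_lab[[t + 1]] <- lab
      dets[[t + 1]] <- empty_detections()
      next
    }
    new_ids <- off + seq_along(ids)
    map <- integer(max(ids) + 1L)
    map[ids + 1L] <- new_ids
    relab <- lab
    posv <- lab > 0L
    relab[posv] <- map[lab[posv] + 1L]
    m <- measure_labels(relab, vol, vs, frame = t)
    m$label_in_frame <- ids[match(m$id, new_ids)]
    if (!is.null(vol)) {
      bg <- median(vol)
      nsd <- max(estimate_noise_sd(vol), 1e-12)
      m$z_score <- (m$mean_intensity - bg) / (nsd / sqrt(m$n_voxels))
    } else {
      m$z_score <- Inf
    }
    out_lab[[t + 1]] <- relab
    dets[[t + 1]] <- m
    off <- off + length(ids)
  }
  list(detections = bind_rows(dets),
       labels = label_series(out_lab, vs, labels$frame_interval_s))
}
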