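# Ground-truthed synthetic embryo scenes: moving, dividing nuclei on a
# spherical shell, rendered as Gaussian blobs through a Gaussian PSF with
# Poisson and read noise, exported with matching labels and lineage forest.

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulation parameters
#'
#' Defaults emulate a gastrulation-stage embryo crop: a few hundred nuclei on
#' a spherical shell, pole-ward drift with Brownian jitter, occasional
#' divisions with a cell-cycle refractory period, and light-sheet-like
#' anisotropic sampling. SNR is defined as
#' `peak_contrast / read_noise_sd` (nuclei render additively on the
#' background, so the contrast is `peak_intensity`); the read noise sd follows from
#' `snr`. Poisson noise is applied to the pre-read-noise signal.
#'
#' @param ... overrides of any field.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(...) {
  p <- list(
    n_cells_initial = 200L,
    n_frames = 50L,
    domain_um = c(40, 200, 200),
    voxel_size_um = c(2, 1, 1),
    frame_interval_s = 60,
    shell_center_um = c(-117, 100, 100),
    shell_radius_um = 147,
    drift_um_per_frame = 1.0,
    brownian_sigma_um = 0.4,
    division_prob = 0.01,
    division_refractory_frames = 8L,
    nucleus_radius_um = c(2.8, 3.2),
    peak_intensity = 100,
    background = 10,
    psf_sigma_um = c(1.0, 0.6, 0.6),
    snr = 10,
    poisson = TRUE,
    seed = 1L
  )
  over <- list(...)
  for (nm in names(over)) p[[nm]] <- over[[nm]]
  stopifnot(p$division_prob >= 0, p$division_prob <= 1,
            all(p$nucleus_radius_um > 0), p$n_frames >= 1)
  structure(p, class = "sim_params")
}

# tangential pole-ward drift on the shell (um per frame)
shell_drift <- function(pos, params) {
  u <- sweep(pos, 2, params$shell_center_um)
  u <- u / sqrt(rowSums(u^2))
  pole <- c(-1, 0, 0) # toward low z: the vegetal direction in this geometry
  tang <- -(outer(rowSums(sweep(u, 2, pole, `*`)), c(1, 1, 1)) * u)
  tang <- sweep(tang, 2, pole, `+`)
  nrm <- sqrt(rowSums(tang^2))
  nrm[nrm < 1e-9] <- 1
  tang / nrm * params$drift_um_per_frame
}

# push apart centroid pairs closer than one nucleus radius; pull softly back
# onto the shell
relax_positions <- function(pos, radius, params) {
  for (iter in 1:4) {
    D <- as.matrix(dist(pos))
    diag(D) <- Inf
    minsep <- outer(radius, radius, pmax)
    bad <- which(D < minsep, arr.ind = TRUE)
    bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
    if (nrow(bad) == 0) break
    for (k in seq_len(nrow(bad))) {
      i <- bad[k, 1]; j <- bad[k, 2]
      dir <- pos[j, ] - pos[i, ]
      dd <- sqrt(sum(dir^2))
      if (dd < 1e-9) { dir <- c(0, 1, 0); dd <- 1 }
      push <- (minsep[i, j] - dd) / 2
      pos[i, ] <- pos[i, ] - dir / dd * push
      pos[j, ] <- pos[j, ] + dir / dd * push
    }
  }
  u <- sweep(pos, 2, params$shell_center_um)
  r <- sqrt(rowSums(u^2))
  target <- params$shell_radius_um + 0.5 * (r - params$shell_radius_um)
  pos <- sweep(u * (target / r), 2, params$shell_center_um, `+`)
  # keep a safety margin inside the domain
  m <- 2 * max(params$nucleus_radius_um)
  for (ax in 1:3) pos[, ax] <- pmin(pmax(pos[, ax], m), params$domain_um[ax] - m)
  pos
}

# render one frame: returns list(intensity (noisy), labels)
render_frame <- function(inst, params) {
  vs <- params$voxel_size_um
  dims <- as.integer(ceiling(params$domain_um / vs))
  signal <- array(0, dims)
  labels <- array(0L, dims)
  claim_d2 <- array(Inf, dims)
  for (k in seq_len(nrow(inst))) {
    r <- inst$radius[k]
    sig <- sqrt((r / sqrt(2))^2 + params$psf_sigma_um^2)
    ctr <- c(inst$z[k], inst$y[k], inst$x[k])
    w <- voxel_window(ctr, 3.2 * sig, vs, dims)
    if (is.null(w)) next
    g <- window_grid(w)
    p <- voxel_to_um(g, vs)
    q <- ((p[, 1] - ctr[1]) / sig[1])^2 + ((p[, 2] - ctr[2]) / sig[2])^2 +
      ((p[, 3] - ctr[3]) / sig[3])^2
    s <- params$peak_intensity * exp(-0.5 * q)
    lin <- lin_index(g, dims)
    signal[lin] <- signal[lin] + s
    own <- s >= 0.5 * params$peak_intensity
    if (any(own)) {
      d2 <- (p[own, 1] - ctr[1])^2 + (p[own, 2] - ctr[2])^2 +
        (p[own, 3] - ctr[3])^2
      lo <- lin[own]
      better <- d2 < claim_d2[lo]
      labels[lo[better]] <- inst$node_id[k]
      claim_d2[lo[better]] <- d2[better]
    }
  }
  noisy <- signal + params$background
  if (params$poisson) noisy <- array(rpois(length(noisy), noisy), dims)
  # nuclei are rendered additively on the background, so the blob-peak
  # contrast equals peak_intensity and SNR = peak_intensity / read_sd
  read_sd <- params$peak_intensity / params$snr
  noisy <- noisy + array(rnorm(length(noisy), 0, read_sd), dims)
  noisy[noisy < 0] <- 0
  list(intensity = noisy, labels = labels)
}

#' Simulate an embryo-like 3D+t scene with ground truth
#'
#' Cells start on a spherical shell, drift tangentially toward the pole with
#' Brownian jitter and soft mutual repulsion, and divide (after a refractory
#' period) into two half-volume children displaced one radius apart. Frames
#' are rendered as Gaussian nuclei through the PSF with Poisson and Gaussian
#' read noise; ground-truth labels assign every voxel above a nucleus'
#' half-peak to the nearest nucleus centre.
#'
#' @param params a [sim_params()].
#' @return a `synthetic_scene`: list with `series` ([volume_series()]),
#'   `labels` ([label_series()], values = ground-truth node ids), `forest`
#'   (ground-truth [lineage_forest()]), and `params`.
#' @export
simulate_embryo <- function(params = sim_params()) {
  with_seed_local(params$seed, {
    n0 <- params$n_cells_initial
    # sample initial positions on the shell cap inside the domain
    margin <- 2 * max(params$nucleus_radius_um) + 1
    pos <- matrix(NA_real_, 0, 3)
    tries <- 0
    while (nrow(pos) < n0) {
      tries <- tries + 1
      if (tries > 200) abort("domain too small for n_cells_initial")
      u <- matrix(rnorm(3 * n0 * 2), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      cand <- sweep(u * params$shell_radius_um, 2, params$shell_center_um, `+`)
      ok <- cand[, 1] > margin & cand[, 1] < params$domain_um[1] - margin &
        cand[, 2] > margin & cand[, 2] < params$domain_um[2] - margin &
        cand[, 3] > margin & cand[, 3] < params$domain_um[3] - margin
      pos <- rbind(pos, cand[ok, , drop = FALSE])
    }
    pos <- pos[seq_len(n0), , drop = FALSE]
    radius <- runif(n0, params$nucleus_radius_um[1],
                    if (length(params$nucleus_radius_um) > 1)
                      params$nucleus_radius_um[2] else params$nucleus_radius_um[1])
    pos <- relax_positions(pos, radius, params)
    birth <- rep(-params$division_refractory_frames, n0)
    parent_node <- rep(NA_integer_, n0)

    node_id <- 0L
    inst <- list()
    rendered <- vector("list", params$n_frames)
    for (t in seq_len(params$n_frames) - 1L) {
      ids <- node_id + seq_len(nrow(pos))
      node_id <- node_id + nrow(pos)
      inst[[t + 1]] <- tibble(node_id = ids, frame = t,
                              z = pos[, 1], y = pos[, 2], x = pos[, 3],
                              radius = radius, parent_id = parent_node)
      rendered[[t + 1]] <- render_frame(inst[[t + 1]], params)
      if (t == params$n_frames - 1L) break
      # move
      drift <- shell_drift(pos, params)
      pos2 <- pos + drift +
        matrix(rnorm(length(pos), 0, params$brownian_sigma_um), ncol = 3)
      parent_node <- ids
      # divide
      age <- t - birth
      can <- age >= params$division_refractory_frames
      divides <- can & (runif(nrow(pos)) < params$division_prob)
      if (any(divides)) {
        keep <- which(!divides)
        new_pos <- pos2[keep, , drop = FALSE]
        new_rad <- radius[keep]
        new_birth <- birth[keep]
        new_parent <- parent_node[keep]
        for (i in which(divides)) {
          dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
          for (sgn in c(-1, 1)) {
            new_pos <- rbind(new_pos, pos2[i, ] + sgn * dir * radius[i])
            new_rad <- c(new_rad, radius[i] * 2^(-1 / 3))
            new_birth <- c(new_birth, t + 1L)
            new_parent <- c(new_parent, parent_node[i])
          }
        }
        pos2 <- new_pos; radius <- new_rad; birth <- new_birth
        parent_node <- new_parent
      }
      pos <- relax_positions(pos2, radius, params)
    }
    inst <- bind_rows(inst)
    labels <- label_series(lapply(rendered, `[[`, "labels"),
                           params$voxel_size_um, params$frame_interval_s)
    series <- volume_series(lapply(rendered, `[[`, "intensity"),
                            params$voxel_size_um, params$frame_interval_s)
    # ground-truth forest: volumes from the rendered labels
    nvox <- integer(max(inst$node_id))
    for (t in seq_len(n_frames(labels)) - 1L) {
      tb <- tabulate(frame_volume(labels, t), nbins = max(inst$node_id))
      nvox <- nvox + tb
    }
    nodes <- tibble(id = inst$node_id, frame = inst$frame, z = inst$z,
                    y = inst$y, x = inst$x,
                    volume_um3 = nvox[inst$node_id] * prod(params$voxel_size_um),
                    parent_id = inst$parent_id, interpolated = FALSE)
    nodes$track_id <- assign_track_ids(nodes)
    structure(list(series = series, labels = labels,
                   forest = lineage_forest(nodes), params = params),
              class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat("<synthetic_scene>\n")
  print(x$series)
  print(x$forest)
  invisible(x)
}

#' Inject segmentation corruptions into a scene
#'
#' Applies an error manifest to a copy of the ground-truth labels: `delete`
#' removes a node's label in its frame, `split` partitions a label by a plane
#' through its centroid, `merge` unions two same-frame labels. The corrupted
#' detection set is recomputed from the corrupted labels.
#'
#' @param scene a `synthetic_scene`.
#' @param manifest tibble with columns kind (`delete`/`split`/`merge`),
#'   node_id, node_id2 (merges only), and optional plane normal columns
#'   nz, ny, nx (splits; default z-axis... the normal is normalised).
#' @return list `(state, labels, manifest)` where `state` is a
#'   [scene_state()] ready for tracking and `labels` the corrupted series.
#' @export
inject_errors <- function(scene, manifest) {
  lab <- scene$labels
  nodes <- scene$forest$nodes
  if (nrow(manifest)) {
    ids <- c(manifest$node_id,
             if ("node_id2" %in% names(manifest)) manifest$node_id2)
    ids <- ids[!is.na(ids)]
    if (anyDuplicated(ids)) abort("a node may be corrupted at most once")
    if (!all(ids %in% nodes$id)) abort("manifest references unknown nodes")
  }
  next_id <- max(nodes$id) + 1L
  for (k in seq_len(nrow(manifest))) {
    mk <- manifest[k, ]
    i <- match(mk$node_id, nodes$id)
    t <- nodes$frame[i]
    L <- frame_volume(lab, t)
    vox <- which(L == mk$node_id)
    if (length(vox) == 0) abort("manifest node has no voxels")
    if (mk$kind == "delete") {
      L[vox] <- 0L
    } else if (mk$kind == "split") {
      nrm <- c(mk$nz %||% 0, mk$ny %||% 1, mk$nx %||% 0)
      if (all(nrm == 0)) nrm <- c(0, 1, 0)
      nrm <- nrm / sqrt(sum(nrm^2))
      um <- voxel_to_um(unlin_index(vox, dim(L)), lab$voxel_size_um)
      ctr <- colMeans(um)
      side <- as.numeric(sweep(um, 2, ctr) %*% nrm) >= 0
      if (all(side) || !any(side)) side <- um[, 2] >= median(um[, 2])
      L[vox[side]] <- next_id
      L[vox[!side]] <- next_id + 1L
      next_id <- next_id + 2L
    } else if (mk$kind == "merge") {
      j <- match(mk$node_id2, nodes$id)
      if (is.na(j) || nodes$frame[j] != t) abort("merge partner must share the frame")
      L[L == mk$node_id | L == mk$node_id2] <- next_id
      next_id <- next_id + 1L
    } else abort(sprintf("unknown corruption kind '%s'", mk$kind))
    lab$frames[[t + 1]] <- L
  }
  dd <- detections_from_labels(lab, scene$series)
  list(state = scene_state(scene$series, dd$labels, dd$detections),
       labels = lab, manifest = manifest)
}

#' Sample a random corruption manifest
#'
#' Draws deletions, splits and merges on a simulated scene under constraints
#' that keep the injected errors locally isolated: corrupted frames stay away
#' from track ends and divisions, at most one corruption per track within a
#' few frames, and merge partners are nearby same-frame nodes on different
#' tracks.
#'
#' @param scene a `synthetic_scene`.
#' @param n_delete,n_split,n_merge event counts.
#' @param seed RNG seed.
#' @param merge_dist_um maximum partner distance for merges.
#' @return manifest tibble for [inject_errors()].
#' @export
sample_error_manifest <- function(scene, n_delete = 10, n_split = 10,
                                  n_merge = 10, seed = 1,
                                  merge_dist_um = NULL) {
  nodes <- scene$forest$nodes
  merge_dist_um <- merge_dist_um %||% (2 * max(scene$params$nucleus_radius_um))
  tmax <- max(nodes$frame)
  kids <- table(nodes$parent_id[!is.na(nodes$parent_id)])
  div_parents <- as.integer(names(kids)[kids == 2])
  div_frames <- nodes$frame[match(div_parents, nodes$id)]
  div_tracks <- nodes$track_id[match(div_parents, nodes$id)]
  track_span <- nodes |> group_by(.data$track_id) |>
    summarise(f0 = min(.data$frame), f1 = max(.data$frame))
  near_div <- function(track, frame, w = 3) {
    any(div_tracks == track & abs(div_frames - frame) <= w) ||
      any(nodes$track_id[match(div_parents, nodes$id)] == track &
            abs(div_frames - frame) <= w)
  }
  eligible <- function(nd) {
    sp <- track_span[match(nd$track_id, track_span$track_id), ]
    nd$frame >= sp$f0 + 2 & nd$frame <= sp$f1 - 2 &
      nd$frame >= 2 & nd$frame <= tmax - 2
  }
  with_seed_local(seed, {
    cand <- nodes[eligible(nodes), ]
    cand <- cand[!vapply(seq_len(nrow(cand)), function(i)
      near_div(cand$track_id[i], cand$frame[i]), TRUE), ]
    used_nodes <- integer(0)
    used_track_frame <- character(0)
    ok_pick <- function(nd) {
      if (nd$id %in% used_nodes) return(FALSE)
      key <- paste(nd$track_id, round(nd$frame / 5))
      !(key %in% used_track_frame)
    }
    take <- function(nd) {
      used_nodes <<- c(used_nodes, nd$id)
      used_track_frame <<- c(used_track_frame, paste(nd$track_id,
                                                     round(nd$frame / 5)))
    }
    rows <- list()
    # merges first (they need partners)
    cand <- cand[sample.int(nrow(cand)), ]
    got <- 0
    for (i in seq_len(nrow(cand))) {
      if (got >= n_merge) break
      a <- cand[i, ]
      if (!ok_pick(a)) next
      same <- cand[cand$frame == a$frame & cand$track_id != a$track_id, ]
      if (nrow(same) == 0) next
      dd <- sqrt((same$z - a$z)^2 + (same$y - a$y)^2 + (same$x - a$x)^2)
      j <- which(dd <= merge_dist_um & dd > 0)
      j <- j[vapply(j, function(jj) ok_pick(same[jj, ]), TRUE)]
      if (length(j) == 0) next
      b <- same[j[which.min(dd[j])], ]
      take(a); take(b)
      got <- got + 1
      rows[[length(rows) + 1]] <- tibble(kind = "merge", node_id = a$id,
                                         node_id2 = b$id, frame = a$frame,
                                         nz = NA_real_, ny = NA_real_,
                                         nx = NA_real_)
    }
    for (kind in c("delete", "split")) {
      want <- if (kind == "delete") n_delete else n_split
      got <- 0
      cand <- cand[sample.int(nrow(cand)), ]
      for (i in seq_len(nrow(cand))) {
        if (got >= want) break
        a <- cand[i, ]
        if (!ok_pick(a)) next
        take(a)
        got <- got + 1
        nrm <- rnorm(3); nrm <- nrm / sqrt(sum(nrm^2))
        rows[[length(rows) + 1]] <- tibble(kind = kind, node_id = a$id,
                                           node_id2 = NA_integer_,
                                           frame = a$frame, nz = nrm[1],
                                           ny = nrm[2], nx = nrm[3])
      }
    }
    bind_rows(rows)
  })
}

#' Canonical two-lineage correction fixture
#'
#' A deterministic scene of two well-separated lineages over 20 frames, each
#' dividing once at frame 4, corrupted with exactly ten events: two missing
#' detections (deletions on distinct tracks), two over-segmentations (a
#' ground-truth nucleus split in two) and six under-segmentations (sibling
#' pairs merged into one label). The canonical worked example for the
#' iterative error-correction loop.
#'
#' @param seed RNG seed for the (small) rendering jitter and noise.
#' @return list: `scene` (ground truth), `state` (corrupted, ready for
#'   [iterate_correction()]), `labels` (corrupted series), `manifest`.
#' @export
fig3a_fixture <- function(seed = 1) {
  params <- sim_params(
    n_cells_initial = 2L, n_frames = 20L,
    domain_um = c(24, 48, 56), voxel_size_um = c(1, 1, 1),
    drift_um_per_frame = 1.0, brownian_sigma_um = 0,
    division_prob = 0, nucleus_radius_um = c(3, 3),
    psf_sigma_um = c(0.8, 0.8, 0.8), snr = 10, seed = seed)
  r <- 3; rc <- 3 * 2^(-1 / 3)
  with_seed_local(seed, {
    jit <- function() rnorm(3, 0, 0.12)
    build_lineage <- function(y0, id0) {
      rows <- list()
      nid <- id0
      # root: frames 0..4
      root_ids <- integer(5)
      for (t in 0:4) {
        p <- c(12, y0, 16 + t) + jit()
        nid <- nid + 1L
        root_ids[t + 1] <- nid
        rows[[length(rows) + 1]] <- tibble(
          node_id = nid, frame = t, z = p[1], y = p[2], x = p[3],
          radius = r,
          parent_id = if (t == 0) NA_integer_ else root_ids[t])
      }
      # two children: frames 5..19, offset +-3 um in y
      prev <- c(root_ids[5], root_ids[5])
      child_ids <- list(integer(15), integer(15))
      for (t in 5:19) for (ci in 1:2) {
        sgn <- if (ci == 1) -1 else 1
        p <- c(12, y0 + sgn * 3, 16 + t) + jit()
        nid <- nid + 1L
        child_ids[[ci]][t - 4] <- nid
        rows[[length(rows) + 1]] <- tibble(
          node_id = nid, frame = t, z = p[1], y = p[2], x = p[3],
          radius = rc, parent_id = prev[ci])
        prev[ci] <- nid
      }
      list(rows = bind_rows(rows), root = root_ids, children = child_ids,
           next_id = nid)
    }
    A <- build_lineage(14, 0L)
    B <- build_lineage(34, A$next_id)
    inst <- bind_rows(A$rows, B$rows)
    rendered <- vector("list", params$n_frames)
    for (t in 0:19)
      rendered[[t + 1]] <- render_frame(inst[inst$frame == t, ], params)
    labels <- label_series(lapply(rendered, `[[`, "labels"),
                           params$voxel_size_um, params$frame_interval_s)
    series <- volume_series(lapply(rendered, `[[`, "intensity"),
                            params$voxel_size_um, params$frame_interval_s)
    nvox <- integer(max(inst$node_id))
    for (t in 0:19) nvox <- nvox +
      tabulate(frame_volume(labels, t), nbins = max(inst$node_id))
    nodes <- tibble(id = inst$node_id, frame = inst$frame, z = inst$z,
                    y = inst$y, x = inst$x,
                    volume_um3 = nvox[inst$node_id] * prod(params$voxel_size_um),
                    parent_id = inst$parent_id, interpolated = FALSE)
    nodes$track_id <- assign_track_ids(nodes)
    scene <- structure(list(series = series, labels = labels,
                            forest = lineage_forest(nodes), params = params),
                       class = "synthetic_scene")
    node_at <- function(lin, which_child, t) {
      if (which_child == 0) lin$root[t + 1] else lin$children[[which_child]][t - 4]
    }
    manifest <- bind_rows(
      # two over-segmentations: the roots split in two at frame 2
      tibble(kind = "split", node_id = node_at(A, 0, 2), node_id2 = NA_integer_,
             frame = 2L, nz = 0, ny = 1, nx = 0),
      tibble(kind = "split", node_id = node_at(B, 0, 2), node_id2 = NA_integer_,
             frame = 2L, nz = 0, ny = 1, nx = 0),
      # six under-segmentations: sibling pairs merged
      bind_rows(lapply(c(7, 10, 13), function(t)
        tibble(kind = "merge", node_id = node_at(A, 1, t),
               node_id2 = node_at(A, 2, t), frame = as.integer(t),
               nz = NA_real_, ny = NA_real_, nx = NA_real_))),
      bind_rows(lapply(c(8, 11, 14), function(t)
        tibble(kind = "merge", node_id = node_at(B, 1, t),
               node_id2 = node_at(B, 2, t), frame = as.integer(t),
               nz = NA_real_, ny = NA_real_, nx = NA_real_))),
      # two missing detections on distinct tracks
      tibble(kind = "delete", node_id = node_at(A, 1, 16),
             node_id2 = NA_integer_, frame = 16L,
             nz = NA_real_, ny = NA_real_, nx = NA_real_),
      tibble(kind = "delete", node_id = node_at(B, 2, 17),
             node_id2 = NA_integer_, frame = 17L,
             nz = NA_real_, ny = NA_real_, nx = NA_real_)
    )
    inj <- inject_errors(scene, manifest)
    list(scene = scene, state = inj$state, labels = inj$labels,
         manifest = manifest)
  })
}
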