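#' Scene state for tracking and correction
#'
#' Bundles the three synchronised views the corrector edits in lockstep: the
#' intensity series (may be `NULL` when only labels are available), the label
#' series whose voxel values are global detection ids, and the detection
#' table.
#'
#' @param series a [volume_series()] or `NULL`.
#' @param labels a [label_series()] with values equal to detection ids.
#' @param detections detection tibble as from [detect_series()] or
#'   [detections_from_labels()].
#' @param domain_um optional physical extent `(z, y, x)` in um (defaults to
#'   the label volume extent).
#' @return a `scene_state` list.
#' @export
scene_state <- function(series, labels, detections, domain_um = NULL) {
  d <- dim(labels$frames[[1]])
  domain_um <- domain_um %||% (d * labels$voxel_size_um)
  structure(list(series = series, labels = labels, det = detections,
                 domain_um = domain_um),
            class = "scene_state")
}

#' Gap descriptors for active frame-skipping connections
#'
#' One row per intermediate frame of every skip arc that carries flow: the
#' optimizer chose to jump the gap, which suggests a missing detection there.
#' Interpolated centroids are linear between the endpoints (plus the motion
#' flow offset when a flow field is supplied at network build time).
#'
#' @param sol a `flow_solution`.
#' @return tibble with columns det_a, det_b, frame, z, y, x (interpolated
#'   position, um).
#' @export
find_skip_events <- function(sol) {
  a <- sol$arcs |> filter(.data$kind == "skip", .data$flow > 0)
  det <- sol$net$det
  if (nrow(a) == 0)
    return(tibble(det_a = integer(), det_b = integer(), frame = integer(),
                  z = numeric(), y = numeric(), x = numeric()))
  rows <- list()
  for (k in seq_len(nrow(a))) {
    da <- det[match(a$det[k], det$id), ]
    db <- det[match(a$det2[k], det$id), ]
    gap <- db$frame - da$frame
    for (g in seq_len(gap - 1)) {
      w <- g / gap
      rows[[length(rows) + 1]] <- tibble(
        det_a = da$id, det_b = db$id, frame = da$frame + g,
        z = (1 - w) * da$z + w * db$z,
        y = (1 - w) * da$y + w * db$y,
        x = (1 - w) * da$x + w * db$x)
    }
  }
  bind_rows(rows)
}

#' Re-detect a missing cell inside a gap
#'
#' Runs detection in a window of three nominal diameters around the
#' interpolated centroid with the significance threshold relaxed by
#' `correct$redetect_relax`, masking voxels already claimed by existing
#' labels. A recovered detection is accepted when it lies within the gating
#' radius of the interpolated position and passes the volume gates; on
#' acceptance the labels and detection table are updated in the returned
#' state.
#'
#' @param state a [scene_state()].
#' @param gap one row of [find_skip_events()].
#' @param config a [pipeline_config()].
#' @return list `(state, detection, accepted)`; `detection` is `NULL` when
#'   nothing acceptable was found.
#' @export
redetect_missing <- function(state, gap, config) {
  if (is.null(state$series))
    return(list(state = state, detection = NULL, accepted = FALSE))
  t <- gap$frame
  vol <- frame_volume(state$series, t)
  lab <- frame_volume(state$labels, t)
  vs <- state$labels$voxel_size_um
  d <- dim(vol)
  r <- config$nucleus_radius_um
  center <- c(gap$z, gap$y, gap$x)
  w <- voxel_window(center, rep(3 * r, 3), vs, d)
  if (is.null(w)) return(list(state = state, detection = NULL, accepted = FALSE))
  sub <- vol[w$lo[1]:w$hi[1], w$lo[2]:w$hi[2], w$lo[3]:w$hi[3], drop = FALSE]
  sub_lab <- lab[w$lo[1]:w$hi[1], w$lo[2]:w$hi[2], w$lo[3]:w$hi[3], drop = FALSE]
  bg <- median(vol)
  # flatten existing labels plus a dilation margin (their PSF tails), so only
  # unexplained intensity can seed a redetection
  masked <- sub
  if (any(sub_lab > 0L)) {
    delta <- 0.7 * r
    occupied <- sub_lab > 0L
    dil <- occupied
    steps <- lapply(1:3, function(ax) seq(-floor(delta / vs[ax]),
                                          floor(delta / vs[ax])))
    for (dz in steps[[1]]) for (dy in steps[[2]]) for (dx in steps[[3]]) {
      if (sqrt(sum((c(dz, dy, dx) * vs)^2)) > delta) next
      if (dz == 0 && dy == 0 && dx == 0) next
      dil <- dil | ax_shift(ax_shift(ax_shift(occupied, dz, 1), dy, 2), dx, 3)
    }
    masked[dil] <- bg
  }
  sc <- principal_curvature_score(masked, config$detect$scales_um, vs,
                                  return_scale = TRUE)
  z_rel <- config$detect$z_threshold * config$correct$redetect_relax
  seeds <- tryCatch(detect_seeds(sc, masked, z_rel, vs), error = function(e) list())
  if (length(seeds) == 0)
    return(list(state = state, detection = NULL, accepted = FALSE))
  origin_um <- (w$lo - 1) * vs
  gate <- config$link$gating_radius_um * config$link$strict_factor
  dists <- vapply(seeds, function(s) sqrt(sum((s$center_um + origin_um - center)^2)), 1)
  if (min(dists) > gate)
    return(list(state = state, detection = NULL, accepted = FALSE))
  seed <- seeds[[which.min(dists)]]
  new_id <- max(state$det$id, 0L) + 1L
  sub_seg <- refine_boundaries_mincut(masked, list(seed), vs,
                                      gradient_sigma = config$detect$gradient_sigma,
                                      labels = new_id)
  vox <- which(sub_seg == new_id & sub_lab == 0L)
  if (length(vox) == 0)
    return(list(state = state, detection = NULL, accepted = FALSE))
  volume <- length(vox) * prod(vs)
  if (volume < config$detect$min_volume_um3 || volume > config$detect$max_volume_um3)
    return(list(state = state, detection = NULL, accepted = FALSE))
  # grayscale prior: a recovered cell must be about as bright as the cohort
  # (residual PSF tails of neighbouring, already-explained nuclei are not)
  cohort_contrast <- median(state$det$mean_intensity, na.rm = TRUE) - bg
  if (is.finite(cohort_contrast) && cohort_contrast > 0) {
    got <- mean(sub[vox]) - bg
    if (got < 0.35 * cohort_contrast)
      return(list(state = state, detection = NULL, accepted = FALSE))
  }
  # write back into the frame
  ixf <- sweep(unlin_index(vox, dim(sub)), 2, w$lo - 1L, `+`)
  linf <- lin_index(ixf, d)
  lab[linf] <- new_id
  state$labels$frames[[t + 1]] <- lab
  m <- measure_labels(lab * (lab == new_id), vol, vs, frame = t)
  m$z_score <- seed$z
  m$scale_um <- seed$scale_um
  if ("label_in_frame" %in% names(state$det)) m$label_in_frame <- NA_integer_
  state$det <- bind_rows(state$det, m)
  list(state = state, detection = m, accepted = TRUE)
}

# tracklet membership helpers
tracklet_of <- function(tracklets, det_id) {
  i <- match(det_id, tracklets$det_id)
  if (is.na(i)) NA_integer_ else tracklets$tracklet_id[i]
}

#' Propose segmentation corrections from the current solution
#'
#' Under-segmentation (one detection covering two cells) is flagged from the
#' flow itself: a frame-skipping connection whose missing-cell redetection
#' failed because an existing label already covers the interpolated position,
#' while that label's volume exceeds `underseg_gamma` times the windowed
#' median volume of its own tracklet. The failed-gap position and the host
#' track's flow predecessor provide the split seeds. Over-segmentation (one
#' cell split in two) is flagged for a close pair where one member is a
#' one-frame orphan and the combined volume matches the pair's flow
#' predecessor and successor within `volume_tolerance`.
#'
#' @param sol a `flow_solution`.
#' @param state a [scene_state()].
#' @param config a [pipeline_config()].
#' @param tracklets tracklet tibble from [extract_tracklets()].
#' @param failed_gaps rows of [find_skip_events()] whose redetection was
#'   rejected (under-segmentation evidence).
#' @return tibble of proposals: kind (`split_underseg`/`merge_overseg`),
#'   frame, det1, det2, seed coordinates for splits, evidence string.
#' @export
find_seg_conflicts <- function(sol, state, config, tracklets,
                               failed_gaps = NULL) {
  det <- state$det
  cc <- config$correct
  props <- list()
  id <- det$id; fr <- det$frame
  zz <- det$z; yv <- det$y; xv <- det$x; vol <- det$volume_um3
  tl_of <- tracklets$tracklet_id[match(id, tracklets$det_id)]
  tl_len_tab <- table(tracklets$tracklet_id)
  tl_len <- as.integer(tl_len_tab[as.character(tl_of)])
  tl_len[is.na(tl_len)] <- 1L
  # flow predecessor / successor per detection (transition + skip arcs)
  tr <- sol$arcs[sol$arcs$flow > 0 &
                   sol$arcs$kind %in% c("transition", "skip"), ]
  maxid <- max(id)
  succ <- rep(NA_integer_, maxid); pred <- rep(NA_integer_, maxid)
  succ[tr$det] <- tr$det2; pred[tr$det2] <- tr$det
  row_of <- rep(NA_integer_, maxid); row_of[id] <- seq_along(id)
  idx_by_frame <- split(seq_along(id), fr)
  frame_rows <- function(t) {
    i <- match(as.character(t), names(idx_by_frame))
    if (is.na(i)) integer(0) else idx_by_frame[[i]]
  }
  # windowed median volume along the same tracklet, excluding self
  win_med <- rep(NA_real_, length(id))
  ord <- order(tl_of, fr)
  for (grp in split(ord, tl_of[ord])) {
    if (length(grp) < 3) next
    vg <- vol[grp]; fg <- fr[grp]
    for (a in seq_along(grp)) {
      sel <- abs(fg - fg[a]) <= cc$window_frames
      sel[a] <- FALSE
      if (sum(sel) >= 2) win_med[grp[a]] <- median(vg[sel])
    }
  }

  # --- under-segmentation -> split proposals. Evidence: a frame-skipping
  # connection whose missing-cell redetection failed because an existing,
  # volume-inflated label already covers the interpolated position.
  # a second evidence source for the same error: a two-to-one arc into a
  # detection at t-1 paired with a one-to-two arc out of it at t+1 (the
  # victim track was absorbed for one frame)
  mrg <- sol$arcs[sol$arcs$flow > 0 & sol$arcs$kind == "merge_parent", ]
  dvc <- sol$arcs[sol$arcs$flow > 0 & sol$arcs$kind == "div_child", ]
  bundle <- merge(data.frame(M = mrg$det2, a = mrg$det),
                  data.frame(M = dvc$det2, b = dvc$det), by = "M")
  if (nrow(bundle)) {
    ra <- row_of[bundle$a]; rb <- row_of[bundle$b]
    gaps2 <- tibble(det_a = bundle$a, det_b = bundle$b,
                    frame = fr[row_of[bundle$M]],
                    z = (zz[ra] + zz[rb]) / 2, y = (yv[ra] + yv[rb]) / 2,
                    x = (xv[ra] + xv[rb]) / 2)
    failed_gaps <- bind_rows(failed_gaps, gaps2)
  }
  if (!is.null(failed_gaps) && nrow(failed_gaps)) {
    seen_m <- integer(0)
    for (k in seq_len(nrow(failed_gaps))) {
      g <- failed_gaps[k, ]
      rows <- frame_rows(g$frame)
      if (length(rows) == 0) next
      dd <- sqrt((zz[rows] - g$z)^2 + (yv[rows] - g$y)^2 + (xv[rows] - g$x)^2)
      m <- rows[which.min(dd)]
      if (m %in% seen_m) next
      seen_m <- c(seen_m, m)
      if (min(dd) > 2 * config$nucleus_radius_um) next
      # size prior, two routes: the host label matches the sum of the two
      # putative members' previous volumes, or it clearly exceeds its own
      # track's windowed median
      va <- if (g$det_a <= maxid && !is.na(row_of[g$det_a]))
        vol[row_of[g$det_a]] else NA_real_
      hp <- if (!is.na(pred[id[m]])) vol[row_of[pred[id[m]]]] else NA_real_
      sum_ok <- !is.na(va) && !is.na(hp) &&
        abs(vol[m] / (va + hp) - 1) <= cc$volume_tolerance
      med_ok <- !is.na(win_med[m]) && vol[m] > cc$underseg_gamma * win_med[m]
      if (!sum_ok && !med_ok) next
      # second seed: the host track's own position (flow predecessor
      # projected), falling back to the reflection of the gap position
      pm <- if (!is.na(pred[id[m]])) row_of[pred[id[m]]] else NA_integer_
      if (!is.na(pm)) s2 <- c(zz[pm], yv[pm], xv[pm])
      else s2 <- 2 * c(zz[m], yv[m], xv[m]) - c(g$z, g$y, g$x)
      props[[length(props) + 1]] <- tibble(
        kind = "split_underseg", frame = fr[m], det1 = id[m],
        det2 = NA_integer_,
        seed1_z = g$z, seed1_y = g$y, seed1_x = g$x,
        seed2_z = s2[1], seed2_y = s2[2], seed2_x = s2[3],
        evidence = sprintf("failed redetection inside label %d (vol %.0f > %.2f x %.0f)",
                           id[m], vol[m], cc$underseg_gamma, win_med[m]))
    }
  }

  # --- over-segmentation -> merge proposals: a close same-frame pair where
  # one member is a one-frame orphan (or only enters/leaves through
  # one-to-two / two-to-one arcs) and the combined volume matches the pair's
  # own flow predecessor and successor
  orphan <- tl_len <= 1L
  vol_ok <- function(rows_nb, vol_sum) {
    rows_nb <- rows_nb[!is.na(rows_nb)]
    if (length(rows_nb) == 0) return(FALSE)
    ratio <- vol_sum / vol[rows_nb]
    any(ratio >= 1 - cc$volume_tolerance & ratio <= 1 + cc$volume_tolerance)
  }
  for (t in sort(unique(fr))) {
    rows <- frame_rows(t)
    if (length(rows) < 2) next
    D <- sqrt(outer(zz[rows], zz[rows], `-`)^2 +
                outer(yv[rows], yv[rows], `-`)^2 +
                outer(xv[rows], xv[rows], `-`)^2)
    pair <- which(D <= cc$merge_pair_dist_um & upper.tri(D), arr.ind = TRUE)
    if (nrow(pair) == 0) next
    keep <- orphan[rows[pair[, 1]]] | orphan[rows[pair[, 2]]]
    pair <- pair[keep, , drop = FALSE]
    for (q in seq_len(nrow(pair))) {
      i <- rows[pair[q, 1]]; j <- rows[pair[q, 2]]
      vol_sum <- vol[i] + vol[j]
      preds <- row_of[stats::na.omit(c(pred[id[i]], pred[id[j]]))]
      succs <- row_of[stats::na.omit(c(succ[id[i]], succ[id[j]]))]
      if (!vol_ok(preds, vol_sum) || !vol_ok(succs, vol_sum)) next
      props[[length(props) + 1]] <- tibble(
        kind = "merge_overseg", frame = t, det1 = id[i], det2 = id[j],
        seed1_z = NA_real_, seed1_y = NA_real_, seed1_x = NA_real_,
        seed2_z = NA_real_, seed2_y = NA_real_, seed2_x = NA_real_,
        evidence = sprintf("pair %.1f um apart, combined volume matches flow neighbours",
                           D[pair[q, 1], pair[q, 2]]))
    }
  }
  if (length(props) == 0)
    return(tibble(kind = character(), frame = integer(), det1 = integer(),
                  det2 = integer(), seed1_z = numeric(), seed1_y = numeric(),
                  seed1_x = numeric(), seed2_z = numeric(), seed2_y = numeric(),
                  seed2_x = numeric(), evidence = character()))
  bind_rows(props)
}

#' Split one detection into two by a seeded min-cut
#'
#' Partitions the detection's voxel set by a two-seed, intensity-weighted
#' min-cut; the voxel union is preserved exactly and both parts are
#' non-empty. The two input detections' id is retired and two fresh ids are
#' created.
#'
#' @param state a [scene_state()].
#' @param det_id detection to split.
#' @param seeds_um 2x3 matrix of seed positions (um, rows = seeds, cols z,y,x).
#' @param gradient_sigma optional intensity scale for the boundary term.
#' @return list `(state, new_ids)` or an error if the seeds coincide.
#' @export
apply_split <- function(state, det_id, seeds_um, gradient_sigma = NULL) {
  if (all(abs(seeds_um[1, ] - seeds_um[2, ]) < 1e-9)) abort("split seeds coincide")
  i <- match(det_id, state$det$id)
  if (is.na(i)) abort("unknown detection id")
  t <- state$det$frame[i]
  lab <- frame_volume(state$labels, t)
  vs <- state$labels$voxel_size_um
  d <- dim(lab)
  vox <- which(lab == det_id)
  if (length(vox) < 2) abort("detection too small to split")
  ix <- unlin_index(vox, d)
  um <- voxel_to_um(ix, vs)
  vol <- if (is.null(state$series)) NULL else frame_volume(state$series, t)
  I <- if (is.null(vol)) rep(1, length(vox)) else vol[vox]
  # seed anchor voxels = nearest set voxel to each seed position
  d1 <- colSums((t(um) - seeds_um[1, ])^2)
  d2 <- colSums((t(um) - seeds_um[2, ])^2)
  s1 <- which.min(d1); s2 <- which.min(d2)
  if (s1 == s2) abort("split seeds coincide within the voxel set")
  # hard anchors are small balls, not single voxels, so the minimum cut falls
  # on the neck between the lobes rather than around one anchor voxel
  r_anchor <- max(1.5, min(sqrt(d1[s2]), sqrt(d2[s1])) * 0.25)
  s1v <- which(d1 <= r_anchor^2 & d1 < d2)
  s2v <- which(d2 <= r_anchor^2 & d2 < d1)
  if (length(s1v) == 0) s1v <- s1
  if (length(s2v) == 0) s2v <- s2
  # 6-neighbour graph restricted to the voxel set
  key <- setNames(seq_along(vox), vox)
  edges <- NULL; wts <- NULL
  sg <- gradient_sigma %||% max(stats::sd(I), 1e-6)
  for (ax in 1:3) {
    ix2 <- ix; ix2[, ax] <- ix2[, ax] + 1L
    inside <- ix2[, ax] <= d[ax]
    lin2 <- lin_index(ix2[inside, , drop = FALSE], d)
    j <- key[as.character(lin2)]
    iidx <- which(inside)[!is.na(j)]
    jidx <- j[!is.na(j)]
    if (length(jidx)) {
      edges <- rbind(edges, cbind(iidx, as.integer(jidx)))
      wts <- c(wts, exp(-((I[iidx] - I[jidx])^2) / (2 * sg^2)) + 1e-5)
    }
  }
  n <- length(vox); S <- n + 1L; T <- n + 2L
  HARD <- 1e5
  ed <- rbind(edges, cbind(S, s1v), cbind(s2v, T))
  cap <- c(wts, rep(HARD, length(s1v)), rep(HARD, length(s2v)))
  g <- igraph::graph_from_edgelist(ed, directed = FALSE)
  if (igraph::vcount(g) < T) g <- igraph::add_vertices(g, T - igraph::vcount(g))
  fl <- igraph::max_flow(g, source = S, target = T, capacity = cap)
  part1 <- setdiff(as.integer(fl$partition1), c(S, T))
  part1 <- intersect(part1, seq_len(n))
  part2 <- setdiff(seq_len(n), part1)
  # stray components fall on the sink side; reassign by nearer seed anchor
  if (length(part1) == 0 || length(part2) == 0) {
    part1 <- which(d1 <= d2); part2 <- which(d1 > d2)
  }
  if (length(part1) == 0 || length(part2) == 0)
    abort("split produced an empty part")
  new_ids <- max(state$det$id) + 1:2
  lab[vox[part1]] <- new_ids[1]
  lab[vox[part2]] <- new_ids[2]
  state$labels$frames[[t + 1]] <- lab
  keepcols <- names(state$det)
  m <- measure_labels(lab * (lab %in% new_ids), vol, vs, frame = t)
  m$z_score <- state$det$z_score[i]
  state$det <- bind_rows(state$det[-i, ], m[, intersect(names(m), keepcols)])
  list(state = state, new_ids = new_ids)
}

#' Merge two same-frame detections into one
#'
#' The merged detection is the exact voxel union; its centroid is the
#' volume-weighted mean. The two input ids are retired and a fresh id is
#' created.
#'
#' @param state a [scene_state()].
#' @param id_a,id_b detection ids in the same frame, disjoint voxel sets.
#' @return list `(state, new_id)`.
#' @export
apply_merge <- function(state, id_a, id_b) {
  ia <- match(id_a, state$det$id); ib <- match(id_b, state$det$id)
  if (is.na(ia) || is.na(ib)) abort("unknown detection id")
  if (state$det$frame[ia] != state$det$frame[ib])
    abort("detections to merge must share a frame")
  t <- state$det$frame[ia]
  lab <- frame_volume(state$labels, t)
  new_id <- max(state$det$id) + 1L
  lab[lab == id_a | lab == id_b] <- new_id
  state$labels$frames[[t + 1]] <- lab
  vol <- if (is.null(state$series)) NULL else frame_volume(state$series, t)
  m <- measure_labels(lab * (lab == new_id), vol, state$labels$voxel_size_um,
                      frame = t)
  m$z_score <- max(state$det$z_score[c(ia, ib)], na.rm = TRUE)
  keepcols <- names(state$det)
  state$det <- bind_rows(state$det[-c(ia, ib), ],
                         m[, intersect(names(m), keepcols)])
  list(state = state, new_id = new_id)
}

#' Iterative error correction
#'
#' The pipeline's correction loop: link the current detections with the
#' stringent gate, read active frame-skipping connections off the optimal
#' flow and try to re-detect the implied missing cells, then propose and
#' apply segmentation corrections (splits of under-segmented detections,
#' merges of over-segmented pairs), and re-link. The loop stops when an
#' iteration accepts no corrections or after `correct$max_iterations`
#' (default 5).
#'
#' @param state a [scene_state()].
#' @param config a [pipeline_config()].
#' @param flow optional motion flow field.
#' @param keep_history record the detection table and tracklets at the start
#'   of each iteration (for convergence diagnostics).
#' @return a `correction_result`: list with the corrected `state`, final
#'   `tracklets` and `events`, the per-iteration `report` tibble
#'   (iteration, missing_redetect, split_underseg, merge_overseg, accepted),
#'   `converged` flag, and the final `solution`.
#' @export
iterate_correction <- function(state, config, flow = NULL,
                               keep_history = FALSE) {
  all_events <- list()
  report <- list()
  memo <- character(0)
  converged <- FALSE
  history <- list()
  sol <- NULL; tk <- NULL
  for (it in seq_len(config$correct$max_iterations)) {
    net <- build_circulation(state$det, config, flow = flow, strict = TRUE,
                             domain_um = state$domain_um)
    sol <- solve_circulation(net)
    tk <- extract_tracklets(sol)
    if (keep_history)
      history[[it]] <- list(state = state, tracklets = tk$tracklets)
    n_md <- 0L; n_sp <- 0L; n_mg <- 0L
    gaps <- find_skip_events(sol)
    failed_gaps <- gaps[0, ]
    for (k in seq_len(nrow(gaps))) {
      g <- gaps[k, ]
      key <- sprintf("miss:%d:%.0f:%.0f:%.0f", g$frame, g$z, g$y, g$x)
      if (key %in% memo) next
      res <- redetect_missing(state, g, config)
      all_events[[length(all_events) + 1]] <- tibble(
        iteration = it, kind = "missing_redetect", frame = g$frame,
        det1 = if (res$accepted) res$detection$id else NA_integer_,
        det2 = NA_integer_, accepted = res$accepted,
        evidence = sprintf("skip %d->%d", g$det_a, g$det_b))
      if (res$accepted) { state <- res$state; n_md <- n_md + 1L }
      else {
        memo <- c(memo, key)
        failed_gaps <- bind_rows(failed_gaps, g)
      }
    }
    props <- find_seg_conflicts(sol, state, config, tk$tracklets, failed_gaps)
    for (k in seq_len(nrow(props))) {
      pr <- props[k, ]
      dk <- state$det[match(pr$det1, state$det$id), ]
      if (nrow(dk) == 0 || is.na(dk$id)) next
      key <- sprintf("%s:%d:%.0f:%.0f:%.0f", pr$kind, pr$frame, dk$z, dk$y, dk$x)
      if (key %in% memo) next
      accepted <- FALSE
      if (pr$kind == "split_underseg") {
        res <- tryCatch(apply_split(state, pr$det1,
                                    rbind(c(pr$seed1_z, pr$seed1_y, pr$seed1_x),
                                          c(pr$seed2_z, pr$seed2_y, pr$seed2_x)),
                                    config$detect$gradient_sigma),
                        error = function(e) NULL)
        if (!is.null(res)) {
          vols <- res$state$det$volume_um3[match(res$new_ids, res$state$det$id)]
          if (all(vols >= config$detect$min_volume_um3)) {
            state <- res$state; accepted <- TRUE; n_sp <- n_sp + 1L
          }
        }
      } else if (pr$kind == "merge_overseg") {
        if (!is.na(match(pr$det2, state$det$id))) {
          res <- tryCatch(apply_merge(state, pr$det1, pr$det2),
                          error = function(e) NULL)
          if (!is.null(res)) { state <- res$state; accepted <- TRUE; n_mg <- n_mg + 1L }
        }
      }
      all_events[[length(all_events) + 1]] <- tibble(
        iteration = it, kind = pr$kind, frame = pr$frame, det1 = pr$det1,
        det2 = pr$det2, accepted = accepted, evidence = pr$evidence)
      if (!accepted) memo <- c(memo, key)
    }
    report[[it]] <- tibble(iteration = it, missing_redetect = n_md,
                           split_underseg = n_sp, merge_overseg = n_mg,
                           accepted = n_md + n_sp + n_mg)
    if (n_md + n_sp + n_mg == 0L) { converged <- TRUE; break }
  }
  # final re-link reflecting the last round of corrections
  net <- build_circulation(state$det, config, flow = flow, strict = TRUE,
                           domain_um = state$domain_um)
  sol <- solve_circulation(net)
  tk <- extract_tracklets(sol)
  structure(list(state = state, tracklets = tk$tracklets, events_flow = tk$events,
                 events = bind_rows(all_events) %||% tibble(),
                 report = bind_rows(report), converged = converged,
                 solution = sol, history = if (keep_history) history else NULL),
            class = "correction_result")
}

#' @export
print.correction_result <- function(x, ...) {
  cat("<correction_result>\n")
  print(as.data.frame(x$report), row.names = FALSE)
  cat(if (x$converged) "converged\n" else "stopped at iteration cap\n")
  invisible(x)
}
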