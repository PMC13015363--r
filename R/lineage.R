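#' Lineage forest
#'
#' The pipeline's product: one node per cell instance per frame, directed
#' parent->child edges, divisions as nodes with two children. Gap frames
#' inside merged tracks are filled with interpolated virtual nodes (flagged)
#' so exported lineages have a node in every frame they span.
#'
#' @param nodes tibble with columns id, frame, z, y, x, volume_um3,
#'   parent_id (NA for roots), track_id, interpolated.
#' @return a `lineage_forest`.
#' @export
lineage_forest <- function(nodes) {
  need <- c("id", "frame", "z", "y", "x", "volume_um3", "parent_id",
            "track_id", "interpolated")
  for (nm in setdiff(need, names(nodes))) {
    nodes[[nm]] <- switch(nm, track_id = NA_integer_, interpolated = FALSE,
                          parent_id = NA_integer_, volume_um3 = NA_real_,
                          NA)
  }
  nodes <- as_tibble(nodes)[, need]
  if (anyDuplicated(nodes$id)) abort("node ids must be unique")
  has_par <- !is.na(nodes$parent_id)
  pf <- nodes$frame[match(nodes$parent_id[has_par], nodes$id)]
  if (any(is.na(pf))) abort("parent_id references a missing node")
  if (any(pf >= nodes$frame[has_par])) abort("parent must precede child in time")
  outdeg <- table(nodes$parent_id[has_par])
  if (length(outdeg) && max(outdeg) > 2) abort("out-degree must be <= 2")
  structure(list(nodes = nodes), class = "lineage_forest")
}

#' @export
print.lineage_forest <- function(x, ...) {
  n <- x$nodes
  ndiv <- sum(table(n$parent_id[!is.na(n$parent_id)]) == 2)
  cat(sprintf("<lineage_forest> %d nodes, %d roots, %d divisions, frames %d..%d\n",
              nrow(n), sum(is.na(n$parent_id)), ndiv,
              min(n$frame), max(n$frame)))
  invisible(x)
}

#' @export
as_tibble.lineage_forest <- function(x, ...) x$nodes

#' Tidy a lineage forest into its node table
#' @param x a `lineage_forest`
#' @param ... unused
#' @return the nodes tibble
#' @export
tidy.lineage_forest <- function(x, ...) x$nodes

#' One-line summary statistics of a forest
#' @param x a `lineage_forest`
#' @param ... unused
#' @return tibble with node/root/division/track counts and frame span
#' @export
glance.lineage_forest <- function(x, ...) {
  n <- x$nodes
  tibble(n_nodes = nrow(n), n_roots = sum(is.na(n$parent_id)),
         n_divisions = sum(table(n$parent_id[!is.na(n$parent_id)]) == 2),
         n_tracks = length(unique(n$track_id)),
         first_frame = min(n$frame), last_frame = max(n$frame))
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")
#' @export
glance <- function(x, ...) UseMethod("glance")

forest_edges <- function(forest) {
  n <- forest$nodes
  e <- n[!is.na(n$parent_id), c("parent_id", "id", "frame")]
  names(e) <- c("from", "to", "to_frame")
  e
}

forest_children <- function(forest) {
  n <- forest$nodes
  split(n$id[!is.na(n$parent_id)], n$parent_id[!is.na(n$parent_id)])
}

division_nodes <- function(forest) {
  ch <- forest_children(forest)
  as.integer(names(ch)[lengths(ch) == 2])
}

#' Re-associate tracklets into full tracks
#'
#' Tracklets become nodes of a second, smaller circulation network whose
#' transition arcs join a tracklet's end to another's start across a gap of
#' up to `lineage$tracklet_gap_max` frames within the relaxed gate
#' `gating_radius_um * gap * relax_factor`; solving it exactly merges
#' tracklets into chains. One-to-two junctions surface later as division
#' candidates.
#'
#' @param tracklets tibble from [extract_tracklets()].
#' @param det detection table.
#' @param config a [pipeline_config()].
#' @param frame_range `c(t0, t1)` of the processed block.
#' @return tibble of merged tracks: chain_id, frame, det_id.
#' @export
associate_tracklets <- function(tracklets, det, config, frame_range = NULL) {
  if (nrow(tracklets) == 0)
    return(tibble(chain_id = integer(), frame = integer(), det_id = integer()))
  if (is.null(frame_range)) frame_range <- range(tracklets$frame)
  lp <- config$link; lg <- config$lineage
  ends <- tracklets |> group_by(.data$tracklet_id) |>
    summarise(start_frame = min(.data$frame), end_frame = max(.data$frame),
              start_det = .data$det_id[which.min(.data$frame)],
              end_det = .data$det_id[which.max(.data$frame)])
  m <- nrow(ends)
  di <- det[match(ends$end_det, det$id), ]
  dj <- det[match(ends$start_det, det$id), ]
  arcs_t <- list(); ti <- 0
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) next
    gap <- ends$start_frame[j] - ends$end_frame[i]
    if (gap < 1 || gap > lg$tracklet_gap_max) next
    dd <- sqrt((di$z[i] - dj$z[j])^2 + (di$y[i] - dj$y[j])^2 +
               (di$x[i] - dj$x[j])^2)
    if (dd > lp$gating_radius_um * gap * lg$relax_factor) next
    cost <- dd^2 / (2 * lp$sigma_motion_um^2) +
      lp$w_volume * log(dj$volume_um3[j] / di$volume_um3[i])^2 +
      (gap - 1) * lp$c_skip
    ti <- ti + 1
    arcs_t[[ti]] <- c(tail = 2L * i + 2L, head = 2L * j + 1L, cap = 1L,
                      cost = unname(cost), i = i, j = j)
  }
  pre <- 2L * seq_len(m) + 1L; post <- pre + 1L
  tails <- c(pre, rep(1L, m), post)
  heads <- c(post, pre, rep(2L, m))
  caps <- rep(1L, 3 * m)
  costs <- c(rep(-1000, m),
             ifelse(ends$start_frame == frame_range[1],
                    lp$c_border * lp$border_time_factor, lp$c_border),
             ifelse(ends$end_frame == frame_range[2],
                    lp$c_border * lp$border_time_factor, lp$c_border))
  tmat <- do.call(rbind, arcs_t)
  if (!is.null(tmat)) {
    tails <- c(tails, tmat[, "tail"]); heads <- c(heads, tmat[, "head"])
    caps <- c(caps, rep(1L, nrow(tmat))); costs <- c(costs, tmat[, "cost"])
  }
  r <- .mcf_solve(2L + 2L * m, as.integer(tails), as.integer(heads),
                  as.integer(caps), costs, 1L, 2L, TRUE, Inf)
  nxt <- rep(NA_integer_, m)
  if (!is.null(tmat)) {
    fl <- r$flow[(3 * m + 1):length(r$flow)]
    used <- which(fl > 0)
    nxt[tmat[used, "i"]] <- tmat[used, "j"]
  }
  has_pred <- rep(FALSE, m); has_pred[nxt[!is.na(nxt)]] <- TRUE
  chains <- list(); cid <- 0L
  for (s in which(!has_pred)) {
    cid <- cid + 1L
    seq_t <- s
    while (!is.na(nxt[tail(seq_t, 1)])) seq_t <- c(seq_t, nxt[tail(seq_t, 1)])
    rows <- tracklets |> filter(.data$tracklet_id %in% ends$tracklet_id[seq_t])
    ord <- order(rows$frame)
    chains[[cid]] <- tibble(chain_id = cid, frame = rows$frame[ord],
                            det_id = rows$det_id[ord])
  }
  bind_rows(chains)
}

#' Detect divisions among track junctions
#'
#' A chain start adjacent (next frame, within the gating radius) to a
#' continuing chain proposes that chain's node as a dividing parent. A
#' candidate is accepted when the parent's observed track length reaches
#' `division_min_parent_len` (tracks already present at the block's first
#' frame are exempt, since their true start is unobserved), both children's
#' volumes fall within `division_child_volume_frac` of the parent volume, and
#' parent and new child are mutually nearest. Rejected candidates are
#' returned so callers can route them back to segmentation correction.
#'
#' @param tracks merged tracks from [associate_tracklets()].
#' @param det detection table.
#' @param config a [pipeline_config()].
#' @param frame_range `c(t0, t1)` of the processed block.
#' @return list `divisions` (tibble parent, child1, child2, frame) and
#'   `rejected` (tibble with a reason column).
#' @export
detect_divisions <- function(tracks, det, config, frame_range = NULL) {
  lg <- config$lineage
  if (nrow(tracks) == 0)
    return(list(divisions = tibble(parent = integer(), child1 = integer(),
                                   child2 = integer(), frame = integer()),
                rejected = tibble()))
  if (is.null(frame_range)) frame_range <- range(tracks$frame)
  info <- tracks |> group_by(.data$chain_id) |>
    summarise(start_frame = min(.data$frame), end_frame = max(.data$frame))
  tracks <- tracks |> left_join(det |> select("id", "z", "y", "x", "volume_um3"),
                                by = c(det_id = "id"))
  # volume estimates smoothed along the chain: instantaneous label volumes
  # fluctuate with rendering/segmentation noise
  vol_around <- function(chain, f_lo, f_hi) {
    v <- tracks$volume_um3[tracks$chain_id == chain &
                             tracks$frame >= f_lo & tracks$frame <= f_hi]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  starts <- tracks |> group_by(.data$chain_id) |>
    filter(.data$frame == min(.data$frame)) |> ungroup() |>
    filter(.data$frame > frame_range[1])
  acc <- list(); rej <- list()
  taken_parent <- integer(0)
  R <- config$link$gating_radius_um
  if (nrow(starts)) starts <- starts[order(starts$frame, starts$det_id), ]
  for (k in seq_len(nrow(starts))) {
    s <- starts[k, ]
    f <- s$frame - 1L
    cand <- tracks |> filter(.data$frame == f)
    if (nrow(cand) == 0) next
    dd <- sqrt((cand$z - s$z)^2 + (cand$y - s$y)^2 + (cand$x - s$x)^2)
    if (min(dd) > R) next
    near3 <- order(dd)[seq_len(min(3, nrow(cand)))]
    near3 <- near3[dd[near3] <= R]
    verdicts <- list()
    for (pidx in near3) {
    parent <- cand[pidx, ]
    reason <- NULL
    vol_tier <- 3L
    pinfo <- info[match(parent$chain_id, info$chain_id), ]
    cont <- tracks |> filter(.data$chain_id == parent$chain_id,
                             .data$frame == s$frame)
    if (nrow(cont) == 0) reason <- "parent track does not continue"
    if (is.null(reason)) {
      # mutuality: s must be the nearest same-frame chain start to the parent
      other_starts <- starts |> filter(.data$frame == s$frame)
      d2 <- sqrt((other_starts$z - parent$z)^2 + (other_starts$y - parent$y)^2 +
                 (other_starts$x - parent$x)^2)
      if (other_starts$det_id[which.min(d2)] != s$det_id)
        reason <- "not mutually nearest"
    }
    if (is.null(reason)) {
      plen <- f - pinfo$start_frame + 1L
      if (pinfo$start_frame > frame_range[1] && plen < lg$division_min_parent_len)
        reason <- "parent track too short"
    }
    if (is.null(reason)) {
      fr <- lg$division_child_volume_frac
      pv <- vol_around(parent$chain_id, f - 2L, f)
      c1v <- vol_around(parent$chain_id, f + 1L, f + 3L)
      c2v <- vol_around(s$chain_id, s$frame, s$frame + 2L)
      r1 <- c1v / pv
      r2 <- c2v / pv
      # per-child window, or volume conservation (children together
      # reconstitute the parent) with a floor against asymmetric junk
      in_window <- !is.na(r1) && !is.na(r2) &&
        r1 >= fr[1] && r1 <= fr[2] && r2 >= fr[1] && r2 <= fr[2]
      conserved <- !is.na(r1) && !is.na(r2) &&
        abs(r1 + r2 - 1) <= 0.3 && min(r1, r2) >= 0.2
      if (!in_window && !conserved)
        reason <- "child volumes inconsistent with a division"
      vol_tier <- if (in_window) 1L else if (conserved) 2L else 3L
    }
    if (is.null(reason) && parent$det_id %in% taken_parent)
      reason <- "parent already divided"
    if (is.null(reason) &&
        sqrt(sum((c(cont$z[1], cont$y[1], cont$x[1]) - c(parent$z, parent$y,
                                                          parent$x))^2)) > R)
      reason <- "continuation child outside gate"
    verdicts[[length(verdicts) + 1]] <- list(parent = parent,
                                             cont = cont, reason = reason,
                                             tier = vol_tier)
    if (is.null(reason) && vol_tier == 1L) break
    }
    ok <- which(vapply(verdicts, function(v) is.null(v$reason), TRUE))
    if (length(ok) > 1) ok <- ok[order(vapply(verdicts[ok], function(v) v$tier, 1L))]
    if (length(ok)) {
      v <- verdicts[[ok[1]]]
      taken_parent <- c(taken_parent, v$parent$det_id)
      acc[[length(acc) + 1]] <- tibble(parent = v$parent$det_id,
                                       child1 = v$cont$det_id[1],
                                       child2 = s$det_id, frame = f)
    } else if (length(verdicts)) {
      v <- verdicts[[1]]
      rej[[length(rej) + 1]] <- tibble(parent = v$parent$det_id,
                                       child2 = s$det_id, frame = f,
                                       reason = v$reason)
    }
  }
  list(divisions = bind_rows(acc) %||%
         tibble(parent = integer(), child1 = integer(), child2 = integer(),
                frame = integer()),
       rejected = bind_rows(rej))
}

# assemble a forest from merged tracks + accepted divisions,
# filling frame gaps with interpolated virtual nodes
build_forest <- function(tracks, det, divisions) {
  if (nrow(tracks) == 0) return(lineage_forest(tibble(
    id = integer(), frame = integer(), z = numeric(), y = numeric(),
    x = numeric(), volume_um3 = numeric(), parent_id = integer(),
    track_id = integer(), interpolated = logical())))
  tracks <- tracks |> left_join(det |> select("id", "z", "y", "x", "volume_um3"),
                                by = c(det_id = "id")) |>
    arrange(.data$chain_id, .data$frame)
  next_id <- max(det$id) + 1L
  rows <- list()
  for (cid in unique(tracks$chain_id)) {
    tt <- tracks[tracks$chain_id == cid, ]
    prev_id <- NA_integer_
    for (k in seq_len(nrow(tt))) {
      if (k > 1 && tt$frame[k] > tt$frame[k - 1] + 1L) {
        gap <- tt$frame[k] - tt$frame[k - 1]
        for (g in seq_len(gap - 1)) {
          w <- g / gap
          rows[[length(rows) + 1]] <- tibble(
            id = next_id, frame = tt$frame[k - 1] + g,
            z = (1 - w) * tt$z[k - 1] + w * tt$z[k],
            y = (1 - w) * tt$y[k - 1] + w * tt$y[k],
            x = (1 - w) * tt$x[k - 1] + w * tt$x[k],
            volume_um3 = (1 - w) * tt$volume_um3[k - 1] + w * tt$volume_um3[k],
            parent_id = prev_id, interpolated = TRUE)
          prev_id <- next_id
          next_id <- next_id + 1L
        }
      }
      rows[[length(rows) + 1]] <- tibble(
        id = tt$det_id[k], frame = tt$frame[k], z = tt$z[k], y = tt$y[k],
        x = tt$x[k], volume_um3 = tt$volume_um3[k], parent_id = prev_id,
        interpolated = FALSE)
      prev_id <- tt$det_id[k]
    }
  }
  nodes <- bind_rows(rows)
  # wire divisions: the new child's root gets the parent node as parent
  for (k in seq_len(nrow(divisions))) {
    i <- match(divisions$child2[k], nodes$id)
    if (!is.na(i)) nodes$parent_id[i] <- divisions$parent[k]
  }
  nodes$track_id <- assign_track_ids(nodes)
  lineage_forest(nodes)
}

# CTC-style track ids: a new track starts at every root and division child
assign_track_ids <- function(nodes) {
  n <- nrow(nodes)
  if (n == 0) return(integer(0))
  parent_idx <- match(nodes$parent_id, nodes$id)
  outdeg <- tabulate(parent_idx[!is.na(parent_idx)], nbins = n)
  is_div <- outdeg == 2
  tid <- integer(n)
  cur <- 0L
  for (i in order(nodes$frame, nodes$id)) {
    p <- parent_idx[i]
    if (is.na(p) || is_div[p]) { cur <- cur + 1L; tid[i] <- cur }
    else tid[i] <- tid[p]
  }
  tid
}

#' Assemble final lineages from corrected tracklets
#'
#' Runs tracklet association, division detection and forest construction.
#'
#' @param corr a `correction_result` from [iterate_correction()].
#' @param config a [pipeline_config()].
#' @param frame_range optional `c(t0, t1)`.
#' @return a `lineage_forest`.
#' @export
assemble_lineage <- function(corr, config, frame_range = NULL) {
  det <- corr$state$det
  if (is.null(frame_range) && nrow(det)) frame_range <- range(det$frame)
  tracks <- associate_tracklets(corr$tracklets, det, config, frame_range)
  dv <- detect_divisions(tracks, det, config, frame_range)
  build_forest(tracks, det, dv$divisions)
}

#' Run the full tracking pipeline on a scene
#'
#' Detection (unless a detection table is supplied), iterative error
#' correction, and lineage assembly; optionally in overlapping batches that
#' are stitched by mutual nearest neighbours.
#'
#' @param state a [scene_state()] (use [detect_series()] or
#'   [detections_from_labels()] to construct one from raw data).
#' @param config a [pipeline_config()].
#' @return list `(forest, correction)`.
#' @export
track_scene <- function(state, config) {
  bs <- config$lineage$batch_size
  frames <- sort(unique(state$det$frame))
  t0 <- min(frames); t1 <- max(frames)
  if (bs <= 0 || bs >= (t1 - t0 + 1)) {
    corr <- iterate_correction(state, config)
    return(list(forest = assemble_lineage(corr, config, c(t0, t1)),
                correction = corr))
  }
  ov <- config$lineage$batch_overlap
  starts <- seq(t0, t1, by = bs - ov)
  starts <- starts[starts + ov <= t1]
  forests <- list(); corrs <- list()
  for (b in seq_along(starts)) {
    f0 <- starts[b]
    f1 <- if (b == length(starts)) t1 else min(starts[b] + bs - 1, t1)
    sub <- subset_state(state, f0, f1)
    corr <- iterate_correction(sub, config)
    fb <- assemble_lineage(corr, config, c(0L, f1 - f0))
    fb$nodes$frame <- fb$nodes$frame + f0
    forests[[b]] <- fb
    corrs[[b]] <- corr
    if (f1 == t1) break
  }
  list(forest = stitch_batches(forests, overlap = ov,
                               gating_um = config$link$gating_radius_um),
       correction = corrs)
}

# restrict a scene state to frames [f0, f1] (frames keep their absolute index)
subset_state <- function(state, f0, f1) {
  idx <- (f0:f1) + 1L
  series <- if (is.null(state$series)) NULL else
    volume_series(state$series$frames[idx], state$series$voxel_size_um,
                  state$series$frame_interval_s)
  labels <- label_series(state$labels$frames[idx], state$labels$voxel_size_um,
                         state$labels$frame_interval_s)
  # frames stay absolute: rewrap with an offset-aware shim
  series2 <- series
  labels2 <- labels
  st <- scene_state(series2, labels2, state$det |> filter(.data$frame >= f0,
                                                          .data$frame <= f1),
                    domain_um = state$domain_um)
  st$frame_offset <- f0
  # shift frame indices to local, remembering the offset
  st$det$frame <- st$det$frame - f0
  st
}

#' Stitch lineage forests computed on overlapping frame batches
#'
#' Consecutive batches must share at least one frame. In the middle overlap
#' frame detections are matched across batches by mutual nearest neighbour
#' within the gating radius; matched pairs splice tracks, unmatched tracks
#' terminate or begin as in their own batch, and the earlier batch's topology
#' wins up to the splice frame.
#'
#' @param forests list of `lineage_forest` over overlapping frame ranges
#'   (in temporal order; node frames are absolute).
#' @param overlap number of shared frames between consecutive batches.
#' @param gating_um match radius for the mutual-nearest-neighbour splice.
#' @return a single `lineage_forest`.
#' @export
stitch_batches <- function(forests, overlap, gating_um) {
  stopifnot(length(forests) >= 1)
  acc <- forests[[1]]
  for (b in seq_along(forests)[-1]) {
    acc <- stitch_pair(acc, forests[[b]], overlap, gating_um)
  }
  acc
}

stitch_pair <- function(fa, fb, overlap, gating_um) {
  na <- fa$nodes; nb <- fb$nodes
  if (nrow(nb) == 0) return(fa)
  if (nrow(na) == 0) return(fb)
  lo <- min(nb$frame); hi <- max(na$frame)
  if (lo > hi) abort("batches do not overlap")
  mid <- floor((lo + hi) / 2)
  a_mid <- na |> filter(.data$frame == mid)
  b_mid <- nb |> filter(.data$frame == mid)
  # mutual nearest neighbours within the gate
  map_b_to_a <- integer(0)
  if (nrow(a_mid) && nrow(b_mid)) {
    D <- outer(a_mid$z, b_mid$z, `-`)^2 + outer(a_mid$y, b_mid$y, `-`)^2 +
      outer(a_mid$x, b_mid$x, `-`)^2
    nn_a <- apply(D, 2, which.min)   # for each b, nearest a
    nn_b <- apply(D, 1, which.min)   # for each a, nearest b
    ok <- which(nn_b[nn_a] == seq_len(nrow(b_mid)) &
                  D[cbind(nn_a, seq_len(nrow(b_mid)))] <= gating_um^2)
    map_b_to_a <- setNames(a_mid$id[nn_a[ok]], b_mid$id[ok])
  }
  keep_a <- na |> filter(.data$frame <= mid)
  keep_b <- nb |> filter(.data$frame > mid)
  # batch-b ids may collide with batch-a ids: remap keep_b ids
  offset <- max(na$id, nb$id) + 1L
  remap <- function(ids) {
    out <- ids
    hit <- !is.na(ids) & as.character(ids) %in% names(map_b_to_a)
    out[hit] <- map_b_to_a[as.character(ids[hit])]
    clash <- !is.na(out) & !hit & out %in% keep_a$id
    out[clash] <- out[clash] + offset
    out
  }
  keep_b$parent_id_new <- remap(keep_b$parent_id)
  keep_b$id_new <- remap(keep_b$id)
  # parents of keep_b nodes at frame mid+1 that were NOT matched: they start anew
  at_first <- keep_b$frame == mid + 1
  par_ok <- keep_b$parent_id_new %in% c(keep_a$id, keep_b$id_new)
  keep_b$parent_id_new[!par_ok] <- NA_integer_
  keep_b <- keep_b |> mutate(id = .data$id_new, parent_id = .data$parent_id_new) |>
    select(-"id_new", -"parent_id_new")
  nodes <- bind_rows(keep_a, keep_b)
  nodes$track_id <- assign_track_ids(nodes)
  lineage_forest(nodes)
}

#' Trace selected cells back to their ancestors
#'
#' Follows unique parent pointers from a selection at frame `T` back to
#' `t_target`, returning each ancestor's position and the selected
#' descendants it accounts for. Cells whose track begins after `t_target`
#' are reported with `entered_after = TRUE` rather than an error.
#'
#' @param forest a `lineage_forest`.
#' @param selected node ids at the later frame.
#' @param t_target earlier frame to trace back to.
#' @return tibble: ancestor_id, frame, z, y, x, n_descendants,
#'   entered_after; plus a `descendants` list-column of selected ids.
#' @export
backtrack_fates <- function(forest, selected, t_target) {
  n <- forest$nodes
  parent_idx <- match(n$parent_id, n$id)
  anc <- vapply(selected, function(id) {
    i <- match(id, n$id)
    if (is.na(i)) abort(sprintf("node %s not in forest", id))
    if (n$frame[i] < t_target) abort("selected node precedes t_target")
    while (n$frame[i] > t_target && !is.na(parent_idx[i]))
      i <- parent_idx[i]
    i
  }, 1L)
  res <- tibble(selected = selected, anc_row = anc)
  out <- res |> group_by(.data$anc_row) |>
    summarise(descendants = list(.data$selected), n_descendants = dplyr::n())
  tibble(ancestor_id = n$id[out$anc_row], frame = n$frame[out$anc_row],
         z = n$z[out$anc_row], y = n$y[out$anc_row], x = n$x[out$anc_row],
         n_descendants = out$n_descendants,
         entered_after = n$frame[out$anc_row] > t_target,
         descendants = out$descendants)
}

#' Forest view of raw tracklets (no gap filling, no divisions)
#'
#' Builds a `lineage_forest` directly from a tracklet decomposition: nodes
#' are the detections in tracks, edges join consecutive tracklet entries
#' (skip gaps stay unfilled). This is the object the error-correction loop
#' iterates on, and the right basis for per-iteration error curves.
#'
#' @param det detection table.
#' @param tracklets tibble from [extract_tracklets()].
#' @return a `lineage_forest`.
#' @export
tracklet_forest <- function(det, tracklets) {
  tt <- tracklets |>
    left_join(det |> select("id", "z", "y", "x", "volume_um3"),
              by = c(det_id = "id")) |>
    arrange(.data$tracklet_id, .data$frame) |>
    group_by(.data$tracklet_id) |>
    mutate(parent_id = dplyr::lag(.data$det_id)) |>
    ungroup()
  nodes <- tibble(id = tt$det_id, frame = tt$frame, z = tt$z, y = tt$y,
                  x = tt$x, volume_um3 = tt$volume_um3,
                  parent_id = tt$parent_id, track_id = tt$tracklet_id,
                  interpolated = FALSE)
  lineage_forest(nodes)
}
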