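#' Motion/size cost of linking two detections
#'
#' `cost = d^2 / (2 sigma_m^2) + w_v * log(vol_b / vol_a)^2 + (gap - 1) * C_skip`
#' where `d` is the distance between `b` and the flow-predicted position of
#' `a`. Returns `Inf` (arc omitted) when `d` exceeds the gating radius times
#' the frame gap.
#'
#' @param a,b detection rows (lists with `frame`, `z`, `y`, `x`,
#'   `volume_um3`); `b$frame > a$frame`.
#' @param flow_offset length-3 displacement (um) predicted for `a`, usually
#'   from a motion [FlowField][estimate_motion_flow].
#' @param params the `link` section of a [pipeline_config()]; the gating
#'   radius used is `gating_radius_um * strict` where `strict` is the
#'   `strict_factor` when `strict = TRUE`.
#' @param strict use the stringent first-pass gate?
#' @return non-negative cost, or `Inf` when gated out.
#' @export
transition_cost <- function(a, b, flow_offset = c(0, 0, 0), params,
                            strict = TRUE) {
  gap <- b$frame - a$frame
  stopifnot(gap >= 1)
  if (gap > params$g_max) return(Inf)
  R <- params$gating_radius_um * (if (strict) params$strict_factor else 1)
  d <- sqrt((b$z - (a$z + flow_offset[1]))^2 +
            (b$y - (a$y + flow_offset[2]))^2 +
            (b$x - (a$x + flow_offset[3]))^2)
  if (d > R * gap) return(Inf)
  d^2 / (2 * params$sigma_motion_um^2) +
    params$w_volume * log(b$volume_um3 / a$volume_um3)^2 +
    (gap - 1) * params$c_skip
}

# logistic detection confidence -> observation cost
detection_cost <- function(z_score, z_thr) {
  p <- 1 / (1 + exp(-(z_score - z_thr)))
  p <- pmin(pmax(p, 1e-3), 1 - 1e-3)
  -log(p / (1 - p))
}

# border cost with reductions at sequence ends and near the spatial border
border_cost <- function(det, at_end, params, domain_um = NULL, radius_um = 3) {
  f <- rep(1, nrow(det))
  f[at_end] <- params$border_time_factor
  if (!is.null(domain_um)) {
    near <- det$z < 2 * radius_um | det$y < 2 * radius_um | det$x < 2 * radius_um |
      det$z > domain_um[1] - 2 * radius_um | det$y > domain_um[2] - 2 * radius_um |
      det$x > domain_um[3] - 2 * radius_um
    f[near & !at_end] <- params$border_space_factor
  }
  params$c_border * f
}

#' Build the association network over a block of frames
#'
#' Every detection contributes a unit-capacity observation arc between its
#' pre and post node, priced by its detection confidence; appearance and
#' disappearance arcs connect to a dummy source/sink with border-dependent
#' cost; transition (and frame-skipping) arcs follow [transition_cost()];
#' discounted division-child entry arcs and merge-parent exit arcs realise
#' one-to-two and two-to-one matchings while keeping unit flow conservation.
#'
#' @param det detections tibble (all frames of the block).
#' @param config a [pipeline_config()].
#' @param flow optional motion flow field (see [estimate_motion_flow()]).
#' @param strict stringent gating (first pass) or relaxed.
#' @param domain_um optional physical extent for spatial-border cost
#'   reduction.
#' @param frame_range optional `c(t0, t1)`; defaults to the detection range.
#' @return a `circulation_network`: list with `arcs` tibble
#'   (tail, head, cap, cost, kind, det, det2, gap), node bookkeeping and the
#'   parameters used.
#' @export
build_circulation <- function(det, config, flow = NULL, strict = TRUE,
                              domain_um = NULL, frame_range = NULL) {
  p <- config$link
  det <- arrange(det, .data$frame, .data$id)
  n <- nrow(det)
  if (is.null(frame_range)) {
    frame_range <- if (n) range(det$frame) else c(0L, 0L)
  }
  net_nodes <- 2L + 2L * n
  if (n == 0) {
    return(structure(list(arcs = tibble(tail = integer(), head = integer(),
                                        cap = integer(), cost = numeric(),
                                        kind = character(), det = integer(),
                                        det2 = integer(), gap = integer()),
                          n_nodes = 2L, det = det, frame_range = frame_range,
                          config = config, strict = strict),
                     class = "circulation_network"))
  }
  pre <- 2L * seq_len(n) + 1L
  post <- pre + 1L
  R <- p$gating_radius_um * (if (strict) p$strict_factor else 1)

  arcs <- list()
  arcs$obs <- tibble(tail = pre, head = post, cap = 1L,
                     cost = detection_cost(det$z_score, config$detect$z_threshold),
                     kind = "observation", det = det$id, det2 = NA_integer_,
                     gap = 0L)
  app_cost <- border_cost(det, det$frame == frame_range[1], p, domain_um,
                          config$nucleus_radius_um)
  dis_cost <- border_cost(det, det$frame == frame_range[2], p, domain_um,
                          config$nucleus_radius_um)
  arcs$appear <- tibble(tail = 1L, head = pre, cap = 1L, cost = app_cost,
                        kind = "appear", det = det$id, det2 = NA_integer_,
                        gap = 0L)
  arcs$disappear <- tibble(tail = post, head = 2L, cap = 1L, cost = dis_cost,
                           kind = "disappear", det = det$id,
                           det2 = NA_integer_, gap = 0L)

  by_frame <- split(seq_len(n), det$frame)
  fr_names <- as.integer(names(by_frame))
  pos <- cbind(det$z, det$y, det$x)
  trans <- list(); ti <- 0L
  for (fi in seq_along(fr_names)) {
    t <- fr_names[fi]
    ia <- by_frame[[fi]]
    for (gap in 1:p$g_max) {
      fj <- match(t + gap, fr_names)
      if (is.na(fj)) next
      ib <- by_frame[[fj]]
      off <- if (is.null(flow)) matrix(0, length(ia), 3) else
        t(apply(pos[ia, , drop = FALSE], 1, function(q)
          flow_at(flow, t, q) * gap))
      pa <- pos[ia, , drop = FALSE] + off
      D2 <- outer(pa[, 1], pos[ib, 1], `-`)^2 +
        outer(pa[, 2], pos[ib, 2], `-`)^2 +
        outer(pa[, 3], pos[ib, 3], `-`)^2
      ok <- which(D2 <= (R * gap)^2, arr.ind = TRUE)
      if (nrow(ok) == 0) next
      i <- ia[ok[, 1]]; j <- ib[ok[, 2]]
      cost <- D2[ok] / (2 * p$sigma_motion_um^2) +
        p$w_volume * log(det$volume_um3[j] / det$volume_um3[i])^2 +
        (gap - 1) * p$c_skip
      det_i <- det$id[i]; det_j <- det$id[j]
      ti <- ti + 1L
      trans[[ti]] <- tibble(tail = post[i], head = pre[j], cap = 1L,
                            cost = cost,
                            kind = ifelse(gap == 1L, "transition", "skip"),
                            det = det_i, det2 = det_j,
                            gap = as.integer(gap))
      # one-to-two / two-to-one candidates (gap-1 neighbours only)
      if (gap == 1L) {
        vr <- det$volume_um3[j] / det$volume_um3[i]
        div_ok <- ok[vr >= p$div_volume_frac[1] & vr <= p$div_volume_frac[2], ,
                     drop = FALSE]
        if (nrow(div_ok)) {
          di <- ia[div_ok[, 1]]; dj <- ib[div_ok[, 2]]
          dd2 <- D2[div_ok]
          # division displacement ~ one radius on top of normal motion, so
          # the distance term uses a doubled motion scale
          dcost <- p$div_discount * p$c_border + dd2 / (2 * (2 * p$sigma_motion_um)^2)
          det_dj <- det$id[dj]; det_di <- det$id[di]
          dtb <- tibble(tail = 1L, head = pre[dj], cap = 1L, cost = dcost,
                        kind = "div_child", det = det_dj,
                        det2 = det_di, gap = 1L)
          dtb <- dtb |> group_by(.data$det) |>
            arrange(.data$cost, .by_group = TRUE) |>
            slice(seq_len(p$div_merge_knn)) |> ungroup()
          ti <- ti + 1L; trans[[ti]] <- dtb
          vr2 <- det$volume_um3[i] / det$volume_um3[j]
          mrg_ok <- ok[vr2 >= p$div_volume_frac[1] & vr2 <= p$div_volume_frac[2], ,
                       drop = FALSE]
          if (nrow(mrg_ok)) {
            mi <- ia[mrg_ok[, 1]]; mj <- ib[mrg_ok[, 2]]
            md2 <- D2[mrg_ok]
            mcost <- p$div_discount * p$c_border + md2 / (2 * (2 * p$sigma_motion_um)^2)
            det_mi <- det$id[mi]; det_mj <- det$id[mj]
            mtb <- tibble(tail = post[mi], head = 2L, cap = 1L, cost = mcost,
                          kind = "merge_parent", det = det_mi,
                          det2 = det_mj, gap = 1L)
            mtb <- mtb |> group_by(.data$det) |>
              arrange(.data$cost, .by_group = TRUE) |>
              slice(seq_len(p$div_merge_knn)) |> ungroup()
            ti <- ti + 1L; trans[[ti]] <- mtb
          }
        }
      }
    }
  }
  arcs <- bind_rows(c(arcs, trans))
  # deterministic arc order (tie-break rule: frame, then detection id)
  kind_rank <- match(arcs$kind, c("observation", "appear", "disappear",
                                  "transition", "skip", "div_child",
                                  "merge_parent"))
  arcs <- arcs[order(kind_rank, arcs$det, arcs$det2, arcs$gap), ]
  structure(list(arcs = arcs, n_nodes = net_nodes, det = det,
                 pre = setNames(pre, det$id), post = setNames(post, det$id),
                 frame_range = frame_range, config = config, strict = strict),
            class = "circulation_network")
}

#' @export
print.circulation_network <- function(x, ...) {
  cat(sprintf("<circulation_network> %d detections, %d arcs (%s)\n",
              nrow(x$det), nrow(x$arcs),
              paste(names(table(x$arcs$kind)), table(x$arcs$kind),
                    sep = ":", collapse = " ")))
  invisible(x)
}

#' Solve the minimum-cost circulation exactly
#'
#' Successive shortest augmenting paths with node potentials; the number of
#' tracks emerges from the optimisation (augmentation stops when no
#' cost-reducing path through the network remains). Exact and deterministic
#' for a fixed network.
#'
#' @param net a `circulation_network` from [build_circulation()].
#' @return a `flow_solution`: the network's arcs with a `flow` column, the
#'   optimal `total_cost`, and the network itself.
#' @export
solve_circulation <- function(net) {
  a <- net$arcs
  if (nrow(a) == 0) {
    return(structure(list(arcs = a, total_cost = 0, net = net),
                     class = "flow_solution"))
  }
  r <- .mcf_solve(net$n_nodes, a$tail, a$head, a$cap, a$cost, 1L, 2L,
                  TRUE, Inf)
  a$flow <- r$flow
  structure(list(arcs = a, total_cost = r$total_cost, net = net),
            class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  used <- sum(x$arcs$flow > 0 & x$arcs$kind == "observation")
  cat(sprintf("<flow_solution> cost %.4f, %d detections in tracks\n",
              x$total_cost, used))
  invisible(x)
}

#' Exhaustive small-instance association oracle
#'
#' Enumerates every feasible track decomposition of the same network (entry
#' via appearance or a division-child arc, exit via disappearance or a
#' merge-parent arc, transitions/skips between used detections) and returns
#' the global optimum. Independent of the flow solver; intended as a test
#' oracle for up to ~18 detections.
#'
#' @inheritParams build_circulation
#' @return list with `cost` (optimal total) and `used` (ids of detections in
#'   tracks at the optimum).
#' @export
brute_force_association <- function(det, config, flow = NULL, strict = TRUE,
                                    domain_um = NULL, frame_range = NULL) {
  if (nrow(det) > 18) abort("instance too large for exhaustive search")
  net <- build_circulation(det, config, flow, strict, domain_um, frame_range)
  a <- net$arcs
  det <- net$det
  n <- nrow(det)
  if (n == 0) return(list(cost = 0, used = integer(0)))
  idx_of <- setNames(seq_len(n), det$id)
  obs <- a$cost[match(det$id, a$det[a$kind == "observation"])]
  obs <- a |> filter(.data$kind == "observation")
  obs_cost <- obs$cost[match(det$id, obs$det)]
  entry_best <- rep(Inf, n); exit_best <- rep(Inf, n)
  ap <- a |> filter(.data$kind %in% c("appear", "div_child"))
  for (k in seq_len(nrow(ap))) {
    i <- idx_of[[as.character(ap$det[k])]]
    entry_best[i] <- min(entry_best[i], ap$cost[k])
  }
  dp <- a |> filter(.data$kind %in% c("disappear", "merge_parent"))
  for (k in seq_len(nrow(dp))) {
    i <- idx_of[[as.character(dp$det[k])]]
    exit_best[i] <- min(exit_best[i], dp$cost[k])
  }
  tr <- a |> filter(.data$kind %in% c("transition", "skip"))
  trans_in <- vector("list", n) # per detection: matrix (from_idx, cost)
  for (k in seq_len(nrow(tr))) {
    j <- idx_of[[as.character(tr$det2[k])]]
    trans_in[[j]] <- rbind(trans_in[[j]],
                           c(idx_of[[as.character(tr$det[k])]], tr$cost[k]))
  }
  g_max <- config$link$g_max
  best <- Inf
  best_used <- NULL
  frames <- det$frame
  rec <- function(i, open, acc, used) {
    # finalize opens that can no longer be matched (costs may be negative,
    # so no branch-and-bound pruning on the running total)
    if (i <= n) {
      stale <- open[frames[open] < frames[i] - g_max]
      if (length(stale)) {
        acc <- acc + sum(exit_best[stale])
        open <- setdiff(open, stale)
      }
    }
    if (i > n) {
      tot <- acc + sum(exit_best[open])
      if (tot < best) { best <<- tot; best_used <<- used }
      return(invisible())
    }
    # option: unused
    rec(i + 1L, open, acc, used)
    # option: used, entry via best dummy entry
    base <- acc + obs_cost[i]
    if (is.finite(entry_best[i]))
      rec(i + 1L, c(open, i), base + entry_best[i], c(used, i))
    # option: used, entry via transition from an open detection
    ti <- trans_in[[i]]
    if (!is.null(ti)) for (k in seq_len(nrow(ti))) {
      j <- ti[k, 1]
      if (j %in% open)
        rec(i + 1L, c(setdiff(open, j), i), base + ti[k, 2], c(used, i))
    }
  }
  rec(1L, integer(0), 0, integer(0))
  list(cost = if (is.finite(best)) best else 0,
       used = det$id[best_used])
}

#' Decompose an optimal flow into tracklets and events
#'
#' Unit-flow paths become tracklets (frames strictly increasing; gaps only
#' where a skip arc carried the flow). Division-child and merge-parent arcs
#' are recorded as events rather than inlined into the paths.
#'
#' @param sol a `flow_solution`.
#' @return list with `tracklets` (tibble: tracklet_id, frame, det_id,
#'   confidence) and `events` (tibble: kind, frame, det, partner).
#' @export
extract_tracklets <- function(sol) {
  a <- sol$arcs
  det <- sol$net$det
  used <- a |> filter(.data$kind == "observation", .data$flow > 0)
  ev <- a |> filter(.data$flow > 0, .data$kind %in% c("div_child", "merge_parent"))
  events <- tibble(kind = ev$kind,
                   frame = det$frame[match(ev$det, det$id)],
                   det = ev$det, partner = ev$det2)
  if (nrow(used) == 0) {
    return(list(tracklets = tibble(tracklet_id = integer(), frame = integer(),
                                   det_id = integer(), confidence = numeric()),
                events = events))
  }
  tr <- a |> filter(.data$flow > 0, .data$kind %in% c("transition", "skip"))
  maxid <- max(det$id)
  nxt <- rep(NA_integer_, maxid)
  link_cost <- rep(NA_real_, maxid)
  nxt[tr$det] <- tr$det2
  link_cost[tr$det] <- tr$cost
  has_pred <- used$det %in% tr$det2
  starts <- used$det[!has_pred]
  frame_of <- rep(NA_integer_, maxid)
  frame_of[det$id] <- det$frame
  rows <- list(); k <- 0L
  for (s in starts) {
    k <- k + 1L
    chain <- integer(0)
    costs <- numeric(0)
    cur <- s
    repeat {
      chain <- c(chain, cur)
      nx <- nxt[cur]
      if (is.na(nx)) break
      costs <- c(costs, link_cost[cur])
      cur <- nx
    }
    conf <- if (length(costs)) mean(1 / (1 + exp(costs))) else 1
    rows[[k]] <- tibble(tracklet_id = k, det_id = chain,
                        frame = frame_of[chain],
                        confidence = conf)
  }
  list(tracklets = bind_rows(rows) |>
         select("tracklet_id", "frame", "det_id", "confidence"),
       events = events)
}
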