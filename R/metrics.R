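# Evaluation against ground truth and downstream analytics.

# exact bipartite assignment via the min-cost flow core.
# costs >= 0; pairs with cost > gate are forbidden; each A node may stay
# unmatched at `penalty`. Returns integer vector: for each A row the matched
# B row or NA.
solve_assignment <- function(cost, gate = Inf, penalty = NULL) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0) return(integer(0))
  penalty <- penalty %||% (max(cost[is.finite(cost)], 0) + 1)
  if (!is.finite(penalty)) penalty <- (max(cost[is.finite(cost)], 0) + 1) * n
  S <- 1L; T <- 2L
  A <- 2L + seq_len(n); B <- 2L + n + seq_len(m)
  ok <- which(cost <= gate, arr.ind = TRUE)
  tails <- c(rep(S, n), A, if (m) B else integer(0), A[ok[, 1]])
  heads <- c(A, rep(T, n), rep(T, m), B[ok[, 2]])
  caps <- rep(1L, length(tails))
  costs <- c(rep(0, n), rep(penalty, n), rep(0, m), cost[ok])
  r <- .mcf_solve(2L + n + m, as.integer(tails), as.integer(heads),
                  as.integer(caps), costs, S, T, FALSE, n)
  match_arcs <- seq_along(tails) > (2L * n + m)
  fl <- r$flow[match_arcs]
  out <- rep(NA_integer_, n)
  used <- which(fl > 0)
  out[ok[used, 1]] <- ok[used, 2]
  out
}

#' Match predicted to ground-truth nodes frame by frame
#'
#' Per frame, an optimal one-to-one assignment minimising total distance
#' among pairs within `radius`.
#'
#' @param pred,gt `lineage_forest` objects.
#' @param radius match radius in um.
#' @return tibble: frame, gt_id, pred_id (`NA` when unmatched).
#' @export
match_detections <- function(pred, gt, radius) {
  stopifnot(radius > 0)
  gp <- gt$nodes; pp <- pred$nodes
  if (all(is.na(pp$z)) || all(is.na(gp$z)))
    abort("forest carries no node geometry (was it parsed without masks?)")
  out <- list()
  for (t in sort(unique(gp$frame))) {
    g <- gp[gp$frame == t, ]
    p <- pp[pp$frame == t, ]
    if (nrow(p) == 0) {
      out[[length(out) + 1]] <- tibble(frame = t, gt_id = g$id,
                                       pred_id = NA_integer_)
      next
    }
    D <- sqrt(outer(g$z, p$z, `-`)^2 + outer(g$y, p$y, `-`)^2 +
              outer(g$x, p$x, `-`)^2)
    mi <- solve_assignment(D, gate = radius, penalty = radius)
    out[[length(out) + 1]] <- tibble(frame = t, gt_id = g$id,
                                     pred_id = p$id[mi])
  }
  bind_rows(out)
}

#' Edge-level tracking errors per ground-truth edge
#'
#' A ground-truth edge `u -> v` is correct iff both endpoints are matched and
#' the prediction links `match(u) -> match(v)`. The error count is the number
#' of incorrect ground-truth edges plus the number of predicted edges between
#' matched nodes that correspond to no ground-truth edge; the error rate
#' divides by the number of ground-truth edges.
#'
#' @param pred,gt `lineage_forest` objects.
#' @param corr correspondence tibble from [match_detections()].
#' @return list of class `edge_error_report` with counts, `n_gt_edges` and
#'   `error_rate`.
#' @export
edge_error_rate <- function(pred, gt, corr) {
  ge <- forest_edges(gt); pe <- forest_edges(pred)
  if (nrow(ge) == 0) abort("ground truth has no edges")
  map <- setNames(corr$pred_id, corr$gt_id)
  mu <- map[as.character(ge$from)]; mv <- map[as.character(ge$to)]
  pred_key <- paste(pe$from, pe$to)
  gt_correct <- !is.na(mu) & !is.na(mv) & paste(mu, mv) %in% pred_key
  # predicted edges between matched nodes with no ground-truth counterpart
  rmap <- setNames(corr$gt_id, corr$pred_id)
  pu <- rmap[as.character(pe$from)]; pv <- rmap[as.character(pe$to)]
  gt_key <- paste(ge$from, ge$to)
  false_pred <- sum(!is.na(pu) & !is.na(pv) & !(paste(pu, pv) %in% gt_key))
  missed <- sum(!gt_correct)
  structure(list(counts = list(incorrect_gt_edges = missed,
                               false_pred_edges = false_pred),
                 n_gt_edges = nrow(ge),
                 error_rate = (missed + false_pred) / nrow(ge),
                 gt_edge_correct = tibble(from = ge$from, to = ge$to,
                                          correct = gt_correct)),
            class = "edge_error_report")
}

#' @export
print.edge_error_report <- function(x, ...) {
  cat(sprintf("<edge_error_report> %d GT edges; %d missed/wrong + %d false = rate %.4f\n",
              x$n_gt_edges, x$counts$incorrect_gt_edges,
              x$counts$false_pred_edges, x$error_rate))
  invisible(x)
}

# root-to-leaf paths of a forest, as list of id vectors (frame order)
forest_tracks <- function(forest) {
  n <- forest$nodes
  parent_idx <- match(n$parent_id, n$id)
  has_child <- logical(nrow(n))
  has_child[parent_idx[!is.na(parent_idx)]] <- TRUE
  lapply(which(!has_child), function(i) {
    path <- n$id[i]
    while (!is.na(parent_idx[i])) {
      i <- parent_idx[i]
      path <- c(n$id[i], path)
    }
    path
  })
}

#' Error-free track statistics
#'
#' For each ground-truth track (root-to-leaf path) the error-free length is
#' the number of consecutive correct edges from the track's first frame until
#' the first error; a track is error-free iff that prefix covers its whole
#' length. With `prefix = FALSE` the longest correct run anywhere in the
#' track is used instead.
#'
#' @inheritParams edge_error_rate
#' @param prefix measure the prefix from the track start (default) or the
#'   longest correct run.
#' @return list: `proportion_error_free`, `average_error_free_length`,
#'   per-track tibble.
#' @export
error_free_stats <- function(pred, gt, corr, prefix = TRUE) {
  rep <- edge_error_rate(pred, gt, corr)
  ok <- setNames(rep$gt_edge_correct$correct,
                 paste(rep$gt_edge_correct$from, rep$gt_edge_correct$to))
  tracks <- forest_tracks(gt)
  per <- vapply(tracks, function(path) {
    if (length(path) < 2) return(c(0, 1))
    e_ok <- ok[paste(path[-length(path)], path[-1])]
    if (prefix) {
      len <- if (all(e_ok)) length(e_ok) else which(!e_ok)[1] - 1
    } else {
      r <- rle(e_ok)
      len <- max(c(0, r$lengths[r$values]))
    }
    c(len, as.numeric(len == length(e_ok)))
  }, numeric(2))
  tibble_tracks <- tibble(track = seq_along(tracks),
                          n_edges = vapply(tracks, length, 1L) - 1L,
                          error_free_length = per[1, ],
                          error_free = per[2, ] == 1)
  list(proportion_error_free = mean(per[2, ]),
       average_error_free_length = mean(per[1, ]),
       tracks = tibble_tracks)
}

#' Division detection precision and recall
#'
#' A ground-truth division is recovered when its parent node is matched and
#' the matched predicted node also has two children whose matches are the
#' ground-truth children.
#'
#' @inheritParams edge_error_rate
#' @return tibble with n_gt, n_pred, matched, precision, recall.
#' @export
division_scores <- function(pred, gt, corr) {
  gd <- division_nodes(gt); pd <- division_nodes(pred)
  map <- setNames(corr$pred_id, corr$gt_id)
  rmap <- setNames(corr$gt_id, corr$pred_id)
  gkids <- forest_children(gt); pkids <- forest_children(pred)
  hit <- vapply(gd, function(u) {
    mu <- map[[as.character(u)]] %||% NA_integer_
    if (is.na(mu)) return(FALSE)
    pk <- pkids[[as.character(mu)]]
    if (is.null(pk) || length(pk) != 2) return(FALSE)
    gk <- gkids[[as.character(u)]]
    mk <- map[as.character(gk)]
    !any(is.na(mk)) && setequal(mk, pk)
  }, TRUE)
  matched <- sum(hit)
  tibble(n_gt = length(gd), n_pred = length(pd), matched = matched,
         precision = if (length(pd)) matched / length(pd) else NA_real_,
         recall = if (length(gd)) matched / length(gd) else NA_real_)
}

#' Count segmentation corruption events between two label series
#'
#' Overlap-based event counter: a ground-truth label with no covering
#' predicted label counts as a deletion; a ground-truth label covered by `k`
#' predicted pieces counts `k - 1` splits; a predicted label covering `k`
#' ground-truth labels counts `k - 1` merges. Coverage requires at least 30%
#' of the ground-truth (resp. predicted) label volume.
#'
#' @param pred,gt [label_series()] objects of identical geometry.
#' @return list with deletions, splits, merges and total.
#' @export
segmentation_event_counts <- function(pred, gt) {
  deletions <- 0L; splits <- 0L; merges <- 0L
  for (t in seq_len(n_frames(gt)) - 1L) {
    gl <- frame_volume(gt, t); pl <- frame_volume(pred, t)
    fg <- gl > 0L | pl > 0L
    g <- gl[fg]; p <- pl[fg]
    ov <- table(g, p)
    gsz <- rowSums(ov); psz <- colSums(ov)
    gids <- rownames(ov); pids <- colnames(ov)
    gi <- which(gids != "0"); pi <- which(pids != "0")
    for (i in gi) {
      cover <- which(pids != "0" & ov[i, ] >= 0.3 * gsz[i])
      if (length(cover) == 0) deletions <- deletions + 1L
      else splits <- splits + (length(cover) - 1L)
    }
    for (j in pi) {
      cover <- which(gids != "0" & ov[, j] >= 0.3 * pmin(gsz, psz[j]))
      if (length(cover) >= 2) merges <- merges + (length(cover) - 1L)
    }
  }
  list(deletions = deletions, splits = splits, merges = merges,
       total = deletions + splits + merges)
}

#' Mixing index of two labelled point populations
#'
#' Fits a separating hyperplane (max-margin direction on centred,
#' isotropically scaled coordinates; intercept chosen along that direction to
#' minimise the mean misclassified fraction) and reports the per-class
#' misclassified fractions. `mode = "mean"` averages the two fractions (the
#' somite-style index, 0 = fully separated, 0.5 = fully mixed);
#' `mode = "sum"` adds them (0..1).
#'
#' @param points_a,points_b numeric matrices (points x coordinates), same
#'   dimensionality, each with at least 2 rows.
#' @param mode `"mean"` or `"sum"`.
#' @return list of class `mixing_result`: `normal`, `offset`, per-class
#'   fractions, `index_mean`, `index_sum`, `index` (per `mode`),
#'   `degenerate`.
#' @export
mixing_index <- function(points_a, points_b, mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  points_a <- as.matrix(points_a); points_b <- as.matrix(points_b)
  stopifnot(nrow(points_a) >= 2, nrow(points_b) >= 2,
            ncol(points_a) == ncol(points_b))
  X <- rbind(points_a, points_b)
  yy <- factor(rep(c("a", "b"), c(nrow(points_a), nrow(points_b))))
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  scl <- sqrt(mean(rowSums(Xc^2)))
  degenerate <- !is.finite(scl) || scl < 1e-12
  if (degenerate) {
    return(structure(list(normal = rep(NA_real_, ncol(X)), offset = NA_real_,
                          frac_a = 0.5, frac_b = 0.5, index_mean = 0.5,
                          index_sum = 1, index = if (mode == "mean") 0.5 else 1,
                          degenerate = TRUE), class = "mixing_result"))
  }
  Xs <- Xc / scl
  w <- tryCatch({
    m <- e1071::svm(Xs, yy, kernel = "linear", cost = 1, scale = FALSE)
    as.numeric(t(m$coefs) %*% m$SV)
  }, error = function(e) rep(0, ncol(X)))
  if (sqrt(sum(w^2)) < 1e-9) {
    # no usable direction (e.g. identical populations): any hyperplane
    proj_a <- rep(0, nrow(points_a)); proj_b <- rep(0, nrow(points_b))
    w <- c(1, rep(0, ncol(X) - 1))
  } else {
    w <- w / sqrt(sum(w^2))
    proj_a <- as.numeric(Xs[yy == "a", , drop = FALSE] %*% w)
    proj_b <- as.numeric(Xs[yy == "b", , drop = FALSE] %*% w)
  }
  all_p <- sort(unique(c(proj_a, proj_b)))
  cand <- if (length(all_p) > 1)
    c(min(all_p) - 1, (head(all_p, -1) + tail(all_p, -1)) / 2, max(all_p) + 1)
  else c(all_p - 1, all_p + 1)
  best <- list(err = Inf, thr = cand[1], sgn = 1, margin = -Inf)
  for (thr in cand) for (sgn in c(1, -1)) {
    ea <- mean(sgn * proj_a >= sgn * thr) # a on the wrong side
    eb <- mean(sgn * proj_b < sgn * thr)
    err <- (ea + eb) / 2
    margin <- suppressWarnings(min(abs(all_p - thr)))
    if (err < best$err - 1e-12 ||
        (abs(err - best$err) <= 1e-12 && margin > best$margin)) {
      best <- list(err = err, thr = thr, sgn = sgn, margin = margin,
                   ea = ea, eb = eb)
    }
  }
  frac_a <- best$ea; frac_b <- best$eb
  structure(list(normal = best$sgn * w, offset = best$sgn * best$thr * scl +
                   sum(best$sgn * w * ctr),
                 frac_a = frac_a, frac_b = frac_b,
                 index_mean = (frac_a + frac_b) / 2,
                 index_sum = frac_a + frac_b,
                 index = if (mode == "mean") (frac_a + frac_b) / 2 else
                   frac_a + frac_b,
                 degenerate = FALSE), class = "mixing_result")
}

#' @export
print.mixing_result <- function(x, ...) {
  cat(sprintf("<mixing_result> mean %.4f (a: %.3f, b: %.3f)%s\n",
              x$index_mean, x$frac_a, x$frac_b,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Mean-distance dispersion index
#'
#' Mean Euclidean distance over all unordered point pairs (um): the degree of
#' spatial dispersion of (ancestral) cell positions.
#'
#' @param points numeric matrix, points x coordinates, at least 2 rows.
#' @return scalar in the coordinate units.
#' @export
dispersion_index <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2) abort("dispersion index needs at least 2 points")
  mean(dist(points))
}

#' Per-cell migration velocities with local statistics
#'
#' Central-difference velocity along each node's track around frame `t`
#' (one-sided at track ends), in um/min. Local statistics over the `k`
#' nearest same-frame neighbours (including the node itself): mean speed and
#' local velocity variance, the trace of the covariance of the velocity
#' vectors.
#'
#' @param forest a `lineage_forest`.
#' @param t frame at which to evaluate.
#' @param half_window frames on each side for the central difference.
#' @param k neighbourhood size (clamped to the population).
#' @param frame_interval_s seconds per frame.
#' @return tibble: id, z, y, x, vz, vy, vx, speed, local_mean_speed,
#'   local_velocity_var.
#' @export
velocity_field <- function(forest, t, half_window = 2, k = 50,
                           frame_interval_s = 60) {
  stopifnot(k >= 2)
  n <- forest$nodes
  parent_idx <- match(n$parent_id, n$id)
  outdeg <- tabulate(parent_idx[!is.na(parent_idx)], nbins = nrow(n))
  child_idx <- rep(NA_integer_, nrow(n))
  ok <- !is.na(parent_idx) & outdeg[parent_idx] == 1
  child_idx[parent_idx[ok]] <- which(ok)
  cur <- n[n$frame == t, ]
  if (nrow(cur) == 0) abort("no nodes at frame t")
  walk_back <- function(i, steps) {
    while (steps > 0 && !is.na(parent_idx[i])) {
      i <- parent_idx[i]
      steps <- steps - 1
    }
    i
  }
  walk_fwd <- function(i, steps) {
    while (steps > 0 && !is.na(child_idx[i])) {
      i <- child_idx[i]
      steps <- steps - 1
    }
    i
  }
  rows <- list()
  cur_idx <- match(cur$id, n$id)
  for (r in seq_len(nrow(cur))) {
    i <- cur_idx[r]
    ib <- walk_back(i, half_window)
    if_ <- walk_fwd(i, half_window)
    dt <- n$frame[if_] - n$frame[ib]
    if (dt == 0) next # isolated single-frame track
    v <- c(n$z[if_] - n$z[ib], n$y[if_] - n$y[ib], n$x[if_] - n$x[ib]) /
      (dt * frame_interval_s / 60)
    rows[[length(rows) + 1]] <- tibble(id = cur$id[r], z = cur$z[r],
                                       y = cur$y[r], x = cur$x[r],
                                       vz = v[1], vy = v[2], vx = v[3])
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) abort("no node at frame t has a measurable velocity")
  out$speed <- sqrt(out$vz^2 + out$vy^2 + out$vx^2)
  kk <- min(k, nrow(out))
  P <- cbind(out$z, out$y, out$x)
  V <- cbind(out$vz, out$vy, out$vx)
  D <- as.matrix(dist(P))
  lm <- numeric(nrow(out)); lv <- numeric(nrow(out))
  for (r in seq_len(nrow(out))) {
    nb <- order(D[r, ])[seq_len(kk)]
    lm[r] <- mean(out$speed[nb])
    lv[r] <- sum(diag(cov(V[nb, , drop = FALSE])))
  }
  out$local_mean_speed <- lm
  out$local_velocity_var <- lv
  out
}

#' Correlate gene expression with local migration speed
#'
#' Pearson correlation per gene between expression and the per-cell local
#' speed, ranked descending; zero-variance genes are reported with `NA`.
#'
#' @param expr numeric matrix, genes x cells, with gene rownames.
#' @param speeds named numeric vector of per-cell (local) speeds; names must
#'   match `colnames(expr)`.
#' @return tibble: gene, r, rank (NA correlations last, unranked).
#' @export
expression_velocity_correlation <- function(expr, speeds) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3) abort("need at least 3 cells")
  if (!is.null(names(speeds)) && !is.null(colnames(expr)))
    speeds <- speeds[colnames(expr)]
  if (any(is.na(speeds))) abort("speeds do not align with expression columns")
  r <- apply(expr, 1, function(g) {
    if (sd(g) < 1e-15) NA_real_ else cor(g, speeds)
  })
  out <- tibble(gene = rownames(expr) %||% as.character(seq_len(nrow(expr))),
                r = as.numeric(r)) |> arrange(dplyr::desc(.data$r))
  out$rank <- ifelse(is.na(out$r), NA_integer_, seq_len(nrow(out)))
  out
}

#' Globally optimal matching of two point clouds
#'
#' Coarse similarity alignment (centroid, rms scale, principal-axes rotation
#' with the sign ambiguity resolved by the cheaper fit), followed by an exact
#' linear assignment minimising total squared distance with an
#' unmatched-penalty `dummy_cost` per point.
#'
#' @param cloud_a,cloud_b numeric matrices (points x 3).
#' @param dummy_cost penalty for leaving a point of `cloud_a` unmatched.
#' @return list: `assignment` tibble (a, b or NA), `total_cost`, and the
#'   transform applied to `cloud_b`.
#' @export
global_point_matching <- function(cloud_a, cloud_b, dummy_cost = Inf) {
  A <- as.matrix(cloud_a); B <- as.matrix(cloud_b)
  stopifnot(nrow(A) >= 1, nrow(B) >= 1)
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  sa <- sqrt(mean(rowSums(Ac^2))); sb <- sqrt(mean(rowSums(Bc^2)))
  s <- if (sb > 1e-12) sa / sb else 1
  Bs <- Bc * s
  R <- diag(ncol(A))
  if (nrow(A) >= 3 && nrow(B) >= 3 && sa > 1e-12 && sb > 1e-12) {
    ea <- eigen(cov(Ac), symmetric = TRUE)$vectors
    eb <- eigen(cov(Bs), symmetric = TRUE)$vectors
    best <- list(cost = Inf, R = R)
    for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
      S3 <- diag(c(s1, s2, s1 * s2 * sign(det(ea) * det(eb))))
      Rc <- ea %*% S3 %*% t(eb)
      Bt <- Bs %*% t(Rc)
      D <- outer(rowSums(Ac^2), rep(1, nrow(Bt))) +
        outer(rep(1, nrow(Ac)), rowSums(Bt^2)) - 2 * Ac %*% t(Bt)
      cost <- sum(apply(D, 1, min))
      if (cost < best$cost) best <- list(cost = cost, R = Rc)
    }
    R <- best$R
  }
  Bt <- sweep(Bs %*% t(R), 2, ca, `+`)
  D <- outer(rowSums(A^2), rep(1, nrow(Bt))) +
    outer(rep(1, nrow(A)), rowSums(Bt^2)) - 2 * A %*% t(Bt)
  D <- pmax(D, 0)
  mi <- solve_assignment(D, gate = Inf, penalty = dummy_cost)
  total <- sum(D[cbind(which(!is.na(mi)), mi[!is.na(mi)])]) +
    (if (is.finite(dummy_cost)) dummy_cost * sum(is.na(mi)) else 0)
  list(assignment = tibble(a = seq_len(nrow(A)), b = mi),
       total_cost = total,
       transform = list(rotation = R, scale = s, center_a = ca, center_b = cb))
}

#' Full tracking evaluation against ground truth
#'
#' Convenience wrapper: match nodes, compute the edge error report and the
#' error-free track statistics, and score divisions.
#'
#' @param pred,gt `lineage_forest` objects.
#' @param radius match radius in um.
#' @return list: `correspondence`, `edges` (edge_error_report),
#'   `error_free`, `divisions`.
#' @export
evaluate_tracking <- function(pred, gt, radius) {
  corr <- match_detections(pred, gt, radius)
  er <- edge_error_rate(pred, gt, corr)
  ef <- error_free_stats(pred, gt, corr)
  dv <- division_scores(pred, gt, corr)
  list(correspondence = corr, edges = er, error_free = ef, divisions = dv)
}
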