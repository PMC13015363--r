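test_that("node matching is optimal, one-to-one, and radius-gated", {
  gtf <- toy_forest(list(straight_track(0:4, y = 10),
                         straight_track(0:4, y = 30)))
  corr <- match_detections(gtf, gtf, radius = 2)
  expect_true(all(corr$pred_id == corr$gt_id))
  # jitter below radius/2 keeps a full matching
  pf <- gtf; pf$nodes$y <- pf$nodes$y + 0.6
  corr2 <- match_detections(pf, gtf, radius = 2)
  expect_true(all(!is.na(corr2$pred_id)))
  # a node with no prediction within the radius stays unmatched
  pf2 <- gtf
  pf2$nodes <- pf2$nodes[-1, ]
  pf2$nodes$parent_id[pf2$nodes$id == 2] <- NA
  corr3 <- match_detections(lineage_forest(pf2$nodes), gtf, radius = 2)
  expect_equal(sum(is.na(corr3$pred_id)), 1)
})

test_that("edge error counting reproduces hand-built toy cases", {
  gt10 <- toy_forest(list(straight_track(0:10, y = 10)))   # 10 edges
  self <- evaluate_tracking(gt10, gt10, radius = 1)
  expect_equal(self$edges$error_rate, 0)
  # prediction missing exactly one edge, no spurious ones
  nodes <- gt10$nodes
  nodes$parent_id[6] <- NA # break edge 5->6
  pred <- lineage_forest(nodes)
  corr <- match_detections(pred, gt10, radius = 1)
  er <- edge_error_rate(pred, gt10, corr)
  expect_equal(er$n_gt_edges, 10)
  expect_equal(er$error_rate, 0.1)
  # empty prediction: every ground-truth edge is missed
  empty_pred <- toy_forest(list(straight_track(0:10, y = 500)))
  corr0 <- match_detections(empty_pred, gt10, radius = 1)
  er0 <- edge_error_rate(empty_pred, gt10, corr0)
  expect_equal(er0$error_rate, 1.0)
  expect_error(edge_error_rate(gt10, toy_forest(list(straight_track(0, y = 1))),
                               corr), "no edges")
})

test_that("error-free statistics measure the prefix until the first error", {
  gt10 <- toy_forest(list(straight_track(0:10, y = 10)))
  nodes <- gt10$nodes
  nodes$parent_id[7] <- NA # first error at edge 6
  pred <- lineage_forest(nodes)
  corr <- match_detections(pred, gt10, radius = 1)
  ef <- error_free_stats(pred, gt10, corr)
  expect_equal(ef$average_error_free_length, 5)
  expect_equal(ef$proportion_error_free, 0)
  # two tracks, one perfect, one broken at the start
  gt2 <- toy_forest(list(straight_track(0:5, y = 10),
                         straight_track(0:5, y = 40)))
  nodes2 <- gt2$nodes
  nodes2$parent_id[nodes2$id == 8] <- NA # second track: error at edge 1
  pred2 <- lineage_forest(nodes2)
  corr2 <- match_detections(pred2, gt2, radius = 1)
  ef2 <- error_free_stats(pred2, gt2, corr2)
  expect_equal(ef2$proportion_error_free, 0.5)
  expect_equal(ef2$average_error_free_length, (5 + 0) / 2)
  # the longest-run alternative is exposed as a flag
  ef3 <- error_free_stats(pred2, gt2, corr2, prefix = FALSE)
  expect_equal(ef3$average_error_free_length, (5 + 4) / 2)
  # all correct: proportion one, mean length = mean track length
  efall <- error_free_stats(gt2, gt2, match_detections(gt2, gt2, 1))
  expect_equal(efall$proportion_error_free, 1)
  expect_equal(efall$average_error_free_length, 5)
})

test_that("mixing index hits its reference values and is rigidly invariant", {
  set.seed(1)
  A <- matrix(rnorm(60), ncol = 3)
  B <- sweep(matrix(rnorm(60), ncol = 3), 2, c(25, 0, 0), `+`)
  expect_equal(mixing_index(A, B)$index_mean, 0)
  expect_equal(mixing_index(A, A)$index_mean, 0.5)
  m <- mixing_index(matrix(c(0, 1, 2), ncol = 1),
                    matrix(c(1.5, 2.5, 3.5), ncol = 1))
  expect_equal(m$index_mean, 1 / 6)
  expect_equal(m$index_sum, 1 / 3)
  expect_equal(mixing_index(matrix(c(0, 1, 2), ncol = 1),
                            matrix(c(1.5, 2.5, 3.5), ncol = 1),
                            mode = "sum")$index, 1 / 3)
  # joint rigid transforms leave the index unchanged
  th <- 0.61
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  A2 <- matrix(rnorm(30), ncol = 3); B2 <- matrix(rnorm(30, 1), ncol = 3)
  expect_equal(mixing_index(A2 %*% t(R) + 3, B2 %*% t(R) + 3)$index_mean,
               mixing_index(A2, B2)$index_mean)
  # degenerate: all points identical
  P <- matrix(1, 4, 3)
  md <- mixing_index(P, P)
  expect_true(md$degenerate)
  expect_equal(md$index_mean, 0.5)
})

test_that("dispersion index enumerates pairs, scales linearly, ignores shifts", {
  sq <- rbind(c(0, 0, 0), c(0, 0, 1), c(0, 1, 0), c(0, 1, 1))
  expect_equal(dispersion_index(sq), (4 + 2 * sqrt(2)) / 6)
  expect_equal(dispersion_index(matrix(5, 3, 3)), 0)
  expect_equal(dispersion_index(sq * 7), 7 * dispersion_index(sq))
  expect_equal(dispersion_index(sweep(sq, 2, c(3, -2, 9), `+`)),
               dispersion_index(sq))
  expect_error(dispersion_index(sq[1, , drop = FALSE]), "2 points")
})

test_that("velocity fields resolve uniform motion and mixed populations", {
  # uniform translation: identical vectors, zero local variance
  tracks <- lapply(1:6, function(k)
    straight_track(0:8, y = 10 * k, x = 2 * (0:8)))
  f <- toy_forest(tracks)
  vf <- velocity_field(f, t = 4, half_window = 2, k = 4, frame_interval_s = 60)
  expect_equal(unique(round(vf$vx, 9)), 2) # 2 um/frame at 1 frame/min
  expect_true(all(vf$local_velocity_var < 1e-12))
  # static scene
  f0 <- toy_forest(lapply(1:4, function(k) straight_track(0:6, y = 5 * k, x = 3)))
  vf0 <- velocity_field(f0, 3, 2, k = 3)
  expect_true(all(vf0$speed == 0))
  # two spatially separated speed populations
  fast <- lapply(1:5, function(k) straight_track(0:8, y = k * 4, x = 4 * (0:8)))
  slow <- lapply(1:5, function(k) straight_track(0:8, y = 100 + k * 4,
                                                 x = 1 * (0:8)))
  f2 <- toy_forest(c(fast, slow))
  vf2 <- velocity_field(f2, 4, 2, k = 4)
  expect_equal(sort(unique(round(vf2$local_mean_speed, 6))), c(1, 4))
  expect_true(all(vf2$local_velocity_var < 1e-12))
})

test_that("expression-speed correlation ranks a planted gene first", {
  set.seed(2)
  n <- 40
  speed <- runif(n, 0, 5)
  names(speed) <- paste0("c", 1:n)
  expr <- rbind(
    exact = speed,
    neg = -speed,
    planted = 2 * speed + rnorm(n, 0, sqrt(1 - 0.8^2) * 2 * stats::sd(speed)),
    flat = rep(3, n),
    noise = rnorm(n))
  colnames(expr) <- names(speed)
  out <- expression_velocity_correlation(expr, speed)
  expect_equal(out$gene[1], "exact")
  expect_equal(out$r[1], 1)
  expect_equal(out$r[out$gene == "neg"], -1)
  expect_equal(out$gene[which(out$rank == 2)], "planted")
  expect_true(is.na(out$r[out$gene == "flat"]))
  expect_true(is.na(out$rank[out$gene == "flat"]))
  expect_equal(tail(out$gene[!is.na(out$rank)], 1), "neg")
})

test_that("global point matching is optimal against permutation brute force", {
  set.seed(3)
  a <- matrix(runif(15, 0, 10), ncol = 3)
  g1 <- global_point_matching(a, a, dummy_cost = 100)
  expect_equal(g1$assignment$b, 1:5)
  expect_equal(g1$total_cost, 0, tolerance = 1e-9)
  g2 <- global_point_matching(a, sweep(a, 2, c(5, -3, 2), `+`), dummy_cost = 100)
  expect_equal(g2$assignment$b, 1:5)
  perm <- sample(5)
  b <- a[perm, ] + matrix(rnorm(15, 0, 0.05), ncol = 3)
  g3 <- global_point_matching(a, b, dummy_cost = 100)
  expect_equal(g3$assignment$b, order(perm))
  # exhaustive check over all 120 permutations of the aligned cost matrix
  tr <- g3$transform
  Bt <- sweep(sweep(b, 2, tr$center_b) %*% t(tr$rotation) * tr$scale, 2,
              tr$center_a, `+`)
  D <- outer(rowSums(a^2), rep(1, 5)) + outer(rep(1, 5), rowSums(Bt^2)) -
    2 * a %*% t(Bt)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i]))
      out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- min(vapply(perms(1:5), function(p) sum(D[cbind(1:5, p)]), 1))
  expect_equal(g3$total_cost, best, tolerance = 1e-9)
  # never worse than the identity assignment
  expect_lte(g3$total_cost, sum(diag(D)) + 1e-9)
})

test_that("segmentation event counting separates deletions, splits and merges", {
  fx <- fig3a_fixture(seed = 1)
  ev <- segmentation_event_counts(fx$labels, fx$scene$labels)
  expect_equal(ev$deletions, 2)
  expect_equal(ev$splits, 2)
  expect_equal(ev$merges, 6)
  self <- segmentation_event_counts(fx$scene$labels, fx$scene$labels)
  expect_equal(self$total, 0)
})
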