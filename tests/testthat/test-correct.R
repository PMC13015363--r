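cfg <- pipeline_config()

test_that("skip gaps interpolate linearly, one descriptor per missing frame", {
  det <- tibble::tibble(id = 1:2, frame = c(0L, 2L), z = c(0, 0), y = c(0, 0),
                        x = c(0, 8), volume_um3 = 100, n_voxels = 100L,
                        mean_intensity = 50, z_score = 10, scale_um = 3)
  cfg3 <- pipeline_config(link = list(g_max = 3L))
  sol <- solve_circulation(build_circulation(det, cfg3))
  g <- find_skip_events(sol)
  expect_equal(nrow(g), 1)
  expect_equal(c(g$z, g$y, g$x), c(0, 0, 4))
  # a three-frame jump produces two descriptors
  det$frame <- c(0L, 3L)
  det$x <- c(0, 6)
  sol2 <- solve_circulation(build_circulation(det, cfg3))
  g2 <- find_skip_events(sol2)
  expect_equal(nrow(g2), 2)
  expect_equal(sort(g2$x), c(2, 4), tolerance = 1e-9)
  # no skip flow -> empty
  det3 <- det; det3$frame <- c(0L, 1L)
  expect_equal(nrow(find_skip_events(
    solve_circulation(build_circulation(det3, cfg3)))), 0)
})

test_that("merging detections is additive and volume-weighted", {
  lab <- array(0L, c(6, 12, 12))
  lab[1:100] <- 1L
  lab[301:450] <- 2L
  ls <- label_series(list(lab), c(1, 1, 1))
  det <- celltracer:::measure_labels(lab, NULL, c(1, 1, 1), frame = 0L)
  det$z_score <- 10
  st <- scene_state(NULL, ls, det)
  out <- apply_merge(st, 1L, 2L)
  m <- out$state$det
  expect_equal(nrow(m), 1)
  expect_equal(m$volume_um3, 250)
  # centroid = volume-weighted mean of the two parts
  w <- c(100, 150) / 250
  expect_equal(m$x, sum(w * det$x))
  expect_false(any(c(1L, 2L) %in% m$id))
  # different frames refuse to merge
  lab2 <- array(0L, c(6, 12, 12)); lab2[1:50] <- 3L
  ls2 <- label_series(list(lab, lab2), c(1, 1, 1))
  det2 <- rbind(det, celltracer:::measure_labels(lab2, NULL, c(1, 1, 1), 1L) |>
                  dplyr::mutate(z_score = 10))
  st2 <- scene_state(NULL, ls2, det2)
  expect_error(apply_merge(st2, 1L, 3L), "frame")
})

test_that("splitting preserves the voxel union exactly and needs distinct seeds", {
  # dumbbell-shaped label: two 90-intensity lobes joined by a thin neck
  dims <- c(16, 16, 28)
  g <- as.matrix(expand.grid(z = 1:16, y = 1:16, x = 1:28))
  c1 <- c(8, 8, 8); c2 <- c(8, 8, 21)
  d2a <- colSums((t(g) - c1)^2); d2b <- colSums((t(g) - c2)^2)
  neck <- abs(g[, 3] - 14.5) <= 3 & (g[, 1] - 8)^2 + (g[, 2] - 8)^2 <= 1.2^2
  mask <- d2a <= 4.5^2 | d2b <= 4.5^2 | neck
  lab <- array(0L, dims); lab[mask] <- 9L
  vol <- array(10, dims); vol[mask] <- 100
  set.seed(2); vol <- vol + array(rnorm(prod(dims), 0, 3), dims)
  ls <- label_series(list(lab), c(1, 1, 1))
  det <- celltracer:::measure_labels(lab, vol, c(1, 1, 1), 0L)
  det$z_score <- 10
  st <- scene_state(volume_series(list(pmax(vol, 0)), c(1, 1, 1)), ls, det)
  out <- apply_split(st, 9L, rbind(c1 - 1, c2 - 1))
  labs2 <- frame_volume(out$state$labels, 0)
  vox_before <- which(lab == 9L)
  vox_after <- which(labs2 %in% out$new_ids)
  expect_identical(vox_before, vox_after)               # union preserved
  s1 <- labs2[8, 8, 8]; s2 <- labs2[8, 8, 21]
  expect_true(all(c(s1, s2) %in% out$new_ids) && s1 != s2)
  n1 <- sum(labs2 == out$new_ids[1]); n2 <- sum(labs2 == out$new_ids[2])
  expect_true(n1 > 0 && n2 > 0)
  # the cut falls at the neck: both lobes dominate their own part
  expect_gt(min(n1, n2) / max(n1, n2), 0.5)
  expect_error(apply_split(st, 9L, rbind(c1 - 1, c1 - 1)), "coincide")
})

test_that("a perfect scene needs no corrections and converges immediately", {
  scene <- simulate_embryo(small_scene_params(seed = 3))
  dd <- detections_from_labels(scene$labels, scene$series)
  st <- scene_state(scene$series, dd$labels, dd$detections)
  corr <- iterate_correction(st, cfg)
  expect_true(corr$converged)
  expect_equal(corr$report$accepted[1], 0)
  expect_equal(nrow(corr$report), 1)
})

test_that("injected deletions are recovered within a voxel of ground truth", {
  scene <- simulate_embryo(small_scene_params(seed = 6, n_cells_initial = 12L))
  gt <- scene$forest$nodes
  # delete 4 mid-track nodes on distinct, well-separated tracks
  cand <- gt[gt$frame >= 3 & gt$frame <= 8, ]
  iso <- vapply(seq_len(nrow(cand)), function(i) {
    same <- gt[gt$frame == cand$frame[i] & gt$id != cand$id[i], ]
    min(sqrt((same$z - cand$z[i])^2 + (same$y - cand$y[i])^2 +
               (same$x - cand$x[i])^2))
  }, 1)
  cand <- cand[iso >= 10, ]
  cand <- cand[!duplicated(cand$track_id), ]
  pick <- head(cand, 4)
  k <- nrow(pick)
  expect_gte(k, 3)
  mf <- tibble::tibble(kind = "delete", node_id = pick$id, node_id2 = NA_integer_,
                       frame = pick$frame, nz = NA_real_, ny = NA_real_,
                       nx = NA_real_)
  inj <- inject_errors(scene, mf)
  corr <- suppressWarnings(iterate_correction(inj$state, cfg))
  red <- corr$events[corr$events$kind == "missing_redetect" & corr$events$accepted, ]
  expect_gte(nrow(red), ceiling(0.9 * k))
  # recovered centroids sit within one voxel of the deleted ground truth
  got <- corr$state$det[match(red$det1, corr$state$det$id), ]
  D <- sqrt(outer(got$z, pick$z, `-`)^2 + outer(got$y, pick$y, `-`)^2 +
              outer(got$x, pick$x, `-`)^2)
  expect_lt(max(apply(D, 1, min)), 2) # one z-voxel
  # a gap over a true absence is not fabricated: remove the cell's intensity
  expect_true(corr$converged)
})

test_that("redetection refuses gaps with no unexplained intensity", {
  scene <- simulate_embryo(small_scene_params(seed = 8, n_cells_initial = 6L))
  dd <- detections_from_labels(scene$labels, scene$series)
  st <- scene_state(scene$series, dd$labels, dd$detections)
  # ask for a redetection in an empty corner of the volume
  gap <- tibble::tibble(det_a = dd$detections$id[1], det_b = dd$detections$id[2],
                        frame = 5L, z = 4, y = 6, x = 6)
  res <- suppressWarnings(redetect_missing(st, gap, cfg))
  expect_false(res$accepted)
})

test_that("the canonical two-lineage fixture is corrected exactly as narrated", {
  fx <- fig3a_fixture(seed = 1)
  corr <- suppressWarnings(iterate_correction(fx$state, cfg))
  expect_true(corr$converged)
  ev <- corr$events[corr$events$accepted, ]
  expect_equal(sum(ev$kind == "missing_redetect"), 2)
  expect_equal(sum(ev$kind == "split_underseg"), 6)
  expect_equal(sum(ev$kind == "merge_overseg"), 2)
  # re-running from scratch reproduces the identical report
  corr2 <- suppressWarnings(iterate_correction(fig3a_fixture(seed = 1)$state, cfg))
  expect_identical(corr$report, corr2$report)
  expect_identical(corr$events[, c("kind", "frame", "accepted")],
                   corr2$events[, c("kind", "frame", "accepted")])
})
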