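test_that("simulation is byte-identical under a fixed seed", {
  p <- small_scene_params(seed = 42)
  s1 <- simulate_embryo(p)
  s2 <- simulate_embryo(p)
  expect_identical(s1$series$frames, s2$series$frames)
  expect_identical(s1$labels$frames, s2$labels$frames)
  expect_identical(s1$forest$nodes, s2$forest$nodes)
  s3 <- simulate_embryo(small_scene_params(seed = 43))
  expect_false(identical(s1$series$frames, s3$series$frames))
})

test_that("without divisions the cell count is constant and the forest has none", {
  scene <- simulate_embryo(small_scene_params(seed = 1))
  g <- glance(scene$forest)
  expect_equal(g$n_divisions, 0)
  counts <- table(scene$forest$nodes$frame)
  expect_true(all(counts == counts[1]))
})

test_that("division counts follow the branching-process expectation", {
  # memoryless divisions (no refractory period) so N_T ~ N0 * (1+p)^T
  p <- 0.05; T <- 9; N0 <- 20
  finals <- sapply(1:20, function(s) {
    sc <- simulate_embryo(small_scene_params(
      seed = 300 + s, n_cells_initial = N0, n_frames = T + 1L,
      division_prob = p, division_refractory_frames = 0L))
    sum(sc$forest$nodes$frame == T)
  })
  expected <- N0 * (1 + p)^T
  se <- stats::sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - expected), 3 * max(se, 1e-9))
})

test_that("a noise-free static cell renders its argmax at the ground-truth voxel", {
  sc <- simulate_embryo(small_scene_params(
    seed = 5, n_cells_initial = 1L, brownian_sigma_um = 0,
    drift_um_per_frame = 0, poisson = FALSE, snr = 1e9))
  v <- frame_volume(sc$series, 0)
  node <- sc$forest$nodes[sc$forest$nodes$frame == 0, ]
  ix <- celltracer:::unlin_index(which.max(v), dim(v))
  pos <- celltracer:::voxel_to_um(ix, sc$params$voxel_size_um)
  expect_lt(sqrt(sum((pos - c(node$z, node$y, node$x))^2)),
            max(sc$params$voxel_size_um))
})

test_that("measured SNR stays within 10% of the configured value", {
  # a background comfortably above the read noise avoids clipping at zero
  p <- small_scene_params(seed = 9, n_cells_initial = 4L, poisson = FALSE,
                          background = 40)
  sc <- simulate_embryo(p)
  v <- frame_volume(sc$series, 0)
  noise_sd <- estimate_noise_sd(v)
  nodes <- sc$forest$nodes[sc$forest$nodes$frame == 0, ]
  peaks <- vapply(seq_len(nrow(nodes)), function(i) {
    w <- celltracer:::voxel_window(c(nodes$z[i], nodes$y[i], nodes$x[i]),
                                   rep(2, 3), p$voxel_size_um, dim(v))
    max(v[w$lo[1]:w$hi[1], w$lo[2]:w$hi[2], w$lo[3]:w$hi[3]])
  }, 1)
  snr_meas <- (median(peaks) - p$background) / noise_sd
  expect_lt(abs(snr_meas - p$snr) / p$snr, 0.10)
  # and the noise itself matches the configured read noise
  expect_lt(abs(noise_sd - p$peak_intensity / p$snr) / (p$peak_intensity / p$snr),
            0.10)
})

test_that("label centroids agree with forest centroids", {
  scene <- simulate_embryo(small_scene_params(seed = 2))
  dd <- detections_from_labels(scene$labels)
  m <- merge(dd$detections, scene$forest$nodes,
             by.x = "label_in_frame", by.y = "id")
  err <- sqrt((m$z.x - m$z.y)^2 + (m$y.x - m$y.y)^2 + (m$x.x - m$x.y)^2)
  # within half a voxel (largest voxel dimension) for nearly all nuclei
  expect_lt(stats::quantile(err, 0.95), 0.5 * max(scene$params$voxel_size_um))
})

test_that("error injection applies exactly the manifest and nothing else", {
  scene <- simulate_embryo(small_scene_params(seed = 7))
  empty <- inject_errors(scene, tibble::tibble(kind = character(),
                                               node_id = integer(),
                                               node_id2 = integer(),
                                               frame = integer()))
  expect_identical(empty$labels$frames, scene$labels$frames)
  node <- scene$forest$nodes[scene$forest$nodes$frame == 5, ][1, ]
  mf <- tibble::tibble(kind = "delete", node_id = node$id,
                       node_id2 = NA_integer_, frame = 5L)
  inj <- inject_errors(scene, mf)
  n_before <- length(frame_labels(scene$labels, 5))
  expect_equal(length(frame_labels(inj$labels, 5)), n_before - 1)
  expect_error(inject_errors(scene, tibble::tibble(
    kind = "delete", node_id = max(scene$forest$nodes$id) + 99L,
    node_id2 = NA_integer_, frame = 1L)), "unknown")
  expect_error(inject_errors(scene, rbind(mf, mf)), "at most once")
})

test_that("the canonical fixture carries exactly the narrated ten corruptions", {
  fx <- fig3a_fixture(seed = 1)
  expect_equal(sum(is.na(fx$scene$forest$nodes$parent_id)), 2)  # two lineages
  expect_equal(nrow(fx$manifest), 10)
  expect_equal(sum(fx$manifest$kind == "delete"), 2)
  expect_equal(sum(fx$manifest$kind == "split"), 2)
  expect_equal(sum(fx$manifest$kind == "merge"), 6)
  ev <- segmentation_event_counts(fx$labels, fx$scene$labels)
  expect_equal(ev$total, 10)
  fx2 <- fig3a_fixture(seed = 1)
  expect_identical(fx$state$labels$frames, fx2$state$labels$frames)
  expect_identical(fx$scene$series$frames, fx2$scene$series$frames)
})

test_that("ground truth is self-consistent under the evaluation module", {
  scene <- simulate_embryo(small_scene_params(seed = 10, division_prob = 0.04,
                                              division_refractory_frames = 3L))
  ev <- evaluate_tracking(scene$forest, scene$forest, radius = 2)
  expect_equal(ev$edges$error_rate, 0)
  expect_equal(ev$error_free$proportion_error_free, 1)
  expect_equal(ev$divisions$recall, 1)
})
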