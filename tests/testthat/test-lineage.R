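cfg <- pipeline_config()

test_that("forest construction enforces degree and temporal invariants", {
  expect_error(lineage_forest(tibble::tibble(
    id = 1:2, frame = c(1L, 0L), z = 0, y = 0, x = 0, volume_um3 = 1,
    parent_id = c(NA, 1L), track_id = 1L, interpolated = FALSE)),
    "precede")
  expect_error(lineage_forest(tibble::tibble(
    id = 1:4, frame = c(0L, 1L, 1L, 1L), z = 0, y = 0, x = 0, volume_um3 = 1,
    parent_id = c(NA, 1L, 1L, 1L), track_id = 1L, interpolated = FALSE)),
    "out-degree")
  expect_error(lineage_forest(tibble::tibble(
    id = 1:2, frame = 0:1, z = 0, y = 0, x = 0, volume_um3 = 1,
    parent_id = c(NA, 99L), track_id = 1L, interpolated = FALSE)),
    "missing node")
})

make_tracklets <- function(...) {
  segs <- list(...)
  dplyr::bind_rows(lapply(seq_along(segs), function(i) {
    tibble::tibble(tracklet_id = i, frame = segs[[i]]$frame,
                   det_id = segs[[i]]$id, confidence = 1)
  }))
}

test_that("tracklet association closes gaps within the relaxed gate only", {
  det <- tibble::tibble(
    id = 1:8,
    frame = c(0:3, 5:8),
    z = 10, y = 10, x = c(0:3, 5:8) * 1.0,
    volume_um3 = 100, n_voxels = 100L, mean_intensity = 50, z_score = 10,
    scale_um = 3)
  tks <- make_tracklets(list(frame = 0:3, id = 1:4),
                        list(frame = 5:8, id = 5:8))
  merged <- associate_tracklets(tks, det, cfg, frame_range = c(0L, 8L))
  expect_equal(length(unique(merged$chain_id)), 1)
  # forest fills the frame-4 gap with an interpolated node
  forest <- celltracer:::build_forest(merged, det,
                                      tibble::tibble(parent = integer(),
                                                     child1 = integer(),
                                                     child2 = integer(),
                                                     frame = integer()))
  n4 <- forest$nodes[forest$nodes$frame == 4, ]
  expect_equal(nrow(n4), 1)
  expect_true(n4$interpolated)
  expect_equal(n4$x, 4)
  # far-apart tracklets stay apart
  det2 <- det; det2$y[5:8] <- 200
  merged2 <- associate_tracklets(tks, det2, cfg, frame_range = c(0L, 8L))
  expect_equal(length(unique(merged2$chain_id)), 2)
})

test_that("division detection applies its gates", {
  # parent track 0..5 continuing into child1; a second chain starts at 6
  det <- tibble::tibble(
    id = 1:10,
    frame = c(0:7, 6L, 7L),
    z = 10, y = c(rep(10, 6), 8.5, 8, 11.5, 12),
    x = c(0:7, 6, 7) * 1.0,
    volume_um3 = c(rep(100, 6), 50, 50, 50, 50),
    n_voxels = 100L, mean_intensity = 50, z_score = 10, scale_um = 3)
  tracks <- dplyr::bind_rows(
    tibble::tibble(chain_id = 1L, frame = 0:7, det_id = 1:8),
    tibble::tibble(chain_id = 2L, frame = 6:7, det_id = 9:10))
  dv <- detect_divisions(tracks, det, cfg, frame_range = c(0L, 7L))
  expect_equal(nrow(dv$divisions), 1)
  expect_equal(dv$divisions$parent, 6L)
  expect_equal(sort(c(dv$divisions$child1, dv$divisions$child2)), c(7L, 9L))
  # a too-short parent (observed start, < 5 frames) is rejected
  det2 <- det; det2$frame <- det2$frame + 0L
  tracks2 <- tracks
  tracks2 <- tracks2[!(tracks2$chain_id == 1 & tracks2$frame < 4), ]
  dv2 <- detect_divisions(tracks2, det2, cfg, frame_range = c(0L, 7L))
  expect_equal(nrow(dv2$divisions), 0)
  expect_true(any(grepl("too short", dv2$rejected$reason)))
  # but a parent truncated by the block start is exempt
  dv3 <- detect_divisions(tracks2, det2, cfg, frame_range = c(4L, 7L))
  expect_equal(nrow(dv3$divisions), 1)
  # child volumes far from the parent are rejected
  det4 <- det; det4$volume_um3[7:8] <- 95; det4$volume_um3[9:10] <- 5
  dv4 <- detect_divisions(tracks, det4, cfg, frame_range = c(0L, 7L))
  expect_equal(nrow(dv4$divisions), 0)
})

test_that("divisions on simulated scenes are recovered with high precision/recall", {
  scene <- simulate_embryo(small_scene_params(
    seed = 12, n_frames = 20L, division_prob = 0.02,
    division_refractory_frames = 6L))
  dd <- detections_from_labels(scene$labels, scene$series)
  st <- scene_state(scene$series, dd$labels, dd$detections)
  res <- suppressWarnings(track_scene(st, cfg))
  ev <- evaluate_tracking(res$forest, scene$forest, radius = 3)
  expect_gte(ev$divisions$recall, 0.9)
  expect_gte(ev$divisions$precision, 0.9)
  expect_lte(ev$edges$error_rate, 0.02)
})

test_that("batch stitching handles empty and non-overlapping inputs", {
  f1 <- toy_forest(list(straight_track(0:9, y = 10)))
  empty <- lineage_forest(tibble::tibble(id = integer(), frame = integer(),
                                         z = numeric(), y = numeric(),
                                         x = numeric(), volume_um3 = numeric(),
                                         parent_id = integer(),
                                         track_id = integer(),
                                         interpolated = logical()))
  expect_identical(stitch_batches(list(f1, empty), 3, 9)$nodes, f1$nodes)
  # second batch displaced beyond the gate: no splices, tracks truncate
  f2 <- toy_forest(list(straight_track(7:15, y = 200)))
  st <- stitch_batches(list(f1, f2), overlap = 3, gating_um = 9)
  expect_equal(sum(is.na(st$nodes$parent_id)), 2) # both remain roots
})

test_that("fate backtracking walks parents and reports late entrants", {
  par <- straight_track(0:5, y = 10)
  c1 <- straight_track(6:9, y = 8); attr(c1, "parent_track") <- 1L
  c2 <- straight_track(6:9, y = 12); attr(c2, "parent_track") <- 1L
  late <- straight_track(4:9, y = 40)
  f <- toy_forest(list(par, c1, c2, late))
  sel <- f$nodes$id[f$nodes$frame == 9]
  anc <- backtrack_fates(f, sel, 0)
  expect_equal(nrow(anc), 2)
  sib <- anc[anc$n_descendants == 2, ]
  expect_equal(sib$frame, 0)
  expect_false(sib$entered_after)
  expect_true(anc$entered_after[anc$n_descendants == 1])
  # no divisions: ancestors are the same tracks' earlier nodes
  f2 <- toy_forest(list(straight_track(0:9, y = 1),
                        straight_track(0:9, y = 5)))
  anc2 <- backtrack_fates(f2, f2$nodes$id[f2$nodes$frame == 9], 2)
  expect_equal(sort(anc2$frame), c(2, 2))
  expect_true(all(anc2$n_descendants == 1))
})

test_that("simulated ancestors at frame 0 are the initial cells", {
  scene <- simulate_embryo(small_scene_params(seed = 13, division_prob = 0.03,
                                              division_refractory_frames = 3L))
  f <- scene$forest
  sel <- f$nodes$id[f$nodes$frame == max(f$nodes$frame)]
  anc <- backtrack_fates(f, sel, 0)
  roots <- f$nodes$id[f$nodes$frame == 0]
  expect_setequal(anc$ancestor_id, roots)
  expect_equal(sum(anc$n_descendants), length(sel))
})
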