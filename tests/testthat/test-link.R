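cfg <- pipeline_config()

det_row <- function(frame, z = 0, y = 0, x = 0, vol = 100) {
  list(frame = frame, z = z, y = y, x = x, volume_um3 = vol)
}

test_that("transition cost follows its closed form and gates on distance", {
  p <- cfg$link
  a <- det_row(0); b <- det_row(1) # same position, same volume
  expect_equal(transition_cost(a, b, params = p), 0)
  b2 <- det_row(1, x = p$sigma_motion_um)
  expect_equal(transition_cost(a, b2, params = p), 0.5)
  far <- det_row(1, x = p$gating_radius_um * p$strict_factor + 0.01)
  expect_equal(transition_cost(a, far, params = p), Inf)
  # relaxed gate admits it
  expect_lt(transition_cost(a, far, params = p, strict = FALSE), Inf)
  # frame-skip surcharge
  b3 <- det_row(2)
  expect_equal(transition_cost(a, b3, params = p), p$c_skip)
  expect_equal(transition_cost(a, det_row(p$g_max + 1), params = p), Inf)
})

test_that("network construction produces the documented arcs", {
  det <- tibble::tibble(id = 1:2, frame = 0:1, z = 1, y = 2, x = c(3, 3.5),
                        volume_um3 = 100, n_voxels = 100L,
                        mean_intensity = 50, z_score = 8, scale_um = 3)
  net <- build_circulation(det, cfg)
  expect_equal(sum(net$arcs$kind == "observation"), 2)
  expect_equal(sum(net$arcs$kind == "appear"), 2)
  expect_equal(sum(net$arcs$kind == "disappear"), 2)
  expect_equal(sum(net$arcs$kind == "transition"), 1)
  expect_equal(sum(net$arcs$kind == "skip"), 0)
  # detections at t and t+2 only: a skip arc appears iff g_max >= 2
  det2 <- det; det2$frame <- c(0L, 2L)
  net2 <- build_circulation(det2, cfg)
  expect_equal(sum(net2$arcs$kind == "skip"), 1)
  cfg1 <- pipeline_config(link = list(g_max = 1L))
  net3 <- build_circulation(det2, cfg1)
  expect_equal(sum(net3$arcs$kind == "skip"), 0)
  # empty input
  net0 <- build_circulation(det[0, ], cfg)
  sol0 <- solve_circulation(net0)
  expect_equal(sol0$total_cost, 0)
})

test_that("two confident close detections form exactly one two-node track", {
  det <- tibble::tibble(id = 1:2, frame = 0:1, z = 1, y = 2, x = c(3, 3.5),
                        volume_um3 = 100, n_voxels = 100L,
                        mean_intensity = 50, z_score = 10, scale_um = 3)
  sol <- solve_circulation(build_circulation(det, cfg))
  tk <- extract_tracklets(sol)
  expect_equal(max(tk$tracklets$tracklet_id), 1)
  expect_equal(sort(tk$tracklets$det_id), 1:2)
})

test_that("the exact solver matches the exhaustive oracle on random instances", {
  for (s in 1:25) {
    det <- random_detections(seed = 1000 + s)
    sol <- solve_circulation(build_circulation(det, cfg))
    bf <- brute_force_association(det, cfg)
    expect_equal(sol$total_cost, bf$cost, tolerance = 1e-9,
                 label = sprintf("instance %d solver", s),
                 expected.label = "oracle")
  }
  expect_error(brute_force_association(random_detections(1, 10, 4), cfg),
               "too large")
})

test_that("solutions are deterministic for a fixed input", {
  det <- random_detections(seed = 77)
  s1 <- solve_circulation(build_circulation(det, cfg))
  s2 <- solve_circulation(build_circulation(det, cfg))
  expect_identical(s1$arcs$flow, s2$arcs$flow)
})

test_that("adding a detection cannot raise the optimum above its best bundle", {
  for (s in 1:5) {
    det <- random_detections(seed = 2000 + s, max_per_frame = 3)
    base <- solve_circulation(build_circulation(det, cfg))$total_cost
    extra <- det[1, ]
    extra$id <- max(det$id) + 1L
    extra$z <- extra$z + 1
    det2 <- rbind(det, extra)
    net2 <- build_circulation(det2, cfg)
    cost2 <- solve_circulation(net2)$total_cost
    a <- net2$arcs
    bundle <- min(a$cost[a$kind %in% c("appear", "div_child") & a$det == extra$id]) +
      a$cost[a$kind == "observation" & a$det == extra$id] +
      min(a$cost[a$kind %in% c("disappear", "merge_parent") & a$det == extra$id])
    expect_lte(cost2, base + max(bundle, 0) + 1e-9)
  }
})

test_that("tracklet extraction records skip gaps and division events", {
  # three frames, one detection each, middle one missing -> skip
  det <- tibble::tibble(id = 1:2, frame = c(0L, 2L), z = 1, y = 2,
                        x = c(3, 4), volume_um3 = 100, n_voxels = 100L,
                        mean_intensity = 50, z_score = 10, scale_um = 3)
  sol <- solve_circulation(build_circulation(det, cfg))
  tk <- extract_tracklets(sol)
  expect_equal(max(tk$tracklets$tracklet_id), 1)
  expect_equal(sort(tk$tracklets$frame), c(0L, 2L)) # gap recorded implicitly
  gaps <- find_skip_events(sol)
  expect_equal(gaps$frame, 1L)
  expect_equal(gaps$x, 3.5)
  # one parent, two half-volume children: a div_child event is logged
  det2 <- tibble::tibble(id = 1:3, frame = c(0L, 1L, 1L), z = 1, y = c(5, 3, 7),
                         x = 3, volume_um3 = c(100, 50, 50), n_voxels = 100L,
                         mean_intensity = 50, z_score = 10, scale_um = 3)
  sol2 <- solve_circulation(build_circulation(det2, cfg))
  tk2 <- extract_tracklets(sol2)
  expect_true(any(tk2$events$kind == "div_child"))
  expect_equal(sort(unique(tk2$tracklets$det_id)), 1:3)
})
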