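vs1 <- c(1, 1, 1)

test_that("blob score is zero on constant input and on dark blobs", {
  expect_equal(max(principal_curvature_score(array(5, c(12, 12, 12)), 2, vs1)),
               0)
  blob <- blob_volume(c(24, 24, 24), rbind(c(12, 12, 12)), sigma = 3,
                      peak = 100, background = 0)
  dark <- 100 - blob
  expect_equal(principal_curvature_score(dark, 3, vs1)[12, 12, 12], 0)
})

test_that("blob score peaks at the blob centre and matches a finite-difference oracle", {
  blob <- blob_volume(c(24, 24, 24), rbind(c(12, 12, 12)), sigma = 3,
                      peak = 100, background = 0)
  sc <- principal_curvature_score(blob, 3, vs1)
  expect_equal(as.vector(celltracer:::unlin_index(which.max(sc), dim(sc))),
               c(12, 12, 12))
  # oracle: finite-difference Hessian eigenvalues of the smoothed image
  sm <- gauss_smooth(blob, c(3, 3, 3))
  H <- matrix(0, 3, 3)
  ctr <- c(12, 12, 12)
  at <- function(off) sm[matrix(ctr + off, 1)]
  ax <- diag(3)
  for (i in 1:3) H[i, i] <- at(ax[i, ]) - 2 * at(c(0, 0, 0)) + at(-ax[i, ])
  for (i in 1:2) for (j in (i + 1):3) {
    H[i, j] <- H[j, i] <-
      (at(ax[i, ] + ax[j, ]) - at(ax[i, ] - ax[j, ]) -
         at(ax[j, ] - ax[i, ]) + at(-ax[i, ] - ax[j, ])) / 4
  }
  lam <- eigen(H * 3^2, symmetric = TRUE)$values
  expect_equal(sc[12, 12, 12], prod(pmax(0, -lam)), tolerance = 1e-8)
})

test_that("score is offset-invariant and scales with gain cubed", {
  blob <- blob_volume(c(20, 20, 20), rbind(c(10, 10, 10)), sigma = 2.5,
                      peak = 80, background = 5)
  s1 <- principal_curvature_score(blob, 2.5, vs1)
  expect_equal(principal_curvature_score(blob + 37, 2.5, vs1), s1)
  expect_equal(principal_curvature_score(blob * 2, 2.5, vs1), 8 * s1,
               tolerance = 1e-9)
})

test_that("sub-voxel scales are clamped with a warning", {
  v <- blob_volume(c(10, 10, 10), rbind(c(5, 5, 5)), sigma = 2)
  expect_warning(principal_curvature_score(v, 0.5, c(1, 1, 1)), "clamped")
})

test_that("region significance matches its closed form and is monotone", {
  v <- array(0, c(10, 10, 10))
  interior <- 1:100; shell <- 101:200
  v[interior] <- 110; v[shell] <- 100
  expect_equal(region_significance(v, interior, shell, 5),
               10 / (5 * sqrt(0.02)))
  expect_equal(region_significance(v, interior, shell, 5), 14.142, tolerance = 1e-4)
  v0 <- v; v0[interior] <- 100
  expect_equal(region_significance(v0, interior, shell, 5), 0)
  v2 <- v; v2[interior] <- v2[interior] + 7
  expect_gt(region_significance(v2, interior, shell, 5),
            region_significance(v, interior, shell, 5))
  expect_error(region_significance(v, interior, integer(0), 5), "shell")
  expect_error(region_significance(v, interior, interior, 5), "overlap")
})

test_that("well-separated bright blobs are each found exactly once", {
  dims <- c(20, 60, 60)
  ctr <- separated_centers(8, dims, min_sep = 12, seed = 11)
  vol <- blob_volume(dims, ctr, sigma = 2.2, peak = 90, background = 10,
                     noise_sd = 9, seed = 11)
  cfg <- pipeline_config()
  r <- suppressWarnings(detect_frame(vol, cfg, vs1))
  expect_equal(nrow(r$detections), nrow(ctr))
  D <- sqrt(outer(r$detections$z, ctr[, 1] - 1, `-`)^2 +
              outer(r$detections$y, ctr[, 2] - 1, `-`)^2 +
              outer(r$detections$x, ctr[, 3] - 1, `-`)^2)
  expect_lt(max(apply(D, 2, min)), 1)
})

test_that("a blob far below the significance threshold yields no seed", {
  dims <- c(16, 32, 32)
  # SNR 0.5: peak contrast half the noise sd
  vol <- blob_volume(dims, rbind(c(8, 16, 16)), sigma = 2.2, peak = 4.5,
                     background = 50, noise_sd = 9, seed = 3)
  sc <- principal_curvature_score(vol, c(1.5, 2.25, 3), vs1,
                                  return_scale = TRUE)
  seeds <- detect_seeds(sc, vol, z_thr = 4, vs1)
  expect_equal(length(seeds), 0)
})

test_that("false positives on pure noise stay below one seed per 1e5 voxels", {
  cfg <- pipeline_config()
  total_vox <- 0; total_fp <- 0; clean <- 0
  for (s in 1:20) {
    set.seed(500 + s)
    nv <- array(pmax(rnorm(12 * 24 * 24, 50, 9), 0), c(12, 24, 24))
    n <- nrow(suppressWarnings(detect_frame(nv, cfg, vs1))$detections)
    total_fp <- total_fp + n
    total_vox <- total_vox + length(nv)
    clean <- clean + (n == 0)
  }
  expect_lte(total_fp, total_vox / 1e5 + 1)
  expect_gte(clean / 20, 0.95)
})

test_that("min-cut refinement recovers a uniform ball (Dice >= 0.95)", {
  dims <- c(24, 24, 24)
  g <- as.matrix(expand.grid(z = 1:24, y = 1:24, x = 1:24))
  d2 <- colSums((t(g) - 12)^2)
  ball <- array(as.numeric(d2 <= 25) * 90 + 10, dims)
  set.seed(5)
  ball <- ball + array(rnorm(prod(dims), 0, 3), dims)
  sc <- principal_curvature_score(ball, c(3, 4.5), vs1, return_scale = TRUE)
  seeds <- detect_seeds(sc, ball, 4, vs1)
  expect_gte(length(seeds), 1)
  lab <- refine_boundaries_mincut(ball, seeds[1], vs1)
  mask <- array(d2 <= 25, dims)
  dice <- 2 * sum(lab == 1 & mask) / (sum(lab == 1) + sum(mask))
  expect_gte(dice, 0.95)
})

test_that("two seeds in a dumbbell phantom are cut at the neck", {
  dims <- c(24, 24, 24)
  g <- as.matrix(expand.grid(z = 1:24, y = 1:24, x = 1:24))
  c1 <- c(12, 12, 8); c2 <- c(12, 12, 20)
  d2a <- colSums((t(g) - c1)^2); d2b <- colSums((t(g) - c2)^2)
  neck <- abs(g[, 3] - 14) <= 2 & (g[, 1] - 12)^2 + (g[, 2] - 12)^2 <= 1.5^2
  dumb <- array(10 + 90 * as.numeric(d2a <= 4.5^2 | d2b <= 4.5^2 | neck), dims)
  set.seed(6)
  dumb <- dumb + array(rnorm(prod(dims), 0, 3), dims)
  sc <- principal_curvature_score(dumb, c(3, 4.5), vs1, return_scale = TRUE)
  seeds <- detect_seeds(sc, dumb, 4, vs1)
  expect_equal(length(seeds), 2)
  lab <- refine_boundaries_mincut(dumb, seeds, vs1)
  la <- lab[12, 12, 8]; lb <- lab[12, 12, 20]
  expect_true(la > 0 && lb > 0 && la != lb)
  # every seed core keeps its own label; labels are disjoint by construction
  for (i in 1:2) expect_true(all(lab[seeds[[i]]$core] == i))
  for (L in list(list(l = la, m = d2a <= 4.5^2), list(l = lb, m = d2b <= 4.5^2))) {
    dice <- 2 * sum(lab == L$l & array(L$m, dims)) /
      (sum(lab == L$l) + sum(L$m))
    expect_gte(dice, 0.9)
  }
})

test_that("detect_frame is deterministic and invariant to label permutation", {
  dims <- c(16, 40, 40)
  ctr <- separated_centers(4, dims, min_sep = 13, seed = 21)
  vol <- blob_volume(dims, ctr, noise_sd = 9, seed = 21)
  cfg <- pipeline_config()
  r1 <- suppressWarnings(detect_frame(vol, cfg, vs1))
  r2 <- suppressWarnings(detect_frame(vol, cfg, vs1))
  expect_identical(r1$labels, r2$labels)
  # voxel sets are what matters: id offsets only relabel them
  r3 <- suppressWarnings(detect_frame(vol, cfg, vs1, id_offset = 100L))
  sets1 <- split(which(r1$labels > 0), r1$labels[r1$labels > 0])
  sets3 <- split(which(r3$labels > 0), r3$labels[r3$labels > 0])
  expect_equal(unname(sets1), unname(sets3))
})

test_that("detections_from_labels recovers centroids, volumes and global ids", {
  scene <- simulate_embryo(small_scene_params(seed = 2))
  dd <- detections_from_labels(scene$labels, scene$series)
  expect_false(any(duplicated(dd$detections$id)))
  m <- merge(dd$detections, scene$forest$nodes,
             by.x = "label_in_frame", by.y = "id")
  err <- sqrt((m$z.x - m$z.y)^2 + (m$y.x - m$y.y)^2 + (m$x.x - m$x.y)^2)
  expect_lt(stats::quantile(err, 0.95), 1)   # within half a z-voxel
  expect_equal(m$volume_um3.x, m$volume_um3.y)
  expect_true(all(dd$detections$z_score > 4))
})
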