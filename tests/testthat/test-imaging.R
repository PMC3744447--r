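vox <- c(dx = 100, dy = 100, dz = 200)

blank_stack <- function(d = c(12, 12, 6), channels = "x", value = 0) {
  image_stack(setNames(lapply(channels, function(ch) array(value, d)),
                       channels), voxel = vox)
}

test_that("26-connected labelling separates and joins voxel sets", {
  m <- array(FALSE, c(5, 5, 3))
  m[2, 2, 1] <- TRUE; m[3, 3, 2] <- TRUE   # diagonal in 3D: one component
  m[5, 5, 3] <- TRUE                        # far away: second component
  lab <- label_components(m)
  expect_equal(max(lab), 2)
  expect_equal(lab[2, 2, 1], lab[3, 3, 2])
  expect_true(lab[5, 5, 3] != lab[2, 2, 1])
  expect_equal(max(label_components(array(FALSE, c(4, 4, 2)))), 0)
})

test_that("nucleus segmentation recovers a synthetic ellipsoid", {
  sim <- sim_image_stack(seed = 2, n_foci = 5, noise_sd = 0.002)
  mask <- segment_nucleus(sim$stack)
  truth <- sim$truth$nucleus
  expect_gte(sum(mask & truth) / sum(truth), 0.99)
  # all-zero stack: no nucleus
  expect_error(segment_nucleus(blank_stack(channels = "dapi")), "no nucleus")
})

test_that("with two nuclei only the larger is returned", {
  d <- c(40, 40, 8)
  a <- array(0, d)
  a[5:20, 5:20, 2:6] <- 0.8    # large blob
  a[30:35, 30:35, 2:4] <- 0.8  # small blob
  st <- image_stack(list(dapi = a), voxel = vox)
  mask <- segment_nucleus(st)
  expect_true(all(which(mask) %in% which(a > 0)))
  expect_true(any(mask[5:20, 5:20, 2:6]))
  expect_false(any(mask[30:35, 30:35, ]))
})

test_that("positive-voxel calling uses mean + k population SD, strictly", {
  d <- c(2, 2, 1)
  v <- array(c(10, 10, 10, 30) / 100, d)
  st <- image_stack(list(rnap = v), voxel = vox)
  mask <- array(TRUE, d)
  pos <- positive_voxels(st, "rnap", mask, k = 1)
  # mean 15, population SD ~8.66: only the 30 voxel exceeds 23.66
  expect_equal(which(pos), 4L)
  # monotone: raising k never gains positives
  last <- sum(pos)
  for (k in c(1.5, 2, 3)) {
    now <- sum(positive_voxels(st, "rnap", mask, k = k))
    expect_lte(now, last)
    last <- now
  }
  # constant channel: warning and no positives
  expect_warning(p0 <- positive_voxels(blank_stack(channels = "rnap"), "rnap",
                                       array(TRUE, c(12, 12, 6)), k = 1),
                 "constant")
  expect_equal(sum(p0), 0)
})

test_that("object detection weights centroids by intensity", {
  d <- c(24, 24, 8)
  v <- array(0, d)
  v[10, 6, 4] <- 0.9; v[11, 6, 4] <- 0.3          # object 1, 2 voxels
  v[20, 18, 6] <- 0.8; v[20, 19, 6] <- 0.8        # object 2
  v[3, 3, 2] <- 0.95                              # single voxel: dropped
  st <- image_stack(list(fish = v), voxel = vox)
  obj <- detect_objects(st, "fish", threshold = 0.1, min_volume = 2)
  expect_equal(nrow(obj), 2)
  o1 <- obj[which.min(obj$x_nm), ]
  # y centroid: (0.9*9.5 + 0.3*10.5)/1.2 voxels * 100 nm
  expect_equal(o1$y_nm, (0.9 * 9.5 + 0.3 * 10.5) / 1.2 * 100, tolerance = 1e-9)
  expect_equal(o1$x_nm, 550)
  expect_equal(o1$total_intensity, 1.2)
  # empty channel: no objects
  expect_equal(nrow(detect_objects(blank_stack(), "x", threshold = 0.5)), 0)
})

test_that("Gaussian spot centroids land within one voxel of truth", {
  sim <- sim_image_stack(seed = 6, n_foci = 3, spot_distances_nm = c(400, 900),
                         noise_sd = 0)
  mask <- segment_nucleus(sim$stack)
  obj <- detect_objects(sim$stack, "fish", mask = mask, k = 2, min_volume = 2)
  expect_equal(nrow(obj), 2)
  truth <- sim$truth$spots
  for (i in seq_len(nrow(obj))) {
    d <- sqrt((obj$x_nm[i] - truth$x_nm)^2 + (obj$y_nm[i] - truth$y_nm)^2 +
                (obj$z_nm[i] - truth$z_nm)^2)
    expect_lte(min(d), sqrt(sum(vox^2)) / 2)  # half a voxel diagonal
  }
})

test_that("nearest positive distances follow anisotropic geometry", {
  d <- c(8, 8, 4)
  pos <- array(FALSE, d)
  pos[4, 4, 2] <- TRUE
  center <- c((4 - 0.5) * 100, (4 - 0.5) * 100, (2 - 0.5) * 200)
  expect_equal(nearest_positive_distance(center, pos, vox), 0)
  # two voxels along x
  expect_equal(nearest_positive_distance(center + c(200, 0, 0), pos, vox), 200)
  # unit offset in all three axes
  p2 <- array(FALSE, d); p2[5, 5, 3] <- TRUE
  expect_equal(nearest_positive_distance(center, p2, vox),
               sqrt(100^2 + 100^2 + 200^2))
  # no positive voxel: Inf and a warning
  expect_warning(di <- nearest_positive_distance(center, array(FALSE, d), vox),
                 "Inf")
  expect_equal(di, Inf)
})

test_that("distances equal an exhaustive scan and scale with voxel size", {
  set.seed(12)
  d <- c(16, 16, 8)
  pos <- array(runif(prod(d)) < 0.03, d)
  pos[1, 1, 1] <- TRUE
  pts <- matrix(runif(9, 0, 800), ncol = 3)
  for (i in 1:3) {
    got <- nearest_positive_distance(pts[i, ], pos, vox)
    expect_equal(got, oracle_nearest_distance(pts[i, ], pos, vox),
                 tolerance = 1e-9)
    # scale covariance: scaling voxel sizes by c scales distances by c
    expect_equal(nearest_positive_distance(pts[i, ] * 3, pos, vox * 3),
                 3 * got, tolerance = 1e-9)
  }
})

test_that("in-plane rotation preserves counts and distances", {
  sim <- sim_image_stack(dim = c(48, 48, 16), n_foci = 10, seed = 14)
  st <- sim$stack
  rot <- function(a) {
    # 90-degree in-plane rotation of a [y,x,z] array (square slices)
    aperm(a, c(2, 1, 3))[, dim(a)[1]:1, , drop = FALSE]
  }
  st_r <- image_stack(lapply(st$channels, rot), voxel = st$voxel)
  m <- segment_nucleus(st); m_r <- segment_nucleus(st_r)
  expect_equal(count_factories(st_r, "rnap", m_r),
               count_factories(st, "rnap", m))
  pos <- positive_voxels(st, "rnap", m)
  pos_r <- positive_voxels(st_r, "rnap", m_r)
  # a focus center maps to the rotated frame with identical distance
  f <- sim$truth$foci[1, ]
  probe <- c(f$x_nm + 310, f$y_nm + 130, f$z_nm)
  L <- dim(pos)[1] * st$voxel[["dy"]]
  probe_r <- c(L - probe[2], probe[1], probe[3])
  expect_equal(nearest_positive_distance(probe_r, pos_r, st$voxel),
               nearest_positive_distance(probe, pos, st$voxel),
               tolerance = 1e-6)
})

test_that("colocalization is inclusive at the 225-nm threshold", {
  rec <- tibble::tibble(distance_nm = c(200, 225, 300))
  out <- colocalize(rec)
  expect_equal(out$colocalized, c(TRUE, TRUE, FALSE))
})

test_that("condition comparisons use the exact Fisher test", {
  expect_equal(compare_colocalization(c(2, 2), c(0, 2))$p, 1 / 3)
  expect_equal(compare_colocalization(c(5, 10), c(5, 10))$p, 1)
  expect_equal(compare_colocalization(c(0, 30), c(0, 30))$p, 1)
})

test_that("factory counting honours min_volume and merging limits", {
  sim <- sim_image_stack(dim = c(48, 48, 20), n_foci = 15, seed = 21)
  mask <- segment_nucleus(sim$stack)
  expect_equal(count_factories(sim$stack, "rnap", mask), 15)
  # two foci closer than the resolution limit merge into one component
  d <- c(20, 20, 6)
  v <- array(0, d)
  v[10, 10, 3] <- 0.9; v[10, 11, 3] <- 0.9  # touching: one factory
  v[4, 4, 2] <- 0.9; v[4, 5, 2] <- 0.9
  st <- image_stack(list(rnap = v), voxel = vox)
  mask2 <- array(TRUE, d)
  expect_equal(count_factories(st, "rnap", mask2, k = 1), 2)
})

test_that("particle totals integrate per-object intensities", {
  d <- c(24, 24, 8)
  mask <- array(TRUE, d)
  st0 <- blank_stack(d, channels = "fish")
  expect_equal(particle_intensities(st0, "fish", mask)$total_intensity, 0)
  # one uniform particle of m voxels at intensity v totals m*v
  v <- array(0, d); v[8:10, 8, 3] <- 0.6
  st1 <- image_stack(list(fish = v), voxel = vox)
  p1 <- particle_intensities(st1, "fish", mask)
  expect_equal(p1$total_intensity, 3 * 0.6)
  expect_equal(p1$particles$volume, 3L)
  # three blurred particles: total within 5% of the planted integrals
  sim <- sim_image_stack(dim = c(48, 48, 16), n_foci = 3,
                         spot_distances_nm = c(600, 800, 1000),
                         noise_sd = 0, seed = 33)
  nm <- segment_nucleus(sim$stack)
  pp <- particle_intensities(sim$stack, "fish", nm, k = 2)
  expect_equal(nrow(pp$particles), 3)
  per <- pp$particles$total_intensity
  expect_lt(max(abs(per - mean(per))) / mean(per), 0.05)
})

test_that("stacks round-trip through TIFF with sidecar metadata", {
  sim <- sim_image_stack(dim = c(24, 24, 10), n_foci = 1, seed = 3)
  f <- withr::local_tempfile(fileext = ".tif")
  write_image_stack(sim$stack, f)
  back <- read_image_stack(f)
  expect_equal(names(back$channels), names(sim$stack$channels))
  expect_equal(back$voxel, sim$stack$voxel)
  expect_equal(back$channels$rnap, sim$stack$channels$rnap, tolerance = 1e-6)
})
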