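one_seg_morph <- function(x0, y0, z0, x1, y1, z1, type = 3) {
  neuron_morphology(data.frame(
    id = 1:2, type = c(1, type), x = c(x0, x1), y = c(y0, y1),
    z = c(z0, z1), radius = c(5, 1), parent = c(-1, 1)))
}

test_that("voxelization apportions segments exactly and conserves length", {
  ctx <- layer_context(barrel_center_x_um = 0)
  # 30 um segment strictly inside one voxel (soma-centered frame)
  m <- one_seg_morph(0, 1000, 0, 10, 1010, 0, type = 3)
  dm <- voxelize(m, ctx, 50, "soma_centered", "dendrite")
  expect_equal(map_total(dm), segment_lengths(m)$length_um[1],
               tolerance = 1e-12)
  expect_identical(sum(dm$values > 0), 1L)
  # 60 um segment crossing one voxel face at its midpoint -> 30 + 30
  m2 <- one_seg_morph(20, 1000, 0, 80, 1000, 0)
  dm2 <- voxelize(m2, ctx, 50, "barrel_centered", "dendrite")
  vals <- sort(dm2$values[dm2$values > 0])
  expect_equal(vals, c(30, 30), tolerance = 1e-9)
})

test_that("voxelization equals a 0.1-um fine-sampling oracle per voxel", {
  ctx <- layer_context()
  set.seed(41)
  for (s in 1:6) {
    arc <- c("upright_pc", "inverted_pc", "multipolar")[1 + s %% 3]
    gen <- generate_morphology(arc, ctx, seed = 300 + s)
    dm <- voxelize(gen$morphology, ctx, 50, "barrel_centered", "dendrite")
    h <- fine_voxel_oracle(gen$morphology, ctx, 3:4)
    for (k in ls(h)) {
      v <- map_voxel_at(dm, k)
      hv <- get(k, envir = h)
      # 0.5 % agreement, with a small absolute floor for the oracle's own
      # 0.1 um midpoint-assignment granularity on near-empty voxels
      expect_lt(abs(v - hv), pmax(0.005 * pmax(v, hv), 0.3))
    }
  }
})

test_that("voxelization is translation-equivariant by whole voxels", {
  ctx <- layer_context()
  gen <- generate_morphology("multipolar", ctx, seed = 9)
  m <- gen$morphology
  dm <- voxelize(m, ctx, 50, "soma_centered", "dendrite")
  m2 <- m; m2$x <- m2$x + 50
  # soma moves too, so use the barrel frame where the shift is visible
  dmb <- voxelize(m, ctx, 50, "barrel_centered", "dendrite")
  m3 <- m; m3$x <- m3$x + 50
  dmb2 <- voxelize(neuron_morphology(as.data.frame(m3)), ctx, 50,
                   "barrel_centered", "dendrite")
  expect_equal(dmb2$origin_um[1], dmb$origin_um[1] + 50)
  expect_equal(dmb2$values, dmb$values, tolerance = 1e-9)
})

test_that("group averaging unions grids and preserves per-neuron mass", {
  ctx <- layer_context()
  mk <- function(x0) {
    voxelize(one_seg_morph(x0 + 5, 1005, 5, x0 + 35, 1005, 5), ctx, 50,
             "barrel_centered", "dendrite")
  }
  a <- mk(0)
  avg_same <- average_group(list(a, a))
  expect_equal(avg_same$values, a$values)
  # map + disjoint map -> each voxel at half value
  b <- mk(200)
  avg <- average_group(list(a, b))
  expect_equal(map_total(avg), (map_total(a) + map_total(b)) / 2,
               tolerance = 1e-9)
  expect_equal(max(avg$values), 15, tolerance = 1e-9)
  # zero map halves values
  z <- a; z$values <- a$values * 0
  expect_equal(max(average_group(list(a, z))$values), max(a$values) / 2)
  bad <- voxelize(one_seg_morph(0, 1000, 0, 10, 1010, 0), ctx, 50,
                  "soma_centered", "dendrite")
  expect_error(average_group(list(a, bad)), "mixed frames")
})

test_that("Gaussian smoothing conserves mass and reproduces the kernel", {
  ctx <- layer_context()
  gen <- generate_morphology("upright_pc", ctx, seed = 14)
  dm <- voxelize(gen$morphology, ctx, 50, "barrel_centered", "dendrite")
  sm <- smooth_map(dm, 50)
  expect_equal(map_total(sm), map_total(dm), tolerance = 1e-6 * map_total(dm))
  # single impulse spreads as the sampled separable Gaussian
  imp <- density_map(array(c(rep(0, 13), 100, rep(0, 13)), c(3, 3, 3)),
                     c(0, 0, 0), 50)
  smi <- smooth_map(imp, 50)
  k <- dnorm((-4:4) * 50, sd = 50); k <- k / sum(k)
  centre <- smi$values[4 + 2, 4 + 2, 4 + 2]
  expect_equal(centre, 100 * k[5]^3, tolerance = 1e-9)
  off <- smi$values[4 + 3, 4 + 2, 4 + 2]
  expect_equal(off, 100 * k[6] * k[5]^2, tolerance = 1e-9)
  # near-delta kernel acts as the identity
  smd <- smooth_map(dm, 1e-6)
  core <- smd$values[2:(dim(dm$values)[1] + 1),
                     2:(dim(dm$values)[2] + 1),
                     2:(dim(dm$values)[3] + 1)]
  expect_equal(core, dm$values, tolerance = 1e-9)
})

test_that("percentile thresholding interpolates over positive voxels only", {
  v <- array(0, c(10, 10, 2))
  v[1:100] <- 1:100
  dm <- density_map(v, c(0, 0, 0), 50)
  pt <- percentile_threshold(dm, 80)
  expect_equal(pt$threshold, 80.2)   # type-7 interpolation on 1..100
  expect_identical(sum(pt$mask), 20L)
  # uniform positive values: threshold c, mask = all positive voxels
  v2 <- array(0, c(4, 4, 1)); v2[3:10] <- 2.5
  dm2 <- density_map(v2, c(0, 0, 0), 50)
  pt2 <- percentile_threshold(dm2, 80)
  expect_equal(pt2$threshold, 2.5)
  expect_identical(sum(pt2$mask), 8L)
  expect_identical(sum(percentile_threshold(dm, 0)$mask), 100L)
  expect_error(percentile_threshold(
    density_map(array(0, c(2, 2, 2)), c(0, 0, 0), 50)), "all-zero")
  # mask monotone in pct
  m80 <- percentile_threshold(dm, 80)$mask
  m95 <- percentile_threshold(dm, 95)$mask
  expect_true(all(m80[m95]))
})

test_that("projections preserve totals and use the WM border as 1D origin", {
  ctx <- layer_context()
  gen <- generate_morphology("upright_pc", ctx, seed = 31)
  dm <- voxelize(gen$morphology, ctx, 50, "barrel_centered", "dendrite")
  sm <- smooth_map(dm, 50)
  p2 <- project_map(sm, "2d_slab")
  p1 <- project_map(sm, "1d_depth", ctx)
  expect_equal(sum(p2), map_total(sm), tolerance = 1e-9)
  expect_equal(sum(p1$length_um), map_total(sm), tolerance = 1e-9)
  # single voxel at the WM border projects to coordinate ~0
  one <- density_map(array(42, c(1, 1, 1)),
                     c(0, ctx$wm_depth_um - 50, 0), 50)
  pr <- project_map(one, "1d_depth", ctx)
  expect_equal(pr$depth_um, 25)  # voxel centre half an edge above border
  # upright cells place a local dendritic maximum in the tuft depth band
  band <- gen$ground_truth$tuft_depth_band_um
  prof <- project_map(smooth_map(voxelize(gen$morphology, ctx, 50,
                                          "barrel_centered", "apical"), 50),
                      "1d_depth", ctx)
  sel <- which(ctx$wm_depth_um - prof$depth_um >= band[1] - 25 &
                 ctx$wm_depth_um - prof$depth_um <= band[2] + 25)
  interior <- sel[sel > 1 & sel < nrow(prof)]
  is_local_max <- vapply(interior, function(i) {
    prof$length_um[i] >= prof$length_um[i - 1] &&
      prof$length_um[i] >= prof$length_um[i + 1] &&
      prof$length_um[i] > 0
  }, logical(1))
  expect_true(any(is_local_max))
})
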