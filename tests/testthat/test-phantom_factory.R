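# voxel centres deliberately off the port's face planes (no boundary-layer
# double counting in centre-inclusion masks)
small_ic_grid <- grid_spec(c(-20.3, 0.5, -20.1), c(1, 1, 1), c(42, 210, 42))

test_that("ion-chamber tank encodes the measurement setup", {
  vol <- build_ic_phantom(grid = small_ic_grid)
  expect_equal(vol$meta$ssd_mm, 850)
  expect_equal(vol$meta$isocenter_depth_mm, 150)
  expect_equal(vol$meta$field_mm, c(100, 100))
  expect_equal(vol$meta$ic_depths_mm, seq(70, 150, 10))
  # water off the port path
  expect_equal(sample_volume(vol, c(15, 100, 15)), 1.0)
  # inside the port (top face 5 cm deep, perpendicular -> 50..55 mm)
  expect_equal(sample_volume(vol, c(0, 52.5, 0)), 7.5)
  expect_equal(sample_volume(vol, c(0, 48, 0)), 1.0)
  expect_error(build_ic_phantom(grid = grid_spec(c(-5, 0.5, -5), c(1, 1, 1),
                                                 c(11, 100, 11))), "shallow")
})

test_that("perpendicular and parallel tanks differ only by port orientation", {
  vp <- build_ic_phantom(orientation = "perpendicular", grid = small_ic_grid)
  vl <- build_ic_phantom(orientation = "parallel", grid = small_ic_grid)
  np <- sum(vp$values > 1); nl <- sum(vl$values > 1)
  expect_gt(np, 0)
  expect_lt(abs(np - nl) / np, 0.01)
  expect_equal(vp$meta$port$axis, c(0, 1, 0))
  expect_equal(vl$meta$port$axis, c(-1, 0, 0))
  # parallel port still has its top face 5 cm deep
  expect_equal(sample_volume(vl, c(0, 50 + 17.5 / 2, 0)), 7.5)
})

test_that("anthropomorphic phantoms encode blocks, lung, port and SSDs", {
  vi <- build_anthro_phantom("inflated", spacing = c(2, 2, 2.5))
  vd <- build_anthro_phantom("deflated", spacing = c(2, 2, 2.5))
  expect_equal(vi$meta$ssd_mm, 907)
  expect_equal(vd$meta$ssd_mm, 950)
  expect_equal(vi$meta$block_mm, 63)
  expect_equal(vd$meta$block_mm, 20)
  # water-equivalent column above the port centre is 20 mm in both states
  expect_equal(vi$meta$port$center, c(0, 20, 0))
  expect_equal(vd$meta$port$center, c(0, 20, 0))
  # lung voxels at the configured density, read back through the grid
  expect_equal(sample_volume(vi, c(0, vi$meta$block_mm + 10 + 30, 0)), 0.30)
  expect_equal(sample_volume(vd, c(0, 50, 0)), 0.30)
  # isocenter at the lung / chest-wall interface
  expect_equal(vi$meta$isocenter_mm, c(0, 73, 0))
  expect_equal(vd$meta$isocenter_mm, c(0, 30, 0))
  expect_error(build_anthro_phantom("half-full"))
})

test_that("TLD points sit 25 mm from the port with point 3 under it", {
  mp <- place_measurement_points("inflated")
  expect_equal(nrow(mp$points), 4)
  pc <- mp$meta$port_center
  for (i in c(1, 2, 4)) {
    d <- sqrt(sum((unlist(mp$points[i, c("x", "y", "z")]) - pc)^2))
    expect_equal(d, 25)
  }
  # point 3: on the beam-side axis directly under the port
  expect_equal(mp$points$x[3], pc[1])
  expect_equal(mp$points$z[3], pc[3])
  expect_gt(mp$points$y[3], pc[2])
})

test_that("CT conversion tables interpolate, clamp and invert", {
  std <- ct_conversion_table()
  ext <- ct_conversion_table(extended = TRUE)
  expect_equal(density_from_hu(std, 0), 1.0)
  expect_equal(density_from_hu(std, 1e5), 3.0)   # clamp at the clinical cap
  expect_gte(max(ext$density), 7.5)
  expect_equal(density_from_hu(ext, hu_from_density(ext, 7.5)), 7.5)
  expect_true(all(diff(std$hu) > 0) && all(diff(std$density) >= 0))
  expect_error(density_from_hu(list(), 0), "table")
})

test_that("metal artifacts are seeded, bounded, decaying and HU-only", {
  vol <- build_anthro_phantom("inflated", spacing = c(2, 2, 2.5))
  hu <- voxel_volume(hu_from_density(ct_conversion_table(TRUE), vol$values),
                     vol$origin, vol$spacing, unit = "HU", meta = vol$meta)
  pm <- rasterize(vol$meta$port, hu)
  a1 <- add_metal_artifacts(hu, pm, 300, seed = 5)
  expect_identical(a1$values, add_metal_artifacts(hu, pm, 300, seed = 5)$values)
  expect_false(identical(a1$values, add_metal_artifacts(hu, pm, 300, seed = 6)$values))
  expect_identical(add_metal_artifacts(hu, pm, 0, seed = 5)$values, hu$values)
  dHU <- abs(a1$values - hu$values)
  expect_lte(max(dHU), 300 + 1e-9)
  ctr <- xpanderdose:::vol_centers(hu)
  r <- sqrt(ctr[, 1]^2 + (ctr[, 2] - 20)^2)
  expect_gt(mean(dHU[r < 20 & !pm]), mean(dHU[r >= 50 & r <= 80]))
  expect_true(all(dHU[r > 81] == 0))
  expect_error(add_metal_artifacts(vol, pm, 300, seed = 1), "HU")
})

test_that("override policies assign the documented densities", {
  vol <- build_anthro_phantom("inflated", spacing = c(2, 2, 2.5))
  hu <- voxel_volume(hu_from_density(ct_conversion_table(TRUE), vol$values),
                     vol$origin, vol$spacing, unit = "HU", meta = vol$meta)
  ss <- policy_structures(vol$meta$port, hu, with_shell = TRUE)
  masks <- rasterize(ss, hu, combine = FALSE)
  in_art <- masks$artifact & !masks$port & !masks$shell
  outside <- !(masks$port | masks$shell | masks$artifact)
  base <- density_from_hu(ct_conversion_table(TRUE), hu$values)

  d_new <- apply_override_policy(hu, ss, "new")
  expect_equal(unique(d_new$values[masks$port]), 7.5)
  expect_true(all(d_new$values[in_art] == 1.0))
  expect_true(all(d_new$values[outside] == base[outside]))

  d_c1 <- apply_override_policy(hu, ss, "clinical1")
  expect_equal(unique(d_c1$values[masks$port]), 7.4)
  expect_equal(unique(d_c1$values[masks$shell & !masks$port]), 4.2)
  expect_true(all(d_c1$values[in_art] == 1.0))

  # clinical2: port keeps CT-derived densities through the capped table
  d_c2 <- apply_override_policy(hu, ss, "clinical2")
  expect_equal(unique(d_c2$values[masks$port]), 3.0)
  expect_true(all(d_c2$values[in_art] == 1.0))
  expect_error(apply_override_policy(d_new, ss, "clinical2"), "HU")

  # missing ROI errors name the ROI; idempotency on the density volume
  expect_error(apply_override_policy(hu, structure_set(ss$rois[1]), "new"),
               "artifact")
  expect_identical(apply_override_policy(d_new, ss, "new")$values, d_new$values)
})

test_that("patient-like phantom is deterministic with sane anatomy", {
  pl <- build_patient_like(seed = 3)
  expect_identical(pl$volume$values, build_patient_like(seed = 3)$volume$values)
  expect_false(identical(pl$volume$values, build_patient_like(seed = 4)$volume$values))
  # skin points deeper than 10 mm below the curved surface
  pts <- pl$points$points
  surf_depth <- pts$y - (100 - sqrt(pmax(0, 100^2 - pts$x^2)))
  expect_true(all(surf_depth[pts$label %in% c("skin1", "skin2")] > 10))
  # port contained in the expander dilated by one voxel
  m <- rasterize(pl$structures, pl$volume, combine = FALSE)
  pm <- rasterize(pl$port, pl$volume)
  expect_true(all(dilate_mask(m$expander)[pm]))
  expect_gt(sum(m$ptv), 0)
  expect_true(all(is.finite(pl$volume$values)))
})
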