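water <- narrow_water_tank()

test_that("beam data table validates and PDD has the documented shape", {
  data <- beam_data_table()
  for (e in c(6, 10, 15)) expect_equal(pdd(e, data[[as.character(e)]]$dmax), 1)
  expect_lt(pdd(6, 0), 1)
  expect_lt(pdd(6, 100), pdd(15, 100))
  expect_lt(pdd(10, 100), pdd(15, 100))
  expect_error(pdd(18, 100), "energy")
  expect_error(pdd(6, -5), "depth")
  expect_error(beam_data_table(overrides = list("6" = list(mu_rho = 0.01))),
               "decreasing")
})

test_that("arc expansion counts beams and preserves weight", {
  beams <- arc_to_beams(90, 270, 10)
  expect_length(beams, 19)
  expect_equal(sum(vapply(beams, function(b) b$weight, 0)), 1)
  expect_equal(beams[[1]]$gantry_angle, 90)
  expect_equal(beams[[19]]$gantry_angle, 270)
  expect_error(arc_to_beams(90, 90, 10), "degenerate")
  expect_error(arc_to_beams(90, 270, 0), "step")
})

test_that("homogeneous water on-axis dose equals the closed form", {
  b <- beam_spec(6, 0, ssd_mm = 850, isocenter_mm = c(0, 150, 0))
  d <- compute_beam_dose(water, b, scatter = TRUE)
  depths <- seq(10, 200, by = 5)
  eng <- point_dose(d, cbind(0, depths, 0))
  closed <- pdd(6, depths) * (1000 / (850 + depths))^2
  expect_lt(max(abs(eng - closed) / closed), 0.01)
})

test_that("upstream port strictly attenuates and matches the exponential", {
  g <- grid_spec(c(-30.5, 0.5, -2), c(1, 1, 2), c(62, 220, 3))
  b <- beam_spec(6, 0, ssd_mm = 850, isocenter_mm = c(0, 150, 0))
  vol_port <- build_ic_phantom(orientation = "perpendicular", grid = g)
  vol_open <- build_ic_phantom(include_port = FALSE, grid = g)
  dp <- compute_beam_dose(vol_port, b, scatter = FALSE)
  d0 <- compute_beam_dose(vol_open, b, scatter = FALSE)
  ds <- seq(66, 200, by = 2)
  with_port <- point_dose(dp, cbind(0, ds, 0))
  no_port <- point_dose(d0, cbind(0, ds, 0))
  expect_true(all(with_port < no_port))
  ratio <- with_port / no_port
  expected <- exp(-0.0493 * (7.5 - 1) * 0.5)
  expect_lt(max(abs(ratio - expected) / expected), 0.03)
  # integral dose beyond the port decreases when upstream density increases
  ys <- xpanderdose:::vol_axis(dp, 2)
  downstream <- ys > 70
  expect_lt(sum(dp$values[, downstream, ]), sum(d0$values[, downstream, ]))
})

test_that("mirrored phantom and beam give the mirrored dose grid", {
  b1 <- beam_spec(6, 40, sad_mm = 1000, isocenter_mm = c(0, 80, 0))
  b2 <- beam_spec(6, -40, sad_mm = 1000, isocenter_mm = c(0, 80, 0))
  d1 <- compute_beam_dose(water, b1)
  d2 <- compute_beam_dose(water, b2)
  mirrored <- d2$values[rev(seq_len(d2$dims[1])), , ]
  expect_lt(max(abs(d1$values - mirrored)), 1e-6 * max(d1$values))
})

test_that("wedge factor anchors at unity and tilts the 10 cm isodose", {
  expect_equal(wedge_factor(NULL, c(-30, 0, 30)), rep(1, 3))
  expect_equal(wedge_factor(list(angle = 20, orientation = "x+"), 0), 1)
  expect_true(all(wedge_factor(list(angle = 20, orientation = "x+"),
                               seq(-40, 40, 5)) <= 1))
  bw <- beam_spec(6, 0, sad_mm = 1000, isocenter_mm = c(0, 100, 0),
                  wedge = list(angle = 20, orientation = "x+"))
  dw <- compute_beam_dose(water, bw, scatter = FALSE)
  ref <- point_dose(dw, c(0, 100, 0))
  xs <- seq(2, 24, by = 2)   # thick (attenuated) side of the field
  ds <- seq(60, 140, by = 0.5)
  iso_depth <- vapply(xs, function(x)
    stats::approx(point_dose(dw, cbind(x, ds, 0)), ds, xout = ref)$y, 0)
  tilt <- abs(atan(unname(coef(lm(iso_depth ~ xs))[2])) * 180 / pi)
  expect_lt(abs(tilt - 20), 1)
})

test_that("plan composition normalizes to the prescription at isocenter", {
  vol <- build_anthro_phantom("inflated", spacing = c(2, 2, 2.5))
  plan <- plan_spec(list(beam_spec(6, 90, ssd_mm = vol$meta$ssd_mm),
                         beam_spec(6, 270, ssd_mm = vol$meta$ssd_mm)),
                    prescription_gy = 1)
  d <- compute_plan_dose(vol, plan)
  expect_equal(point_dose(d, vol$meta$isocenter_mm), 1)
  expect_true(all(d$values >= 0))
  # opposed pair on the laterally symmetric phantom: symmetric about x = 0
  xs <- seq(4, 60, by = 8)
  left <- point_dose(d, cbind(-xs, 73, 0))
  right <- point_dose(d, cbind(xs, 73, 0))
  expect_lt(max(abs(left - right) / right), 0.005)
  # single beam of weight 1 equals the normalized beam dose
  plan1 <- plan_spec(list(beam_spec(6, 90, ssd_mm = vol$meta$ssd_mm)),
                     prescription_gy = 1)
  d1 <- compute_plan_dose(vol, plan1)
  raw <- compute_beam_dose(vol, plan1$beams[[1]])
  expect_equal(d1$values, raw$values / point_dose(raw, vol$meta$isocenter_mm),
               tolerance = 1e-12)
  expect_error(compute_plan_dose(vol, plan_spec(list(beam_spec(weight = 0)))),
               "weight")
})

test_that("perpendicular port shadows are wider and shallower than parallel", {
  g <- grid_spec(c(-30.5, 0.5, -2), c(1, 1, 2), c(62, 220, 3))
  b <- beam_spec(6, 0, ssd_mm = 850, isocenter_mm = c(0, 150, 0))
  d0 <- compute_beam_dose(build_ic_phantom(include_port = FALSE, grid = g), b,
                          scatter = FALSE)
  width <- c(); depth <- c()
  for (o in c("perpendicular", "parallel")) {
    dd <- compute_beam_dose(build_ic_phantom(orientation = o, grid = g), b,
                            scatter = FALSE)
    xs <- seq(-25.5, 25.5, by = 1)
    prof <- point_dose(dd, cbind(xs, 105, 0)) / point_dose(d0, cbind(xs, 105, 0))
    width[o] <- fwhm(-prof, 1)
    depth[o] <- 1 - min(prof)
  }
  expect_gt(width["perpendicular"], width["parallel"])
  expect_lt(depth["perpendicular"], depth["parallel"])
})

test_that("point_dose interpolates trilinearly and rejects outside points", {
  vals <- array(runif(64), c(4, 4, 4))
  d <- voxel_volume(vals, c(0, 0, 0), c(1, 1, 1), unit = "Gy")
  expect_equal(point_dose(d, c(1, 2, 3)), vals[2, 3, 4])
  expect_equal(point_dose(d, c(0.5, 2, 3)), mean(vals[1:2, 3, 4]))
  set.seed(4)
  for (i in 1:25) {
    p <- runif(3, 0, 3)
    nb <- vals[floor(p[1]) + 1:2, floor(p[2]) + 1:2, floor(p[3]) + 1:2]
    v <- point_dose(d, p)
    expect_gte(v, min(nb)); expect_lte(v, max(nb))
  }
  expect_error(point_dose(d, c(10, 0, 0)), "outside")
})

test_that("IMRT-style fluence grids modulate the beam", {
  fl <- list(values = matrix(rep(c(1, 1, 0.5, 0.5), 2), 4, 2),
             spacing = 50, origin = c(-75, -50))
  b <- beam_spec(6, 0, ssd_mm = 850, isocenter_mm = c(0, 150, 0), fluence = fl)
  d <- compute_beam_dose(water, b, scatter = FALSE)
  # fluence halves on the +x side of the field
  expect_equal(point_dose(d, c(25, 100, 0)) / point_dose(d, c(-25, 100, 0)),
               0.5 / 1, tolerance = 0.02)
})
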