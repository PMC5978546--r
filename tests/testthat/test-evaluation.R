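test_that("percent difference reproduces published rounding conventions", {
  expect_equal(percent_difference(86.7, 94.8, 1), -8.5)
  expect_equal(percent_difference(4815.8, 5336.7, 2), -9.76)
  expect_equal(percent_difference(103.5, 95.7, 1), 8.2)
  expect_equal(percent_difference(5, 5, 3), 0)
  # sign correctness; the relative metric is not antisymmetric
  expect_lt(percent_difference(90, 100, 2), 0)
  expect_gt(percent_difference(100, 90, 2), 0)
  expect_false(abs(percent_difference(90, 100, 4)) ==
                 abs(percent_difference(100, 90, 4)))
  expect_error(percent_difference(1, 0, 1), "positive")
})

test_that("comparison tables join by label and summarize the worst case", {
  tab <- load_published_table("phantom")
  infl <- tab[tab$state == "inflated" & tab$plan == "open", ]
  pts <- measurement_points(data.frame(label = infl$point, x = 0, y = 0, z = 0,
                                       dose = infl$reference_dose, sd = infl$reference_sd))
  ct <- comparison_table(pts, list(
    clinical1 = setNames(infl$clinical1_dose, infl$point),
    new = setNames(infl$new_dose, infl$point)), decimals = 1)
  expect_equal(ct$table$clinical1_diff_pct, c(-8.5, -5.1, -0.5, 0.6))
  expect_equal(unname(ct$max_abs_diff["clinical1"]), 8.5)
  expect_error(comparison_table(pts, list(m = c(point1 = 90))), "point2")
  one <- measurement_points(data.frame(label = "p", x = 0, y = 0, z = 0,
                                       dose = 50, sd = NA))
  expect_equal(comparison_table(one, list(m = c(p = 50)))$table$m_diff_pct, 0)
})

test_that("the full phantom-validation table keeps the new model within 5 percent", {
  tab <- load_published_table("phantom")
  pts <- measurement_points(data.frame(label = tab$label, x = 0, y = 0, z = 0,
                                       dose = tab$reference_dose, sd = tab$reference_sd))
  ct <- comparison_table(pts, list(new = setNames(tab$new_dose, tab$label),
                                   clinical1 = setNames(tab$clinical1_dose, tab$label),
                                   clinical2 = setNames(tab$clinical2_dose, tab$label)),
                         decimals = 1)
  expect_equal(unname(ct$max_abs_diff["new"]), 5.0)
  expect_gt(ct$max_abs_diff["clinical1"], ct$max_abs_diff["new"])
  expect_gt(ct$max_abs_diff["clinical2"], ct$max_abs_diff["new"])
})

test_that("DVH is a correct cumulative histogram", {
  u <- voxel_volume(array(1, c(4, 4, 4)), c(0, 0, 0), c(1, 1, 1), unit = "Gy")
  mask <- array(TRUE, c(4, 4, 4))
  h <- dvh(u, mask, 0.1)
  expect_equal(h$volume_pct[h$dose_gy <= 1], rep(100, sum(h$dose_gy <= 1)))
  expect_equal(h$volume_pct[h$dose_gy > 1], rep(0, sum(h$dose_gy > 1)))
  half <- voxel_volume(array(rep(c(1, 2), each = 32), c(4, 4, 4)),
                       c(0, 0, 0), c(1, 1, 1), unit = "Gy")
  h2 <- dvh(half, mask, 0.5)
  expect_equal(h2$volume_pct[h2$dose_gy == 1.5], 50)
  set.seed(2)
  r <- voxel_volume(array(runif(64, 0, 3), c(4, 4, 4)), c(0, 0, 0), c(1, 1, 1),
                    unit = "Gy")
  h3 <- dvh(r, mask, 0.05)
  expect_equal(h3$volume_pct[1], 100)
  expect_true(all(diff(h3$volume_pct) <= 0))
  expect_equal(tail(h3$volume_pct, 1), 0)
  expect_error(dvh(u, array(FALSE, c(4, 4, 4))), "empty")
})

test_that("reduced PTV equals exhaustive set arithmetic on a toy grid", {
  set.seed(8)
  dims <- c(20, 20, 20)
  ptv <- array(runif(8000) < 0.4, dims)
  expander <- array(runif(8000) < 0.2, dims)
  port <- array(FALSE, dims)
  port[9:12, 9:12, 8:11] <- runif(64) < 0.5
  got <- reduced_ptv(ptv, expander, port)
  brute <- array(FALSE, dims)
  for (i in 1:20) for (j in 1:20) for (k in 1:20)
    brute[i, j, k] <- ptv[i, j, k] && any(port[, , k]) &&
      !expander[i, j, k] && !port[i, j, k]
  expect_identical(got, brute)
  # no port on the grid -> empty; expander covering PTV -> empty
  expect_false(any(reduced_ptv(ptv, expander, array(FALSE, dims))))
  expect_false(any(reduced_ptv(ptv, ptv | expander, port)))
  expect_error(reduced_ptv(ptv, expander, array(FALSE, c(5, 5, 5))), "geometry")
})

test_that("FWHM is unbiased on box troughs and rejects flat profiles", {
  for (sp in c(0.1, 0.25, 0.5)) {
    for (w in seq(2, 30, by = 2)) {
      x <- seq(-25, 25, by = sp)
      prof <- ifelse(abs(x - 0.3 * sp) < w / 2, 0.2, 1.0)
      expect_lt(abs(fwhm(prof, sp) - w), sp + 1e-9)
    }
  }
  expect_equal(fwhm(ifelse(abs(seq(-25, 25, 0.25)) < 8.75, 0.2, 1), 0.25), 17.5)
  expect_error(fwhm(rep(1, 100), 0.2), "flat")
})

test_that("port projections yield the model diameter and thickness", {
  perp <- port_projection(make_port(), "perpendicular", pixel_mm = 0.2)
  expect_equal(unname(port_dims_from_projection(perp)), 17.5, tolerance = 0.4 / 17.5)
  expect_named(port_dims_from_projection(perp), "diameter")
  par <- port_projection(make_port(), "parallel", pixel_mm = 0.2)
  expect_equal(unname(port_dims_from_projection(par)), 5, tolerance = 0.4 / 5)
  expect_named(port_dims_from_projection(par), "thickness")
  # a tilted port projects the same dimensions along its own axes
  tilted <- make_port(tilt_transverse = 25, tilt_sagittal = -10)
  expect_equal(unname(port_dims_from_projection(
    port_projection(tilted, "perpendicular", 0.2))), 17.5, tolerance = 0.03)
})

test_that("TLD calibration fits a line and inverts it", {
  fit <- tld_calibration_fit(c(0, 100), c(0, 1))
  expect_equal(fit$slope, 0.01)
  expect_equal(tld_dose(50, fit), 0.5)
  exact <- tld_calibration_fit(c(10, 20, 30, 40, 50), 0.3 + 0.02 * c(10, 20, 30, 40, 50))
  expect_lt(max(abs(exact$residuals)), 1e-12)
  expect_error(tld_calibration_fit(c(1, 2), c(1, 1)), "distinct")
  # seeded noise study: fitted slope within 3 standard errors in ~95% of runs
  set.seed(31)
  hits <- replicate(200, {
    r <- seq(10, 150, by = 20)
    dose <- 0.01 * r + rnorm(length(r), 0, 0.02)
    f <- tld_calibration_fit(r, dose)
    se <- summary(f$fit)$coefficients["readings", "Std. Error"]
    abs(f$slope - 0.01) <= 3 * se
  })
  expect_gte(mean(hits), 0.95)
})

test_that("the TLD experiment design enumerates 28 packets", {
  d <- tld_experiment_design()
  expect_equal(nrow(d), 28)
  expect_equal(sum(d$role == "measurement"), 24)
  expect_equal(sum(d$role == "background"), 1)
  expect_equal(sum(d$role == "calibration"), 3)
  expect_equal(nrow(unique(d[d$role == "measurement", c("state", "plan", "point")])), 24)
})
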