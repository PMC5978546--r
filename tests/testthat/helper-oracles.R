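# Independent oracles and small fixture builders used across the suite.

# Dense-sampling chord oracle: integrate the inside-indicator along the ray
# at `step` mm (1 um for the acceptance check). Independent of the analytic
# intersection code path.
chord_oracle <- function(port, origin, direction, tmax = 120, step = 0.001) {
  t <- seq(0, tmax, by = step)
  total <- 0
  for (i in seq(1, length(t), by = 200000)) {
    tt <- t[i:min(i + 199999, length(t))]
    pts <- cbind(origin[1] + tt * direction[1], origin[2] + tt * direction[2],
                 origin[3] + tt * direction[3])
    total <- total + sum(point_in_port(port, pts))
  }
  total * step
}

random_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

random_port <- function() {
  make_port(center = runif(3, -5, 5),
            tilt_transverse = runif(1, -90, 90),
            tilt_sagittal = runif(1, -90, 90),
            diameter = runif(1, 10, 25),
            thickness = runif(1, 2, 8),
            density = runif(1, 4, 10))
}

# narrow water tank for on-axis engine checks: surface at y = 0, beam from -y
narrow_water_tank <- function(halfwidth = 30, depth = 220, spacing = c(1, 1, 2)) {
  nx <- 2 * halfwidth / spacing[1] + 1
  nz <- 11
  g <- grid_spec(c(-halfwidth, spacing[2] / 2, -(nz - 1) / 2 * spacing[3]),
                 spacing, c(nx, depth / spacing[2], nz))
  voxel_volume(array(1, g$dims), g$origin, g$spacing, unit = "density",
               frame = "water_tank")
}

# brute-force 6-connected mask dilation
dilate_mask <- function(m) {
  out <- m
  idx <- which(m, arr.ind = TRUE)
  for (sh in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))) {
    idx2 <- sweep(idx, 2, sh, "+")
    keep <- idx2[, 1] >= 1 & idx2[, 1] <= dim(m)[1] &
      idx2[, 2] >= 1 & idx2[, 2] <= dim(m)[2] &
      idx2[, 3] >= 1 & idx2[, 3] <= dim(m)[3]
    out[idx2[keep, , drop = FALSE]] <- TRUE
  }
  out
}

circle_vertices <- function(center2, radius, n = 60) {
  a <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center2[1] + radius * cos(a), center2[2] + radius * sin(a))
}

# structure set with port + surrounding artifact ROI (+ optional shell) for
# the override-policy tests, built on a phantom's port
policy_structures <- function(port, grid, with_shell = FALSE) {
  ss_port <- slice_contours(port, grid)
  ct <- ss_port$rois[[1]]$contours
  art <- lapply(ct, function(c0) list(z = c0$z,
                                      vertices = circle_vertices(port$center[1:2], 22)))
  rois <- list(ss_port$rois[[1]],
               roi("artifact", art, 1.0, 2L))
  if (with_shell) {
    shell <- lapply(ct, function(c0) list(z = c0$z,
                                          vertices = circle_vertices(port$center[1:2], 12)))
    rois <- append(rois, list(roi("shell", shell, 4.2, 8L)), after = 1)
  }
  structure_set(rois)
}
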