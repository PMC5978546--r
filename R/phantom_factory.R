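#' CT number to mass density conversion tables
#'
#' Piecewise-linear lookup between Hounsfield units and mass density. The
#' non-extended clinical table saturates at `max_density` (3.0 g/cm^3 by
#' default), which is what makes CT-number-derived overrides underestimate a
#' 7.5 g/cm^3 port; the extended table continues up to 10 g/cm^3 so that
#' high-density overrides are representable.
#'
#' @param extended logical; extend the table beyond the clinical cap.
#' @param max_density saturation density for the non-extended table, g/cm^3.
#' @return object of class `ct_table` with fields `hu`, `density`,
#'   `extended`, `max_density`.
#' @export
ct_conversion_table <- function(extended = FALSE, max_density = 3.0) {
  hu <- c(-1000, -500, -100, 0, 100, 1000, 2000, 3000)
  de <- c(0.001, 0.50, 0.92, 1.0, 1.09, 1.60, 2.30, 3.00)
  if (extended) {
    hu <- c(hu, 6000, 9000, 12000)
    de <- c(de, 5.00, 7.50, 10.0)
  } else if (max_density != 3.0) {
    de[de > max_density] <- max_density
    keep <- !duplicated(de) | de < max_density
    hu <- hu[keep]; de <- de[keep]
  }
  structure(list(hu = hu, density = de, extended = extended,
                 max_density = if (extended) max(de) else max_density),
            class = "ct_table")
}

#' @rdname ct_conversion_table
#' @param table a `ct_table`.
#' @param hu,density values to convert.
#' @return converted values, clamped at the table ends (the non-extended table
#'   saturates at its `max_density`).
#' @export
density_from_hu <- function(table, hu) {
  if (!inherits(table, "ct_table") || !length(table$hu)) stop("empty or invalid CT table")
  out <- approx(table$hu, table$density, xout = hu, rule = 2)$y
  dim(out) <- dim(hu)
  out
}

#' @rdname ct_conversion_table
#' @export
hu_from_density <- function(table, density) {
  if (!inherits(table, "ct_table") || !length(table$hu)) stop("empty or invalid CT table")
  out <- approx(table$density, table$hu, xout = density, rule = 2, ties = "ordered")$y
  dim(out) <- dim(density)
  out
}

# fill a value into voxels inside the port
set_port_voxels <- function(vol, port, value) {
  mask <- rasterize(port, vol)
  vol$values[mask] <- value
  vol
}

#' Water-tank phantom for ion-chamber depth-dose measurements
#'
#' Builds the depth-dose measurement geometry: a water tank irradiated from
#' the anterior (-y) side at SSD 85 cm, isocenter at 15 cm depth, 10 x 10 cm^2
#' field, with the metallic port resting so its upstream ("top") face is 5 cm
#' below the water surface. The ion chamber samples the central axis between
#' 7 and 15 cm depth. `orientation = "perpendicular"` puts the disk axis along
#' the beam (chord = thickness); `"parallel"` puts it across the beam
#' (chord = diameter).
#'
#' @param port a [make_port()] model (its center/tilts are overridden by the
#'   setup geometry; dimensions and density are kept).
#' @param orientation `"perpendicular"` or `"parallel"` to the beam axis.
#' @param grid optional [grid_spec()]; must cover at least 200 mm of depth.
#'   Default: 1 mm isotropic, x,z in [-40, 40] mm, y (depth) in [0, 220] mm.
#' @param include_port set `FALSE` for the matching water-only volume.
#' @return a density [voxel_volume()] with setup metadata in `$meta` (`ssd_mm`
#'   850, `isocenter_depth_mm` 150, `field_mm` c(100, 100), `ic_depths_mm`
#'   70-150, `port` parameters, `orientation`).
#' @export
build_ic_phantom <- function(port = make_port(), orientation = c("perpendicular", "parallel"),
                             grid = NULL, include_port = TRUE) {
  orientation <- match.arg(orientation)
  if (is.null(grid))
    grid <- grid_spec(origin = c(-40, 0.5, -40), spacing = c(1, 1, 1),
                      dims = c(81, 220, 81))
  depth_extent <- grid$origin[2] + (grid$dims[2] - 0.5) * grid$spacing[2]
  if (depth_extent < 200) stop("grid too shallow: must cover >= 200 mm of depth")
  top_depth <- 50  # mm from water surface to the upstream port face
  if (orientation == "perpendicular") {
    p <- make_port(center = c(0, top_depth + port$thickness / 2, 0),
                   diameter = port$diameter, thickness = port$thickness,
                   density = port$density)
  } else {
    p <- make_port(center = c(0, top_depth + port$diameter / 2, 0),
                   tilt_transverse = 90,
                   diameter = port$diameter, thickness = port$thickness,
                   density = port$density)
  }
  vol <- voxel_volume(array(1.0, grid$dims), grid$origin, grid$spacing,
                      unit = "density", frame = "ic_tank")
  if (include_port) vol <- set_port_voxels(vol, p, p$density)
  vol$meta <- list(setup = "ic_tank", ssd_mm = 850, isocenter_depth_mm = 150,
                   field_mm = c(100, 100), ic_depths_mm = seq(70, 150, by = 10),
                   surface_y_mm = 0, orientation = orientation, port = p)
  vol
}

#' Simplified anthropomorphic phantom (inflated / deflated expander)
#'
#' Slab stack irradiated laterally (gantry 90/270): a water-equivalent block
#' standing in for the tissue expander (63 mm inflated, 20 mm deflated) over a
#' 10 mm bolus chest wall over a low-density wooden "lung" slab. The port
#' centre sits 20 mm below the anterior surface; the isocenter is at the
#' lung/chest-wall interface, laterally aligned with the port. Phantom
#' half-widths are chosen so the lateral SSD matches the measurement setups:
#' 90.7 cm (inflated) and 95 cm (deflated) at SAD 100 cm.
#'
#' @param state `"inflated"` or `"deflated"`.
#' @param port a [make_port()] model (dimensions/density kept, placed by setup).
#' @param lung_density wooden lung-slab density, g/cm^3.
#' @param spacing grid spacing mm; default 1 mm in-plane, 2.5 mm slices.
#' @param include_port set `FALSE` for the port-free baseline.
#' @return density [voxel_volume()] with `$meta` (`ssd_mm`, `isocenter_mm`,
#'   `state`, `port`, layer boundaries).
#' @export
build_anthro_phantom <- function(state = c("inflated", "deflated"),
                                 port = make_port(), lung_density = 0.30,
                                 spacing = c(1, 1, 2.5), include_port = TRUE) {
  state <- match.arg(state)
  block <- if (state == "inflated") 63 else 20
  halfw <- if (state == "inflated") 93 else 50   # lateral half-width -> SSD 907 / 950
  bolus <- 10; lung <- 60
  ny <- ceiling((block + bolus + lung) / spacing[2])
  nx <- ceiling(2 * halfw / spacing[1]); nz <- ceiling(100 / spacing[3])
  if (nx %% 2 == 0) nx <- nx + 1
  if (nz %% 2 == 0) nz <- nz + 1
  org <- c(-(nx - 1) / 2 * spacing[1], spacing[2] / 2, -(nz - 1) / 2 * spacing[3])
  vol <- voxel_volume(array(1.0, c(nx, ny, nz)), org, spacing,
                      unit = "density", frame = paste0("anthro_", state))
  ys <- vol_axis(vol, 2)
  vol$values[, ys > block + bolus, ] <- lung_density
  p <- make_port(center = c(0, 20, 0), diameter = port$diameter,
                 thickness = port$thickness, density = port$density)
  if (include_port) vol <- set_port_voxels(vol, p, p$density)
  vol$meta <- list(setup = "anthro", state = state,
                   ssd_mm = 1000 - halfw, isocenter_mm = c(0, block + bolus, 0),
                   surface_y_mm = 0, block_mm = block, bolus_mm = bolus,
                   lung_density = lung_density, port = p,
                   lateral_halfwidth_mm = halfw)
  vol
}

#' TLD measurement point layout for the anthropomorphic phantom
#'
#' Four labelled points around the port: points 1, 2 and 4 are 25 mm from the
#' port centre (lateral, superior, inferior), point 3 is directly under the
#' port on its axis (25 mm deep to the centre, a documented choice - the setup
#' drawing fixes only its lateral position).
#'
#' @param state `"inflated"` or `"deflated"` (same layout in both).
#' @return a `measurement_set` of labelled positions (doses `NA`).
#' @export
place_measurement_points <- function(state = c("inflated", "deflated")) {
  state <- match.arg(state)
  pc <- c(0, 20, 0)
  pts <- data.frame(label = c("point1", "point2", "point3", "point4"),
                    x = pc[1] + c(25, 0, 0, 0),
                    y = pc[2] + c(0, 0, 25, 0),
                    z = pc[3] + c(0, 25, 0, -25),
                    dose = NA_real_, sd = NA_real_)
  measurement_points(pts, meta = list(state = state, port_center = pc))
}

#' Measurement sets
#'
#' Containers for measured or reference doses: labelled points
#' (`measurement_points`) or depth-dose records (`depth_dose_record` /
#' `measurement_depth_doses`).
#'
#' @param points data.frame with columns label, x, y, z, dose, sd.
#' @param meta named list.
#' @return object of class `measurement_set`.
#' @export
measurement_points <- function(points, meta = list()) {
  stopifnot(all(c("label", "x", "y", "z", "dose") %in% names(points)))
  if (anyDuplicated(points$label)) stop("point labels must be unique")
  if (any(points$dose < 0, na.rm = TRUE)) stop("doses must be non-negative")
  structure(list(type = "points", points = points, meta = meta),
            class = "measurement_set")
}

#' @rdname measurement_points
#' @param setup `"parallel"` or `"perpendicular"`.
#' @param energy_mv nominal beam energy.
#' @param depth_mm,dose depth-dose pairs; depths strictly increasing.
#' @export
depth_dose_record <- function(setup, energy_mv, depth_mm, dose) {
  setup <- match.arg(setup, c("parallel", "perpendicular"))
  if (length(depth_mm) != length(dose)) stop("depth and dose lengths differ")
  if (is.unsorted(depth_mm, strictly = TRUE)) stop("depths must be strictly increasing")
  if (any(dose < 0)) stop("doses must be non-negative")
  list(setup = setup, energy_mv = energy_mv,
       data = data.frame(depth_mm = depth_mm, dose = dose))
}

#' @rdname measurement_points
#' @param records list of [depth_dose_record()]s.
#' @export
measurement_depth_doses <- function(records, meta = list()) {
  structure(list(type = "depth_dose", records = records, meta = meta),
            class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  if (x$type == "points")
    cat(sprintf("<measurement_set> %d labelled point(s)\n", nrow(x$points)))
  else
    cat(sprintf("<measurement_set> %d depth-dose record(s)\n", length(x$records)))
  invisible(x)
}

#' Simulate CT metal-streak artifacts around the port
#'
#' Adds alternating bright/dark radial streaks emanating from the port-mask
#' centroid in every slice containing the port: amplitude
#' `magnitude * cos(n_streaks * (phi - phi0))`, decaying linearly to zero at
#' 80 mm from the centroid. Deterministic given `seed` (the streak phase and a
#' small per-slice jitter are the only random draws). A reconstruction-physics
#' simulation is out of scope; this reproduces the geometry that contaminates
#' port contouring.
#'
#' @param volume a [voxel_volume()] in HU.
#' @param port_mask logical array matching the volume.
#' @param magnitude maximum streak amplitude, HU.
#' @param n_streaks number of bright/dark streak pairs around the circle.
#' @param seed integer seed.
#' @param reach_mm artifacts vanish beyond this distance from the port.
#' @return HU [voxel_volume()] with artifacts added.
#' @export
add_metal_artifacts <- function(volume, port_mask, magnitude = 300,
                                n_streaks = 8, seed = 1, reach_mm = 80) {
  if (volume$unit != "HU") stop("artifacts are defined on HU volumes")
  if (!identical(dim(port_mask), dim(volume$values))) stop("mask geometry mismatch")
  if (magnitude == 0) return(volume)
  xs <- vol_axis(volume, 1); ys <- vol_axis(volume, 2)
  with_seed(seed, {
    phi0 <- runif(1, 0, 2 * pi)
    for (k in seq_len(volume$dims[3])) {
      m <- port_mask[, , k]
      if (!any(m)) next
      idx <- which(m, arr.ind = TRUE)
      cx <- mean(xs[idx[, 1]]); cy <- mean(ys[idx[, 2]])
      dx <- outer(xs - cx, rep(1, volume$dims[2]))
      dy <- outer(rep(1, volume$dims[1]), ys - cy)
      rr <- sqrt(dx^2 + dy^2)
      phi <- atan2(dy, dx)
      jit <- runif(1, -0.05, 0.05)
      streak <- magnitude * cos(n_streaks * (phi - phi0 - jit)) *
        pmax(0, 1 - rr / reach_mm)
      streak[m] <- 0  # port voxels themselves are left to the CT values
      volume$values[, , k] <- volume$values[, , k] + streak
    }
    volume
  })
}

#' Apply a port density-override policy
#'
#' Converts an HU volume to mass density and applies one of the three port
#' modeling policies:
#' \describe{
#'   \item{clinical1}{magnet and shell contoured from physical dimensions and
#'     overridden by nominal densities (7.4 and 4.2 g/cm^3); surrounding
#'     artifacts overridden as water.}
#'   \item{clinical2}{the artifact-contaminated port contour keeps CT-derived
#'     densities through the non-extended conversion table (saturating at its
#'     clinical cap); artifacts outside it overridden as water.}
#'   \item{new}{the disk contour overridden by the calibrated density
#'     (7.5 g/cm^3 by default); artifacts overridden as water.}
#' }
#' Overlaps resolve by ROI priority (port > shell > artifact > background).
#' Voxels outside every ROI always get the plain table conversion.
#'
#' @param volume [voxel_volume()] in HU (a density volume is accepted when no
#'   CT-derived values are needed, i.e. any policy except `clinical2`).
#' @param structures a [structure_set()]; required ROIs: `port` (+ `shell` for
#'   clinical1) and `artifact`.
#' @param policy `"clinical1"`, `"clinical2"` or `"new"`.
#' @param table conversion table for the background (and, non-extended, for
#'   clinical2's port voxels).
#' @return density [voxel_volume()].
#' @export
apply_override_policy <- function(volume, structures,
                                  policy = c("new", "clinical1", "clinical2"),
                                  table = ct_conversion_table(extended = TRUE)) {
  policy <- match.arg(policy)
  need <- c("port", "artifact", if (policy == "clinical1") "shell")
  have <- vapply(structures$rois, function(r) r$name, "")
  missing_roi <- setdiff(need, have)
  if (length(missing_roi))
    stop(sprintf("policy %s requires missing ROI(s): %s", policy,
                 paste(missing_roi, collapse = ", ")))
  is_hu <- volume$unit == "HU"
  if (!is_hu && policy == "clinical2")
    stop("clinical2 keeps CT-derived densities and needs an HU volume")
  base <- if (is_hu) density_from_hu(table, volume$values) else volume$values
  base <- array(base, dim = volume$dims)
  masks <- rasterize(structures, volume, combine = FALSE)
  prio <- vapply(structures$rois, function(r) r$priority, 0L)
  ord <- order(prio)  # apply low priority first so high priority wins
  for (i in ord) {
    r <- structures$rois[[i]]
    m <- masks[[r$name]]
    if (!any(m)) next
    val <- switch(r$name,
      artifact = 1.0,
      shell = if (policy == "clinical1") port_reference_dimensions$ti_shell$density_g_cm3
              else NA_real_,
      port = switch(policy,
        clinical1 = port_reference_dimensions$magnet$density_g_cm3,
        clinical2 = NA_real_,  # handled below: capped CT conversion
        new = if (is.na(r$override_density)) 7.5 else r$override_density),
      r$override_density)
    if (r$name == "port" && policy == "clinical2") {
      capped <- ct_conversion_table(extended = FALSE)
      base[m] <- density_from_hu(capped, volume$values[m])
    } else if (!is.na(val)) {
      base[m] <- val
    }
  }
  voxel_volume(base, volume$origin, volume$spacing, unit = "density",
               frame = volume$frame,
               meta = c(volume$meta, list(override_policy = policy)))
}

#' Patient-like chest phantom (synthetic)
#'
#' A synthetic half-cylindrical chest with an embedded water-filled expander
#' sphere, the metallic port at the expander's anterior face (with seeded
#' tilts), a PTV covering the chest wall and wrapping the expander, and four
#' labelled evaluation points: `skin1`/`skin2` at 12 mm depth on the two exit
#' sides of the opposed-tangent (gantry 307/127 degrees) axis through the
#' port - the band where the port casts its skin shadow - and `CW1`/`CW2` on
#' the chest wall behind the expander. This stands in for a patient CT; it is
#' deterministic per seed.
#'
#' @param seed integer seed controlling port tilts and point jitter.
#' @param spacing grid spacing mm.
#' @return list with `volume` (HU [voxel_volume()]), `structures`
#'   ([structure_set()] with `ptv`, `expander`, `port`, `artifact`),
#'   `points` ([measurement_points()]), and `port` (the [make_port()] model).
#' @export
build_patient_like <- function(seed = 1, spacing = c(2, 2, 2.5)) {
  with_seed(seed, {
    R <- 100; y0 <- 100           # chest: anterior half-cylinder, axis along z
    nx <- 111; ny <- 53; nz <- 49
    org <- c(-(nx - 1) / 2 * spacing[1], 1, -(nz - 1) / 2 * spacing[3])
    vol <- voxel_volume(array(-1000, c(nx, ny, nz)), org, spacing,
                        unit = "HU", frame = "patient_like",
                        meta = list(seed = seed))
    ctr <- vol_centers(vol)
    tissue <- (ctr[, 1]^2 + (ctr[, 2] - y0)^2 <= R^2) & ctr[, 2] <= y0
    vol$values[tissue] <- 0
    # expander sphere under the chest wall
    ec <- c(15, 55, 0); re <- 33
    insph <- colSums((t(ctr) - ec)^2) <= re^2
    vol$values[insph & tissue] <- 0
    # port at the expander's anterior face, seeded tilt
    tiltT <- runif(1, -15, 15); tiltS <- runif(1, -15, 15)
    port <- make_port(center = ec - c(0, re - 7, 0),
                      tilt_transverse = tiltT, tilt_sagittal = tiltS)
    pm <- rasterize(port, vol)
    vol$values[pm] <- 3000  # metal saturates the CT scale
    vol <- add_metal_artifacts(vol, pm, magnitude = 300, seed = seed)

    surf_y <- function(x) y0 - sqrt(pmax(0, R^2 - x^2))
    zs <- vol_axis(vol, 3)
    # PTV: chest-wall annulus (surface to 18 mm deep), pushed deeper to wrap
    # the expander where it intrudes
    ptv_contours <- list()
    for (z0 in zs[abs(zs) <= 45]) {
      xr <- seq(-80, 80, by = 2)
      outer_y <- surf_y(xr) + 1
      under <- re^2 - (xr - ec[1])^2 - (z0 - ec[3])^2
      inner_y <- pmax(surf_y(xr) + 18,
                      ifelse(under > 0, ec[2] + sqrt(pmax(0, under)) + 3, -Inf))
      inner_y <- pmin(inner_y, y0 - 2)
      verts <- rbind(cbind(xr, outer_y), cbind(rev(xr), rev(inner_y)))
      ptv_contours[[length(ptv_contours) + 1L]] <- list(z = z0, vertices = verts)
    }
    circle <- function(c2, r, n = 72) {
      a <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
      cbind(c2[1] + r * cos(a), c2[2] + r * sin(a))
    }
    exp_contours <- list()
    for (z0 in zs) {
      rr2 <- re^2 - (z0 - ec[3])^2
      if (rr2 <= 4) next
      exp_contours[[length(exp_contours) + 1L]] <-
        list(z = z0, vertices = circle(ec[1:2], sqrt(rr2)))
    }
    art_contours <- lapply(exp_contours[seq_len(min(6, length(exp_contours)))],
                           function(ct) list(z = ct$z,
                                             vertices = circle(port$center[1:2], 25)))
    port_ss <- slice_contours(port, vol)
    structures <- structure_set(list(
      roi("ptv", ptv_contours, NA_real_, 1L),
      roi("expander", exp_contours, 1.0, 5L),
      port_ss$rois[[1]],
      roi("artifact", art_contours, 1.0, 2L)))

    jit <- function() runif(1, -2, 2)
    # skin points: on the opposed-tangent axis (gantry 307/127) through the
    # port, at 12 mm depth below the curved surface on either exit side
    dtan <- c(sin(127 * pi / 180), -cos(127 * pi / 180))
    depth_at <- function(t) {
      p <- port$center[1:2] + t * dtan
      p[2] - surf_y(p[1]) - 12
    }
    t1 <- stats::uniroot(depth_at, c(-70, -5))$root
    t2 <- stats::uniroot(depth_at, c(60, 120))$root
    s1 <- port$center[1:2] + t1 * dtan
    s2 <- port$center[1:2] + t2 * dtan
    pts <- data.frame(
      label = c("skin1", "skin2", "CW1", "CW2"),
      x = c(s1[1], s2[1], ec[1] + jit(), ec[1] + jit()),
      y = c(s1[2], s2[2], ec[2] + re + 8, ec[2] + re + 8),
      z = c(port$center[3] + jit(), port$center[3] + jit(),
            12 + jit(), -12 + jit()),
      dose = NA_real_, sd = NA_real_)
    list(volume = vol, structures = structures,
         points = measurement_points(pts, meta = list(seed = seed)),
         port = port)
  })
}
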