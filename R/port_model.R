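#' Physical reference dimensions of the magnetic injection port
#'
#' Nominal manufacturer values for the magnetic injection port: the
#' neodymium magnetic disk and its titanium shell casing. The radiological
#' model determined from depth-dose measurements (17.5 mm diameter, 5 mm
#' thickness, 7.5 g/cm^3) intentionally differs from these physical values.
#'
#' @format named list with `magnet` (diameter_mm 21, thickness_mm 3.5,
#'   density_g_cm3 7.4) and `ti_shell` (diameter_mm 35, thickness_mm 0.4,
#'   density_g_cm3 4.2).
#' @export
port_reference_dimensions <- list(
  magnet   = list(diameter_mm = 21,  thickness_mm = 3.5, density_g_cm3 = 7.4),
  ti_shell = list(diameter_mm = 35,  thickness_mm = 0.4, density_g_cm3 = 4.2)
)

#' Construct a tilted-disk metallic port model
#'
#' The port is a finite homogeneous cylinder (disk). Its axis starts
#' anterior-posterior, `(0, 1, 0)`; the sagittal tilt (rotation about the
#' left-right x axis) is applied first, then the transverse tilt (rotation
#' about the inferior-superior z axis), both in degrees with the right-hand
#' rule. The default dimensions and density are the radiologically determined
#' model values (17.5 mm x 5 mm, 7.5 g/cm^3), not the physical magnet
#' dimensions. The titanium shell is excluded by default (its areal density,
#' under 0.2 g/cm^2, is dosimetrically negligible) but can be carried as an
#' optional `shell` spec.
#'
#' @param center disk centre, world mm (length 3).
#' @param tilt_transverse rotation of the disk axis about z, degrees.
#' @param tilt_sagittal rotation of the disk axis about x, degrees.
#' @param diameter,thickness disk dimensions, mm, > 0.
#' @param density mass density, g/cm^3, > 0.
#' @param shell optional `list(shell_thickness, shell_density)` (mm, g/cm^3).
#' @return object of class `port_model` with a derived unit `axis` vector.
#' @examples
#' p <- make_port()
#' p$diameter  # 17.5
#' p$axis      # (0, 1, 0) for zero tilts
#' @export
make_port <- function(center = c(0, 0, 0), tilt_transverse = 0, tilt_sagittal = 0,
                      diameter = 17.5, thickness = 5, density = 7.5,
                      shell = NULL) {
  num1 <- function(v, nm) {
    if (length(v) != 1 || !is.finite(v)) stop(sprintf("`%s` must be a finite number", nm))
    as.numeric(v)
  }
  center <- as.numeric(center)
  if (length(center) != 3 || any(!is.finite(center))) stop("`center` must be 3 finite numbers")
  tilt_transverse <- num1(tilt_transverse, "tilt_transverse")
  tilt_sagittal <- num1(tilt_sagittal, "tilt_sagittal")
  for (nm in c("diameter", "thickness", "density")) {
    v <- num1(get(nm), nm)
    if (v <= 0) stop(sprintf("`%s` must be positive (got %g)", nm, v))
  }
  if (!is.null(shell)) {
    if (!all(c("shell_thickness", "shell_density") %in% names(shell)))
      stop("`shell` needs fields shell_thickness and shell_density")
    if (shell$shell_thickness <= 0 || shell$shell_density <= 0)
      stop("`shell` dimensions and density must be positive")
  }
  axis <- rot_z(tilt_transverse) %*% rot_x(tilt_sagittal) %*% c(0, 1, 0)
  axis <- as.numeric(axis / sqrt(sum(axis^2)))
  structure(list(center = center, tilt_transverse = tilt_transverse,
                 tilt_sagittal = tilt_sagittal, diameter = as.numeric(diameter),
                 thickness = as.numeric(thickness), density = as.numeric(density),
                 shell = shell, axis = axis),
            class = "port_model")
}

rot_x <- function(deg) {
  t <- deg * pi / 180; c <- cos(t); s <- sin(t)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}
rot_z <- function(deg) {
  t <- deg * pi / 180; c <- cos(t); s <- sin(t)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' @export
print.port_model <- function(x, ...) {
  cat(sprintf("<port_model> %.4g mm diameter x %.4g mm, %.4g g/cm3\n",
              x$diameter, x$thickness, x$density))
  cat(sprintf("  center (%.1f, %.1f, %.1f) mm, tilts %g/%g deg, axis (%.3f, %.3f, %.3f)\n",
              x$center[1], x$center[2], x$center[3],
              x$tilt_transverse, x$tilt_sagittal, x$axis[1], x$axis[2], x$axis[3]))
  invisible(x)
}

#' Are points inside the port solid?
#'
#' @param port a [make_port()] model.
#' @param points n x 3 matrix (or length-3 vector) of world mm.
#' @return logical vector.
#' @export
point_in_port <- function(port, points) {
  p <- sweep(rbind3(points), 2, port$center)
  ax <- p %*% port$axis
  rad2 <- rowSums(p^2) - ax^2
  abs(ax) <= port$thickness / 2 + 1e-12 &
    rad2 <= (port$diameter / 2)^2 + 1e-9
}

#' Chord length of a ray through the port
#'
#' Exact analytic intersection of a ray with the finite cylinder: the lateral
#' surface gives a quadratic interval in the ray parameter, the cap planes a
#' slab interval; the chord is the length of their intersection.
#'
#' @param port a [make_port()] model.
#' @param ray_origin point on the ray, mm (or n x 3 matrix).
#' @param ray_direction unit direction (or n x 3 matrix, rows unit-norm).
#' @return chord length(s) in mm; 0 for rays that miss.
#' @export
chord_length <- function(port, ray_origin, ray_direction) {
  O <- rbind3(ray_origin); D <- rbind3(ray_direction)
  if (nrow(O) == 1 && nrow(D) > 1) O <- O[rep(1, nrow(D)), , drop = FALSE]
  if (nrow(D) == 1 && nrow(O) > 1) D <- D[rep(1, nrow(O)), , drop = FALSE]
  nrm <- sqrt(rowSums(D^2))
  if (any(nrm < 1e-12)) stop("ray_direction must have non-zero norm")
  if (any(abs(nrm - 1) > 1e-6)) stop("ray_direction must be unit-norm")
  u <- port$axis; R <- port$diameter / 2; h <- port$thickness / 2
  o <- sweep(O, 2, port$center)
  opar <- as.numeric(o %*% u); dpar <- as.numeric(D %*% u)
  op <- o - outer(opar, u); dp <- D - outer(dpar, u)
  A <- rowSums(dp^2); B <- 2 * rowSums(op * dp); C <- rowSums(op^2) - R^2

  n <- nrow(O)
  lo <- rep(-Inf, n); hi <- rep(Inf, n)
  # lateral surface interval
  quad <- A > 1e-14
  disc <- B^2 - 4 * A * C
  missq <- quad & disc <= 0
  qi <- which(quad & disc > 0)
  if (length(qi)) {
    sq <- sqrt(disc[qi])
    t1 <- (-B[qi] - sq) / (2 * A[qi]); t2 <- (-B[qi] + sq) / (2 * A[qi])
    lo[qi] <- pmax(lo[qi], pmin(t1, t2)); hi[qi] <- pmin(hi[qi], pmax(t1, t2))
  }
  missd <- !quad & C > 0  # ray parallel to axis, outside radius
  # cap-plane slab interval
  slab <- abs(dpar) > 1e-14
  si <- which(slab)
  if (length(si)) {
    ta <- (-h - opar[si]) / dpar[si]; tb <- (h - opar[si]) / dpar[si]
    lo[si] <- pmax(lo[si], pmin(ta, tb)); hi[si] <- pmin(hi[si], pmax(ta, tb))
  }
  missp <- !slab & abs(opar) > h  # ray in a plane outside the slab
  len <- pmax(0, hi - lo)
  len[missq | missd | missp] <- 0
  len[!is.finite(len)] <- 0
  len
}

#' Areal density of a uniform slab
#'
#' @param thickness_cm slab thickness, cm, >= 0.
#' @param density_g_cm3 mass density, g/cm^3, >= 0.
#' @return areal density in g/cm^2 (thickness x density).
#' @examples
#' areal_density(0.04, 4.5)  # 0.18 g/cm^2, the titanium-shell effective wall
#' @export
areal_density <- function(thickness_cm, density_g_cm3) {
  if (any(thickness_cm < 0) || any(density_g_cm3 < 0))
    stop("thickness and density must be non-negative")
  thickness_cm * density_g_cm3
}

# ---- structure sets ---------------------------------------------------------

#' Build a structure set of named regions of interest
#'
#' A structure set carries per-slice closed planar polygons for each ROI,
#' together with an optional override density and an override priority (larger
#' wins on overlap).
#'
#' @param rois list of ROIs as returned by [roi()].
#' @return object of class `structure_set`.
#' @export
structure_set <- function(rois = list()) {
  nms <- vapply(rois, function(r) r$name, "")
  if (anyDuplicated(nms)) stop("ROI names must be unique")
  structure(list(rois = rois), class = "structure_set")
}

#' @rdname structure_set
#' @param name ROI name.
#' @param contours list of `list(z = <mm>, vertices = <n x 2 matrix, mm>)`;
#'   vertices are an open polygon (first vertex not repeated), counter-clockwise.
#' @param override_density density assigned inside the ROI by override
#'   policies, g/cm^3, or `NA` to keep CT-derived values.
#' @param priority integer override priority; larger wins where ROIs overlap.
#' @export
roi <- function(name, contours = list(), override_density = NA_real_, priority = 0L) {
  stopifnot(is.character(name), length(name) == 1)
  for (ct in contours) {
    if (!all(c("z", "vertices") %in% names(ct)) || ncol(ct$vertices) != 2)
      stop("each contour needs `z` and an n x 2 `vertices` matrix")
  }
  list(name = name, contours = contours,
       override_density = as.numeric(override_density),
       priority = as.integer(priority))
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> %d ROI(s)\n", length(x$rois)))
  for (r in x$rois)
    cat(sprintf("  %s: %d contour slice(s), override %s, priority %d\n", r$name,
                length(r$contours),
                ifelse(is.na(r$override_density), "none",
                       sprintf("%.3g g/cm3", r$override_density)), r$priority))
  invisible(x)
}

get_roi <- function(structures, name) {
  for (r in structures$rois) if (identical(r$name, name)) return(r)
  NULL
}

#' Generate per-slice contours of the port
#'
#' For every axial slice plane of `grid` that intersects the port solid, a
#' closed counter-clockwise polygon approximating the planar cross-section of
#' the tilted cylinder is generated. Cross-sections of a convex solid are
#' convex, so each polygon is traced by bisection along rays fanning out from
#' an interior point; the number of vertices is chosen so that vertex spacing
#' stays below `max_vertex_spacing`.
#'
#' @param port a [make_port()] model.
#' @param grid a [voxel_volume()] or [grid_spec()] providing slice geometry.
#' @param name,override_density,priority passed to [roi()].
#' @param max_vertex_spacing maximum polygon vertex spacing, mm.
#' @return a [structure_set()] with one ROI (empty if no slice intersects).
#' @export
slice_contours <- function(port, grid, name = "port",
                           override_density = port$density, priority = 10L,
                           max_vertex_spacing = 0.5) {
  zs <- vol_axis(grid, 3)
  half_extent <- sqrt((port$diameter / 2)^2 + (port$thickness / 2)^2)
  zs <- zs[zs >= port$center[3] - half_extent - 1e-9 &
           zs <= port$center[3] + half_extent + 1e-9]
  contours <- list()
  for (z0 in zs) {
    poly <- port_section_polygon(port, z0, max_vertex_spacing)
    if (!is.null(poly)) contours[[length(contours) + 1L]] <- list(z = z0, vertices = poly)
  }
  structure_set(list(roi(name, contours, override_density, priority)))
}

# convex cross-section polygon of the port in the plane z = z0, or NULL
port_section_polygon <- function(port, z0, max_vertex_spacing = 0.5) {
  R <- port$diameter / 2; h <- port$thickness / 2
  half_extent <- sqrt(R^2 + h^2)
  inside <- function(x, y) point_in_port(port, cbind(x, y, z0))
  # interior seed by coarse-to-fine scan of the bounding square
  seed <- NULL
  for (step in c(1, 0.25, 0.05)) {
    g <- seq(-half_extent, half_extent, by = step)
    xs <- rep(port$center[1] + g, times = length(g))
    ys <- rep(port$center[2] + g, each = length(g))
    ok <- inside(xs, ys)
    if (any(ok)) {
      seed <- c(mean(xs[ok]), mean(ys[ok]))
      if (!inside(seed[1], seed[2])) {
        # centroid can fall outside for grazing sections; use nearest scan hit
        k <- which(ok)[which.min((xs[ok] - seed[1])^2 + (ys[ok] - seed[2])^2)]
        seed <- c(xs[k], ys[k])
      }
      break
    }
  }
  if (is.null(seed)) return(NULL)
  trace_poly <- function(n) {
    ang <- (seq_len(n) - 1) / n * 2 * pi
    ca <- cos(ang); sa <- sin(ang)
    lo <- rep(0, n); hi <- rep(2 * half_extent + 1, n)
    for (it in 1:45) {
      mid <- (lo + hi) / 2
      ok <- inside(seed[1] + mid * ca, seed[2] + mid * sa)
      lo[ok] <- mid[ok]; hi[!ok] <- mid[!ok]
    }
    cbind(seed[1] + lo * ca, seed[2] + lo * sa)
  }
  poly <- trace_poly(64)
  per <- sum(sqrt(rowSums((poly - poly[c(2:64, 1), ])^2)))
  n <- max(16L, ceiling(per / (0.8 * max_vertex_spacing)))
  trace_poly(n)
}

polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

# ---- rasterization ----------------------------------------------------------

#' Rasterize a port or structure set onto a grid
#'
#' Boolean occupancy by voxel-centre inclusion test.
#'
#' @param x a `port_model` or `structure_set`.
#' @param grid a [voxel_volume()] or [grid_spec()] defining the geometry.
#' @param ... unused.
#' @return for a port or with `combine = TRUE`, a logical array of `grid$dims`;
#'   with `combine = FALSE` (structure sets) a named list of such arrays.
#' @export
rasterize <- function(x, grid, ...) UseMethod("rasterize")

#' @export
rasterize.port_model <- function(x, grid, ...) {
  mask <- point_in_port(x, vol_centers(grid))
  array(mask, dim = grid$dims)
}

#' @rdname rasterize
#' @param combine union all ROIs into one mask (`TRUE`) or return a named list
#'   of per-ROI masks (`FALSE`).
#' @export
rasterize.structure_set <- function(x, grid, combine = TRUE, ...) {
  zs <- vol_axis(grid, 3)
  xs <- vol_axis(grid, 1); ys <- vol_axis(grid, 2)
  px <- rep(xs, times = grid$dims[2]); py <- rep(ys, each = grid$dims[1])
  masks <- list()
  for (r in x$rois) {
    m <- array(FALSE, dim = grid$dims)
    for (ct in r$contours) {
      k <- which(abs(zs - ct$z) <= grid$spacing[3] / 2 + 1e-9)
      if (!length(k)) next
      k <- k[which.min(abs(zs[k] - ct$z))]
      inpoly <- cpp_point_in_poly(px, py, ct$vertices[, 1], ct$vertices[, 2])
      m[, , k] <- m[, , k] | matrix(inpoly, grid$dims[1], grid$dims[2])
    }
    masks[[r$name]] <- m
  }
  if (!combine) return(masks)
  out <- array(FALSE, dim = grid$dims)
  for (m in masks) out <- out | m
  out
}

# analytic volume of the port disk, cm^3
port_volume_cm3 <- function(port) {
  pi * (port$diameter / 20)^2 * (port$thickness / 10)
}
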