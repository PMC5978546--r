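#' Create a voxel volume
#'
#' Regular 3D grid of scalar values (Hounsfield units or mass density) with the
#' value located at the voxel centre. The grid extent is half-open:
#' `[origin - spacing/2, origin + (dims - 1/2) * spacing)`.
#'
#' @param values numeric 3D array (x, y, z order) or a single value to fill.
#' @param origin world coordinates (mm) of the centre of voxel (1,1,1).
#' @param spacing voxel spacing (mm), length 3, all positive.
#' @param dims grid dimensions, length 3, all >= 1. Defaults to `dim(values)`.
#' @param unit `"HU"` or `"density"` (g/cm^3).
#' @param frame free-text frame label.
#' @param meta named list of provenance metadata (seed, recipe, ...).
#' @return object of class `voxel_volume`.
#' @export
voxel_volume <- function(values, origin, spacing, dims = NULL,
                         unit = c("density", "HU", "Gy"), frame = "world",
                         meta = list()) {
  unit <- match.arg(unit)
  if (is.null(dims)) {
    if (is.null(dim(values)) || length(dim(values)) != 3L)
      stop("`values` must be a 3D array when `dims` is not given")
    dims <- dim(values)
  }
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L)) stop("`dims` must be 3 positive integers")
  if (length(values) == 1L) values <- array(values, dim = dims)
  if (!identical(dim(values), dims)) dim(values) <- dims
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers")
  if (any(!is.finite(values))) stop("volume values must be finite")
  if (unit %in% c("density", "Gy") && any(values < -1e-12))
    stop(sprintf("%s values must be non-negative", unit))
  structure(list(values = values, origin = origin, spacing = spacing,
                 dims = dims, unit = unit, frame = frame, meta = meta),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("<voxel_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, unit %s\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3], x$unit))
  cat(sprintf("  origin (%.2f, %.2f, %.2f) mm, value range [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$values), max(x$values)))
  invisible(x)
}

# axis coordinates of voxel centres
vol_axis <- function(vol, a) vol$origin[a] + (seq_len(vol$dims[a]) - 1) * vol$spacing[a]

# n x 3 matrix of all voxel centre coordinates (x fastest, matching array layout)
vol_centers <- function(vol) {
  xs <- vol_axis(vol, 1); ys <- vol_axis(vol, 2); zs <- vol_axis(vol, 3)
  cbind(rep(xs, times = vol$dims[2] * vol$dims[3]),
        rep(rep(ys, each = vol$dims[1]), times = vol$dims[3]),
        rep(zs, each = vol$dims[1] * vol$dims[2]))
}

# bounding box [lo, hi) of the grid extent
vol_box <- function(vol) {
  lo <- vol$origin - vol$spacing / 2
  list(lo = lo, hi = lo + vol$dims * vol$spacing)
}

same_geometry <- function(a, b, tol = 1e-9) {
  identical(a$dims, b$dims) &&
    max(abs(a$origin - b$origin)) < tol &&
    max(abs(a$spacing - b$spacing)) < tol
}

#' Sample a volume at arbitrary points by trilinear interpolation
#'
#' @param vol a [voxel_volume()].
#' @param points numeric n x 3 matrix (or length-3 vector) of world mm.
#' @return numeric vector; `NA` outside the grid of voxel centres.
#' @export
sample_volume <- function(vol, points) {
  points <- rbind3(points)
  cpp_trilinear(as.numeric(vol$values), vol$dims, vol$origin, vol$spacing, points)
}

# coerce a point or matrix of points to an n x 3 numeric matrix
rbind3 <- function(p) {
  if (is.null(dim(p))) p <- matrix(as.numeric(p), ncol = 3, byrow = TRUE)
  storage.mode(p) <- "double"
  if (ncol(p) != 3) stop("points must have 3 columns")
  p
}

#' Define a grid geometry without values
#'
#' Convenience constructor for grid specifications handed to rasterizers,
#' contour generators and dose engines.
#'
#' @param origin,spacing,dims as in [voxel_volume()].
#' @return a zero-filled density `voxel_volume` usable as a geometry.
#' @export
grid_spec <- function(origin, spacing, dims) {
  voxel_volume(array(0, dim = as.integer(dims)), origin, spacing,
               unit = "density")
}
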