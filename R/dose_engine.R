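#' Beam data table: effective attenuation and depth-dose parameters
#'
#' A compact stand-in for a commissioned photon beam model: one effective mass
#' attenuation coefficient per nominal energy, an analytic percent-depth-dose
#' parameterization, and a depth-dependent lateral scatter kernel width.
#' `mu_rho` must be positive and strictly decreasing across 6, 10, 15 MV.
#'
#' PDD form: `(1 - exp(-a d)) * exp(-b (d - dmax))`, normalized to 1 at
#' `dmax`; `a` (1/mm) controls build-up, `b` (1/mm) the exponential fall-off.
#' Scatter width: `sigma(d) = sigma0 + k d` (mm).
#'
#' @param overrides named list of per-energy parameter overrides, e.g.
#'   `list("6" = list(b = 0.0052))`.
#' @return object of class `beam_data`.
#' @export
beam_data_table <- function(overrides = NULL) {
  tab <- list(
    "6"  = list(mu_rho = 0.0493, a = 0.25, b = 0.0050, dmax = 15,
                sigma0 = 3, sigma_k = 0.05, output = 1),
    "10" = list(mu_rho = 0.0382, a = 0.15, b = 0.0042, dmax = 25,
                sigma0 = 3, sigma_k = 0.05, output = 1),
    "15" = list(mu_rho = 0.0327, a = 0.12, b = 0.0035, dmax = 30,
                sigma0 = 3, sigma_k = 0.05, output = 1))
  if (!is.null(overrides))
    for (e in names(overrides)) tab[[e]] <- modifyList(tab[[e]], overrides[[e]])
  mu <- vapply(tab, function(p) p$mu_rho, 0)
  if (any(mu <= 0) || is.unsorted(rev(mu), strictly = TRUE))
    stop("mu_rho must be positive and decreasing with energy")
  structure(tab, class = "beam_data")
}

beam_params <- function(data, energy) {
  p <- data[[as.character(energy)]]
  if (is.null(p)) stop(sprintf("unknown energy %s MV (supported: %s)",
                               energy, paste(names(data), collapse = ", ")))
  p
}

# field-size-adjusted fall-off slope (1/mm); mild, anchored at 10x10
b_eff <- function(p, field_size) {
  fs <- sqrt(prod(field_size))
  p$b * (100 / fs)^0.05
}

#' Percent depth dose in water
#'
#' @param energy nominal MV (6, 10 or 15 with the default [beam_data_table()]).
#' @param depth_mm depth(s) below the surface, mm, >= 0.
#' @param field_size field size (x, y) mm at isocenter; scalar is squared.
#' @param data a [beam_data_table()].
#' @return relative dose, 1 at `dmax`.
#' @export
pdd <- function(energy, depth_mm, field_size = c(100, 100),
                data = beam_data_table()) {
  if (any(depth_mm < 0)) stop("depth must be >= 0")
  if (length(field_size) == 1) field_size <- rep(field_size, 2)
  p <- beam_params(data, energy)
  b <- b_eff(p, field_size)
  f <- function(d) (1 - exp(-p$a * d)) * exp(-b * (d - p$dmax))
  f(depth_mm) / f(p$dmax)
}

#' Specify a beam
#'
#' @param energy nominal MV.
#' @param gantry_angle degrees; 0 = beam entering from anterior (-y side),
#'   90 = from the patient's left (+x side), rotating about z.
#' @param field_size (x, y) mm at SAD; scalar is squared.
#' @param ssd_mm source-to-surface distance setup (mm); the source is placed
#'   on the central axis so the surface (first non-air voxel) is at this
#'   distance. Mutually exclusive with `sad_mm`.
#' @param sad_mm source-to-axis distance setup (mm), with `isocenter_mm`.
#' @param isocenter_mm isocenter, world mm; defaults to the volume's
#'   `meta$isocenter_mm` at compute time.
#' @param wedge optional `list(angle = <deg>, orientation = "x+"|"x-")`.
#' @param weight relative beam weight, >= 0.
#' @param fluence optional `list(values = <matrix>, spacing = <mm>,`
#'   `origin = <mm, length 2>)` sampled bilinearly in the isocenter plane
#'   (field coordinates); replaces the open-field aperture.
#' @return object of class `beam_spec`.
#' @export
beam_spec <- function(energy = 6, gantry_angle = 0, field_size = c(100, 100),
                      ssd_mm = NULL, sad_mm = 1000, isocenter_mm = NULL,
                      wedge = NULL, weight = 1, fluence = NULL) {
  if (length(field_size) == 1) field_size <- rep(field_size, 2)
  if (any(field_size <= 0)) stop("field size must be positive")
  if (weight < 0) stop("weight must be >= 0")
  if (!is.null(wedge) && is.null(wedge$orientation)) wedge$orientation <- "x+"
  structure(list(energy = energy, gantry_angle = gantry_angle,
                 field_size = field_size, ssd_mm = ssd_mm, sad_mm = sad_mm,
                 isocenter_mm = isocenter_mm, wedge = wedge, weight = weight,
                 fluence = fluence),
            class = "beam_spec")
}

#' Specify a plan
#'
#' @param beams list of [beam_spec()]s.
#' @param prescription_gy total prescription, Gy, > 0.
#' @param fractions number of fractions, >= 1.
#' @param normalization_point world mm; default: the isocenter. The summed
#'   dose grid is scaled so this point receives the prescription.
#' @return object of class `plan_spec`.
#' @export
plan_spec <- function(beams, prescription_gy = 1, fractions = 1L,
                      normalization_point = NULL) {
  if (!length(beams)) stop("plan needs at least one beam")
  if (prescription_gy <= 0) stop("prescription must be positive")
  if (fractions < 1) stop("fractions must be >= 1")
  structure(list(beams = beams, prescription_gy = prescription_gy,
                 fractions = as.integer(fractions),
                 normalization_point = normalization_point),
            class = "plan_spec")
}

#' Expand an arc into a list of discrete beams
#'
#' @param start_deg,stop_deg,step_deg arc span and discretization, degrees;
#'   `step_deg > 0`, span non-degenerate.
#' @param template a [beam_spec()] cloned at each control angle.
#' @return list of `beam_spec`s at start, start+step, ..., stop (inclusive),
#'   equal weights summing to the template's weight.
#' @export
arc_to_beams <- function(start_deg, stop_deg, step_deg = 10, template = beam_spec()) {
  if (step_deg <= 0) stop("step must be positive")
  if (stop_deg == start_deg) stop("degenerate arc span")
  angles <- seq(start_deg, stop_deg, by = if (stop_deg > start_deg) step_deg else -step_deg)
  lapply(angles, function(a) {
    b <- template; b$gantry_angle <- a
    b$weight <- template$weight / length(angles)
    b
  })
}

#' Wedge transmission factor
#'
#' Transmission gradient across the wedged direction: unity at the field
#' centre and on the thin side, log-linear (exponential) on the thick side so
#' the factor stays in (0, 1] and the isodose tilt is uniform across the
#' field. The gradient is set so that the nominal wedge angle equals the tilt
#' of the 10 cm-depth isodose line in water, accounting for the exponential
#' depth fall-off plus the inverse-square slope at the nominal SAD 100 cm
#' geometry.
#'
#' @param wedge `NULL` (no wedge, factor 1) or `list(angle, orientation)`.
#' @param off_axis_mm position across the wedged direction in the isocenter
#'   plane, mm.
#' @param field_size field size mm (for the fall-off slope's field factor).
#' @param energy,data beam model used for the fall-off slope.
#' @return transmission factor(s) in (0, 1].
#' @export
wedge_factor <- function(wedge, off_axis_mm, field_size = c(100, 100),
                         energy = 6, data = beam_data_table()) {
  if (is.null(wedge)) return(rep(1, length(off_axis_mm)))
  p <- beam_params(data, energy)
  slope_depth <- b_eff(p, field_size) + 2 / 1000  # ln-dose per mm at ~10 cm, SAD 1000
  s <- slope_depth * tan(wedge$angle * pi / 180)
  dir <- if (identical(wedge$orientation, "x-")) -1 else 1
  off <- dir * off_axis_mm
  pmax(1e-6, ifelse(off > 0, exp(-s * off), 1))
}

# source position for a beam on a volume; u points from isocenter to source
beam_geometry <- function(volume, beam) {
  iso <- beam$isocenter_mm
  if (is.null(iso)) iso <- volume$meta$isocenter_mm
  if (is.null(iso)) {
    d <- volume$meta$isocenter_depth_mm
    iso <- if (!is.null(d)) c(0, d, 0) else volume$origin + (volume$dims - 1) / 2 * volume$spacing
  }
  g <- beam$gantry_angle * pi / 180
  u <- c(sin(g), -cos(g), 0)
  sad <- if (is.null(beam$sad_mm)) 1000 else beam$sad_mm
  if (!is.null(beam$ssd_mm)) {
    # march outward from iso to the surface (last non-air sample), then back off
    tmax <- sum(volume$dims * volume$spacing)
    ts <- seq(0, tmax, by = 0.25)
    pts <- cbind(iso[1] + ts * u[1], iso[2] + ts * u[2], iso[3] + ts * u[3])
    dens <- sample_volume(volume, pts)
    solid <- which(!is.na(dens) & dens >= 0.05)
    if (!length(solid)) stop("central axis never intersects the volume")
    surf <- pts[max(solid), ] + 0.125 * u
    source <- surf + beam$ssd_mm * u
    sad <- sqrt(sum((source - iso)^2))
  } else {
    source <- iso + sad * u
  }
  list(iso = iso, source = source, u = u, sad = sad, beam_dir = -u)
}

#' Compute dose for a single beam
#'
#' Per voxel: `fluence x wedge x inverse-square x PDD(depth) x
#' exp(-mu/rho * max(0, excess areal density))`, where depth is the physical
#' path from the beam's entry into tissue and the excess areal density is the
#' Siddon radiological path minus the same path in unit-density water -
#' heterogeneity enters only through that excess. With `scatter = TRUE` the
#' primary grid is then laterally convolved (in planes perpendicular to the
#' dominant beam axis) with a unit-mass Gaussian of width
#' `sigma(d) = sigma0 + k d`, which smears shadow edges but preserves broad
#' flat fields.
#'
#' @param volume density [voxel_volume()].
#' @param beam a [beam_spec()].
#' @param data a [beam_data_table()].
#' @param grid optional [grid_spec()] for the dose grid; defaults to the
#'   volume geometry.
#' @param scatter apply the lateral scatter kernel (`FALSE` = primary only).
#' @return dose [voxel_volume()] (unit `"Gy"`, machine-unit scale; absolute
#'   calibration happens at plan normalization).
#' @export
compute_beam_dose <- function(volume, beam, data = beam_data_table(),
                              grid = NULL, scatter = TRUE) {
  if (volume$unit != "density") stop("dose engine needs a density volume")
  if (is.null(grid)) grid <- volume
  geo <- beam_geometry(volume, beam)
  p <- beam_params(data, beam$energy)
  targets <- vol_centers(grid)
  rd <- cpp_rad_depth(as.numeric(volume$values), volume$dims, volume$origin,
                      volume$spacing, geo$source, targets, 0.05)
  raddepth <- rd[, 1]; physdepth <- rd[, 2]
  hit <- physdepth >= 0
  if (!any(hit)) warning("beam rays never intersect the volume; dose is zero")

  v <- sweep(targets, 2, geo$source)
  dist <- sqrt(rowSums(v^2))
  along <- as.numeric(v %*% geo$beam_dir)
  proj <- geo$sad / pmax(along, 1e-6)
  e1 <- c(cos(beam$gantry_angle * pi / 180), sin(beam$gantry_angle * pi / 180), 0)
  e2 <- c(0, 0, 1)
  fx <- as.numeric(v %*% e1) * proj
  fy <- as.numeric(v %*% e2) * proj
  if (is.null(beam$fluence)) {
    fl <- as.numeric(abs(fx) <= beam$field_size[1] / 2 &
                     abs(fy) <= beam$field_size[2] / 2)
  } else {
    fg <- beam$fluence
    fl <- bilinear_lookup(fg$values, fg$origin, fg$spacing, fx, fy)
  }
  wf <- wedge_factor(beam$wedge, fx, beam$field_size, beam$energy, data)
  invsq <- (1000 / dist)^2
  depth <- pmax(0, physdepth)
  pddv <- pdd(beam$energy, depth, beam$field_size, data)
  excess <- pmax(0, raddepth - depth / 10)
  dosev <- p$output * fl * wf * invsq * pddv * exp(-p$mu_rho * excess)
  dosev[!hit] <- 0
  dose <- array(dosev, dim = grid$dims)
  if (scatter) {
    darr <- array(depth, dim = grid$dims)
    dose <- lateral_blur(dose, darr, grid$spacing, geo$beam_dir, p)
  }
  voxel_volume(dose, grid$origin, grid$spacing, unit = "Gy",
               frame = volume$frame,
               meta = list(beam = beam, source = geo$source, sad = geo$sad,
                           isocenter_mm = geo$iso))
}

bilinear_lookup <- function(values, origin, spacing, x, y) {
  if (length(spacing) == 1) spacing <- rep(spacing, 2)
  fi <- (x - origin[1]) / spacing[1]; fj <- (y - origin[2]) / spacing[2]
  n1 <- nrow(values); n2 <- ncol(values)
  out <- numeric(length(x))
  ok <- fi >= 0 & fi <= n1 - 1 & fj >= 0 & fj <= n2 - 1
  i0 <- pmin(pmax(floor(fi[ok]), 0), n1 - 2); j0 <- pmin(pmax(floor(fj[ok]), 0), n2 - 2)
  if (n1 < 2 || n2 < 2) stop("fluence grid must be at least 2 x 2")
  wx <- fi[ok] - i0; wy <- fj[ok] - j0
  idx <- function(i, j) values[cbind(i + 1, j + 1)]
  out[ok] <- idx(i0, j0) * (1 - wx) * (1 - wy) + idx(i0 + 1, j0) * wx * (1 - wy) +
    idx(i0, j0 + 1) * (1 - wx) * wy + idx(i0 + 1, j0 + 1) * wx * wy
  out
}

# in-plane Gaussian blur perpendicular to the dominant beam axis;
# kernel rows renormalized so flat fields are preserved at grid edges
lateral_blur <- function(dose, depth, spacing, beam_dir, p) {
  k <- which.max(abs(beam_dir))
  inplane <- setdiff(1:3, k)
  dims <- dim(dose)
  kmat <- function(n, sp, sigma) {
    if (sigma < sp / 4) return(NULL)
    x <- (seq_len(n) - 1) * sp
    K <- exp(-outer(x, x, "-")^2 / (2 * sigma^2))
    K / rowSums(K)
  }
  perm <- c(inplane, k)
  dp <- aperm(dose, perm); dd <- aperm(depth, perm)
  for (s in seq_len(dims[k])) {
    pl <- dp[, , s]
    w <- pl > 0
    dmean <- if (any(w)) mean(dd[, , s][w]) else mean(dd[, , s])
    sigma <- p$sigma0 + p$sigma_k * dmean
    K1 <- kmat(dims[inplane[1]], spacing[inplane[1]], sigma)
    K2 <- kmat(dims[inplane[2]], spacing[inplane[2]], sigma)
    if (!is.null(K1)) pl <- K1 %*% pl
    if (!is.null(K2)) pl <- pl %*% t(K2)
    dp[, , s] <- pl
  }
  aperm(dp, order(perm))
}

#' Compute dose for a plan
#'
#' Weighted sum of per-beam doses, scaled so the normalization point (default:
#' isocenter) receives the prescription dose.
#'
#' @param volume density [voxel_volume()].
#' @param plan a [plan_spec()].
#' @param data a [beam_data_table()].
#' @param grid,scatter passed to [compute_beam_dose()].
#' @return dose [voxel_volume()] in Gy.
#' @export
compute_plan_dose <- function(volume, plan, data = beam_data_table(),
                              grid = NULL, scatter = TRUE) {
  w <- vapply(plan$beams, function(b) b$weight, 0)
  if (sum(w) <= 0) stop("total beam weight is zero")
  total <- NULL
  for (i in seq_along(plan$beams)) {
    if (w[i] == 0) next
    d <- compute_beam_dose(volume, plan$beams[[i]], data, grid, scatter)
    total <- if (is.null(total)) { d$values <- d$values * w[i]; d }
             else { total$values <- total$values + w[i] * d$values; total }
  }
  np <- plan$normalization_point
  if (is.null(np)) np <- beam_geometry(volume, plan$beams[[1]])$iso
  nd <- point_dose(total, np)
  if (!is.finite(nd) || nd <= 0) stop("zero dose at the normalization point")
  total$values <- total$values * plan$prescription_gy / nd
  total$meta <- list(plan = plan, normalization_point = np)
  total
}

#' Dose at a point
#'
#' Trilinear interpolation of a dose grid.
#'
#' @param dose dose [voxel_volume()].
#' @param point world mm (length 3) or n x 3 matrix.
#' @return dose in Gy; error if any point is outside the grid.
#' @export
point_dose <- function(dose, point) {
  v <- sample_volume(dose, point)
  if (any(is.na(v))) stop("point outside the dose grid")
  v
}
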