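#' Percent difference with half-away-from-zero rounding
#'
#' `(calculated - reference) / reference * 100`, rounded half away from zero
#' (the convention under which the published comparison tables reproduce:
#' -8.544 prints as -8.5 and -9.760 as -9.76, which banker's rounding would
#' not always give).
#'
#' @param calculated,reference doses; `reference` must be positive.
#' @param decimals digits kept after the decimal point.
#' @return rounded percent difference(s).
#' @export
percent_difference <- function(calculated, reference, decimals = 1) {
  if (any(reference <= 0)) stop("reference dose must be positive")
  round_half_away((calculated - reference) / reference * 100, decimals)
}

round_half_away <- function(x, d = 0) {
  s <- 10^d
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Build a measured-vs-calculated comparison table
#'
#' Joins per-model calculated point doses against reference measurements and
#' computes percent differences per model, plus a summary of the maximum
#' absolute difference per model.
#'
#' @param points a [measurement_points()] set carrying the reference doses.
#' @param model_doses named list of numeric vectors (one per model), each
#'   named by point label or aligned with `points` order.
#' @param decimals rounding for the differences.
#' @return object of class `comparison_table`: `table` (data.frame) and
#'   `max_abs_diff` (named vector per model).
#' @export
comparison_table <- function(points, model_doses, decimals = 1) {
  pts <- points$points
  tab <- data.frame(label = pts$label, reference = pts$dose)
  if (any(is.na(tab$reference))) stop("reference doses missing")
  for (m in names(model_doses)) {
    d <- model_doses[[m]]
    if (!is.null(names(d))) {
      missing_lab <- setdiff(tab$label, names(d))
      if (length(missing_lab))
        stop(sprintf("model %s is missing labels: %s", m,
                     paste(missing_lab, collapse = ", ")))
      d <- d[tab$label]
    } else if (length(d) != nrow(tab)) {
      stop(sprintf("model %s has %d doses for %d points", m, length(d), nrow(tab)))
    }
    tab[[paste0(m, "_dose")]] <- as.numeric(d)
    tab[[paste0(m, "_diff_pct")]] <- percent_difference(as.numeric(d), tab$reference,
                                                        decimals)
  }
  mx <- vapply(names(model_doses),
               function(m) max(abs(tab[[paste0(m, "_diff_pct")]])), 0)
  structure(list(table = tab, max_abs_diff = mx, decimals = decimals),
            class = "comparison_table")
}

#' @export
print.comparison_table <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat("max |difference| per model (%):\n")
  print(x$max_abs_diff)
  invisible(x)
}

#' Cumulative dose-volume histogram
#'
#' @param dose dose [voxel_volume()].
#' @param mask logical array matching the dose grid; must be non-empty.
#' @param bin_width_gy histogram bin width, Gy.
#' @return data.frame with `dose_gy` (bin edges from 0) and `volume_pct`
#'   (percent of the masked volume receiving at least that dose); starts at
#'   100 and is non-increasing.
#' @export
dvh <- function(dose, mask, bin_width_gy = 0.01) {
  if (!identical(dim(mask), dim(dose$values))) stop("mask geometry mismatch")
  d <- dose$values[mask]
  if (!length(d)) stop("empty mask")
  edges <- seq(0, max(d) + bin_width_gy, by = bin_width_gy)
  vol <- vapply(edges, function(e) mean(d >= e) * 100, 0)
  data.frame(dose_gy = edges, volume_pct = vol)
}

#' @rdname dvh
#' @param x a DVH data.frame from `dvh()` (or a named list of them).
#' @param ... passed to [graphics::plot()].
#' @export
plot_dvh <- function(x, ...) {
  if (is.data.frame(x)) x <- list(DVH = x)
  plot(NA, xlim = range(unlist(lapply(x, `[[`, "dose_gy"))), ylim = c(0, 100),
       xlab = "Dose (Gy)", ylab = "Volume (%)", ...)
  for (i in seq_along(x)) lines(x[[i]]$dose_gy, x[[i]]$volume_pct, col = i, lwd = 2)
  legend("bottomleft", names(x), col = seq_along(x), lwd = 2, bty = "n")
  invisible(x)
}

#' Reduced planning target volume
#'
#' Narrows the PTV to the axial slices that contain the metallic port and
#' removes the tissue expander and the port themselves, leaving only patient
#' tissue near the port.
#'
#' @param ptv_mask,expander_mask,port_mask logical arrays on one geometry.
#' @return logical array: `PTV & (slice contains port) & !(expander | port)`.
#' @export
reduced_ptv <- function(ptv_mask, expander_mask, port_mask) {
  if (!identical(dim(ptv_mask), dim(expander_mask)) ||
      !identical(dim(ptv_mask), dim(port_mask)))
    stop("masks must share one grid geometry")
  slice_has_port <- apply(port_mask, 3, any)
  out <- ptv_mask & !(expander_mask | port_mask)
  out[, , !slice_has_port] <- FALSE
  out
}

#' Full width at half maximum of a 1D profile
#'
#' The baseline is the median of the outer 20% of samples (10% each end);
#' the extremum is whichever of the profile minimum or maximum departs
#' farther from the baseline (transmission troughs and dose peaks both
#' work). Half-maximum crossings are located by linear interpolation on each
#' side of the extremum.
#'
#' @param values numeric profile.
#' @param spacing_mm sample spacing, mm.
#' @return width in mm.
#' @export
fwhm <- function(values, spacing_mm) {
  n <- length(values)
  if (n < 5) stop("profile too short")
  k <- max(2L, round(0.1 * n))
  baseline <- median(c(head(values, k), tail(values, k)))
  lo <- min(values); hi <- max(values)
  if (hi - lo < 1e-12 * max(1, abs(baseline))) stop("flat profile: no FWHM")
  extremum <- if (baseline - lo >= hi - baseline) lo else hi
  i0 <- if (extremum == lo) which.min(values) else which.max(values)
  half <- (baseline + extremum) / 2
  crossed <- if (extremum == lo) function(v) v >= half else function(v) v <= half
  left <- NA_real_
  for (i in seq(i0, 2, by = -1)) {
    if (crossed(values[i - 1]) && !crossed(values[i])) {
      f <- (half - values[i]) / (values[i - 1] - values[i])
      left <- (i - 1) - f  # 1-based sample position of the crossing
      break
    }
  }
  right <- NA_real_
  for (i in seq(i0, n - 1)) {
    if (crossed(values[i + 1]) && !crossed(values[i])) {
      f <- (half - values[i]) / (values[i + 1] - values[i])
      right <- i + f
      break
    }
  }
  if (is.na(left) || is.na(right)) stop("profile does not cross half maximum on both sides")
  (right - left) * spacing_mm
}

#' Synthetic transmission projection of the port
#'
#' Parallel-ray projection image of the port: per pixel, the chord length
#' through the disk converts to a transmission `exp(-mu/rho rho chord)`. The
#' perpendicular setup projects along the disk axis (the image of the disk is
#' a circle of the port diameter); the parallel setup projects along an
#' in-plane direction (the image is a strip of the port thickness).
#'
#' @param port a [make_port()] model.
#' @param setup `"perpendicular"` or `"parallel"`.
#' @param pixel_mm detector pixel spacing.
#' @param extent_mm half-extent of the square detector.
#' @param mu_rho effective attenuation coefficient, cm^2/g.
#' @return object of class `projection_image`: `values` (matrix, transmission),
#'   `spacing_mm`, `setup`, axis labels.
#' @export
port_projection <- function(port, setup = c("perpendicular", "parallel"),
                            pixel_mm = 0.2, extent_mm = 25, mu_rho = 0.0493) {
  setup <- match.arg(setup)
  u <- port$axis
  # in-plane orthonormal basis of the disk
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * u) * u; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  if (setup == "perpendicular") {
    dir <- u; a1 <- e1; a2 <- e2          # image axes span the disk plane
    labels <- c("diameter", "diameter")
  } else {
    dir <- e2; a1 <- u; a2 <- e1          # rows run along the disk axis
    labels <- c("thickness", "diameter")
  }
  g <- seq(-extent_mm, extent_mm, by = pixel_mm)
  origins <- outer(rep(g, times = length(g)), a1) +
    outer(rep(g, each = length(g)), a2) - outer(rep(50, length(g)^2), dir)
  origins <- sweep(origins, 2, port$center, "+")
  ch <- chord_length(port, origins, matrix(dir, 1))
  tr <- exp(-mu_rho * port$density * ch / 10)
  structure(list(values = matrix(tr, length(g), length(g)),
                 spacing_mm = pixel_mm, setup = setup, axis_labels = labels),
            class = "projection_image")
}

#' Dimension the port from a projection image
#'
#' Extracts the central profile of a [port_projection()]-style image and
#' returns its FWHM: the diameter estimate for the perpendicular setup, the
#' thickness estimate for the parallel setup.
#'
#' @param image a `projection_image` (or `list(values, spacing_mm, setup)`).
#' @param setup overrides `image$setup` when given.
#' @return named extent in mm (`diameter` or `thickness`).
#' @export
port_dims_from_projection <- function(image, setup = NULL) {
  if (is.null(setup)) setup <- image$setup
  setup <- match.arg(setup, c("perpendicular", "parallel"))
  v <- image$values
  mid <- ceiling(ncol(v) / 2)
  profile <- v[, mid]  # rows: diameter axis (perpendicular) / thickness axis (parallel)
  w <- fwhm(profile, image$spacing_mm)
  setNames(w, if (setup == "perpendicular") "diameter" else "thickness")
}

#' TLD calibration: linear least-squares fit and dose lookup
#'
#' Ordinary least-squares line `dose = intercept + slope * reading` over the
#' calibration irradiations; `tld_dose()` applies the fitted line to new
#' readings.
#'
#' @param readings TLD reader outputs at the calibration points.
#' @param delivered_doses known delivered doses (>= 2 distinct levels).
#' @return list with `slope`, `intercept`, `residuals`, `fit` (the `lm`).
#' @export
tld_calibration_fit <- function(readings, delivered_doses) {
  if (length(readings) != length(delivered_doses)) stop("length mismatch")
  if (length(unique(delivered_doses)) < 2) stop("need >= 2 distinct dose levels")
  fit <- lm(delivered_doses ~ readings)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       residuals = unname(fit$residuals), fit = fit)
}

#' @rdname tld_calibration_fit
#' @param reading new reading(s).
#' @param fit result of `tld_calibration_fit()`.
#' @export
tld_dose <- function(reading, fit) fit$intercept + fit$slope * reading

#' TLD packet inventory for the phantom validation experiment
#'
#' Enumerates the thermoluminescent dosimeter packets the anthropomorphic
#' phantom validation needs: 4 measurement points x 3 plans (open, VMAT,
#' 4-field IMRT) x 2 expander states, plus 1 background packet and 3
#' calibration packets - 28 in total.
#'
#' @return data.frame with columns `role`, `state`, `plan`, `point`.
#' @export
tld_experiment_design <- function() {
  meas <- expand.grid(point = paste0("point", 1:4),
                      plan = c("open", "vmat", "imrt4"),
                      state = c("inflated", "deflated"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meas <- data.frame(role = "measurement", meas[, c("state", "plan", "point")])
  extra <- data.frame(role = c("background", rep("calibration", 3)),
                      state = NA, plan = NA,
                      point = c("background", paste0("cal", 1:3)))
  rbind(meas, extra)
}

# ---- published-table fixtures ----------------------------------------------

#' Load the published comparison-table fixtures
#'
#' Dose columns of the two point-dose comparison tables shipped with the
#' package: the anthropomorphic-phantom TLD table (24 rows, reference = TLD
#' dose, 1 printed decimal) and the patient point-dose table (12 rows,
#' reference = the port-free "no disk" calculation, 2 printed decimals).
#'
#' @param which `"phantom"` or `"patient"`.
#' @return data.frame of labels, reference doses, per-model doses and the
#'   printed percent differences.
#' @export
load_published_table <- function(which = c("phantom", "patient")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   if (which == "phantom") "table_phantom_tld.csv"
                   else "table_patient_points.csv",
                   package = "xpanderdose", mustWork = TRUE)
  read.csv(f, stringsAsFactors = FALSE)
}

#' Recompute the published percent differences
#'
#' Recomputes every model-vs-reference percent difference from the printed
#' dose columns and compares with the printed differences. The patient table
#' reproduces exactly; in the phantom table the printed dose columns are
#' themselves rounded to 0.1 cGy, so a minority of recomputed differences land
#' one unit of the last printed digit away from the printed value.
#'
#' @param which `"phantom"`, `"patient"` or `"both"`.
#' @return data.frame with one row per (row, model): recomputed and printed
#'   differences, their deviation, and the table's printed precision.
#' @export
reproduce_published_tables <- function(which = c("both", "phantom", "patient")) {
  which <- match.arg(which)
  out <- NULL
  spec <- list(phantom = list(decimals = 1, ref = "reference_dose"),
               patient = list(decimals = 2, ref = "reference_dose"))
  for (tb in intersect(c("phantom", "patient"),
                       if (which == "both") c("phantom", "patient") else which)) {
    df <- load_published_table(tb)
    dec <- spec[[tb]]$decimals
    for (m in c("clinical1", "clinical2", "new")) {
      rec <- percent_difference(df[[paste0(m, "_dose")]], df$reference_dose, dec)
      out <- rbind(out, data.frame(
        table = tb, label = df$label, model = m,
        recomputed = rec, printed = df[[paste0(m, "_diff_pct")]],
        deviation = rec - df[[paste0(m, "_diff_pct")]],
        ulp = 10^-dec))
    }
  }
  out
}
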