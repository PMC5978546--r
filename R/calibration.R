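#' Define a port-calibration problem
#'
#' Bundles the depth-dose measurements (parallel and perpendicular setups,
#' one record per setup and energy), the fixed setup geometry, the parameter
#' search space and the engine configuration used to predict depth doses.
#'
#' @param measurements a [measurement_depth_doses()] set; every record needs
#'   at least 2 depths.
#' @param search named list of ranges `c(lo, hi, step)` for `density`
#'   (g/cm^3) and optionally `diameter`, `thickness` (mm).
#' @param fixed list of fixed parameter values used when a parameter is not
#'   searched (`diameter`, `thickness` in mm).
#' @param geometry list: `port_top_depth_mm` (upstream port face below the
#'   water surface) and `ssd_mm`.
#' @param config engine configuration: `data` (a [beam_data_table()]) and
#'   `scatter` (logical; the shadow-smearing term, see
#'   [ic_depth_dose()]).
#' @return object of class `calibration_problem`.
#' @export
calibration_problem <- function(measurements,
                                search = list(density = c(4, 10, 0.5)),
                                fixed = list(diameter = 17.5, thickness = 5),
                                geometry = list(port_top_depth_mm = 50, ssd_mm = 850),
                                config = list(data = beam_data_table(), scatter = TRUE)) {
  if (!inherits(measurements, "measurement_set") || measurements$type != "depth_dose")
    stop("measurements must be a depth-dose measurement_set")
  if (!length(measurements$records)) stop("measurements are empty")
  for (r in measurements$records) {
    if (nrow(r$data) < 2)
      stop("degenerate record: every depth-dose record needs at least 2 depths")
    if (any(r$data$dose <= 0)) stop("measured doses must be positive")
  }
  for (nm in names(search)) {
    rg <- search[[nm]]
    if (length(rg) != 3 || rg[3] <= 0 || rg[2] < rg[1])
      stop(sprintf("search range for %s must be c(lo, hi, step) with step > 0", nm))
    if (length(seq(rg[1], rg[2], by = rg[3])) < 2)
      stop(sprintf("search space too coarse for %s: need >= 2 points", nm))
  }
  structure(list(measurements = measurements, search = search, fixed = fixed,
                 geometry = geometry, config = config),
            class = "calibration_problem")
}

#' Analytic ion-chamber depth dose under the port
#'
#' Closed-form central-axis dose for the water-tank setup: the open-water
#' term (PDD times inverse square at SSD 85 cm) multiplied by an observed
#' transmission factor. With `scatter = TRUE` the transmission accounts for
#' lateral scatter smearing of the port shadow: the dose deficit at depth is
#' the chord attenuation weighted by the fraction of a 2D Gaussian of width
#' `sigma(d)` covered by the shadow (a disk of the port diameter for the
#' perpendicular setup; a strip of the port thickness, with the chord varying
#' across the diameter, for the parallel setup). With `scatter = FALSE` the
#' transmission is the bare central-ray chord attenuation
#' `exp(-mu/rho (rho - 1) chord)`.
#'
#' Parameters are vectorized over candidates: `density`, `diameter` and
#' `thickness` may be equal-length vectors, giving a candidates x depths
#' matrix.
#'
#' @param density,diameter,thickness port parameters (g/cm^3, mm, mm);
#'   `density` >= 0 (0 = no port).
#' @param setup `"perpendicular"` (beam along the disk axis) or `"parallel"`
#'   (beam in the disk plane).
#' @param energy nominal MV.
#' @param depth_mm ion-chamber depths below the water surface, mm.
#' @param geometry,config as in [calibration_problem()].
#' @return matrix `length(density)` x `length(depth_mm)` of doses (machine
#'   units), or a vector when a single candidate is given.
#' @export
ic_depth_dose <- function(density, diameter, thickness,
                          setup = c("perpendicular", "parallel"),
                          energy = 6, depth_mm = seq(70, 150, by = 10),
                          geometry = list(port_top_depth_mm = 50, ssd_mm = 850),
                          config = list(data = beam_data_table(), scatter = TRUE)) {
  setup <- match.arg(setup)
  n <- max(length(density), length(diameter), length(thickness))
  density <- rep_len(density, n); diameter <- rep_len(diameter, n)
  thickness <- rep_len(thickness, n)
  data <- config$data; scatter <- isTRUE(config$scatter)
  p <- beam_params(data, energy)
  top <- geometry$port_top_depth_mm; ssd <- geometry$ssd_mm
  open_d <- pdd(energy, depth_mm, c(100, 100), data) * (1000 / (ssd + depth_mm))^2
  katt <- p$mu_rho * pmax(0, density - 1)   # 1/cm
  R <- diameter / 2
  if (setup == "perpendicular") {
    Tchord <- exp(-katt * thickness / 10)
    if (!scatter) {
      Tobs <- matrix(Tchord, n, length(depth_mm))
    } else {
      s <- pmax(1, outer(rep(1, n), depth_mm) - (top + thickness))   # n x d, mm past port
      sigma <- p$sigma0 + p$sigma_k * s
      cover <- 1 - exp(-(R^2) / (2 * sigma^2))
      Tobs <- 1 - cover * (1 - Tchord)
    }
  } else {
    if (!scatter) {
      Tobs <- matrix(exp(-katt * diameter / 10), n, length(depth_mm))
    } else {
      s <- pmax(1, outer(rep(1, n), depth_mm) - (top + diameter))
      sigma <- p$sigma0 + p$sigma_k * s
      m_u <- 2 * stats::pnorm(thickness / 2 / sigma) - 1   # strip coverage
      # chord deficit averaged across the diameter with Gaussian weights
      nn <- 81
      frac <- (seq_len(nn) - 0.5) / nn * 2 - 1             # midpoints in (-1, 1)
      m_v <- matrix(0, n, length(depth_mm))
      for (q in seq_len(nn)) {
        v <- frac[q] * R                                    # per candidate
        chord <- 2 * sqrt(pmax(0, R^2 - v^2)) / 10          # cm
        defic <- 1 - exp(-katt * chord)                     # n
        w <- stats::dnorm(outer(v, rep(1, length(depth_mm))) / sigma) / sigma *
          outer(2 * R / nn, rep(1, length(depth_mm)))
        m_v <- m_v + defic * w
      }
      Tobs <- 1 - m_u * m_v
    }
  }
  out <- Tobs * outer(rep(1, n), open_d)
  if (n == 1) as.numeric(out) else out
}

# objective: RMS of relative calc-vs-measured differences over all records
objective_rms <- function(problem, density, diameter, thickness) {
  n <- max(length(density), length(diameter), length(thickness))
  ss <- matrix(0, n, 1); cnt <- 0
  for (r in problem$measurements$records) {
    calc <- ic_depth_dose(density, diameter, thickness, r$setup, r$energy_mv,
                          r$data$depth_mm, problem$geometry, problem$config)
    calc <- matrix(calc, n, nrow(r$data))
    rel <- sweep(sweep(calc, 2, r$data$dose), 2, r$data$dose, "/")
    ss <- ss + rowSums(rel^2)
    cnt <- cnt + nrow(r$data)
  }
  sqrt(as.numeric(ss) / cnt)
}

#' Calibration objective for one candidate port
#'
#' Root-mean-square of relative differences `(calc - meas) / meas` over all
#' depths, setups and energies, equally weighted.
#'
#' @param problem a [calibration_problem()].
#' @param candidate a [make_port()] model (density/diameter/thickness used).
#' @return scalar RMS relative difference.
#' @export
discrepancy <- function(problem, candidate) {
  if (any(vapply(problem$measurements$records,
                 function(r) any(r$data$dose == 0), TRUE)))
    stop("zero measured dose")
  objective_rms(problem, candidate$density, candidate$diameter, candidate$thickness)
}

# Coarse-to-fine grid search over a named parameter box. The objective can be
# nearly flat along density/dimension trade-off ridges, so each refinement
# zooms (step x 0.1, window +/- one previous step) around the several best
# candidates of the previous stage rather than a single argmin; the windows
# tile the ridge and the stage-wide best is kept. Candidates are sorted by
# ascending density so objective ties break toward the smaller density.
grid_search <- function(problem, search, fixed, refinements = 2, n_seeds = 10) {
  nms <- names(search)
  evaluate <- function(cand, stage) {
    dens <- if ("density" %in% nms) cand$density else fixed$density
    diam <- if ("diameter" %in% nms) cand$diameter else fixed$diameter
    thick <- if ("thickness" %in% nms) cand$thickness else fixed$thickness
    cand$objective <- objective_rms(problem, dens, diam, thick)
    cand$stage <- stage
    cand
  }
  grids <- lapply(search, function(rg) seq(rg[1], rg[2], by = rg[3]))
  cand <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  names(cand) <- nms
  cand <- cand[do.call(order, cand[nms]), , drop = FALSE]
  cand <- evaluate(cand, 0)
  curve <- cand
  steps <- vapply(search, `[`, 0, 3)
  for (stage in seq_len(refinements)) {
    seeds <- cand[order(cand$objective), , drop = FALSE]
    seeds <- utils::head(seeds, if (stage == 1) n_seeds else 3)
    pieces <- lapply(seq_len(nrow(seeds)), function(i) {
      g <- lapply(nms, function(nm) {
        lo <- max(search[[nm]][1], seeds[[nm]][i] - steps[[nm]])
        hi <- min(search[[nm]][2], seeds[[nm]][i] + steps[[nm]])
        seq(lo, hi, by = steps[[nm]] / 10)
      })
      p <- expand.grid(g, KEEP.OUT.ATTRS = FALSE)
      names(p) <- nms
      p
    })
    cand <- unique(do.call(rbind, pieces))
    cand <- cand[do.call(order, cand[nms]), , drop = FALSE]
    cand <- evaluate(cand, stage)
    curve <- rbind(curve, cand)
    steps <- steps / 10
  }
  i <- which.min(cand$objective)
  best <- cand[i, , drop = FALSE]
  # the refined argmin can still sit a few grid steps away along a flat
  # ridge; a bounded local polish of the smooth objective pins the optimum
  resid_fn <- function(par) {
    p <- as.list(par); names(p) <- nms
    dens <- if ("density" %in% nms) p$density else fixed$density
    diam <- if ("diameter" %in% nms) p$diameter else fixed$diameter
    thick <- if ("thickness" %in% nms) p$thickness else fixed$thickness
    unlist(lapply(problem$measurements$records, function(r) {
      calc <- ic_depth_dose(dens, diam, thick, r$setup, r$energy_mv,
                            r$data$depth_mm, problem$geometry, problem$config)
      (as.numeric(calc) - r$data$dose) / r$data$dose
    }))
  }
  # polish from the top few refined candidates; bounds are relaxed by one
  # coarse step so an optimum adjacent to the search-box boundary does not
  # stall the solver on the active bound, then clamped back into the box
  lo <- vapply(search, `[`, 0, 1); hi <- vapply(search, `[`, 0, 2)
  coarse <- vapply(search, `[`, 0, 3)
  starts <- cand[order(cand$objective), , drop = FALSE]
  starts <- utils::head(starts, 3)
  improved <- FALSE
  for (s in seq_len(nrow(starts))) {
    op <- tryCatch(
      minpack.lm::nls.lm(unlist(starts[s, nms]), resid_fn,
                         lower = lo - coarse, upper = hi + coarse,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(op)) next
    par <- pmin(pmax(op$par, lo), hi)
    val <- sqrt(mean(resid_fn(par)^2))
    if (val < best$objective) {
      best[nms] <- as.list(par)
      best$objective <- val
      improved <- TRUE
    }
  }
  if (improved) {
    best$stage <- max(cand$stage) + 1L
    curve <- rbind(curve, best)
  }
  list(best = best, curve = curve)
}

#' Fit the port density to depth-dose measurements
#'
#' Coarse-to-fine grid search over density only (dimensions fixed at
#' `problem$fixed`): coarse step from the search range, refined twice by a
#' factor 10 around the running optimum. Ties break toward the smaller
#' density.
#'
#' @param problem a [calibration_problem()] with a `density` search range.
#' @return list with `density`, `objective`, and `diagnostics` (the full
#'   objective curve across stages).
#' @export
fit_density <- function(problem) {
  if (!"density" %in% names(problem$search)) stop("no density search range")
  gs <- grid_search(problem, problem$search["density"], problem$fixed)
  list(density = gs$best$density, objective = gs$best$objective,
       diagnostics = list(curve = gs$curve))
}

#' Jointly fit port density, diameter and thickness
#'
#' Grid search over the 2-3 dimensional box with the same coarse-to-fine
#' refinement and tie rules as [fit_density()]. When `check_parallel_only`
#' is set, the diagnostics also report the experiment of adjusting density
#' against the parallel-setup records only - with the film-derived (biased)
#' thickness held fixed - and evaluating the perpendicular records, which
#' reproduces why single-setup fitting fails.
#'
#' @param problem a [calibration_problem()] with >= 2 search dimensions.
#' @param check_parallel_only run the parallel-only consistency experiment.
#' @param film_thickness_mm thickness assumed in that experiment (the film
#'   projection underestimates the radiological thickness).
#' @return list with `port` (a [make_port()]), `objective`, `diagnostics`
#'   (`curve`, and optionally `parallel_only` with perpendicular RMS under
#'   both fits).
#' @export
fit_port_parameters <- function(problem, check_parallel_only = FALSE,
                                film_thickness_mm = 2.5) {
  if (length(problem$search) < 2) stop("joint fit needs a 2-3 dimensional search space")
  gs <- grid_search(problem, problem$search, problem$fixed)
  b <- gs$best
  port <- make_port(diameter = if (!is.null(b$diameter)) b$diameter else problem$fixed$diameter,
                    thickness = if (!is.null(b$thickness)) b$thickness else problem$fixed$thickness,
                    density = b$density)
  diags <- list(curve = gs$curve)
  if (check_parallel_only) {
    recs <- problem$measurements$records
    is_par <- vapply(recs, function(r) r$setup == "parallel", TRUE)
    par_prob <- problem; par_prob$measurements$records <- recs[is_par]
    par_prob$fixed <- list(diameter = port$diameter, thickness = film_thickness_mm)
    fd <- fit_density(par_prob)
    perp_prob <- problem; perp_prob$measurements$records <- recs[!is_par]
    rms_par_only <- objective_rms(perp_prob, fd$density, port$diameter, film_thickness_mm)
    rms_joint <- objective_rms(perp_prob, port$density, port$diameter, port$thickness)
    diags$parallel_only <- list(density = fd$density,
                                perpendicular_rms = rms_par_only,
                                joint_perpendicular_rms = rms_joint)
  }
  list(port = port, objective = b$objective, diagnostics = diags)
}

#' Generate synthetic ion-chamber measurements
#'
#' Depth-dose records for both setups and the requested energies from the
#' analytic engine model ([ic_depth_dose()]), with optional seeded
#' multiplicative Gaussian noise.
#'
#' @param port ground-truth [make_port()].
#' @param energies nominal MVs.
#' @param depth_mm measurement depths below the surface.
#' @param noise_sd relative standard deviation of multiplicative noise.
#' @param seed integer seed (used when `noise_sd > 0`).
#' @param geometry,config as in [calibration_problem()].
#' @return a [measurement_depth_doses()] set.
#' @export
make_ic_measurements <- function(port, energies = c(6, 10, 15),
                                 depth_mm = seq(70, 150, by = 10),
                                 noise_sd = 0, seed = 1,
                                 geometry = list(port_top_depth_mm = 50, ssd_mm = 850),
                                 config = list(data = beam_data_table(), scatter = TRUE)) {
  recs <- list()
  noise <- function(n) if (noise_sd > 0) rnorm(n, 1, noise_sd) else rep(1, n)
  gen <- function() {
    for (setup in c("parallel", "perpendicular")) for (e in energies) {
      d <- ic_depth_dose(port$density, port$diameter, port$thickness,
                         setup, e, depth_mm, geometry, config)
      recs[[length(recs) + 1L]] <<- depth_dose_record(setup, e, depth_mm,
                                                      d * noise(length(d)))
    }
  }
  if (noise_sd > 0) with_seed(seed, gen()) else gen()
  measurement_depth_doses(recs, meta = list(truth = port, noise_sd = noise_sd,
                                            seed = seed))
}
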