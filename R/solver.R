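# Wave propagation: configuration, stability checking, the propagate()
# front-end to the compiled staggered-grid kernel, and a convergence probe.

#' Solver configuration
#'
#' Numerical parameters of the staggered-grid finite-difference solver.
#' The perfectly matched layer (PML) is positioned outside the user grid
#' (the domain is enlarged by `pml_thickness` on every side and the medium
#' edge-replicated into it), so detectors may be placed anywhere in the
#' grid. The PML absorption profile is quartic with the toolbox-style
#' dimensionless coefficient `pml_alpha` (sigma_max = pml_alpha * c_max/dx).
#'
#' @param dt time step, s (default 10 ns).
#' @param n_steps number of steps; `NULL` lets [propagate()] callers size the
#'   run themselves.
#' @param pml_thickness PML thickness in grid points (>= 10).
#' @param pml_absorption dimensionless PML absorption coefficient.
#' @param cfl_limit maximum admissible CFL number c_max * dt / dx.
#' @param precision `"single"` (default) or `"double"` arithmetic.
#' @param source_mode `"pressure"` (incremental waveform drive; the source
#'   voxel's pressure follows amplitude x pulse, default) or
#'   `"pressure_rate"` (mass-rate drive yielding the classic N-shaped far
#'   field).
#' @param absorption_d power-law absorption exponent d.
#' @param absorption_ref_freq frequency (Hz) at which the solver's viscous
#'   loss is matched to the power law alpha0 * omega^d.
#' @return an object of class `solver_config`.
#' @export
solver_config <- function(dt = 10e-9, n_steps = NULL, pml_thickness = 20,
                          pml_absorption = 2.0, cfl_limit = 0.3,
                          precision = c("single", "double"),
                          source_mode = c("pressure", "pressure_rate"),
                          absorption_d = 1.05, absorption_ref_freq = 1.35e5) {
  precision <- match.arg(precision)
  source_mode <- match.arg(source_mode)
  stopifnot(dt > 0, pml_absorption > 0, cfl_limit > 0, cfl_limit < 0.78,
            absorption_d > 0, absorption_ref_freq > 0)
  if (pml_thickness < 10) stop("pml_thickness must be >= 10", call. = FALSE)
  structure(list(dt = dt, n_steps = n_steps, pml_thickness = pml_thickness,
                 pml_absorption = pml_absorption, cfl_limit = cfl_limit,
                 precision = precision, source_mode = source_mode,
                 absorption_d = absorption_d,
                 absorption_ref_freq = absorption_ref_freq),
            class = "solver_config")
}

#' Check the CFL stability condition for a medium/configuration pair
#'
#' @param medium a [medium_grid()].
#' @param cfg a [solver_config()].
#' @return a list with the maximum CFL number, the limiting voxel index,
#'   whether the configuration is stable, and the recommended dt reaching
#'   `cfl_limit` exactly.
#' @export
check_stability <- function(medium, cfg = solver_config()) {
  stopifnot(inherits(medium, "medium_grid"), inherits(cfg, "solver_config"))
  if (prod(medium$shape) == 0L || length(medium$speed) == 0L)
    stop("empty grid", call. = FALSE)
  i_max <- which.max(medium$speed)
  c_max <- medium$speed[i_max]
  dx_m <- medium$spacing * 1e-3
  cfl <- c_max * cfg$dt / dx_m
  list(cfl = cfl,
       limiting_voxel = arrayInd(i_max, medium$shape)[1, ],
       c_max = c_max,
       stable = cfl <= cfg$cfl_limit,
       recommended_dt = cfg$cfl_limit * dx_m / c_max)
}

#' Pressure time series recorded at one detector
#'
#' @param samples pressure samples, Pa.
#' @param dt sample interval, s.
#' @param t0 time of the first sample, s.
#' @param detector_position voxel index vector of the detector.
#' @return an object of class `pressure_trace`.
#' @export
pressure_trace <- function(samples, dt, t0 = dt, detector_position = NULL) {
  stopifnot(is.numeric(samples), length(samples) >= 1L, dt > 0)
  if (any(!is.finite(samples))) stop("trace samples must be finite", call. = FALSE)
  structure(list(samples = as.numeric(samples), dt = dt, t0 = t0,
                 detector_position = detector_position),
            class = "pressure_trace")
}

#' @export
print.pressure_trace <- function(x, ...) {
  cat("<pressure_trace> ", length(x$samples), " samples @ ",
      format(x$dt * 1e9), " ns, peak ", format(max(x$samples), digits = 4),
      " Pa\n", sep = "")
  invisible(x)
}

#' @export
plot.pressure_trace <- function(x, ...) {
  t_us <- (x$t0 + (seq_along(x$samples) - 1) * x$dt) * 1e6
  plot(t_us, x$samples * 1e3, type = "l", xlab = "time [us]",
       ylab = "pressure [mPa]", ...)
}

# Edge-replicate a property volume into the PML frame.
.pad_edge <- function(x, pml) {
  d <- dim(x)
  ix <- pmin(pmax(seq_len(d[1] + 2 * pml) - pml, 1L), d[1])
  iy <- pmin(pmax(seq_len(d[2] + 2 * pml) - pml, 1L), d[2])
  iz <- if (d[3] > 1L) pmin(pmax(seq_len(d[3] + 2 * pml) - pml, 1L), d[3]) else 1L
  x[ix, iy, iz, drop = FALSE]
}

#' Propagate a source through a medium and record detector traces
#'
#' Runs the staggered-grid solver: 8th-order spatial stencils, leapfrog
#' time stepping, split-field PML outside the grid, optional power-law
#' viscous absorption. Heterogeneous speed and density fields are honoured
#' voxel-wise; an error is raised if the CFL condition is violated
#' (reporting the limiting voxel) or if the state becomes non-finite.
#'
#' @param medium a [medium_grid()].
#' @param source a [source_term()]; its pulse must be sampled at `cfg$dt`.
#' @param detectors integer matrix of detector voxel indices (one row per
#'   detector, 2 or 3 columns, 1-based), or a single index vector.
#' @param cfg a [solver_config()]; `cfg$n_steps` must be set.
#' @param energy_stride record the total acoustic energy every this many
#'   steps (0 = off); returned as the `energy` attribute.
#' @return a list of [pressure_trace()] objects (one per detector) with a
#'   `metadata` attribute recording the scheme, CFL number, precision,
#'   source mode and grid parameters.
#' @export
propagate <- function(medium, source, detectors, cfg, energy_stride = 0L) {
  stopifnot(inherits(medium, "medium_grid"), inherits(source, "source_term"),
            inherits(cfg, "solver_config"))
  if (is.null(cfg$n_steps)) stop("cfg$n_steps must be set", call. = FALSE)
  st <- check_stability(medium, cfg)
  if (!st$stable)
    stop(sprintf("CFL violation: %.3f > %.3f at voxel (%s); dt <= %.3g s required",
                 st$cfl, cfg$cfl_limit,
                 paste(st$limiting_voxel, collapse = ","), st$recommended_dt),
         call. = FALSE)
  pulse <- source$pulse
  if (abs(pulse$dt - cfg$dt) > 1e-15)
    stop("the source pulse must be sampled at the solver time step", call. = FALSE)

  detectors <- rbind(detectors)
  if (ncol(detectors) == 2L) detectors <- cbind(detectors, 1L)
  stopifnot(ncol(detectors) == 3L)
  if (any(detectors < 1L) || any(t(detectors) > medium$shape))
    stop("detector positions lie outside the grid", call. = FALSE)
  if (any(source$positions < 1L) || any(t(source$positions) > medium$shape))
    stop("source positions lie outside the grid", call. = FALSE)

  pml <- as.integer(cfg$pml_thickness)
  pml3 <- if (medium$shape[3] > 1L) pml else 0L
  speed_p <- .pad_edge(medium$speed, pml)
  density_p <- .pad_edge(medium$density, pml)

  delta <- numeric(0)
  if (!is.null(medium$alpha0) && any(medium$alpha0 > 0)) {
    omega_ref <- 2 * pi * cfg$absorption_ref_freq
    delta_vol <- 2 * medium$speed^3 * medium$alpha0 * omega_ref^(cfg$absorption_d - 2)
    delta <- as.numeric(.pad_edge(delta_vol, pml))
  }

  shift <- c(pml, pml, pml3)
  src <- sweep(source$positions, 2L, shift, "+")
  det <- sweep(detectors, 2L, shift, "+")

  pulse_vec <- c(pulse$samples, numeric(max(0L, cfg$n_steps + 1L - length(pulse$samples))))
  pulse_vec <- pulse_vec[seq_len(cfg$n_steps + 1L)]

  res <- .fdtd_run(as.numeric(speed_p), as.numeric(density_p), delta,
                   dim(speed_p), medium$spacing * 1e-3, cfg$dt,
                   as.integer(cfg$n_steps),
                   matrix(as.integer(src), ncol = 3L), source$amplitudes,
                   pulse_vec, match(cfg$source_mode, c("pressure", "pressure_rate")) - 1L,
                   pulse$sigma, matrix(as.integer(det), ncol = 3L),
                   pml, cfg$pml_absorption,
                   identical(cfg$precision, "single"), as.integer(energy_stride))

  traces <- lapply(seq_len(nrow(detectors)), function(m)
    pressure_trace(res$traces[, m], dt = cfg$dt, t0 = cfg$dt,
                   detector_position = detectors[m, ]))
  meta <- list(scheme = "staggered-grid FDTD, 8th-order space / 2nd-order time",
               cfl = st$cfl, precision = cfg$precision,
               source_mode = cfg$source_mode, dt = cfg$dt,
               n_steps = cfg$n_steps, spacing_mm = medium$spacing,
               pml_thickness = cfg$pml_thickness,
               pml_absorption = cfg$pml_absorption,
               absorption = if (length(delta) > 0)
                 list(model = "viscous loss matched to alpha0*omega^d",
                      d = cfg$absorption_d,
                      ref_freq_hz = cfg$absorption_ref_freq) else NULL)
  structure(traces, metadata = meta, energy = res$energy,
            class = c("pressure_trace_list", "list"))
}

#' Peak-arrival convergence probe under grid refinement
#'
#' Re-runs a propagation at a sequence of voxel sizes (nearest-neighbour
#' resampling of the medium, dt rescaled proportionally so the CFL number
#' is constant) and reports the detected peak arrival time at each
#' refinement. Successive differences shrinking indicates convergence.
#'
#' @param medium a [medium_grid()].
#' @param source_mm,detector_mm physical source and detector positions in mm
#'   (cell-centred continuum coordinates).
#' @param cfg a [solver_config()] applying to the *finest* spacing given.
#' @param spacings_mm decreasing vector (>= 2 values) of voxel sizes, mm.
#' @param amplitude source amplitude, Pa.
#' @return a data.frame with columns `spacing_mm`, `dt_s`, `t_peak_s`.
#' @export
convergence_probe <- function(medium, source_mm, detector_mm, cfg,
                              spacings_mm, amplitude = 12e-3) {
  stopifnot(length(spacings_mm) >= 2L)
  finest <- min(spacings_mm)
  out <- lapply(spacings_mm, function(h) {
    med_h <- resample_grid(medium, h)
    scale <- h / finest
    cfg_h <- cfg
    cfg_h$dt <- cfg$dt * scale
    cfg_h$n_steps <- as.integer(ceiling(cfg$n_steps / scale))
    to_idx <- function(pos_mm) {
      idx <- pmin(pmax(ceiling(pos_mm / h), 1L), med_h$shape[seq_along(pos_mm)])
      if (length(idx) == 2L) idx <- c(idx, 1L)
      idx
    }
    pulse <- gaussian_pulse(width = 10e-6, dt = cfg_h$dt)
    src <- source_term(matrix(to_idx(source_mm), nrow = 1), amplitude, pulse)
    tr <- propagate(med_h, src, rbind(to_idx(detector_mm)), cfg_h)
    data.frame(spacing_mm = h, dt_s = cfg_h$dt,
               t_peak_s = detect_peak_time(tr[[1]]))
  })
  do.call(rbind, out)
}
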