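# Study drivers reproducing the three analyses end-to-end at configurable
# scale: thermal-water arrival times, homogeneous-tissue and bimaterial
# range estimates, and per-detector range reports on CT-like volumes.

#' Study configuration
#'
#' Desk-scale defaults: 2-D, 1 mm voxels (matching the heterogeneity
#' correlation length of the reference voxel size), 10 ns time step,
#' 100 mm source-detector separation along x, 5 replicate seeds for
#' stochastic phantoms. `ndim = 3` switches to a 3-D slab of the same
#' cross-section. Double-precision arithmetic is the study default because
#' thermal arrival-time shifts are resolved at the 10 ns level.
#'
#' @param study one of `"thermal_water"`, `"homogeneous"`, `"bimaterial"`,
#'   `"ct_detectors"`.
#' @param ndim 2 or 3.
#' @param spacing voxel size, mm.
#' @param separation source-detector distance, mm (must be a multiple of
#'   `2 * spacing`).
#' @param margin padding between source/detector and the grid edge, mm.
#' @param lateral transverse grid extent, mm. The default (180 mm) keeps
#'   aperture-truncation and grazing-incidence PML artifacts from off-axis
#'   scattered energy well below the direct arrival in every tissue
#'   (slow media need the widest margin); uniform media are insensitive
#'   to it.
#' @param dt solver time step, s.
#' @param pulse_width Gaussian pulse total width, s.
#' @param amplitude Bragg-peak source amplitude, Pa.
#' @param replicates number of random-phantom replicates per configuration.
#' @param seed base RNG seed; per-run seeds are derived deterministically.
#' @param temperature_sds thermal-water temperature SDs, degC.
#' @param tissues tissue names for the homogeneous study.
#' @param pml_thickness,precision,source_mode passed to [solver_config()].
#' @param scale `"desk"` (default) or `"reference"`; reference scale
#'   restores the full 200 mm cube at 1 mm in 3-D (slow; a warning is
#'   emitted).
#' @return an object of class `study_config`.
#' @export
study_config <- function(study = c("thermal_water", "homogeneous",
                                   "bimaterial", "ct_detectors"),
                         ndim = 2, spacing = 1, separation = 100,
                         margin = 15, lateral = 180, dt = 10e-9,
                         pulse_width = 10e-6, amplitude = 12e-3,
                         replicates = 5, seed = 1,
                         temperature_sds = c(0, 5, 10, 15),
                         tissues = c("soft_tissue", "bone", "lung"),
                         pml_thickness = 10, precision = "double",
                         source_mode = "pressure",
                         scale = c("desk", "reference")) {
  study <- match.arg(study)
  scale <- match.arg(scale)
  stopifnot(ndim %in% c(2, 3), spacing > 0, separation > 0, margin > 0,
            lateral > 0, replicates >= 1)
  if (scale == "reference") {
    warning("reference scale: 200 mm cube in 3-D at 1 mm; this is slow",
            call. = FALSE)
    ndim <- 3; spacing <- 1; lateral <- 200; margin <- 50
  }
  if (abs(separation / (2 * spacing) - round(separation / (2 * spacing))) > 1e-9)
    stop("separation must be a multiple of 2 * spacing", call. = FALSE)
  structure(list(study = study, ndim = ndim, spacing = spacing,
                 separation = separation, margin = margin, lateral = lateral,
                 dt = dt, pulse_width = pulse_width, amplitude = amplitude,
                 replicates = as.integer(replicates), seed = seed,
                 temperature_sds = temperature_sds, tissues = tissues,
                 pml_thickness = pml_thickness, precision = precision,
                 source_mode = source_mode, scale = scale),
            class = "study_config")
}

# Grid geometry shared by the phantom studies: source and detector on the
# x axis, exactly `separation` mm apart, with the bimaterial interface
# placed so that midpoint path sampling weighs both halves equally.
.study_geometry <- function(cfg) {
  h <- cfg$spacing
  nx <- 2L * as.integer(ceiling((cfg$separation + 2 * cfg$margin) / (2 * h)))
  ny <- as.integer(round(cfg$lateral / h))
  half_sep <- as.integer(round(cfg$separation / (2 * h)))
  ix0 <- nx %/% 2L - half_sep + 1L
  ix1 <- ix0 + 2L * half_sep
  iy <- as.integer(ceiling(ny / 2))
  shape <- if (cfg$ndim == 2) c(nx, ny, 1L) else c(nx, ny, ny)
  iz <- if (cfg$ndim == 2) 1L else iy
  list(shape = shape, src = c(ix0, iy, iz), det = c(ix1, iy, iz))
}

.study_solver_config <- function(cfg, c_slowest) {
  t_end <- cfg$separation * 1e-3 / (0.8 * c_slowest) + 3 * cfg$pulse_width
  solver_config(dt = cfg$dt, n_steps = as.integer(ceiling(t_end / cfg$dt)),
                pml_thickness = cfg$pml_thickness, precision = cfg$precision,
                source_mode = cfg$source_mode)
}

# Grid-refinement level needed so the solver resolves the pulse's
# wavelength in the slowest material at >= `ppw_min` points per wavelength
# (the phantom keeps its native voxel noise; the solver grid is a
# nearest-neighbour refinement, so the heterogeneity correlation length is
# preserved).
.solver_refinement <- function(spacing, c_slowest, f_c = 1.35e5, ppw_min = 8) {
  ppw <- c_slowest / (f_c * spacing * 1e-3)
  max(0L, ceiling(log2(ppw_min / ppw)))
}

# One propagation + TOF analysis on a generated phantom realisation.
# `c_slowest` is the slowest involved tissue's mean speed, used to size the
# run duration and the solver-grid refinement.
.study_run <- function(cfg, medium, geom, scfg, c_slowest) {
  refine <- .solver_refinement(cfg$spacing, c_slowest)
  pos_mm <- function(idx) (idx - 0.5) * cfg$spacing
  if (refine > 0L) {
    h2 <- cfg$spacing / 2^refine
    medium_s <- resample_grid(medium, h2)
    to_fine <- function(idx) pmin(pmax(ceiling(pos_mm(idx) / h2), 1L),
                                  medium_s$shape)
    src_idx <- to_fine(geom$src); det_idx <- to_fine(geom$det)
  } else {
    medium_s <- medium
    src_idx <- geom$src; det_idx <- geom$det
  }
  pulse <- gaussian_pulse(width = cfg$pulse_width, dt = cfg$dt)
  src <- source_term(matrix(src_idx, nrow = 1), cfg$amplitude, pulse)
  tr <- propagate(medium_s, src, rbind(det_idx), scfg)[[1]]
  t_peak <- detect_peak_time(tr)
  pa <- path_average_speed(medium, pos_mm(geom$src), pos_mm(geom$det))
  est <- range_estimate(t_peak, pa$c_avg, d_real = cfg$separation,
                        valid = signal_is_valid(tr))
  est$peak_pa <- max(tr$samples)
  list(estimate = est, trace = tr, metadata = attr(tr, "metadata"))
}

.report <- function(rows, cfg, meta) {
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("study_report", "data.frame"),
            metadata = c(list(study = cfg$study, scale = cfg$scale,
                              base_seed = cfg$seed, spacing_mm = cfg$spacing,
                              ndim = cfg$ndim), meta))
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> ", attr(x, "metadata")$study, ", ",
      nrow(x), " rows\n", sep = "")
  print.data.frame(x, digits = 4, ...)
  invisible(x)
}

#' Check the defining TOF identities of a study report
#'
#' Verifies row-wise that d_tof = t_peak * c_avg, delta_d = |d_real -
#' d_tof| and epsilon_d = delta_d / d_real * 100 hold exactly.
#'
#' @param report a `study_report`.
#' @return TRUE invisibly; errors otherwise.
#' @export
validate_study_report <- function(report) {
  stopifnot(inherits(report, "study_report"))
  with(report, {
    stopifnot(isTRUE(all.equal(d_tof_mm, tof_us * 1e-6 * c_avg * 1e3,
                               tolerance = 1e-12)),
              isTRUE(all.equal(delta_d_mm, abs(d_real_mm - d_tof_mm),
                               tolerance = 1e-12)),
              isTRUE(all.equal(epsilon_d_pct, delta_d_mm / d_real_mm * 100,
                               tolerance = 1e-12)))
  })
  invisible(TRUE)
}

.row_from_estimate <- function(label, replicate, seed, est) {
  data.frame(config = label, replicate = replicate, seed = seed,
             tof_us = est$t_peak * 1e6, c_avg = est$c_avg,
             d_tof_mm = est$d_tof, d_real_mm = est$d_real,
             delta_d_mm = est$delta_d, epsilon_d_pct = est$epsilon_d,
             valid = est$valid, peak_pa = est$peak_pa,
             stringsAsFactors = FALSE)
}

#' Thermal-water study: arrival time vs spatial temperature heterogeneity
#'
#' Simulates the protoacoustic arrival in water phantoms whose voxel
#' temperatures fluctuate around 25 degC with the configured standard
#' deviations (0 degC = homogeneous baseline, single run; otherwise
#' `replicates` seeds each), and reports each run's arrival time plus the
#' delay relative to the baseline.
#'
#' @param cfg a [study_config()] (`temperature_sds` holds the SD list).
#' @return a `study_report` with one row per run; the `summary` attribute
#'   aggregates mean/SD of arrival and delay per temperature SD.
#' @export
run_thermal_water_study <- function(cfg = study_config("thermal_water")) {
  geom <- .study_geometry(cfg)
  scfg <- .study_solver_config(cfg, c_slowest = 1400)
  rows <- list()
  baseline_tof <- NA_real_
  for (ci in seq_along(cfg$temperature_sds)) {
    sdt <- cfg$temperature_sds[ci]
    n_rep <- if (sdt == 0) 1L else cfg$replicates
    for (r in seq_len(n_rep)) {
      seed_r <- if (sdt == 0) NULL else cfg$seed + 131L * ci + r
      pc <- phantom_config("thermal_water", temperature_sd = sdt,
                           shape = geom$shape, spacing = cfg$spacing,
                           seed = seed_r)
      run <- .study_run(cfg, make_thermal_water_phantom(pc), geom, scfg,
                        c_slowest = 1498)
      row <- .row_from_estimate(sprintf("sd%g", sdt), r,
                                seed_r %||% NA_integer_, run$estimate)
      if (sdt == 0 && r == 1L) baseline_tof <- row$tof_us
      row$delay_us <- row$tof_us - baseline_tof
      rows[[length(rows) + 1L]] <- row
    }
  }
  rep <- .report(rows, cfg, list(solver = attr(rows, "metadata")))
  agg <- do.call(rbind, lapply(split(as.data.frame(rep), rep$config), function(d)
    data.frame(config = d$config[1], n = nrow(d),
               tof_us_mean = mean(d$tof_us), tof_us_sd = sd(d$tof_us),
               delay_us_mean = mean(d$delay_us), delay_us_sd = sd(d$delay_us))))
  rownames(agg) <- NULL
  attr(rep, "summary") <- agg
  rep
}

.gap_summary <- function(rep, by = "config") {
  # mean nonuniform - uniform DTOF per configuration label
  key <- sub("\\|(uniform|nonuniform)$", "", rep$config)
  mode <- sub("^.*\\|", "", rep$config)
  out <- lapply(split(seq_len(nrow(rep)), key), function(ii) {
    uni <- mean(rep$d_tof_mm[ii][mode[ii] == "uniform"])
    non <- mean(rep$d_tof_mm[ii][mode[ii] == "nonuniform"])
    data.frame(config = key[ii][1], d_tof_uniform_mm = uni,
               d_tof_nonuniform_mm = non, difference_mm = non - uni)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Homogeneous-tissue study: uniform vs nonuniform range estimates
#'
#' For each configured tissue, simulates the 100 mm source-detector
#' configuration in a uniform phantom (tissue means everywhere) and in
#' nonuniform phantoms (voxel-wise variation with the tissue SDs,
#' `replicates` seeds), reporting TOF range estimates and the
#' nonuniform-minus-uniform distance gap.
#'
#' @param cfg a [study_config()].
#' @return a `study_report`; the `summary` attribute holds per-tissue
#'   uniform/nonuniform mean DTOF and their difference.
#' @export
run_homogeneous_study <- function(cfg = study_config("homogeneous")) {
  geom <- .study_geometry(cfg)
  rows <- list()
  for (ti in seq_along(cfg$tissues)) {
    spec_t <- .as_tissue_spec(cfg$tissues[[ti]])
    tn <- spec_t$name
    scfg <- .study_solver_config(cfg, c_slowest = spec_t$speed_mean)
    for (mode in c("uniform", "nonuniform")) {
      n_rep <- if (mode == "uniform") 1L else cfg$replicates
      for (r in seq_len(n_rep)) {
        seed_r <- if (mode == "uniform") NULL else cfg$seed + 977L * ti + r
        pc <- phantom_config("homogeneous", tissues = list(spec_t),
                             heterogeneity = mode, shape = geom$shape,
                             spacing = cfg$spacing, seed = seed_r)
        run <- .study_run(cfg, make_tissue_phantom(pc), geom, scfg,
                          c_slowest = spec_t$speed_mean)
        rows[[length(rows) + 1L]] <-
          .row_from_estimate(paste0(tn, "|", mode), r,
                             seed_r %||% NA_integer_, run$estimate)
      }
    }
  }
  rep <- .report(rows, cfg, list())
  attr(rep, "summary") <- .gap_summary(rep)
  rep
}

#' Bimaterial study: twelve two-material configurations
#'
#' Three tissue pairs (bone-lung, bone-soft tissue, lung-soft tissue), each
#' with both Bragg-peak placements (the first named tissue hosts the Bragg
#' peak) and both uniform and nonuniform properties: 12 configurations. The
#' interface is perpendicular to the source-detector axis at its midpoint,
#' so the straight path crosses ~50 mm of each material.
#'
#' @param cfg a [study_config()].
#' @return a `study_report`; the `summary` attribute is shaped like the
#'   reference range table (uniform and nonuniform mean DTOF per ordered
#'   pair plus their difference).
#' @export
run_bimaterial_study <- function(cfg = study_config("bimaterial")) {
  geom <- .study_geometry(cfg)
  pairs <- list(c("bone", "lung"), c("lung", "bone"),
                c("bone", "soft_tissue"), c("soft_tissue", "bone"),
                c("lung", "soft_tissue"), c("soft_tissue", "lung"))
  rows <- list()
  for (pi in seq_along(pairs)) {
    pr <- pairs[[pi]]
    c_slow <- min(vapply(pr, function(t) .as_tissue_spec(t)$speed_mean, 0))
    scfg <- .study_solver_config(cfg, c_slowest = c_slow)
    for (mode in c("uniform", "nonuniform")) {
      n_rep <- if (mode == "uniform") 1L else cfg$replicates
      for (r in seq_len(n_rep)) {
        seed_r <- if (mode == "uniform") NULL else cfg$seed + 7919L * pi + r
        pc <- phantom_config("bimaterial", tissues = pr, heterogeneity = mode,
                             shape = geom$shape, spacing = cfg$spacing,
                             seed = seed_r)
        run <- .study_run(cfg, make_bimaterial_phantom(pc), geom, scfg,
                          c_slowest = c_slow)
        rows[[length(rows) + 1L]] <-
          .row_from_estimate(paste0(pr[1], ">", pr[2], "|", mode), r,
                             seed_r %||% NA_integer_, run$estimate)
      }
    }
  }
  rep <- .report(rows, cfg, list())
  attr(rep, "summary") <- .gap_summary(rep)
  rep
}

#' Per-detector range report on a CT-like volume
#'
#' Propagates one Bragg-peak source through a supplied medium (a loaded CT
#' volume or a CT-like labelled fixture) and reports, per detector, the TOF
#' range estimate, errors against the known geometry and the 0.2 mPa
#' signal-validity flag.
#'
#' @param medium a [medium_grid()].
#' @param bragg voxel index vector of the Bragg peak.
#' @param detectors matrix of detector voxel indices (rows).
#' @param cfg a [study_config()] (timing/source parameters; geometry fields
#'   are ignored in favour of the supplied positions).
#' @return a `study_report` with one row per detector.
#' @export
run_ct_detector_study <- function(medium, bragg, detectors,
                                  cfg = study_config("ct_detectors")) {
  stopifnot(inherits(medium, "medium_grid"))
  detectors <- rbind(detectors)
  if (ncol(detectors) == 2L) detectors <- cbind(detectors, 1L)
  bragg <- as.integer(bragg)
  if (length(bragg) == 2L) bragg <- c(bragg, 1L)
  if (any(bragg < 1L) || any(bragg > medium$shape))
    stop("bragg position lies outside the grid", call. = FALSE)
  if (any(detectors < 1L) || any(t(detectors) > medium$shape))
    stop("invalid detector position", call. = FALSE)
  scfg <- .study_solver_config(cfg, c_slowest = max(300, min(medium$speed)))
  pulse <- gaussian_pulse(width = cfg$pulse_width, dt = cfg$dt)
  src <- source_term(matrix(bragg, nrow = 1), cfg$amplitude, pulse)
  traces <- propagate(medium, src, detectors, scfg)
  pos_mm <- function(idx) (idx - 0.5) * medium$spacing
  rows <- lapply(seq_len(nrow(detectors)), function(m) {
    tr <- traces[[m]]
    d_real <- sqrt(sum((pos_mm(detectors[m, ]) - pos_mm(bragg))^2))
    pa <- path_average_speed(medium, pos_mm(bragg), pos_mm(detectors[m, ]))
    est <- range_estimate(detect_peak_time(tr), pa$c_avg, d_real,
                          valid = signal_is_valid(tr))
    est$peak_pa <- max(tr$samples)
    .row_from_estimate(sprintf("detector_%d", m), 1L, NA_integer_, est)
  })
  .report(rows, cfg, list(bragg = bragg))
}

#' Reference clinical TOF ranges
#'
#' The five-case clinical evaluation shipped with the package: true
#' Bragg-peak-to-detector distances and TOF-estimated distances for five
#' detector positions in each of five treatment sites (brain, head & neck,
#' liver, prostate, lung), used to exercise the range-error arithmetic at
#' full clinical scale.
#'
#' @return a data.frame with columns `case`, `position`, `d_real_mm`,
#'   `d_tof_mm`.
#' @export
clinical_tof_cases <- function() {
  path <- system.file("extdata", "clinical_tof_ranges.csv",
                      package = "protorange", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Range-error report for tabulated D_real / D_TOF pairs
#'
#' @param cases a data.frame with columns `d_real_mm` and `d_tof_mm`
#'   (defaults to [clinical_tof_cases()]).
#' @return the input with `delta_d_mm` and `epsilon_d_pct` columns appended.
#' @export
clinical_range_report <- function(cases = clinical_tof_cases()) {
  err <- range_error(cases$d_real_mm, cases$d_tof_mm)
  cases$delta_d_mm <- err$delta_d
  cases$epsilon_d_pct <- err$epsilon_d
  cases
}
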