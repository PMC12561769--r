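# Thermoacoustic source construction: Grueneisen-scaled initial pressure,
# Gaussian temporal pulse, and the Bragg-peak + entrance-path study sources.

#' Sampled Gaussian proton-pulse waveform
#'
#' The proton pulse's temporal profile: a Gaussian with total width `width`
#' interpreted as a 6-sigma support (sigma = width/6), peak value 1 at
#' width/2. The sampled waveform is pedestal-subtracted so that it reaches
#' exactly zero at the support edges (the truncated Gaussian's ~1.1%
#' edge discontinuity would otherwise inject a broadband numerical click
#' into the incremental pressure drive), then renormalised to peak 1.
#'
#' @param width total pulse width in seconds (default 10 us).
#' @param dt sample interval in seconds; must satisfy dt <= width/20.
#' @return an object of class `acoustic_pulse`: list with `samples`
#'   (values on `t = (0:(n-1)) * dt`), `dt`, `width`, `sigma`.
#' @export
gaussian_pulse <- function(width = 10e-6, dt = 10e-9) {
  stopifnot(is.numeric(width), width > 0, is.numeric(dt), dt > 0)
  if (dt > width / 20)
    stop("dt too coarse: need dt <= width/20 to resolve the pulse", call. = FALSE)
  n <- floor(width / dt + 1e-9) + 1L
  t <- (seq_len(n) - 1) * dt
  sigma <- width / 6
  mu <- width / 2
  g <- exp(-(t - mu)^2 / (2 * sigma^2))
  g0 <- exp(-mu^2 / (2 * sigma^2))
  g <- pmax((g - g0) / (1 - g0), 0)
  structure(list(samples = g, dt = dt, width = width, sigma = sigma),
            class = "acoustic_pulse")
}

#' Spatio-temporal pressure source
#'
#' A set of source voxels with per-voxel peak amplitudes sharing one
#' temporal pulse; the injected signal at each voxel is separable,
#' amplitude x pulse. Two drive conventions are supported (see
#' [solver_config()]): `"pressure"` imposes the waveform on the source
#' voxel's pressure incrementally, `"pressure_rate"` adds it as a mass-rate
#' term.
#'
#' @param positions integer matrix of voxel indices (1-based), one row per
#'   source, 2 or 3 columns.
#' @param amplitudes peak pressure amplitude per source, Pa (>= 0).
#' @param pulse an [gaussian_pulse()] (or compatible) waveform: peak value 1,
#'   non-negative, unimodal.
#' @return an object of class `source_term`.
#' @export
source_term <- function(positions, amplitudes, pulse) {
  positions <- rbind(positions)
  if (ncol(positions) == 2L) positions <- cbind(positions, 1L)
  stopifnot(ncol(positions) == 3L, nrow(positions) >= 1L)
  if (!is.numeric(amplitudes) || length(amplitudes) != nrow(positions) ||
      any(amplitudes < 0) || any(!is.finite(amplitudes)))
    stop("amplitudes must be non-negative, one per source position", call. = FALSE)
  stopifnot(inherits(pulse, "acoustic_pulse"))
  s <- pulse$samples
  # the sampled maximum may fall slightly below the unit continuous-time
  # peak when the crest lies between samples
  if (any(s < 0) || max(s) > 1 + 1e-9 || max(s) < 0.95)
    stop("pulse must be non-negative with peak value 1", call. = FALSE)
  ds <- diff(s); ds <- ds[ds != 0]
  if (length(ds) > 1L && any(diff(ds > 0) > 0))
    stop("pulse must be unimodal", call. = FALSE)
  structure(list(positions = positions, amplitudes = amplitudes, pulse = pulse),
            class = "source_term")
}

#' Initial pressure from a dose deposition
#'
#' Voxel-wise thermoacoustic conversion: P0 = Gamma * rho * Dose, with the
#' Grueneisen coefficient from the supplied thermoacoustic parameters and
#' the density taken from the medium.
#'
#' @param dose per-voxel absorbed dose, Gy (array matching the medium shape,
#'   all >= 0).
#' @param medium a [medium_grid()].
#' @param thermo a single [thermo_params()] applied everywhere, or a list of
#'   them indexed by the medium's tissue labels.
#' @return per-voxel initial pressure, Pa (array of the medium's shape).
#' @export
initial_pressure <- function(dose, medium, thermo = thermo_params()) {
  stopifnot(inherits(medium, "medium_grid"))
  dose <- .as_vol(dose)
  if (!identical(dim(dose), medium$shape))
    stop("dose and medium shapes differ", call. = FALSE)
  if (any(dose < 0) || any(!is.finite(dose)))
    stop("dose must be finite and non-negative", call. = FALSE)
  if (inherits(thermo, "thermo_params")) {
    gamma <- array(gruneisen(thermo), medium$shape)
  } else {
    if (is.null(medium$labels))
      stop("per-tissue thermo parameters need a labelled medium", call. = FALSE)
    gamma <- array(NA_real_, medium$shape)
    for (lab in unique(as.vector(medium$labels))) {
      tp <- thermo[[as.character(lab)]] %||% thermo[[lab]]
      if (is.null(tp)) stop("no thermo parameters for label ", lab, call. = FALSE)
      gamma[medium$labels == lab] <- gruneisen(tp)
    }
  }
  gamma * medium$density * dose
}

#' Bragg-peak plus entrance-path study sources
#'
#' The study source model: one high-amplitude source at the Bragg peak and
#' lower-amplitude sources at every voxel along the proton entrance path
#' (continuous energy deposition before the peak), all sharing the same
#' Gaussian pulse. Default amplitudes are 12 mPa (Bragg) and 2 mPa
#' (entrance), a 6:1 ratio.
#'
#' @param bragg_position voxel index vector (length 2 or 3, 1-based).
#' @param medium a [medium_grid()] (for bounds checking).
#' @param pulse a [gaussian_pulse()].
#' @param beam_axis axis (1, 2 or 3) along which the beam travels towards
#'   +infinity; entrance voxels lie at lower indices than the Bragg peak.
#' @param entrance_length length of the entrance path in mm (0 = Bragg-peak
#'   source only).
#' @param bragg_amplitude,entrance_amplitude peak amplitudes, Pa.
#' @return a [source_term()] whose first row is the Bragg-peak source.
#' @export
build_study_sources <- function(bragg_position, medium, pulse, beam_axis = 1,
                                entrance_length = 0,
                                bragg_amplitude = 12e-3,
                                entrance_amplitude = 2e-3) {
  stopifnot(inherits(medium, "medium_grid"))
  pos <- as.integer(bragg_position)
  if (length(pos) == 2L) pos <- c(pos, 1L)
  stopifnot(length(pos) == 3L)
  if (any(pos < 1L) || any(pos > medium$shape))
    stop("bragg_position lies outside the grid", call. = FALSE)
  stopifnot(beam_axis %in% 1:3, entrance_length >= 0)
  n_entrance <- round(entrance_length / medium$spacing)
  positions <- matrix(pos, nrow = 1L)
  if (n_entrance > 0) {
    steps <- seq_len(n_entrance)
    entr <- matrix(rep(pos, each = n_entrance), ncol = 3L)
    entr[, beam_axis] <- pos[beam_axis] - steps
    if (any(entr[, beam_axis] < 1L))
      stop("entrance path exits the grid", call. = FALSE)
    positions <- rbind(positions, entr)
  }
  source_term(positions,
              c(bragg_amplitude, rep(entrance_amplitude, n_entrance)),
              pulse)
}
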