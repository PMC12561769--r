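# Time-of-flight analysis: peak arrival extraction, signal validity gating,
# path-averaged sound speed, and range estimates / errors.

#' Arrival time of the peak protoacoustic signal
#'
#' Returns the time of the global maximum of the trace. Ties are broken to
#' the earliest: any local maximum within a relative tolerance `tie_tol` of
#' the global maximum counts as tied (the far field of a symmetric pulse is
#' bipolar with two nearly equal compression lobes, whose numerical order
#' is not meaningful), and the earliest tied local maximum is returned.
#' `tie_tol = 0` reduces to the plain earliest-global-maximum rule.
#'
#' @param trace a [pressure_trace()].
#' @param tie_tol relative tie tolerance on the peak amplitude.
#' @return arrival time in seconds (`t0 + (index - 1) * dt`).
#' @export
detect_peak_time <- function(trace, tie_tol = 0.02) {
  stopifnot(inherits(trace, "pressure_trace"))
  s <- trace$samples
  if (length(s) == 0L || all(s == 0))
    stop("no signal: the trace is empty or identically zero", call. = FALSE)
  m <- max(s)
  if (tie_tol > 0) {
    n <- length(s)
    is_peak <- s >= c(-Inf, s[-n]) & s >= c(s[-1], -Inf)
    cand <- which(is_peak & s >= m - tie_tol * abs(m))
    idx <- cand[1]
  } else {
    idx <- which(s == m)[1]
  }
  trace$t0 + (idx - 1) * trace$dt
}

#' Signal validity gate
#'
#' A protoacoustic signal is considered valid if its peak-to-valley
#' amplitude (max minus min) exceeds the threshold, 0.2 mPa by default.
#'
#' @param trace a [pressure_trace()].
#' @param threshold peak-to-valley threshold, Pa.
#' @return logical flag.
#' @export
signal_is_valid <- function(trace, threshold = 0.2e-3) {
  stopifnot(inherits(trace, "pressure_trace"))
  s <- trace$samples
  length(s) > 0L && (max(s) - min(s)) > threshold
}

#' Path-averaged speed of sound along the Bragg-peak-to-detector segment
#'
#' Samples the straight segment between the two points at one-voxel
#' intervals using midpoint (cell-centred) sampling -- `N = round(L /
#' spacing)` samples at the midpoints of equal sub-segments, so every
#' traversed voxel carries equal weight -- with nearest-voxel property
#' lookup. By default the per-sample sound speeds are averaged
#' arithmetically (`method = "speed_mean"`); `method = "hu_mean"` instead
#' averages the CT numbers along the path and converts the mean through
#' [hu_to_speed()] (the two differ in mixed media because the anchor map is
#' nonlinear; the speed average reproduces the reference range tables).
#'
#' @param medium a [medium_grid()].
#' @param p_bragg,p_detector positions in mm (cell-centred continuum
#'   coordinates, length 2 or 3) of the Bragg peak and the detector.
#' @param method `"speed_mean"` (default) or `"hu_mean"`.
#' @return an object of class `path_average`: list with `c_avg` (m/s),
#'   `length_mm`, `method` and the per-sample `profile` data.frame
#'   (distance along the path, voxel indices, speed, CT number if stored).
#' @export
path_average_speed <- function(medium, p_bragg, p_detector,
                               method = c("speed_mean", "hu_mean")) {
  stopifnot(inherits(medium, "medium_grid"))
  method <- match.arg(method)
  a <- as.numeric(p_bragg); b <- as.numeric(p_detector)
  if (length(a) == 2L) a <- c(a, medium$spacing / 2)
  if (length(b) == 2L) b <- c(b, medium$spacing / 2)
  stopifnot(length(a) == 3L, length(b) == 3L)
  # canonicalize the direction so the average is endpoint-order-invariant
  if (isTRUE(b[1] < a[1]) || (b[1] == a[1] && b[2] < a[2]) ||
      (b[1] == a[1] && b[2] == a[2] && b[3] < a[3])) {
    tmp <- a; a <- b; b <- tmp
  }
  L <- sqrt(sum((b - a)^2))
  if (L == 0) stop("zero-length path", call. = FALSE)
  ext <- medium$shape * medium$spacing
  if (any(a < 0 | a > ext) || any(b < 0 | b > ext))
    stop("path endpoints lie outside the grid", call. = FALSE)
  n <- max(1L, as.integer(round(L / medium$spacing)))
  frac <- (seq_len(n) - 0.5) / n
  pts <- cbind(a[1] + frac * (b[1] - a[1]),
               a[2] + frac * (b[2] - a[2]),
               a[3] + frac * (b[3] - a[3]))
  # samples falling exactly on a voxel boundary belong to the lower-index
  # voxel (the tiny bias keeps the assignment float-stable)
  vox <- pmin(pmax(ceiling(pts / medium$spacing - 1e-9),
                   matrix(1L, n, 3)),
              matrix(medium$shape, n, 3, byrow = TRUE))
  lin <- vox[, 1] + medium$shape[1] * (vox[, 2] - 1) +
    prod(medium$shape[1:2]) * (vox[, 3] - 1)
  speeds <- medium$speed[lin]
  hu <- if (!is.null(medium$hu)) medium$hu[lin] else rep(NA_real_, n)
  c_avg <- if (method == "speed_mean") mean(speeds) else hu_to_speed(mean(hu))
  profile <- data.frame(s_mm = frac * L, ix = vox[, 1], iy = vox[, 2],
                        iz = vox[, 3], speed = speeds, hu = hu)
  structure(list(c_avg = c_avg, length_mm = L, method = method,
                 profile = profile),
            class = "path_average")
}

#' @export
print.path_average <- function(x, ...) {
  cat("<path_average> ", round(x$c_avg, 2), " m/s over ",
      round(x$length_mm, 2), " mm (", nrow(x$profile), " samples, ",
      x$method, ")\n", sep = "")
  invisible(x)
}

#' Time-of-flight range estimate
#'
#' The estimated Bragg-peak-to-detector distance D_TOF = T_peak * c.
#'
#' @param t_peak peak arrival time, s (>= 0).
#' @param c_avg path-averaged sound speed, m/s (> 0).
#' @return distance in mm.
#' @export
tof_to_distance <- function(t_peak, c_avg) {
  if (any(t_peak < 0)) stop("t_peak must be >= 0", call. = FALSE)
  if (any(c_avg <= 0)) stop("c_avg must be > 0", call. = FALSE)
  t_peak * c_avg * 1e3
}

#' Absolute and relative range error
#'
#' Delta_D = |D_real - D_TOF| and epsilon_D = Delta_D / D_real * 100.
#'
#' @param d_real true Bragg-peak-to-detector distance, mm (> 0).
#' @param d_tof TOF-estimated distance, mm.
#' @return a data.frame with columns `delta_d` (mm) and `epsilon_d` (%).
#' @export
range_error <- function(d_real, d_tof) {
  if (any(d_real <= 0)) stop("d_real must be positive", call. = FALSE)
  delta <- abs(d_real - d_tof)
  data.frame(delta_d = delta, epsilon_d = delta / d_real * 100)
}

#' Assemble a full range estimate for one detector
#'
#' @param t_peak peak arrival time, s.
#' @param c_avg path-averaged sound speed, m/s.
#' @param d_real true distance, mm.
#' @param valid signal validity flag.
#' @return a one-row data.frame of class `range_estimate` with fields
#'   `t_peak`, `c_avg`, `d_tof`, `d_real`, `delta_d`, `epsilon_d`, `valid`,
#'   satisfying the defining identities exactly.
#' @export
range_estimate <- function(t_peak, c_avg, d_real, valid = NA) {
  d_tof <- tof_to_distance(t_peak, c_avg)
  err <- range_error(d_real, d_tof)
  out <- data.frame(t_peak = t_peak, c_avg = c_avg, d_tof = d_tof,
                    d_real = d_real, delta_d = err$delta_d,
                    epsilon_d = err$epsilon_d, valid = valid)
  class(out) <- c("range_estimate", "data.frame")
  out
}
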