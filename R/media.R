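# Material models: temperature -> water properties, CT number -> tissue
# properties, thermoacoustic (Grueneisen) coefficients, power-law absorption.

# Reference water properties at 25 degC used throughout the package.
WATER_SPEED_25 <- 1498   # m/s
WATER_DENSITY_25 <- 997  # kg/m^3

# Marczak's fifth-order polynomial for the speed of sound in pure water,
# c(T) in m/s with T in degC, valid on [0, 95] degC.
.marczak <- function(t) {
  1402.385 + 5.038813 * t - 5.799136e-2 * t^2 + 3.287156e-4 * t^3 -
    1.398845e-6 * t^4 + 2.787860e-9 * t^5
}

# Kell's density formula for air-free water, kg/m^3, T in degC.
.kell <- function(t) {
  (999.83952 + 16.945176 * t - 7.9870401e-3 * t^2 - 46.170461e-6 * t^3 +
     105.56302e-9 * t^4 - 280.54253e-12 * t^5) / (1 + 16.879850e-3 * t)
}

.check_water_temperature <- function(t) {
  if (!is.numeric(t) || length(t) == 0L || any(!is.finite(t)))
    stop("temperature must be finite and numeric", call. = FALSE)
  if (any(t <= 0 | t >= 100))
    stop("temperature out of the supported (0, 100) degC range", call. = FALSE)
}

#' Speed of sound in water as a function of temperature
#'
#' Marczak's fifth-order polynomial, offset so that the value at the 25 degC
#' reference temperature is exactly 1498 m/s (the reference used for all
#' water phantoms in this package). Monotonically increasing up to ~74 degC.
#'
#' @param temperature_celsius numeric scalar or array, degC, in (0, 100).
#' @return sound speed in m/s, same shape as the input.
#' @examples
#' water_speed_of_sound(25)  # exactly 1498
#' @export
water_speed_of_sound <- function(temperature_celsius) {
  .check_water_temperature(temperature_celsius)
  .marczak(temperature_celsius) + (WATER_SPEED_25 - .marczak(25))
}

#' Density of water as a function of temperature
#'
#' Kell's formulation, rescaled so that the 25 degC value is exactly
#' 997 kg/m^3. Strictly decreasing above the ~4 degC density maximum.
#'
#' @inheritParams water_speed_of_sound
#' @return density in kg/m^3, same shape as the input.
#' @export
water_density <- function(temperature_celsius) {
  .check_water_temperature(temperature_celsius)
  .kell(temperature_celsius) * (WATER_DENSITY_25 / .kell(25))
}

#' Built-in tissue property statistics
#'
#' Per-tissue CT-number and acoustic-property statistics (mean and standard
#' deviation of the CT number, mass density and speed of sound) for the three
#' reference materials used to build phantoms: soft tissue, bone and lung.
#' CT numbers are on the offset scale where water is approximately 1000 and
#' air approximately 0 (see [hu_from_conventional()]).
#'
#' The `alpha0_db` column holds representative power-law absorption
#' prefactors in dB/(MHz^d cm) (soft tissue ~0.54, cortical bone ~6.9,
#' inflated lung ~40, standard tissue-property tabulations); they damp the
#' multiply-scattered coda so that the detected global maximum is the
#' direct Bragg-peak compression, as the time-of-flight method assumes.
#'
#' @return a data.frame with one row per tissue and columns `name`, `hu_mean`,
#'   `hu_sd`, `density_mean`, `density_sd`, `speed_mean`, `speed_sd`,
#'   `alpha0_db`.
#' @export
tissue_table <- function() {
  data.frame(
    name = c("soft_tissue", "bone", "lung"),
    hu_mean = c(1042.5, 1850.0, 234.5),
    hu_sd = c(62.5, 50.0, 71.5),
    density_mean = c(1050.4, 1574.4, 234.0),
    density_sd = c(32.8, 19.3, 42.7),
    speed_mean = c(1567.1, 2153.9, 652.8),
    speed_sd = c(36.8, 21.6, 47.8),
    alpha0_db = c(0.54, 6.9, 40),
    stringsAsFactors = FALSE
  )
}

#' Convert an absorption prefactor from dB/(MHz^d cm) to Np/((rad/s)^d m)
#'
#' Tissue absorption is usually tabulated as dB/(MHz^d cm); the solver's
#' power-law coefficient alpha0 is in Np/((rad/s)^d m).
#'
#' @param alpha_db prefactor in dB/(MHz^d cm).
#' @param d power-law exponent.
#' @return prefactor in Np/((rad/s)^d m).
#' @export
alpha0_np_from_db <- function(alpha_db, d = 1.05) {
  alpha_db * 100 / 8.6858896 / (2 * pi * 1e6)^d
}

#' Look up or construct a tissue specification
#'
#' @param name tissue name; one of the built-ins (`"soft_tissue"`, `"bone"`,
#'   `"lung"`, with `"tissue"` accepted as an alias for soft tissue) or any
#'   label when the remaining statistics are supplied explicitly.
#' @param hu_mean,hu_sd,density_mean,density_sd,speed_mean,speed_sd optional
#'   overrides of the built-in statistics (CT number; kg/m^3; m/s).
#' @return an object of class `tissue_spec`.
#' @export
tissue_spec <- function(name, hu_mean = NULL, hu_sd = NULL,
                        density_mean = NULL, density_sd = NULL,
                        speed_mean = NULL, speed_sd = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (identical(name, "tissue")) name <- "soft_tissue"
  tab <- tissue_table()
  row <- tab[tab$name == name, ]
  if (nrow(row) == 0L) {
    if (is.null(hu_mean) || is.null(density_mean) || is.null(speed_mean))
      stop("unknown tissue '", name, "'; built-ins are: ",
           paste(tab$name, collapse = ", "), call. = FALSE)
    row <- data.frame(name = name, hu_mean = hu_mean, hu_sd = hu_sd %||% 0,
                      density_mean = density_mean, density_sd = density_sd %||% 0,
                      speed_mean = speed_mean, speed_sd = speed_sd %||% 0)
  }
  if (is.null(row$alpha0_db)) row$alpha0_db <- 0
  for (f in c("hu_mean", "hu_sd", "density_mean", "density_sd",
              "speed_mean", "speed_sd")) {
    override <- get(f)
    if (!is.null(override)) row[[f]] <- override
  }
  spec <- as.list(row)
  if (spec$hu_sd < 0 || spec$density_sd < 0 || spec$speed_sd < 0)
    stop("standard deviations must be non-negative", call. = FALSE)
  if (spec$density_mean <= 0 || spec$speed_mean <= 0)
    stop("mean density and speed must be positive", call. = FALSE)
  structure(spec, class = "tissue_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert a conventional Hounsfield unit to the offset CT-number scale
#'
#' The package works on the offset scale where water is ~1000 and air ~0
#' (consistent with the built-in tissue statistics); conventional CT scanners
#' report HU with water at 0 and air at -1000.
#'
#' @param hu_conventional numeric, conventional HU (water = 0).
#' @return CT number on the offset scale (water = 1000).
#' @export
hu_from_conventional <- function(hu_conventional) hu_conventional + 1000

# Anchor points of the CT-number -> property maps: air, lung, water,
# soft tissue and bone, on the offset scale.
.hu_anchors <- function() {
  data.frame(
    name = c("air", "lung", "water", "soft_tissue", "bone"),
    hu = c(0, 234.5, 1000, 1042.5, 1850),
    speed = c(343, 652.8, WATER_SPEED_25, 1567.1, 2153.9),
    density = c(1.2, 234.0, WATER_DENSITY_25, 1050.4, 1574.4)
  )
}

.hu_interp <- function(hu, what) {
  if (!is.numeric(hu) || any(!is.finite(hu)))
    stop("CT numbers must be finite and numeric", call. = FALSE)
  a <- .hu_anchors()
  rng <- range(a$hu)
  if (any(hu < rng[1] | hu > rng[2])) {
    warning("CT numbers outside [", rng[1], ", ", rng[2],
            "] clamped to the anchor range", call. = FALSE)
    hu <- pmin(pmax(hu, rng[1]), rng[2])
  }
  out <- approx(a$hu, a[[what]], xout = as.vector(hu), rule = 2)$y
  if (!is.null(dim(hu))) dim(out) <- dim(hu)
  out
}

#' Map CT numbers to speed of sound
#'
#' Piecewise-linear interpolation through the air, lung, water, soft-tissue
#' and bone anchors; exact at the anchors, clamped (with a warning) outside
#' the air-to-bone range.
#'
#' @param hu CT number(s) on the offset scale (water ~ 1000).
#' @return sound speed in m/s.
#' @export
hu_to_speed <- function(hu) .hu_interp(hu, "speed")

#' Map CT numbers to mass density
#'
#' @inheritParams hu_to_speed
#' @return density in kg/m^3.
#' @export
hu_to_density <- function(hu) .hu_interp(hu, "density")

#' Thermoacoustic parameters of a material
#'
#' The quantities entering the Grueneisen coefficient: sound speed, thermal
#' expansion coefficient, specific heat capacity, plus the mass density used
#' when converting dose to pressure. Defaults are water-like values
#' calibrated so that 1.0 cGy deposited in water-equivalent tissue yields an
#' initial pressure of ~1.2 Pa.
#'
#' @param c sound speed, m/s (> 0).
#' @param beta volumetric thermal expansion coefficient, 1/K.
#' @param cp specific heat capacity, J/(K kg) (> 0).
#' @param rho mass density, kg/m^3 (> 0).
#' @return an object of class `thermo_params`.
#' @export
thermo_params <- function(c = WATER_SPEED_25, beta = 2.24e-4, cp = 4178,
                          rho = WATER_DENSITY_25) {
  if (!all(is.finite(c(c, beta, cp, rho))))
    stop("thermoacoustic parameters must be finite", call. = FALSE)
  if (c <= 0 || rho <= 0) stop("c and rho must be positive", call. = FALSE)
  if (cp <= 0) stop("cp must be positive", call. = FALSE)
  structure(list(c = c, beta = beta, cp = cp, rho = rho),
            class = "thermo_params")
}

#' Grueneisen coefficient
#'
#' Dimensionless efficiency of converting deposited thermal energy into
#' pressure: c^2 * beta / cp.
#'
#' @param params a [thermo_params()] object.
#' @return the Grueneisen coefficient (dimensionless).
#' @examples
#' gruneisen(thermo_params(c = 1498, beta = 2.57e-4, cp = 4178))  # ~0.138
#' @export
gruneisen <- function(params) {
  stopifnot(inherits(params, "thermo_params"))
  params$c^2 * params$beta / params$cp
}

#' Power-law acoustic absorption
#'
#' Frequency power-law attenuation alpha(omega) = alpha0 * omega^d, in Np/m
#' with omega in rad/s. The default exponent d = 1.05 is a value commonly
#' used for soft tissue.
#'
#' @param alpha0 attenuation prefactor, Np/((rad/s)^d m), >= 0.
#' @param d power-law exponent (dimensionless).
#' @return an object of class `attenuation_law`.
#' @export
attenuation_law <- function(alpha0 = 0, d = 1.05) {
  if (!is.numeric(alpha0) || any(alpha0 < 0) || any(!is.finite(alpha0)))
    stop("alpha0 must be finite and non-negative", call. = FALSE)
  stopifnot(is.numeric(d), length(d) == 1L, is.finite(d))
  structure(list(alpha0 = alpha0, d = d), class = "attenuation_law")
}

#' Evaluate a power-law absorption law
#'
#' @param law an [attenuation_law()] object.
#' @param omega angular frequency, rad/s, >= 0.
#' @return attenuation in Np/m.
#' @export
attenuation_at <- function(law, omega) {
  stopifnot(inherits(law, "attenuation_law"))
  if (!is.numeric(omega) || any(!is.finite(omega)) || any(omega < 0))
    stop("omega must be finite and non-negative", call. = FALSE)
  law$alpha0 * omega^law$d
}
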