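# Phantom factory: voxel grids of acoustic properties for the study's
# thermal-water, homogeneous-tissue, bimaterial and CT-derived media.

# Property floor: 1% of the lung means, applied to Gaussian tails so that no
# voxel becomes non-physical or destabilises the solver.
.SPEED_FLOOR <- 0.01 * 652.8
.DENSITY_FLOOR <- 0.01 * 234.0

.as_vol <- function(x) {
  if (is.null(dim(x))) dim(x) <- c(length(x), 1L, 1L)
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 3L) stop("property arrays must be 2-D or 3-D", call. = FALSE)
  x
}

#' Voxel grid of acoustic material properties
#'
#' The propagation medium: per-voxel speed of sound and mass density on an
#' isotropic grid, with optional per-voxel absorption prefactor, tissue
#' labels and CT numbers. A third dimension of 1 selects 2-D mode; positions
#' are cell-centred, so voxel `i` is centred at `(i - 0.5) * spacing` mm.
#'
#' @param speed per-voxel sound speed, m/s (matrix or 3-D array, all > 0).
#' @param density per-voxel density, kg/m^3 (same shape, all > 0).
#' @param spacing isotropic voxel size in mm (> 0).
#' @param alpha0 optional per-voxel power-law absorption prefactor,
#'   Np/((rad/s)^d m) (scalar or same shape).
#' @param labels optional integer per-voxel tissue id (same shape).
#' @param hu optional per-voxel CT number on the offset scale (same shape).
#' @return an object of class `medium_grid`.
#' @export
medium_grid <- function(speed, density, spacing = 1, alpha0 = NULL,
                        labels = NULL, hu = NULL) {
  speed <- .as_vol(speed); density <- .as_vol(density)
  if (!identical(dim(speed), dim(density)))
    stop("speed and density must share a shape", call. = FALSE)
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("spacing must be a positive scalar (mm)", call. = FALSE)
  if (any(!is.finite(speed)) || any(speed <= 0))
    stop("speed must be finite and positive everywhere", call. = FALSE)
  if (any(!is.finite(density)) || any(density <= 0))
    stop("density must be finite and positive everywhere", call. = FALSE)
  for (nm in c("alpha0", "labels", "hu")) {
    val <- get(nm)
    if (!is.null(val)) {
      if (length(val) == 1L) val <- array(val, dim(speed))
      val <- .as_vol(val)
      if (!identical(dim(val), dim(speed)))
        stop(nm, " must match the grid shape", call. = FALSE)
      assign(nm, val)
    }
  }
  structure(list(speed = speed, density = density, alpha0 = alpha0,
                 labels = labels, hu = hu, spacing = spacing,
                 shape = dim(speed)),
            class = "medium_grid")
}

#' @export
print.medium_grid <- function(x, ...) {
  cat("<medium_grid> ", paste(x$shape, collapse = " x "),
      " voxels @ ", x$spacing, " mm\n", sep = "")
  cat("  speed  : ", round(min(x$speed), 1), "-", round(max(x$speed), 1), " m/s\n", sep = "")
  cat("  density: ", round(min(x$density), 1), "-", round(max(x$density), 1), " kg/m^3\n", sep = "")
  invisible(x)
}

#' Phantom construction recipe
#'
#' @param kind phantom family: `"thermal_water"`, `"homogeneous"`,
#'   `"bimaterial"` or `"ct_volume"`.
#' @param tissues one or two tissues, as names or [tissue_spec()] objects
#'   (a list for two); unused for thermal water.
#' @param heterogeneity `"uniform"` (all voxels at the tissue means) or
#'   `"nonuniform"` (voxel-wise Gaussian variation with the tissue SDs).
#' @param temperature_sd spatial temperature standard deviation in degC
#'   (thermal water only; the replication studies use 0, 5, 10 and 15).
#' @param shape grid shape in voxels, length 2 or 3 (third entry 1 = 2-D).
#' @param spacing isotropic voxel size, mm.
#' @param seed RNG seed for the voxel draws (NULL = current RNG stream).
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(kind, tissues = NULL,
                           heterogeneity = c("uniform", "nonuniform"),
                           temperature_sd = 0, shape = c(100, 100),
                           spacing = 1, seed = NULL) {
  kind <- match.arg(kind, c("thermal_water", "homogeneous", "bimaterial", "ct_volume"))
  heterogeneity <- match.arg(heterogeneity)
  if (!is.numeric(temperature_sd) || temperature_sd < 0)
    stop("temperature_sd must be >= 0", call. = FALSE)
  if (length(shape) == 2L) shape <- c(shape, 1L)
  stopifnot(length(shape) == 3L, all(shape >= 1), spacing > 0)
  structure(list(kind = kind, tissues = tissues, heterogeneity = heterogeneity,
                 temperature_sd = temperature_sd, shape = as.integer(shape),
                 spacing = spacing, seed = seed),
            class = "phantom_config")
}

#' Water phantom with spatial temperature heterogeneity
#'
#' Draws per-voxel temperatures i.i.d. Normal(25, sd^2) degC around the
#' 25 degC reference, winsorised symmetrically to [0.5, 49.5] degC so every
#' voxel stays inside the water property models' validity range while the
#' 25 degC spatial mean is preserved exactly in expectation, then converts
#' voxel-wise to speed of sound and density. Because the conversion curves
#' are nonlinear, the converted fields are re-centred on the 25 degC
#' reference values (1498 m/s, 997 kg/m^3) so that temperature
#' heterogeneity does not alter the bulk medium properties -- the study
#' isolates intra-medium heterogeneity from bulk changes.
#'
#' @param config a [phantom_config()] with `kind = "thermal_water"`.
#' @return a [medium_grid()].
#' @export
make_thermal_water_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  if (config$kind != "thermal_water")
    stop("config$kind must be 'thermal_water'", call. = FALSE)
  sdt <- config$temperature_sd
  n <- prod(config$shape)
  temp <- with_seed(config$seed, {
    if (sdt == 0) rep(25, n) else pmin(pmax(rnorm(n, 25, sdt), 0.5), 49.5)
  })
  dim(temp) <- config$shape
  speed <- water_speed_of_sound(temp)
  density <- water_density(temp)
  if (sdt > 0) {
    # The temperature-to-speed curve is concave, so a zero-mean temperature
    # fluctuation would otherwise lower the *bulk* sound speed by several
    # m/s at sd = 15 degC. The study isolates intra-medium heterogeneity
    # from bulk changes, so the converted fields are re-centred on the
    # 25 degC reference values (variances untouched).
    speed <- speed + (WATER_SPEED_25 - mean(speed))
    density <- density + (WATER_DENSITY_25 - mean(density))
  }
  medium_grid(speed, density, spacing = config$spacing)
}

.as_tissue_spec <- function(x) {
  if (inherits(x, "tissue_spec")) x else tissue_spec(x)
}

# One standard-normal field drives CT number, density and speed jointly:
# per-tissue linear relations calibrated to the built-in (mean, SD) pairs,
# so a generated phantom reproduces all tissue statistics in expectation.
.tissue_fields <- function(spec, z) {
  hu <- spec$hu_mean + z * spec$hu_sd
  speed <- spec$speed_mean + z * spec$speed_sd
  density <- spec$density_mean + z * spec$density_sd
  n_clamped <- sum(speed < .SPEED_FLOOR | density < .DENSITY_FLOOR)
  if (n_clamped > 0)
    message(n_clamped, " voxel(s) clamped to the physical property floor")
  list(hu = hu, speed = pmax(speed, .SPEED_FLOOR),
       density = pmax(density, .DENSITY_FLOOR))
}

#' Homogeneous single-tissue phantom
#'
#' Uniform mode fills the grid with the tissue's mean properties; nonuniform
#' mode draws voxel-wise Gaussian variation with the tissue's CT-number,
#' density and speed standard deviations (one standard-normal draw per voxel
#' drives all three, so the printed tissue statistics are reproduced in
#' expectation). Properties are floored at 1% of the lung means.
#'
#' @param config a [phantom_config()] with `kind = "homogeneous"` and one
#'   tissue name in `tissues`.
#' @return a [medium_grid()] with the CT-number field stored in `$hu`.
#' @export
make_tissue_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  if (config$kind != "homogeneous")
    stop("config$kind must be 'homogeneous'", call. = FALSE)
  if (length(config$tissues) != 1L)
    stop("exactly one tissue name is required", call. = FALSE)
  spec <- .as_tissue_spec(config$tissues[[1]])
  n <- prod(config$shape)
  z <- if (config$heterogeneity == "uniform") rep(0, n) else
    with_seed(config$seed, rnorm(n))
  f <- .tissue_fields(spec, z)
  g <- lapply(f, function(x) { dim(x) <- config$shape; x })
  medium_grid(g$speed, g$density, spacing = config$spacing,
              alpha0 = array(alpha0_np_from_db(spec$alpha0_db), config$shape),
              labels = array(1L, config$shape), hu = g$hu)
}

#' Two-material phantom split at the domain midpoint
#'
#' The grid is split by a plane perpendicular to the first (source-detector)
#' axis at the domain midpoint; the first named tissue fills the lower-x
#' half (the Bragg-peak side), the second the upper-x half. Each half obeys
#' the same uniform/nonuniform rules as [make_tissue_phantom()].
#'
#' @param config a [phantom_config()] with `kind = "bimaterial"` and two
#'   distinct tissue names in `tissues`.
#' @return a [medium_grid()] with `labels` 1 and 2 marking the halves.
#' @export
make_bimaterial_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  if (config$kind != "bimaterial")
    stop("config$kind must be 'bimaterial'", call. = FALSE)
  if (length(config$tissues) != 2L)
    stop("exactly two tissue names are required", call. = FALSE)
  specs <- lapply(config$tissues, .as_tissue_spec)
  if (identical(specs[[1]]$name, specs[[2]]$name))
    stop("the two tissues must be distinct", call. = FALSE)
  shape <- config$shape
  n <- prod(shape)
  z <- if (config$heterogeneity == "uniform") rep(0, n) else
    with_seed(config$seed, rnorm(n))
  dim(z) <- shape
  half1 <- slice.index(z, 1) <= shape[1] / 2
  out <- list(hu = z, speed = z, density = z, alpha0 = z)  # shapes only
  labels <- array(2L, shape); labels[half1] <- 1L
  for (side in 1:2) {
    mask <- if (side == 1) half1 else !half1
    f <- .tissue_fields(specs[[side]], z[mask])
    out$hu[mask] <- f$hu
    out$speed[mask] <- f$speed
    out$density[mask] <- f$density
    out$alpha0[mask] <- alpha0_np_from_db(specs[[side]]$alpha0_db)
  }
  medium_grid(out$speed, out$density, spacing = config$spacing,
              alpha0 = out$alpha0, labels = labels, hu = out$hu)
}

#' Load a CT volume and convert it to acoustic properties
#'
#' Reads a NIfTI volume (via RNifti) or the package's plain-text CT format
#' (see [write_ct_csv()]) and maps CT numbers voxel-wise to speed and
#' density through the anchor interpolation ([hu_to_speed()],
#' [hu_to_density()]). No resampling is performed.
#'
#' @param path file path (`.nii`/`.nii.gz` or `.csv`).
#' @param scale CT-number scale of the stored values: `"offset"` (water ~
#'   1000) or `"conventional"` (water 0, air -1000). Must be stated
#'   explicitly; there is no safe default for raw volumes.
#' @param spacing voxel size in mm; taken from the NIfTI header when NULL.
#' @return a [medium_grid()] with the CT-number field stored in `$hu`.
#' @export
load_ct_volume <- function(path, scale, spacing = NULL) {
  if (missing(scale))
    stop("the CT-number scale must be declared ('offset' or 'conventional')",
         call. = FALSE)
  scale <- match.arg(scale, c("offset", "conventional"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    hu <- array(as.numeric(img), dim = dim(img))
    if (is.null(spacing)) {
      pd <- RNifti::pixdim(img)
      if (length(unique(round(pd, 6))) != 1L)
        stop("anisotropic voxels are not supported; pass spacing explicitly",
             call. = FALSE)
      spacing <- pd[1]
    }
  } else {
    vol <- read_ct_csv(path)
    hu <- vol$hu
    if (is.null(spacing)) spacing <- vol$spacing
  }
  if (is.null(spacing)) stop("voxel spacing is undeclared", call. = FALSE)
  if (scale == "conventional") hu <- hu_from_conventional(hu)
  medium_grid(hu_to_speed(hu), hu_to_density(hu), spacing = spacing, hu = hu)
}

#' Write / read a CT-like volume as plain text
#'
#' A minimal text container for small CT-like volumes: a header line with
#' the shape and spacing, then one CT number per line in column-major order.
#'
#' @param hu CT-number array (offset scale).
#' @param path output file path.
#' @param spacing voxel size, mm.
#' @return `write_ct_csv` returns `path` invisibly; `read_ct_csv` returns a
#'   list with elements `hu` and `spacing`.
#' @export
write_ct_csv <- function(hu, path, spacing = 1) {
  hu <- .as_vol(hu)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# protorange-ct %d %d %d %.17g",
                     dim(hu)[1], dim(hu)[2], dim(hu)[3], spacing), con)
  writeLines(sprintf("%.17g", as.vector(hu)), con)
  invisible(path)
}

#' @rdname write_ct_csv
#' @export
read_ct_csv <- function(path) {
  header <- readLines(path, n = 1L)
  parts <- strsplit(trimws(header), "\\s+")[[1]]
  if (length(parts) != 6L || parts[1] != "#" || parts[2] != "protorange-ct")
    stop("not a protorange CT text volume (bad header)", call. = FALSE)
  shape <- as.integer(parts[3:5])
  spacing <- as.numeric(parts[6])
  hu <- as.numeric(readLines(path)[-1])
  if (length(hu) != prod(shape))
    stop("voxel count does not match the declared shape", call. = FALSE)
  dim(hu) <- shape
  list(hu = hu, spacing = spacing)
}

#' Synthetic CT-like labelled phantom for detector-placement studies
#'
#' Builds a labelled CT-number volume -- a uniform background tissue with
#' optional spherical inclusions (e.g. an air pocket on the acoustic path)
#' -- and converts it to acoustic properties through the anchor maps. This
#' is a synthetic stand-in for a clinical CT slice, useful for studying how
#' low-density structures between the Bragg peak and a detector distort
#' TOF range estimates.
#'
#' @param shape grid shape in voxels (length 2 or 3).
#' @param spacing voxel size, mm.
#' @param background background CT number (offset scale; default soft
#'   tissue, 1042.5).
#' @param inclusions list of inclusions, each a list with `centre_mm`
#'   (length 2 or 3), `radius_mm` and `hu` (e.g. `hu = 0` for air).
#' @return a [medium_grid()] with `hu` and `labels` set (background 1,
#'   inclusions 2, 3, ... in order).
#' @export
make_ct_like_phantom <- function(shape, spacing = 1, background = 1042.5,
                                 inclusions = list()) {
  if (length(shape) == 2L) shape <- c(shape, 1L)
  hu <- array(background, shape)
  labels <- array(1L, shape)
  if (length(inclusions) > 0) {
    centres_x <- (slice.index(hu, 1) - 0.5) * spacing
    centres_y <- (slice.index(hu, 2) - 0.5) * spacing
    centres_z <- (slice.index(hu, 3) - 0.5) * spacing
    for (k in seq_along(inclusions)) {
      inc <- inclusions[[k]]
      ctr <- inc$centre_mm
      if (length(ctr) == 2L) ctr <- c(ctr, spacing / 2)
      d2 <- (centres_x - ctr[1])^2 + (centres_y - ctr[2])^2 +
        (centres_z - ctr[3])^2
      mask <- d2 <= inc$radius_mm^2
      hu[mask] <- inc$hu
      labels[mask] <- k + 1L
    }
  }
  medium_grid(hu_to_speed(hu), hu_to_density(hu), spacing = spacing,
              labels = labels, hu = hu)
}

# Nearest-neighbour resampling of a medium to a new voxel size (used by the
# solver's convergence probe). Positions are cell-centred in both grids.
resample_grid <- function(medium, new_spacing) {
  stopifnot(inherits(medium, "medium_grid"), new_spacing > 0)
  old <- medium$spacing
  ext <- medium$shape * old                 # physical extent per axis, mm
  new_shape <- pmax(1L, as.integer(round(ext / new_spacing)))
  if (medium$shape[3] == 1L) new_shape[3] <- 1L  # keep 2-D grids 2-D
  idx <- lapply(1:3, function(a) {
    centres <- ((seq_len(new_shape[a])) - 0.5) * new_spacing
    pmin(pmax(ceiling(centres / old), 1L), medium$shape[a])
  })
  pick <- function(x) x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  medium_grid(pick(medium$speed), pick(medium$density), spacing = new_spacing,
              alpha0 = if (!is.null(medium$alpha0)) pick(medium$alpha0),
              labels = if (!is.null(medium$labels)) pick(medium$labels),
              hu = if (!is.null(medium$hu)) pick(medium$hu))
}
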