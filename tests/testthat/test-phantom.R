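# Phantom generators: thermal water, homogeneous/bimaterial tissue, and
# CT-like volumes.

test_that("zero-SD thermal water is the uniform 25 degC reference", {
  pc <- phantom_config("thermal_water", temperature_sd = 0, shape = c(20, 10))
  g <- make_thermal_water_phantom(pc)
  expect_true(all(g$speed == 1498))
  expect_true(all(g$density == 997))
})

test_that("thermal phantoms are seed-deterministic and bulk-preserving", {
  pc <- phantom_config("thermal_water", temperature_sd = 15,
                       shape = c(60, 40), seed = 7)
  g1 <- make_thermal_water_phantom(pc)
  g2 <- make_thermal_water_phantom(pc)
  expect_identical(g1$speed, g2$speed)
  pc2 <- pc; pc2$seed <- 8
  expect_false(identical(make_thermal_water_phantom(pc2)$speed, g1$speed))
  # bulk re-centring: spatial means sit exactly on the reference values
  expect_equal(mean(g1$speed), 1498, tolerance = 1e-12)
  expect_equal(mean(g1$density), 997, tolerance = 1e-12)
  expect_error(phantom_config("thermal_water", temperature_sd = -1), ">= 0")
})

test_that("thermal speed-field SD matches the conversion-curve oracle", {
  pc <- phantom_config("thermal_water", temperature_sd = 15,
                       shape = c(200, 200), seed = 42)
  g <- make_thermal_water_phantom(pc)
  # oracle: the same winsorised temperature law pushed through the scalar
  # conversion on an independent large sample
  set.seed(999)
  t_ref <- pmin(pmax(rnorm(4e5, 25, 15), 0.5), 49.5)
  sd_ref <- sd(water_speed_of_sound(t_ref))
  expect_equal(sd(g$speed), sd_ref, tolerance = 0.05)
  # and the delta-method scale: SD ~ 15 * dc/dT(25), within the winsorised
  # reduction
  slope <- (water_speed_of_sound(25.01) - water_speed_of_sound(24.99)) / 0.02
  expect_lt(abs(sd(g$speed) / (15 * slope) - 0.95), 0.08)
})

test_that("uniform tissue phantoms sit at the tabulated means", {
  for (tn in c("soft_tissue", "bone", "lung")) {
    pc <- phantom_config("homogeneous", tissues = tn, shape = c(20, 10))
    g <- make_tissue_phantom(pc)
    spec <- tissue_spec(tn)
    expect_true(all(g$speed == spec$speed_mean))
    expect_true(all(g$density == spec$density_mean))
    expect_true(all(g$hu == spec$hu_mean))
  }
  expect_error(make_tissue_phantom(
    phantom_config("homogeneous", tissues = "jelly", shape = c(4, 4))),
    "unknown tissue")
})

test_that("nonuniform phantoms reproduce the tabulated statistics", {
  pc <- phantom_config("homogeneous", tissues = "bone",
                       heterogeneity = "nonuniform", shape = c(120, 120),
                       seed = 3)
  g <- make_tissue_phantom(pc)
  spec <- tissue_spec("bone")
  expect_equal(mean(g$speed), spec$speed_mean, tolerance = 0.01)
  expect_equal(sd(g$speed), spec$speed_sd, tolerance = 0.05)
  expect_equal(sd(g$density), spec$density_sd, tolerance = 0.05)
  expect_equal(sd(g$hu), spec$hu_sd, tolerance = 0.05)
})

test_that("a nonuniform phantom with zero SDs equals the uniform one", {
  frozen <- tissue_spec("soft_tissue", hu_sd = 0, density_sd = 0, speed_sd = 0)
  pc_n <- phantom_config("homogeneous", tissues = list(frozen),
                         heterogeneity = "nonuniform", shape = c(30, 20),
                         seed = 5)
  pc_u <- phantom_config("homogeneous", tissues = list(frozen),
                         heterogeneity = "uniform", shape = c(30, 20))
  expect_identical(make_tissue_phantom(pc_n)$speed,
                   make_tissue_phantom(pc_u)$speed)
})

test_that("bimaterial phantoms split at the midpoint with labelled halves", {
  pc <- phantom_config("bimaterial", tissues = c("bone", "lung"),
                       shape = c(130, 60))
  g <- make_bimaterial_phantom(pc)
  expect_identical(sort(unique(as.vector(g$labels))), c(1L, 2L))
  expect_true(all(g$speed[g$labels == 1L] == 2153.9))
  expect_true(all(g$speed[g$labels == 2L] == 652.8))
  # swapping the pair mirrors the labels but preserves the mix of speeds
  pc2 <- phantom_config("bimaterial", tissues = c("lung", "bone"),
                        shape = c(130, 60))
  g2 <- make_bimaterial_phantom(pc2)
  expect_true(all(g2$speed[g2$labels == 1L] == 652.8))
  expect_equal(sort(unique(as.vector(g$speed))),
               sort(unique(as.vector(g2$speed))))
  expect_error(make_bimaterial_phantom(
    phantom_config("bimaterial", tissues = c("bone", "bone"),
                   shape = c(10, 10))), "distinct")
})

test_that("uniform and nonuniform phantoms share property means", {
  pc_u <- phantom_config("bimaterial", tissues = c("soft_tissue", "lung"),
                         shape = c(80, 80))
  pc_n <- pc_u; pc_n$heterogeneity <- "nonuniform"; pc_n$seed <- 21
  g_u <- make_bimaterial_phantom(pc_u)
  g_n <- make_bimaterial_phantom(pc_n)
  expect_equal(mean(g_n$speed), mean(g_u$speed), tolerance = 0.01)
  expect_equal(mean(g_n$density), mean(g_u$density), tolerance = 0.02)
})

test_that("generated grids satisfy the medium invariants", {
  for (pc in list(
    phantom_config("thermal_water", temperature_sd = 15, shape = c(40, 30),
                   seed = 1),
    phantom_config("homogeneous", tissues = "lung",
                   heterogeneity = "nonuniform", shape = c(40, 30), seed = 1),
    phantom_config("bimaterial", tissues = c("bone", "lung"),
                   heterogeneity = "nonuniform", shape = c(40, 30), seed = 1))) {
    g <- switch(pc$kind,
                thermal_water = make_thermal_water_phantom(pc),
                homogeneous = make_tissue_phantom(pc),
                bimaterial = make_bimaterial_phantom(pc))
    expect_true(all(g$speed > 0) && all(g$density > 0))
    expect_identical(dim(g$speed), g$shape)
    expect_identical(dim(g$density), g$shape)
  }
})

test_that("CT text volumes round-trip bit-exactly", {
  hu <- array(runif(24, 200, 1800), c(4, 3, 2))
  path <- tempfile(fileext = ".csv")
  write_ct_csv(hu, path, spacing = 2)
  vol <- read_ct_csv(path)
  expect_identical(vol$hu, hu)
  expect_identical(vol$spacing, 2)
  g1 <- load_ct_volume(path, scale = "offset")
  expect_identical(g1$speed, hu_to_speed(hu))
  expect_identical(g1$density, hu_to_density(hu))
})

test_that("NIfTI volumes round-trip through the property pipeline", {
  hu <- array(1000, c(6, 5, 4))
  path <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(hu, pixdim = c(1, 1, 1)), path)
  g <- load_ct_volume(path, scale = "offset")
  expect_true(all(g$speed == 1498))  # all-water volume
  expect_true(all(g$density == 997))
})

test_that("CT loading demands a declared scale and an existing file", {
  expect_error(load_ct_volume("nope.csv", scale = "offset"), "not found")
  path <- tempfile(fileext = ".csv")
  write_ct_csv(array(0, c(2, 2, 1)), path)  # conventional 0 = water
  expect_error(load_ct_volume(path), "scale")
  g <- load_ct_volume(path, scale = "conventional")
  expect_true(all(g$speed == 1498))
})

test_that("an air pocket on the path lowers the path-averaged speed", {
  control <- make_ct_like_phantom(c(80, 40), background = 1042.5)
  pocket <- make_ct_like_phantom(c(80, 40), background = 1042.5,
                                 inclusions = list(list(centre_mm = c(40, 20),
                                                        radius_mm = 6, hu = 0)))
  a <- path_average_speed(control, c(10.5, 19.5), c(70.5, 19.5))$c_avg
  b <- path_average_speed(pocket, c(10.5, 19.5), c(70.5, 19.5))$c_avg
  expect_equal(a, 1567.1)
  expect_lt(b, a)
})

test_that("resampling preserves physical extent and properties", {
  pc <- phantom_config("bimaterial", tissues = c("bone", "lung"),
                       shape = c(40, 20))
  g <- make_bimaterial_phantom(pc)
  g2 <- protorange:::resample_grid(g, 0.5)
  expect_identical(g2$shape, c(80L, 40L, 1L))
  expect_identical(sort(unique(as.vector(g2$speed))),
                   sort(unique(as.vector(g$speed))))
})
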