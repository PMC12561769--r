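# Time-of-flight analysis: peak picking, validity gating, path-averaged
# speed, and the range arithmetic against the published tables.

trace_of <- function(samples, dt = 1e-8, t0 = dt) {
  pressure_trace(samples, dt = dt, t0 = t0)
}

test_that("peak detection returns t0 + (k-1) dt for the maximum sample", {
  s <- c(0, 1, 3, 2, 1, 0.5)
  tr <- trace_of(s)
  expect_equal(detect_peak_time(tr, tie_tol = 0), tr$t0 + 2 * tr$dt)
})

test_that("equal maxima resolve to the earliest, with and without tolerance", {
  s <- c(0, 2, 1, 2, 0)
  expect_equal(detect_peak_time(trace_of(s), tie_tol = 0), 1e-8 + 1e-8)
  expect_equal(detect_peak_time(trace_of(s)), 1e-8 + 1e-8)
  # a slightly smaller early lobe within the tolerance also wins
  s2 <- c(0, 1.99, 0, 2, 0)
  expect_equal(detect_peak_time(trace_of(s2), tie_tol = 0.02), 2e-8)
  expect_equal(detect_peak_time(trace_of(s2), tie_tol = 0), 4e-8)
})

test_that("an all-zero trace has no detectable signal", {
  expect_error(detect_peak_time(trace_of(rep(0, 10))), "no signal")
})

test_that("the validity gate applies the 0.2 mPa peak-to-valley rule", {
  expect_false(signal_is_valid(trace_of(rep(5e-4, 10))))       # constant
  expect_true(signal_is_valid(trace_of(c(0.15e-3, -0.10e-3)))) # span 0.25 mPa
  expect_false(signal_is_valid(trace_of(c(0.1e-3, 0))))        # span 0.10 mPa
})

test_that("path-averaged speed is exact on uniform and bimaterial media", {
  w <- water_grid(nx = 60, ny = 40)
  expect_equal(path_average_speed(w, c(10.5, 19.5), c(50.5, 19.5))$c_avg, 1498)

  soft <- make_tissue_phantom(phantom_config("homogeneous",
                                             tissues = "soft_tissue",
                                             shape = c(60, 40)))
  expect_equal(path_average_speed(soft, c(10.5, 19.5), c(50.5, 19.5))$c_avg,
               1567.1)

  bl <- make_bimaterial_phantom(phantom_config("bimaterial",
                                               tissues = c("bone", "lung"),
                                               shape = c(130, 60)))
  # 50 mm of each material: the arithmetic mean of the tabulated speeds
  pa <- path_average_speed(bl, c(15.5, 29.5), c(115.5, 29.5))
  expect_equal(pa$c_avg, (2153.9 + 652.8) / 2, tolerance = 1e-12)
  expect_equal(pa$length_mm, 100)
  expect_identical(nrow(pa$profile), 100L)

  bt <- make_bimaterial_phantom(phantom_config("bimaterial",
                                               tissues = c("bone", "soft_tissue"),
                                               shape = c(130, 60)))
  expect_equal(path_average_speed(bt, c(15.5, 29.5), c(115.5, 29.5))$c_avg,
               1860.5, tolerance = 1e-12)
})

test_that("path averaging is endpoint-symmetric and rejects empty paths", {
  pc <- phantom_config("bimaterial", tissues = c("bone", "lung"),
                       heterogeneity = "nonuniform", shape = c(130, 60),
                       seed = 2)
  g <- make_bimaterial_phantom(pc)
  a <- path_average_speed(g, c(15.5, 29.5), c(115.5, 29.5))$c_avg
  b <- path_average_speed(g, c(115.5, 29.5), c(15.5, 29.5))$c_avg
  expect_equal(a, b, tolerance = 1e-12)
  expect_error(path_average_speed(g, c(10, 10), c(10, 10)), "zero-length")
})

test_that("HU-first averaging differs from speed averaging on mixed paths", {
  bl <- make_bimaterial_phantom(phantom_config("bimaterial",
                                               tissues = c("bone", "lung"),
                                               shape = c(130, 60)))
  c_speed <- path_average_speed(bl, c(15.5, 29.5), c(115.5, 29.5))$c_avg
  c_hu <- path_average_speed(bl, c(15.5, 29.5), c(115.5, 29.5),
                             method = "hu_mean")$c_avg
  # mean CT number of bone+lung sits near the soft-tissue anchor, so the
  # nonlinear map returns ~1567 m/s instead of the 1403 m/s speed mean
  expect_gt(abs(c_hu - c_speed), 100)
})

test_that("TOF distances reproduce the uniform-phantom reference table", {
  # printed TOFs x tabulated mean speeds, at the tables' printed precision
  # (the soft-tissue/lung product is 122.9159, printed as 122.91)
  expect_lt(abs(tof_to_distance(101.05e-6, (2153.9 + 652.8) / 2) - 141.81),
            0.0101)
  expect_lt(abs(tof_to_distance(56.07e-6, (2153.9 + 1567.1) / 2) - 104.32),
            0.0101)
  expect_lt(abs(tof_to_distance(110.74e-6, (1567.1 + 652.8) / 2) - 122.91),
            0.0101)
  expect_identical(tof_to_distance(0, 1500), 0)
  expect_error(tof_to_distance(-1, 1500), ">= 0")
  expect_error(tof_to_distance(1, 0), "> 0")
})

test_that("range errors reproduce the clinical reference values", {
  expect_equal(range_error(94.7, 93.97),
               data.frame(delta_d = 0.73, epsilon_d = 0.77),
               tolerance = 0.005)
  expect_equal(range_error(121.02, 117.63)$delta_d, 3.39, tolerance = 0.005)
  expect_equal(range_error(121.02, 117.63)$epsilon_d, 2.80, tolerance = 0.005)
  expect_identical(range_error(50, 50), data.frame(delta_d = 0, epsilon_d = 0))
  expect_error(range_error(0, 10), "positive")
})

test_that("the TOF identities hold exactly for arbitrary inputs", {
  set.seed(4)
  for (i in 1:30) {
    t_peak <- runif(1, 1e-6, 3e-4)
    c_avg <- runif(1, 300, 3000)
    d_real <- runif(1, 10, 400)
    est <- range_estimate(t_peak, c_avg, d_real)
    expect_identical(est$d_tof, t_peak * c_avg * 1e3)
    expect_identical(est$delta_d, abs(d_real - est$d_tof))
    expect_identical(est$epsilon_d, est$delta_d / d_real * 100)
    expect_true(all(c(est$d_tof, est$delta_d, est$epsilon_d) >= 0))
  }
})
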