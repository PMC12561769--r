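# Shared fixtures: small media and quick solver settings for unit tests.

water_grid <- function(nx = 150, ny = 80, spacing = 1) {
  medium_grid(array(1498, c(nx, ny, 1)), array(997, c(nx, ny, 1)),
              spacing = spacing)
}

quick_cfg <- function(n_steps, dt = 4e-8, pml_thickness = 10, ...) {
  solver_config(dt = dt, n_steps = n_steps, pml_thickness = pml_thickness,
                precision = "double", ...)
}

point_source <- function(pos, dt = 4e-8, amplitude = 12e-3, width = 10e-6) {
  source_term(matrix(pos, nrow = 1), amplitude, gaussian_pulse(width, dt))
}

# Small fast study configuration (reduced geometry): 40 mm separation.
tiny_study_cfg <- function(study, ...) {
  study_config(study, separation = 40, margin = 10, lateral = 40,
               dt = 4e-8, ...)
}
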