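# shared fixtures, built in code

default_medium <- function() chip_medium()

# quasi-1-D column grid with a full-width left inlet (distribution manifold)
column_grid <- function(nx = 800, ny = 3) {
  g <- build_grid(chip_geometry(port_diameter = 0.018), nx, ny, "single_inlet")
  g$edges$label[g$edges$side == "left"] <- "o2_inlet_normoxia"
  g
}

# diffusion-only column: left face held at c0, everything else walls
diffusion_column_boundaries <- function(c0 = 5.45) {
  list(o2_inlet_normoxia = bc_concentration(c0))
}

# cache for the (moderately expensive) default calibration sweep, shared by
# the calibration, synthetic-data and acceptance tests
.fixture_env <- new.env(parent = emptyenv())

cached_calibration <- function() {
  if (is.null(.fixture_env$curve)) {
    .fixture_env$scenario <- calibration_scenario()
    .fixture_env$curve <- sweep_diffusion(config = .fixture_env$scenario)
    .fixture_env$fit <- fit_calibration(.fixture_env$curve)
  }
  list(scenario = .fixture_env$scenario, curve = .fixture_env$curve,
       fit = .fixture_env$fit)
}

# noiseless forward probe reading at a diffusivity ratio (cached per ratio)
forward_probe <- function(ratio) {
  key <- sprintf("fw_%g", ratio)
  if (is.null(.fixture_env[[key]])) {
    cal <- cached_calibration()
    .fixture_env[[key]] <- gen_probe_readings(
      D_true = ratio * cal$scenario$medium$D_OM, config = cal$scenario,
      positions = cal$scenario$probe_x, noise_sd = 0, seed = 1
    )$o2_mg_per_l
  }
  .fixture_env[[key]]
}

# steady two-inlet oxygen solve at a given diffusivity ratio
two_inlet_steady <- function(ratio, nx = 101, ny = 101,
                             influx_mL_s = 0.007, sink_rate = 0) {
  g <- build_grid(chip_geometry(), nx, ny, "two_inlet_oxygen")
  mat <- hydrogel_material(3, D_ratio = ratio)
  med <- default_medium()
  bnd <- default_boundaries(g, med, inlet_velocity = 0.1,
                            influx_mL_s = influx_mL_s)
  flow <- solve_darcy_flow(g, mat, med, bnd)
  fld <- solve_steady(g, flow, mat, med, bnd, sink_rate = sink_rate)
  list(grid = g, material = mat, medium = med, boundaries = bnd,
       flow = flow, field = fld)
}

transverse_mid_profile <- function(solved) {
  g <- solved$grid
  extract_profile(solved$field, c(g$width / 2, 0), c(g$width / 2, g$depth),
                  n = g$ny)
}
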