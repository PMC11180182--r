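test_that("diffusion column matches the erfc similarity solution", {
  g <- column_grid(800, 3)
  med <- default_medium()
  mat <- hydrogel_material(3, porosity = 1, D_ratio = 1)  # liquid column
  bnd <- diffusion_column_boundaries(5.45)
  fld <- run_transient(g, flow_field_zero(g), mat, med, bnd,
                       t_end = 60, dt = 0.05)
  # compare at x in [0.1, 2] mm (at/above the first cell center)
  prof <- extract_profile(fld, c(1e-4, 0.01), c(2e-3, 0.01), n = 20)
  xs <- 1e-4 + prof$positions
  ana <- 5.45 * (2 * stats::pnorm(-xs / sqrt(2 * 2.88e-9 * 60)))  # erfc form
  expect_lt(max(abs(prof$values - ana)) / 5.45, 1e-3)
  # diffusion alone cannot reach the 10-mm probe point in one minute
  far <- extract_profile(fld, c(0.0099, 0.01), c(0.0101, 0.01), n = 3)
  expect_lt(far$values[2] / 5.45, 1e-6)
})

test_that("closed no-flux system conserves a uniform field exactly", {
  g <- column_grid(20, 4)
  g$edges$label[] <- "wall"
  med <- default_medium()
  mat <- hydrogel_material(2, D_ratio = 0.5)
  fld <- run_transient(g, flow_field_zero(g), mat, med, list(),
                       t_end = 30, dt = 1, c0 = 1)
  expect_equal(max(abs(fld$c - 1)), 0, tolerance = 1e-12)
})

test_that("uniform boundary data give the uniform steady field", {
  s <- two_inlet_steady(0.8, nx = 31, ny = 31, influx_mL_s = 0)
  bnd <- s$boundaries
  bnd$o2_inlet_hypoxia <- bc_concentration(5.45)
  bnd$influx_strip <- NULL
  fld <- solve_steady(s$grid, s$flow, s$material, s$medium, bnd)
  expect_equal(max(abs(fld$c - 5.45)), 0, tolerance = 1e-9)
})

test_that("mirror-symmetric contacts give an antisymmetric steady field", {
  # zero-flow gel between a 5.45 contact (top) and a 0 contact (bottom)
  g <- build_grid(chip_geometry(), 21, 40, "single_inlet")
  g$edges$label[] <- "wall"
  g$edges$label[g$edges$side == "top"] <- "hot"
  g$edges$label[g$edges$side == "bottom"] <- "cold"
  med <- default_medium()
  mat <- hydrogel_material(3, D_ratio = 0.5)
  fld <- solve_steady(g, flow_field_zero(g), mat, med,
                      list(hot = bc_concentration(5.45),
                           cold = bc_concentration(0)))
  s <- fld$c + fld$c[, rev(seq_len(g$ny))]
  expect_lt(max(abs(s - 5.45)) / 5.45, 0.01)
})

test_that("profile extraction is exact on uniform and linear fields", {
  g <- build_grid(chip_geometry(), 20, 20, "single_inlet")
  uni <- structure(list(c = matrix(2, 20, 20), t = Inf, species = "oxygen",
                        grid = g), class = "conc_field")
  p <- extract_profile(uni, c(0.002, 0.002), c(0.018, 0.017), n = 7)
  expect_equal(p$values, rep(2, 7))

  lin <- structure(list(c = outer(rep(1, 20), g$yc), t = Inf,
                        species = "oxygen", grid = g), class = "conc_field")
  pl <- extract_profile(lin, c(0.01, 0.001), c(0.01, 0.019), n = 9)
  expect_equal(linearity_r2(pl), 1, tolerance = 1e-12)
  expect_equal(pl$values, 0.001 + pl$positions, tolerance = 1e-12)

  p11 <- extract_profile(uni, c(0, 0.01), c(0.020, 0.01), n = 11)
  expect_equal(p11$positions, seq(0, 0.020, by = 0.002))
  expect_error(extract_profile(uni, c(-0.001, 0.01), c(0.01, 0.01), n = 5),
               "inside the domain")
})

test_that("discrete maximum principle holds under randomized boundary data", {
  med <- default_medium()
  for (rep in 1:8) {
    set.seed(100 + rep)
    g <- build_grid(chip_geometry(), 12, 12, "single_inlet")
    g$edges$label[g$edges$side == "left"] <- "in1"
    g$edges$label[g$edges$side == "bottom"] <- "fix1"
    g$edges$label[g$edges$side == "right"] <- "out1"
    cin <- runif(1, 0, 8); cfix <- runif(1, 0, 8)
    bnd <- list(in1 = bc_velocity_inlet(10^runif(1, -6, -4), cin),
                fix1 = bc_concentration(cfix),
                out1 = bc_outflow(0))
    mat <- hydrogel_material(sample(0:3, 1), D_ratio = runif(1, 0.05, 1))
    fl <- solve_darcy_flow(g, mat, med, bnd)
    fld <- solve_steady(g, fl, mat, med, bnd)
    expect_gte(min(fld$c), min(cin, cfix) - 1e-9)
    expect_lte(max(fld$c), max(cin, cfix) + 1e-9)
    bal <- steady_flux_balance(fld, g, fl, mat, med, bnd)
    expect_lt(bal$imbalance, 1e-6)
  }
})

test_that("transient L2 error against the analytic solution shrinks with the grid", {
  med <- default_medium()
  errs <- sapply(c(26, 51, 101), function(nx) {
    g <- column_grid(nx, 3)
    mat <- hydrogel_material(3, porosity = 1, D_ratio = 1)
    fld <- run_transient(g, flow_field_zero(g), mat,
                         med, diffusion_column_boundaries(1), t_end = 60,
                         dt = 0.1)
    xs <- g$xc[g$xc < 0.004]
    num <- fld$c[seq_along(xs), 2]
    ana <- 2 * stats::pnorm(-xs / sqrt(2 * 2.88e-9 * 60))
    sqrt(mean((num - ana)^2))
  })
  expect_true(all(diff(errs) < 0))
})

test_that("long transients converge to the steady solution", {
  g <- column_grid(60, 3)
  med <- default_medium()
  mat <- hydrogel_material(3, D_ratio = 0.5)
  bnd <- default_boundaries(g, med, inlet_velocity = 1.15e-4)
  fl <- solve_darcy_flow(g, mat, med, bnd)
  st <- solve_steady(g, fl, mat, med, bnd)
  tr <- run_transient(g, fl, mat, med, bnd, t_end = 500, dt = "auto")
  expect_lt(max(abs(tr$c - st$c)), 1e-6 * max(st$c))
})

test_that("a fixed time step violating the CFL limit is rejected with the bound", {
  g <- column_grid(100, 3)
  med <- default_medium()
  mat <- hydrogel_material(3, D_ratio = 0.5)
  bnd <- default_boundaries(g, med, inlet_velocity = 1e-3)
  fl <- solve_darcy_flow(g, mat, med, bnd)
  expect_error(run_transient(g, fl, mat, med, bnd, t_end = 10, dt = 10),
               "admissible dt")
})
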