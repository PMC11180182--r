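test_that("closed-form Darcy pressure drop matches hand evaluation", {
  # working chip at the 4.71 mL/min supply-channel flow
  dp <- darcy_pressure_drop(Q = 7.85e-8, k = 1 / 7.5e11, A = 1e-4, L = 0.02,
                            mu = 0.958e-3)
  expect_equal(dp, 1.128e4, tolerance = 0.01)
  expect_equal(darcy_pressure_drop(0, 1e-12, 1e-4, 0.02, 1e-3), 0)
  # linearity in Q and inverse scaling in k
  expect_equal(darcy_pressure_drop(2e-8, 1e-12, 1e-4, 0.02, 1e-3),
               2 * darcy_pressure_drop(1e-8, 1e-12, 1e-4, 0.02, 1e-3))
  expect_equal(darcy_pressure_drop(1e-8, 3e-12, 1e-4, 0.02, 1e-3),
               darcy_pressure_drop(1e-8, 1e-12, 1e-4, 0.02, 1e-3) / 3)
  expect_error(darcy_pressure_drop(1e-8, 0, 1e-4, 0.02, 1e-3), "positive")
})

test_that("field solve conserves mass and recovers plug flow", {
  g <- column_grid(41, 5)
  med <- default_medium()
  mat <- hydrogel_material(3, D_ratio = 0.8)
  bnd <- default_boundaries(g, med, inlet_velocity = 1e-4)
  fl <- solve_darcy_flow(g, mat, med, bnd)
  expect_lt(fl$mass_error, 1e-8)
  expect_equal(fl$inflow, 1e-4 * 0.02 * 0.005, tolerance = 1e-10)
  # plug: interior u uniform at the inlet velocity, v ~ 0
  expect_equal(max(abs(fl$u - 1e-4)) / 1e-4, 0, tolerance = 1e-8)
  expect_lt(max(abs(fl$v)), 1e-12)
  # center-to-center pressure drop equals the closed form over (nx-1) dx
  dp_num <- mean(fl$P[1, ]) - mean(fl$P[g$nx, ])
  dp_ref <- darcy_pressure_drop(fl$inflow, mat$permeability, 0.02 * 0.005,
                                (g$nx - 1) * g$dx, med$viscosity)
  expect_equal(dp_num, dp_ref, tolerance = 1e-10)
})

test_that("zero inlet velocity yields zero flow; missing outlet errors", {
  g <- column_grid(11, 5)
  med <- default_medium()
  mat <- hydrogel_material(3)
  bnd <- default_boundaries(g, med, inlet_velocity = 0)
  fl <- solve_darcy_flow(g, mat, med, bnd)
  expect_lt(max(abs(fl$u)) + max(abs(fl$v)), 1e-15)
  expect_error(
    solve_darcy_flow(g, mat, med, list(o2_inlet_normoxia = bc_velocity_inlet(1e-4, 0))),
    "no outflow")
})

test_that("parallel permeability layers split flux 1:2 under a common head", {
  g <- column_grid(101, 10)
  med <- default_medium()
  k0 <- 1 / 7.5e11
  kmat <- matrix(k0, 101, 10)
  kmat[, 6:10] <- 2 * k0
  mat <- hydrogel_material(3)
  mat$permeability <- kmat
  bnd <- list(o2_inlet_normoxia = bc_outflow(P = 100), o2_outlet = bc_outflow(0))
  fl <- solve_darcy_flow(g, mat, med, bnd)
  q_lo <- sum(fl$uf[102, 1:5]); q_hi <- sum(fl$uf[102, 6:10])
  expect_equal(q_hi / q_lo, 2, tolerance = 0.01)
})

test_that("smoothly varying permeability converges monotonically to the analytic drop", {
  med <- default_medium()
  errs <- sapply(c(51, 101, 201), function(nx) {
    g <- column_grid(nx, 3)
    k0 <- 1 / 7.5e11
    # k(x) linear from k0 to 3 k0 across the column
    kx <- k0 * (1 + 2 * (g$xc / g$width))
    mat <- hydrogel_material(3)
    mat$permeability <- matrix(kx, nx, 3)
    bnd <- default_boundaries(g, med, inlet_velocity = 1e-4)
    fl <- solve_darcy_flow(g, mat, med, bnd)
    # analytic: dP = (Q mu / A) * int dx / k(x) between the two cell centers
    a <- g$xc[1]; b <- g$xc[nx]
    kfun_int <- (g$width / (2 * k0)) * log((1 + 2 * b / g$width) / (1 + 2 * a / g$width))
    dp_ref <- (fl$inflow * med$viscosity / (0.02 * 0.005)) * kfun_int
    dp_num <- mean(fl$P[1, ]) - mean(fl$P[nx, ])
    abs(dp_num - dp_ref) / dp_ref
  })
  expect_lt(errs[3], 0.01)
  expect_true(all(diff(errs) < 0))
})

test_that("scaling permeability by c scales the pressure drop by 1/c", {
  g <- column_grid(31, 3)
  med <- default_medium()
  bnd <- default_boundaries(g, med, inlet_velocity = 1e-4)
  dp <- sapply(c(1, 4), function(s) {
    mat <- hydrogel_material(3)
    mat$permeability <- s / 7.5e11
    fl <- solve_darcy_flow(g, mat, med, bnd)
    mean(fl$P[1, ])
  })
  expect_equal(dp[1] / dp[2], 4, tolerance = 1e-8)
})
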