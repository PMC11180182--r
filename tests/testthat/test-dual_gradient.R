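test_that("IC50 log-linear interpolation matches hand results", {
  expect_equal(fit_ic50(c(0.1, 1.0), c(0.7, 0.3)), 10^(-0.5), tolerance = 1e-12)
  expect_equal(fit_ic50(c(0.1, 0.5, 2), c(0.9, 0.5, 0.1)), 0.5)
  expect_error(fit_ic50(c(0.1, 1), c(0.9, 0.7)), "not bracketed")
  # unsorted input is sorted internally; 0-dose control normalizes
  expect_equal(fit_ic50(c(1.0, 0.1), c(0.3, 0.7)), 10^(-0.5), tolerance = 1e-12)
  expect_equal(fit_ic50(c(0, 0.1, 1.0), c(2, 1.4, 0.6)), 10^(-0.5),
               tolerance = 1e-12)
})

test_that("drug presets follow the 3 x IC50 dosing rule", {
  d <- drug_params("doxorubicin", ic50 = 0.4)
  expect_equal(d$inlet_concentration, 1.2)
  expect_equal(d$D_drug, 2.88e-9 * (32 / 543.5)^(1 / 3))
  s <- drug_params("sorafenib", ic50 = 5)
  expect_equal(s$inlet_concentration, 15)
  expect_error(drug_params("custom", ic50 = 1), "D_drug")
})

test_that("steady drug field is bounded, antisymmetric and linear in the inlet", {
  g <- build_grid(chip_geometry(), 41, 41, "dual_gradient")
  mat <- hydrogel_material(3, D_ratio = 0.8)
  med <- default_medium()
  d <- drug_params("doxorubicin", ic50 = 1)
  fld <- solve_drug_field(g, mat, med, d)
  expect_gte(min(fld$c), 0)
  expect_lte(max(fld$c), 3)
  # mirror antisymmetry about the mid-plane perpendicular to the drug axis
  s <- fld$c + fld$c[rev(seq_len(g$nx)), ]
  expect_lt(max(abs(s - 3)) / 3, 0.01)
  d2 <- drug_params("doxorubicin", ic50 = 2)
  fld2 <- solve_drug_field(g, mat, med, d2)
  expect_equal(fld2$c, 2 * fld$c, tolerance = 1e-9)
})

test_that("dual map pairs per-cell concentrations on a shared grid", {
  g <- build_grid(chip_geometry(), 25, 25, "dual_gradient")
  mk <- function(vals, sp) structure(list(c = vals, t = Inf, species = sp,
                                          grid = g), class = "conc_field")
  o2 <- mk(matrix(2, 25, 25), "oxygen")
  dr <- mk(matrix(1, 25, 25), "drug")
  m <- combine_dual_map(o2, dr)
  df <- as.data.frame(m)
  expect_true(all(df$c_o2_mg_per_l == 2) && all(df$c_drug_um == 1))
  expect_equal(nrow(df), 625)

  # perpendicular gradients: O2 varies only in y, drug only in x
  o2y <- mk(outer(rep(1, 25), seq(0, 5.45, length.out = 25)), "oxygen")
  drx <- mk(outer(seq(3, 0, length.out = 25), rep(1, 25)), "drug")
  m2 <- combine_dual_map(o2y, drx)
  expect_equal(max(apply(m2$c_drug, 1, sd)), 0)
  expect_equal(max(apply(m2$c_O2, 2, sd)), 0)

  g2 <- build_grid(chip_geometry(), 10, 25, "dual_gradient")
  o2b <- structure(list(c = matrix(2, 10, 25), t = Inf, species = "oxygen",
                        grid = g2), class = "conc_field")
  expect_error(combine_dual_map(o2b, dr), "same grid")
})

test_that("zone classification covers the line and matches the stated ranges", {
  g <- build_grid(chip_geometry(), 3, 3, "single_inlet")
  mk <- function(v) structure(list(c = matrix(v, 3, 3), t = Inf,
                                   species = "oxygen", grid = g),
                              class = "conc_field")
  expect_equal(classify_zones(mk(5.0))$labels[1, 1], "hepatic_artery")
  expect_equal(classify_zones(mk(0.65))$labels[1, 1], "portal_vein")
  expect_equal(classify_zones(mk(3.0))$labels[1, 1], "intermediate")
  expect_equal(classify_zones(mk(1.0))$labels[1, 1], "intermediate")
  expect_equal(classify_zones(mk(0.2))$labels[1, 1], "below_portal")
  expect_equal(classify_zones(mk(6.0))$labels[1, 1], "above_artery")
  # partition: every concentration gets exactly one label; idempotent
  set.seed(4)
  cs <- runif(200, 0, 8)
  f <- structure(list(c = matrix(cs, 10, 20), t = Inf, species = "oxygen",
                      grid = build_grid(chip_geometry(), 10, 20, "single_inlet")),
                 class = "conc_field")
  z <- classify_zones(f)
  expect_false(any(is.na(z$labels)))
  expect_identical(classify_zones(f)$labels, z$labels)
})

test_that("viability binning counts by hand and conserves points", {
  pts <- data.frame(x_m = c(0.001, 0.002, 0.003, 0.004, 0.015, 0.05),
                    y_m = c(0.001, 0.002, 0.003, 0.004, 0.015, 0.001),
                    status = c("live", "live", "live", "dead", "live", "dead"))
  vg <- bin_viability(pts, c(0, 0.01, 0.02), c(0, 0.01, 0.02))
  expect_equal(vg$live_fraction[1, 1], 0.75)
  expect_equal(vg$live[2, 2], 1)
  expect_true(is.na(vg$live_fraction[2, 1]))
  expect_equal(vg$n_rejected, 1)
  expect_equal(sum(vg$live + vg$dead) + vg$n_rejected, nrow(pts))

  all_live <- data.frame(x_m = runif(50, 0, 0.02), y_m = runif(50, 0, 0.02),
                         status = "live")
  vga <- bin_viability(all_live, seq(0, 0.02, by = 0.005),
                       seq(0, 0.02, by = 0.005))
  expect_true(all(vga$live_fraction[!is.na(vga$live_fraction)] == 1))
  expect_error(bin_viability(data.frame(x_m = 1, y_m = 1, status = "alive"),
                             0:1, 0:1), "live")
})

test_that("4-parameter logistic fit recovers a synthetic IC50 within 10 %", {
  dr <- gen_dose_response(ic50_true = 0.5, hill = 1.3,
                          doses = 10^seq(-2, 2, length.out = 8) * 0.5,
                          noise_sd = 0.02, seed = 31)
  est <- fit_ic50(dr$dose_um, dr$viability_fraction, method = "logistic4p")
  expect_lt(abs(est - 0.5) / 0.5, 0.10)
  est2 <- fit_ic50(dr$dose_um, dr$viability_fraction)
  expect_lt(abs(est2 - 0.5) / 0.5, 0.10)
})
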