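test_that("probe generator is exact at zero noise and seed-reproducible", {
  cal <- cached_calibration()
  pos <- c(0.005, 0.010, 0.015)
  a <- gen_probe_readings(0.5 * 2.88e-9, config = cal$scenario,
                          positions = pos, noise_sd = 0, seed = 9)
  expect_equal(a$o2_mg_per_l, attr(a, "truth"))
  b <- gen_probe_readings(0.5 * 2.88e-9, config = cal$scenario,
                          positions = pos, noise_sd = 0.02, seed = 9)
  b2 <- gen_probe_readings(0.5 * 2.88e-9, config = cal$scenario,
                           positions = pos, noise_sd = 0.02, seed = 9)
  expect_identical(b, b2)
  expect_false(identical(a$o2_mg_per_l, b$o2_mg_per_l))
  expect_error(gen_probe_readings(1e-9, positions = c(0.5), noise_sd = 0,
                                  seed = 1), "inside the domain")
  expect_error(gen_probe_readings(1e-9, noise_sd = 0), "seed")
  # readings decrease with distance from the inlet
  expect_true(all(diff(a$o2_mg_per_l) < 0))
})

test_that("probe noise spread matches its nominal relative SD", {
  cal <- cached_calibration()
  rd <- gen_probe_readings(0.8 * 2.88e-9, config = cal$scenario,
                           positions = cal$scenario$probe_x, noise_sd = 0.01,
                           seed = 77, replicates = 200)
  rel_sd <- sd(rd$o2_mg_per_l) / mean(rd$o2_mg_per_l)
  expect_gt(rel_sd, 0.005)
  expect_lt(rel_sd, 0.02)
})

test_that("dose-response generator honours its logistic midpoint", {
  dr <- gen_dose_response(0.3, hill = 1, doses = c(0, 0.1, 0.3, 1),
                          noise_sd = 0, seed = 5)
  expect_equal(dr$viability_fraction[dr$dose_um == 0.3], 0.5)
  expect_equal(dr$viability_fraction[dr$dose_um == 0], 1.0)
  expect_error(gen_dose_response(0.3, hill = 0, seed = 5), "hill")
  # round trip through the fitter at zero noise
  dr2 <- gen_dose_response(0.3, hill = 1,
                           doses = 10^seq(-2, 1, length.out = 8), noise_sd = 0,
                           seed = 5)
  expect_lt(abs(fit_ic50(dr2$dose_um, dr2$viability_fraction) - 0.3) / 0.3,
            0.05)
})

test_that("live/dead generator respects its survival response", {
  g <- build_grid(chip_geometry(), 21, 21, "dual_gradient")
  mk <- function(vals, sp) structure(list(c = vals, t = Inf, species = sp,
                                          grid = g), class = "conc_field")
  o2 <- mk(outer(rep(1, 21), seq(0, 5.45, length.out = 21)), "oxygen")
  dr <- mk(outer(seq(1.2, 0, length.out = 21), rep(1, 21)), "drug")

  all_live <- gen_livedead_points(o2, dr, function(d, o) rep(1, length(d)),
                                  n = 500, seed = 2)
  expect_true(all(all_live$status == "live"))

  half <- gen_livedead_points(o2, dr, function(d, o) rep(0.5, length(d)),
                              n = 10000, seed = 2)
  expect_lt(abs(mean(half$status == "live") - 0.5), 0.015)

  expect_error(gen_livedead_points(o2, dr, function(d, o) d * 10, n = 10,
                                   seed = 2), "\\[0, 1\\]")

  # hypoxia-protective response: binned viability rises toward hypoxia
  resp <- hypoxia_protective_response(ic50 = 0.4)
  pts <- gen_livedead_points(o2, dr, resp, n = 20000, seed = 6)
  vg <- bin_viability(pts, seq(0, 0.02, length.out = 3),
                      seq(0, 0.02, length.out = 5))
  col_means <- colMeans(vg$live_fraction)
  expect_true(all(diff(col_means) < 0))  # y up = more oxygen = more death
})

test_that("full pipeline recovers the true diffusivity from noisy readings", {
  cal <- cached_calibration()
  ratio_true <- 0.35
  rd <- gen_probe_readings(ratio_true * 2.88e-9, config = cal$scenario,
                           positions = cal$scenario$probe_x, noise_sd = 0.01,
                           seed = 13, replicates = 20)
  est <- estimate_D(rd$o2_mg_per_l, cal$fit)
  err <- abs(est$D_ratio_hat - ratio_true) / ratio_true
  expect_lt(median(err), 0.05)
})
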