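#' Single-inlet calibration scenario
#'
#' Bundles the configuration of the probe-calibration experiment: a
#' deoxygenated quasi-one-dimensional gel column perfused with normoxic medium
#' for one minute, with the oxygen probe read 10 mm from the inlet.
#'
#' The nominal 100 mm/s supply velocity belongs to the 1-mm feed channel; the
#' gel itself sees a much smaller seepage.  The default superficial seepage
#' velocity (1.15e-4 m/s) places the one-minute advective front just short of
#' the 10-mm probe, the regime in which the probe reading is informative about
#' the gel diffusivity (as the measured profiles are).  The inlet manifold is
#' modelled as a strip spanning the inlet face, giving plug flow.
#'
#' A single reference scenario (porosity of the working 3 mg/mL gel) is used
#' for all fiber densities: probe readings from any gel are inverted on the
#' one reference curve, so every density-dependent transport effect is lumped
#' into the estimated diffusion coefficient.
#'
#' @param nx,ny Grid resolution; the default `2400 x 3` keeps the upwind
#'   numerical diffusivity well below the physical sweep values.
#' @param inlet_velocity Superficial seepage velocity in the gel, m/s.
#' @param probe_x Probe distance from the inlet, m.
#' @param t_eval Perfusion time before the probe is read, s.
#' @param reference_fiber_density Fiber density whose porosity anchors the
#'   reference scenario, mg/mL.
#' @param medium A [chip_medium()].
#' @param geometry Chip geometry; the port diameter is widened to (almost)
#'   the full inlet face to represent the distribution manifold.
#' @return A list of class `calibration_scenario`.
#' @export
calibration_scenario <- function(nx = 2400, ny = 3,
                                 inlet_velocity = 1.15e-4,
                                 probe_x = 0.010, t_eval = 60,
                                 reference_fiber_density = 3,
                                 medium = chip_medium(),
                                 geometry = NULL) {
  if (is.null(geometry)) {
    geometry <- chip_geometry(port_diameter = 0.9 * 0.020)
  }
  structure(list(nx = nx, ny = ny, inlet_velocity = inlet_velocity,
                 probe_x = probe_x, t_eval = t_eval,
                 reference_fiber_density = reference_fiber_density,
                 medium = medium, geometry = geometry),
            class = "calibration_scenario")
}

# forward model: probe oxygen after t_eval at diffusivity ratio `ratio`
.calibration_forward <- function(ratio, config, positions = NULL) {
  grid <- build_grid(config$geometry, config$nx, config$ny, "single_inlet")
  mat <- hydrogel_material(fiber_density = config$reference_fiber_density,
                           D_ratio = ratio)
  bnd <- default_boundaries(grid, config$medium,
                            inlet_velocity = config$inlet_velocity)
  flow <- solve_darcy_flow(grid, mat, config$medium, bnd)
  fld <- run_transient(grid, flow, mat, config$medium, bnd,
                       t_end = config$t_eval, dt = "auto")
  if (is.null(positions)) positions <- config$probe_x
  ymid <- grid$depth / 2
  prof <- extract_profile(fld, c(0, ymid), c(grid$width, ymid),
                          n = max(2L, config$nx))
  stats::approx(prof$positions, prof$values, xout = positions, rule = 2)$y
}

#' Sweep diffusivity ratios through the forward single-inlet model
#'
#' Runs the transient single-inlet model once per diffusivity ratio and
#' records the probe-point oxygen, producing the calibration curve of oxygen
#' level versus diffusion coefficient.
#'
#' @param ratios Distinct diffusivity ratios in (0, 1]; at least 3.  Default
#'   is the standard sweep `{1, 0.5, 0.2, 0.1, 0.05}`.
#' @param config A [calibration_scenario()].
#' @param probe_x Probe position override, m from the inlet.
#' @param t_eval Evaluation-time override, s.
#' @return An object of class `calibration_curve` with `D_values` (m^2/s,
#'   ascending), `O2_at_probe` (mg/L) and the scenario used.  Errors if the
#'   resulting curve is not strictly increasing.
#' @export
sweep_diffusion <- function(ratios = c(1, 0.5, 0.2, 0.1, 0.05),
                            config = calibration_scenario(),
                            probe_x = NULL, t_eval = NULL) {
  if (length(ratios) < 3) {
    stop("sweep_diffusion: need at least 3 sweep ratios", call. = FALSE)
  }
  if (anyDuplicated(ratios)) {
    stop("sweep_diffusion: sweep ratios must be distinct", call. = FALSE)
  }
  if (any(ratios <= 0 | ratios > 1)) {
    stop("sweep_diffusion: ratios must lie in (0, 1]", call. = FALSE)
  }
  if (!is.null(probe_x)) config$probe_x <- probe_x
  if (!is.null(t_eval)) config$t_eval <- t_eval
  ord <- order(ratios)
  ratios <- ratios[ord]
  o2 <- vapply(ratios, .calibration_forward, numeric(1), config = config)
  D <- ratios * config$medium$D_OM
  dif <- diff(o2)
  if (any(dif <= 0)) {
    bad <- which(dif <= 0)[1]
    stop(sprintf("sweep_diffusion: calibration curve not strictly increasing between D = %g and %g m^2/s",
                 D[bad], D[bad + 1]), call. = FALSE)
  }
  structure(list(D_values = D, O2_at_probe = o2, ratios = ratios,
                 probe_x = config$probe_x, t_eval = config$t_eval,
                 config = config),
            class = "calibration_curve")
}

#' Fit the monotone calibration interpolant
#'
#' Builds a strictly monotone, shape-preserving piecewise-cubic interpolant
#' of probe oxygen versus log diffusion coefficient, `O2 = f(log D)`, and its
#' numerical inverse.  A log-linear least-squares alternative is available.
#'
#' @param curve A [sweep_diffusion()] result.
#' @param method `"monotone_spline"` (Hyman-filtered cubic, default) or
#'   `"loglinear"` (least-squares line in log D).
#' @return An object of class `calibration_fit` with functions `f(logD)` and
#'   `finv(o2)`.
#' @export
fit_calibration <- function(curve, method = c("monotone_spline", "loglinear")) {
  method <- match.arg(method)
  if (!inherits(curve, "calibration_curve")) {
    stop("fit_calibration: curve must be a calibration_curve", call. = FALSE)
  }
  if (length(curve$D_values) < 3 || any(diff(curve$O2_at_probe) <= 0)) {
    stop("fit_calibration: curve must be strictly increasing with >= 3 points",
         call. = FALSE)
  }
  lx <- log(curve$D_values)
  y <- curve$O2_at_probe
  if (any(y <= 0)) {
    stop("fit_calibration: probe oxygen must be positive", call. = FALSE)
  }
  if (method == "monotone_spline") {
    # interpolate log(O2) against log(D): the probe response decays near-
    # exponentially at the low-diffusivity end, so the log transform
    # linearizes the curve and keeps the 5-node interpolation accurate there
    s <- stats::splinefun(lx, log(y), method = "hyman")
    f <- function(l) exp(s(l))
  } else {
    cf <- stats::coef(stats::lm(y ~ lx))
    f <- function(l) cf[[1]] + cf[[2]] * l
  }
  rng <- range(lx)
  finv <- function(o2) {
    vapply(o2, function(v) {
      stats::uniroot(function(l) f(l) - v, interval = rng, tol = 1e-12)$root
    }, numeric(1))
  }
  structure(list(f = f, finv = finv, logD_range = rng,
                 O2_range = range(y), method = method, curve = curve),
            class = "calibration_fit")
}

#' Estimate the hydrogel diffusion coefficient from a probe reading
#'
#' Inverts a measured probe oxygen level on the calibration interpolant.
#' Measurements outside the curve span are clamped to the nearest endpoint
#' and flagged `in_range = FALSE` rather than extrapolated.
#'
#' @param measured_O2 Measured probe oxygen, mg/L (vectorized).
#' @param fit A [fit_calibration()] result.
#' @param D_OM Oxygen-in-medium diffusion coefficient used to express the
#'   estimate as a ratio, m^2/s.
#' @return A data frame of class `D_estimate` with columns `measured_O2`,
#'   `D_hat` (m^2/s), `D_ratio_hat`, `in_range` and `residual` (mg/L).
#' @export
estimate_D <- function(measured_O2, fit, D_OM = fit$curve$config$medium$D_OM) {
  if (!inherits(fit, "calibration_fit")) {
    stop("estimate_D: fit must come from fit_calibration()", call. = FALSE)
  }
  lo <- fit$O2_range[1]; hi <- fit$O2_range[2]
  clamped <- pmin(pmax(measured_O2, lo), hi)
  in_range <- measured_O2 >= lo & measured_O2 <= hi
  lD <- fit$finv(clamped)
  D_hat <- exp(lD)
  res <- structure(data.frame(measured_O2 = measured_O2,
                              D_hat = D_hat,
                              D_ratio_hat = D_hat / D_OM,
                              in_range = in_range,
                              residual = measured_O2 - fit$f(lD)),
                   class = c("D_estimate", "data.frame"))
  res
}

#' Coefficient of determination of a probe profile against a straight line
#'
#' Gradient linearity metric: the R-squared of the ordinary least-squares
#' line through (position, concentration).  A constant profile is perfectly
#' described by a flat line and returns 1.
#'
#' @param profile A [extract_profile()] result (>= 3 points).
#' @return R-squared in `[0, 1]`.
#' @export
linearity_r2 <- function(profile) {
  x <- profile$positions; y <- profile$values
  if (length(x) < 3) stop("linearity_r2: need at least 3 points", call. = FALSE)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(1)
  fit <- stats::lm(y ~ x)
  1 - sum(stats::residuals(fit)^2) / sst
}
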