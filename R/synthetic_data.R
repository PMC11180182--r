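#' @name synthetic_data
#' @title Seeded synthetic-data generators with known ground truth
#'
#' @description
#' Generators for the three measured inputs the analysis pipeline consumes:
#' oxygen probe profiles at incremental distances from the inlet, sigmoidal
#' dose-response tables, and spatial live/dead point clouds whose survival
#' depends on the local drug and oxygen concentrations.  All generators are
#' pure functions of their parameters and a mandatory seed; the seed has no
#' default, and every output records it as an attribute.
#'
#' Noise models: multiplicative Gaussian noise for the probe (default spread
#' 1 %), additive Gaussian noise for viabilities (default 2 %); both are
#' invented emulations matched to the visual spread of the reported
#' measurements.
NULL

#' Ground-truth diffusivity ratios per fiber density
#'
#' The synthetic-world truth used to emulate the measured stepwise increase
#' of the hydrogel diffusion coefficient with fiber density: ratios 0.06,
#' 0.15, 0.35 and 0.80 of D_OM at 0, 1, 2 and 3 mg/mL.
#'
#' @return Named numeric vector of D ratios keyed by fiber density.
#' @export
fiber_density_d_ratio_truth <- function() {
  c("0" = 0.06, "1" = 0.15, "2" = 0.35, "3" = 0.80)
}

#' Generate noisy oxygen probe readings
#'
#' Runs the forward single-inlet transient model at the true diffusivity,
#' samples the mid-line profile at the probe positions and applies
#' multiplicative Gaussian noise `(1 + N(0, noise_sd))`, clamped at zero.
#'
#' @param D_true True effective diffusivity, m^2/s.
#' @param config A [calibration_scenario()].
#' @param positions Probe positions from the inlet, m.
#' @param noise_sd Relative noise SD (>= 0).
#' @param seed Integer seed (mandatory).
#' @param replicates Number of noisy replicates per position.
#' @return Data frame `(replicate, position_m, o2_mg_per_l)` with attributes
#'   `seed`, `D_true`, `noise_sd` and `truth` (noiseless values).
#' @export
gen_probe_readings <- function(D_true, config = calibration_scenario(),
                               positions = seq(0, 0.020, by = 0.002),
                               noise_sd, seed, replicates = 1) {
  if (missing(seed)) stop("gen_probe_readings: seed is mandatory", call. = FALSE)
  if (noise_sd < 0) stop("gen_probe_readings: noise_sd must be >= 0", call. = FALSE)
  if (any(positions < 0) || any(positions > config$geometry$width)) {
    stop("gen_probe_readings: positions must lie inside the domain", call. = FALSE)
  }
  ratio <- D_true / config$medium$D_OM
  if (ratio <= 0 || ratio > 1) {
    stop("gen_probe_readings: D_true must lie in (0, D_OM]", call. = FALSE)
  }
  truth <- .calibration_forward(ratio, config, positions = positions)
  out <- withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(replicates), function(r) {
      noisy <- pmax(truth * (1 + stats::rnorm(length(truth), 0, noise_sd)), 0)
      data.frame(replicate = r, position_m = positions, o2_mg_per_l = noisy)
    }))
  })
  attr(out, "seed") <- seed
  attr(out, "D_true") <- D_true
  attr(out, "noise_sd") <- noise_sd
  attr(out, "truth") <- truth
  out
}

#' Generate a synthetic dose-response table
#'
#' Viability follows the logistic law `1 / (1 + (dose/ic50)^hill)` with
#' additive Gaussian noise, clipped to `[0, 1.2]`.
#'
#' @param ic50_true True IC50, uM.
#' @param hill Hill exponent (> 0).
#' @param doses Doses, uM (>= 0).
#' @param noise_sd Additive noise SD.
#' @param seed Integer seed (mandatory).
#' @return Data frame `(dose_um, viability_fraction)` with truth attributes.
#' @export
gen_dose_response <- function(ic50_true, hill = 1,
                              doses = 10^seq(-2, 1, length.out = 8) * ic50_true,
                              noise_sd = 0.02, seed) {
  if (missing(seed)) stop("gen_dose_response: seed is mandatory", call. = FALSE)
  if (hill <= 0) stop("gen_dose_response: hill must be > 0", call. = FALSE)
  if (any(doses < 0)) stop("gen_dose_response: doses must be >= 0", call. = FALSE)
  truth <- 1 / (1 + (doses / ic50_true)^hill)
  v <- withr::with_seed(seed, {
    pmin(pmax(truth + stats::rnorm(length(doses), 0, noise_sd), 0), 1.2)
  })
  out <- data.frame(dose_um = doses, viability_fraction = v)
  attr(out, "seed") <- seed
  attr(out, "ic50_true") <- ic50_true
  attr(out, "hill") <- hill
  attr(out, "truth") <- truth
  out
}

#' Default hypoxia-protective survival response
#'
#' Survival probability under local drug and oxygen levels: logistic in dose
#' with an IC50 that rises as oxygen falls (hypoxia-driven drug resistance),
#' \deqn{p = 1 / (1 + (d / (ic50 (1 + k h)))^{hill})}
#' with `h = 1 - o2/o2_max` clipped to `[0, 1]`.
#'
#' @param ic50 Normoxic IC50, uM.
#' @param hill Hill exponent.
#' @param protection Fold-increase factor `k` of the IC50 under full hypoxia.
#' @param o2_max Oxygen level taken as full normoxia, mg/L.
#' @return A vectorized function `p(c_drug, c_o2)` mapping to `[0, 1]`.
#' @export
hypoxia_protective_response <- function(ic50, hill = 2, protection = 3,
                                        o2_max = 5.45) {
  function(c_drug, c_o2) {
    h <- pmin(pmax(1 - c_o2 / o2_max, 0), 1)
    1 / (1 + (c_drug / (ic50 * (1 + protection * h)))^hill)
  }
}

#' Generate a live/dead point cloud over the dual-gradient chip
#'
#' Scatters `n` points uniformly over the domain and marks each live with
#' probability given by the survival response evaluated at the local drug
#' and oxygen concentrations (bilinear interpolation of the two fields).
#'
#' @param o2 Oxygen `conc_field`.
#' @param drug Drug `conc_field` on the same grid.
#' @param response Survival-probability function `p(c_drug, c_o2)`; checked
#'   to map into `[0, 1]` on a test lattice.
#' @param n Number of points (>= 1).
#' @param seed Integer seed (mandatory).
#' @return Data frame `(x_m, y_m, status)` with a `seed` attribute.
#' @export
gen_livedead_points <- function(o2, drug, response, n, seed) {
  if (missing(seed)) stop("gen_livedead_points: seed is mandatory", call. = FALSE)
  if (n < 1) stop("gen_livedead_points: n must be >= 1", call. = FALSE)
  if (!identical(dim(o2$c), dim(drug$c))) {
    stop("gen_livedead_points: fields must share a grid", call. = FALSE)
  }
  g <- o2$grid
  test_d <- seq(min(drug$c), max(drug$c), length.out = 7)
  test_o <- seq(min(o2$c), max(o2$c), length.out = 7)
  p_test <- outer(test_d, test_o, response)
  if (any(!is.finite(p_test)) || any(p_test < 0) || any(p_test > 1)) {
    stop("gen_livedead_points: response must map to [0, 1]", call. = FALSE)
  }
  out <- withr::with_seed(seed, {
    x <- stats::runif(n, 0, g$width)
    y <- stats::runif(n, 0, g$depth)
    cd <- .bilinear(drug$c, g, x, y)
    co <- .bilinear(o2$c, g, x, y)
    p <- response(cd, co)
    live <- stats::rbinom(n, 1, p) == 1
    data.frame(x_m = x, y_m = y, status = ifelse(live, "live", "dead"))
  })
  attr(out, "seed") <- seed
  out
}
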