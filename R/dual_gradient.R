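#' Drug parameters
#'
#' Presets for the two screening drugs.  The inlet concentration defaults to
#' three times the IC50.  When no diffusivity is given it is scaled from the
#' oxygen-in-medium coefficient by a Stokes-Einstein-style molecular-weight
#' ratio, `D_drug = D_OM * (32 / MW)^(1/3)` (32 g/mol is molecular oxygen).
#'
#' @param name `"doxorubicin"`, `"sorafenib"` or `"custom"`.
#' @param ic50 IC50, uM (> 0).
#' @param inlet_concentration Drug inlet concentration, uM (default 3 x IC50).
#' @param D_drug Drug diffusivity in the medium, m^2/s (optional).
#' @param D_OM Oxygen diffusivity used for the scaling, m^2/s.
#' @return An object of class `drug_params`.
#' @export
drug_params <- function(name = c("doxorubicin", "sorafenib", "custom"),
                        ic50, inlet_concentration = 3 * ic50,
                        D_drug = NULL, D_OM = 2.88e-9) {
  name <- match.arg(name)
  if (ic50 <= 0) stop("drug_params: ic50 must be > 0", call. = FALSE)
  if (inlet_concentration <= 0) {
    stop("drug_params: inlet_concentration must be > 0", call. = FALSE)
  }
  mw <- switch(name, doxorubicin = 543.5, sorafenib = 464.8, custom = NA_real_)
  if (is.null(D_drug)) {
    if (is.na(mw)) stop("drug_params: custom drugs need an explicit D_drug", call. = FALSE)
    D_drug <- D_OM * (32 / mw)^(1 / 3)
  }
  structure(list(name = name, ic50 = ic50, mw = mw,
                 inlet_concentration = inlet_concentration, D_drug = D_drug),
            class = "drug_params")
}

#' Fit IC50 from a dose-response table
#'
#' Default method is log-linear interpolation between the two doses
#' bracketing 50 % viability (the trendline read-off); a four-parameter
#' logistic fit is available for synthetic-data work.
#'
#' @param doses Doses, uM; positive except an optional single 0 control used
#'   only to normalize viabilities.
#' @param viabilities Viability fractions matching `doses`.
#' @param method `"loglinear"` (default) or `"logistic4p"`.
#' @return Estimated IC50, uM.
#' @export
fit_ic50 <- function(doses, viabilities, method = c("loglinear", "logistic4p")) {
  method <- match.arg(method)
  if (length(doses) != length(viabilities) || length(doses) < 2) {
    stop("fit_ic50: need matching dose/viability vectors of length >= 2", call. = FALSE)
  }
  ord <- order(doses)
  doses <- doses[ord]; viabilities <- viabilities[ord]
  if (any(doses < 0)) stop("fit_ic50: doses must be >= 0", call. = FALSE)
  if (doses[1] == 0) {
    if (viabilities[1] > 0) viabilities <- viabilities / viabilities[1]
    doses <- doses[-1]; viabilities <- viabilities[-1]
  }
  if (length(doses) < 2) stop("fit_ic50: need >= 2 positive doses", call. = FALSE)

  if (method == "logistic4p") {
    df <- data.frame(d = doses, v = viabilities)
    fit <- minpack.lm::nlsLM(
      v ~ bot + (top - bot) / (1 + (d / ic50)^hill), data = df,
      start = list(top = max(viabilities), bot = min(viabilities),
                   ic50 = exp(mean(log(doses))), hill = 1),
      lower = c(top = 0, bot = 0, ic50 = min(doses) / 100, hill = 0.1),
      upper = c(top = 2, bot = 1, ic50 = max(doses) * 100, hill = 10),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    return(unname(stats::coef(fit)[["ic50"]]))
  }

  exact <- which(viabilities == 0.5)
  if (length(exact)) return(doses[exact[1]])
  cross <- which(viabilities[-length(viabilities)] > 0.5 &
                   viabilities[-1] < 0.5)
  if (length(cross) == 0) {
    stop("fit_ic50: IC50 not bracketed (viability never crosses 0.5)", call. = FALSE)
  }
  k <- cross[1]
  l1 <- log10(doses[k]); l2 <- log10(doses[k + 1])
  v1 <- viabilities[k]; v2 <- viabilities[k + 1]
  10^(l1 + (0.5 - v1) * (l2 - l1) / (v2 - v1))
}

#' Steady drug concentration field
#'
#' Solves the steady drug gradient on a dual-gradient grid: the drug-bearing
#' channel contacts the gel along the drug-inlet strips at the inlet
#' concentration, the drug-free channel holds the opposite side at zero, and
#' transport into the gel is diffusive (zero Darcy flow for the drug solve;
#' the oxygen perfusion jet is confined to its own port pair).
#'
#' @param grid A dual-gradient [build_grid()] result.
#' @param material A [hydrogel_material()].
#' @param medium A [chip_medium()].
#' @param drug A [drug_params()].
#' @return A `conc_field` with `species = "drug"` (units uM).
#' @export
solve_drug_field <- function(grid, material, medium, drug) {
  if (grid$scenario != "dual_gradient") {
    stop("solve_drug_field: grid must use the dual_gradient scenario", call. = FALSE)
  }
  bnd <- list(
    drug_inlet = bc_concentration(drug$inlet_concentration),
    drug_inlet_blank = bc_concentration(0),
    drug_outlet = bc_concentration(0)
  )
  solve_steady(grid, flow_field_zero(grid), material, medium, bnd,
               species = "drug", D = drug$D_drug)
}

#' Combine oxygen and drug fields into a dual-gradient map
#'
#' @param o2 Oxygen `conc_field`.
#' @param drug Drug `conc_field` on the same grid.
#' @return An object of class `dual_gradient_map` holding both per-cell
#'   concentration matrices; `as.data.frame()` yields the long table
#'   `(x_m, y_m, c_o2_mg_per_l, c_drug_um)`.
#' @export
combine_dual_map <- function(o2, drug) {
  if (o2$species != "oxygen" || drug$species != "drug") {
    stop("combine_dual_map: needs one oxygen and one drug field", call. = FALSE)
  }
  if (!identical(dim(o2$c), dim(drug$c)) ||
      !isTRUE(all.equal(o2$grid$dx, drug$grid$dx)) ||
      !isTRUE(all.equal(o2$grid$dy, drug$grid$dy))) {
    stop("combine_dual_map: fields must share the same grid", call. = FALSE)
  }
  structure(list(c_O2 = o2$c, c_drug = drug$c, grid = o2$grid),
            class = "dual_gradient_map")
}

#' @export
as.data.frame.dual_gradient_map <- function(x, ...) {
  g <- x$grid
  data.frame(x_m = rep(g$xc, times = g$ny),
             y_m = rep(g$yc, each = g$nx),
             c_o2_mg_per_l = as.vector(x$c_O2),
             c_drug_um = as.vector(x$c_drug))
}

#' Physiological oxygen zone ranges
#'
#' Closed concentration intervals (mg/L) of the liver's three reference
#' locations: hepatic artery 4.4-5.2, liver tissue 1.5-2.0, portal vein
#' 0.6-0.7.
#'
#' @return Named list of `c(lo, hi)` intervals.
#' @export
zone_ranges <- function() {
  list(hepatic_artery = c(4.4, 5.2),
       liver = c(1.5, 2.0),
       portal_vein = c(0.6, 0.7))
}

.zone_levels <- c("below_portal", "portal_vein", "intermediate", "liver",
                  "above_artery", "hepatic_artery")

#' Classify cells into physiological oxygen zones
#'
#' Labels every cell of an oxygen field by the zone interval containing its
#' concentration.  Concentrations in the gaps between the stated intervals
#' are `intermediate`; below the portal-vein range `below_portal`; above the
#' hepatic-artery range `above_artery`.
#'
#' @param field An oxygen `conc_field`.
#' @param ranges Zone intervals, as [zone_ranges()].
#' @return An object of class `zone_map` with a factor-label matrix and the
#'   ranges used.
#' @export
classify_zones <- function(field, ranges = zone_ranges()) {
  if (field$species != "oxygen") {
    stop("classify_zones: field must be the oxygen species", call. = FALSE)
  }
  c <- field$c
  lab <- matrix("intermediate", nrow(c), ncol(c))
  lab[c < ranges$portal_vein[1]] <- "below_portal"
  lab[c > ranges$hepatic_artery[2]] <- "above_artery"
  for (z in names(ranges)) {
    r <- ranges[[z]]
    lab[c >= r[1] & c <= r[2]] <- z
  }
  structure(list(labels = lab,
                 codes = matrix(match(lab, .zone_levels), nrow(c), ncol(c)),
                 levels = .zone_levels,
                 ranges = ranges, grid = field$grid),
            class = "zone_map")
}

#' Bin live/dead points into a viability grid
#'
#' Counts live and dead points per rectangular bin (half-open convention
#' `[edge, next_edge)`, with the final edge closed) and computes the live
#' fraction; empty bins carry `NA`.  Points outside the bin range are
#' rejected and counted.
#'
#' @param points Data frame with columns `x_m`, `y_m` and `status`
#'   (`"live"`/`"dead"`).
#' @param xbreaks,ybreaks Ascending bin edges, m.
#' @return An object of class `viability_grid` with `live`, `dead`,
#'   `live_fraction` matrices (`length(xbreaks)-1` by `length(ybreaks)-1`)
#'   and `n_rejected`.
#' @export
bin_viability <- function(points, xbreaks, ybreaks) {
  stopifnot(all(c("x_m", "y_m", "status") %in% names(points)))
  if (!all(points$status %in% c("live", "dead"))) {
    stop("bin_viability: status must be 'live' or 'dead'", call. = FALSE)
  }
  nbx <- length(xbreaks) - 1L; nby <- length(ybreaks) - 1L
  ix <- findInterval(points$x_m, xbreaks, rightmost.closed = TRUE)
  iy <- findInterval(points$y_m, ybreaks, rightmost.closed = TRUE)
  ok <- ix >= 1L & ix <= nbx & iy >= 1L & iy <= nby
  live <- matrix(0L, nbx, nby); dead <- matrix(0L, nbx, nby)
  for (r in which(ok)) {
    if (points$status[r] == "live") {
      live[ix[r], iy[r]] <- live[ix[r], iy[r]] + 1L
    } else {
      dead[ix[r], iy[r]] <- dead[ix[r], iy[r]] + 1L
    }
  }
  tot <- live + dead
  frac <- ifelse(tot > 0, live / tot, NA_real_)
  structure(list(xbreaks = xbreaks, ybreaks = ybreaks,
                 live = live, dead = dead, live_fraction = frac,
                 n_rejected = sum(!ok)),
            class = "viability_grid")
}
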