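#' Chip geometry
#'
#' Physical dimensions of the hydrogel block and its supply ports.  Defaults
#' are the working chip: a 20 x 20 mm plan-view hydrogel, 5 mm thick, with
#' 1 mm diameter supply ports.
#'
#' @param width Chip width (x extent, the oxygen-flow direction), m.
#' @param depth Chip depth (y extent, hypoxia at the bottom, normoxia at the
#'   top), m.
#' @param thickness Hydrogel thickness (out-of-plane), m.  The plan-view model
#'   is depth-averaged over this dimension.
#' @param port_diameter Diameter of the supply ports, m.  Ports are modelled
#'   as boundary strips of this width.
#' @param port_length Length of the supply channels, m (metadata; the channels
#'   themselves are outside the simulated gel domain).
#' @return An object of class `chip_geometry`.
#' @export
chip_geometry <- function(width = 0.020, depth = 0.020, thickness = 0.005,
                          port_diameter = 0.001, port_length = 0.020) {
  dims <- c(width = width, depth = depth, thickness = thickness,
            port_diameter = port_diameter, port_length = port_length)
  if (any(!is.finite(dims)) || any(dims <= 0)) {
    stop("chip_geometry: all dimensions must be strictly positive", call. = FALSE)
  }
  if (port_diameter >= min(width, depth)) {
    stop("chip_geometry: port_diameter must be smaller than min(width, depth)",
         call. = FALSE)
  }
  structure(list(width = width, depth = depth, thickness = thickness,
                 port_diameter = port_diameter, port_length = port_length),
            class = "chip_geometry")
}

#' Culture medium properties
#'
#' @param density Medium density, kg/m^3.
#' @param viscosity Dynamic viscosity, kg/(m s).
#' @param D_OM Diffusion coefficient of oxygen in the medium at 37 C, m^2/s.
#' @param inlet_O2 Dissolved oxygen of the normoxic supply, mg/L.
#' @return An object of class `chip_medium`.
#' @export
chip_medium <- function(density = 1007, viscosity = 0.958e-3,
                        D_OM = 2.88e-9, inlet_O2 = 5.45) {
  if (density <= 0 || viscosity <= 0 || D_OM <= 0) {
    stop("chip_medium: density, viscosity and D_OM must be positive", call. = FALSE)
  }
  if (inlet_O2 < 0) stop("chip_medium: inlet_O2 must be >= 0", call. = FALSE)
  structure(list(density = density, viscosity = viscosity,
                 D_OM = D_OM, inlet_O2 = inlet_O2),
            class = "chip_medium")
}

# Measured porosity (fraction) per Soluplus fiber density (mg/mL).
.porosity_table <- data.frame(
  fiber_density = c(0, 1, 2, 3),
  porosity      = c(0.388, 0.444, 0.546, 0.730)
)

#' Hydrogel porosity as a function of fiber density
#'
#' Returns the measured porosity at fiber densities 0, 1, 2 and 3 mg/mL
#' (38.8, 44.4, 54.6 and 73.0 %) and interpolates linearly in between.
#'
#' @param fd Fiber density, mg/mL, in `[0, 3]`.
#' @return Porosity as a fraction in (0, 1).
#' @export
#' @examples
#' porosity_for_fiber_density(3)    # 0.73
#' porosity_for_fiber_density(1.5)  # 0.495
porosity_for_fiber_density <- function(fd) {
  if (any(!is.finite(fd)) || any(fd < 0) || any(fd > 3)) {
    stop("porosity_for_fiber_density: fd must lie in [0, 3]", call. = FALSE)
  }
  stats::approx(.porosity_table$fiber_density, .porosity_table$porosity,
                xout = fd, method = "linear")$y
}

#' Permeability from viscous resistance
#'
#' The hydrogel permeability k (m^2) is the reciprocal of its viscous
#' resistance R_v (1/m^2), the convention used throughout the package for the
#' Darcy flow solve.
#'
#' @param Rv Viscous resistance, 1/m^2.
#' @return Permeability, m^2.
#' @export
permeability_from_resistance <- function(Rv) {
  if (any(!is.finite(Rv)) || any(Rv <= 0)) {
    stop("permeability_from_resistance: Rv must be positive", call. = FALSE)
  }
  1 / Rv
}

#' Hydrogel material parameters
#'
#' @param fiber_density Soluplus fiber density, mg/mL, in `[0, 3]`.
#' @param porosity Porosity fraction in (0, 1]; defaults to the measured value
#'   for `fiber_density` via [porosity_for_fiber_density()].
#' @param viscous_resistance Viscous resistance, 1/m^2.
#' @param D_ratio Effective diffusivity of the gel as a fraction of the
#'   oxygen-in-medium coefficient D_OM, in (0, 1].  The working value comes
#'   from probe calibration, not from porosity.
#' @return An object of class `hydrogel_material` with the derived
#'   `permeability = 1/viscous_resistance`.
#' @export
hydrogel_material <- function(fiber_density = 3, porosity = NULL,
                              viscous_resistance = 7.5e11, D_ratio = 1) {
  if (is.null(porosity)) porosity <- porosity_for_fiber_density(fiber_density)
  if (!is.finite(porosity) || porosity <= 0 || porosity > 1) {
    stop("hydrogel_material: porosity must lie in (0, 1]", call. = FALSE)
  }
  if (!is.finite(D_ratio) || D_ratio <= 0 || D_ratio > 1) {
    stop("hydrogel_material: D_ratio must lie in (0, 1]", call. = FALSE)
  }
  k <- permeability_from_resistance(viscous_resistance)
  structure(list(fiber_density = fiber_density, porosity = porosity,
                 viscous_resistance = viscous_resistance,
                 permeability = k, D_ratio = D_ratio),
            class = "hydrogel_material")
}

#' Effective diffusivity of a species in the gel
#'
#' @param material A [hydrogel_material()].
#' @param medium A [chip_medium()].
#' @return D_eff = D_ratio * D_OM, m^2/s.
#' @export
effective_diffusivity <- function(material, medium) {
  material$D_ratio * medium$D_OM
}

.grid_scenarios <- c("single_inlet", "two_inlet_oxygen", "dual_gradient")

#' Build the plan-view chip grid with labelled boundary segments
#'
#' Discretizes the hydrogel plan view (origin at the lower-left corner,
#' x rightward, y upward) into an `nx` x `ny` cell-centered grid and labels
#' every boundary face of every boundary cell with its role.
#'
#' Scenarios:
#' \describe{
#'   \item{single_inlet}{one velocity-inlet port centered on the left edge,
#'     full-width outflow on the right edge.  Used for the probe-calibration
#'     transients.}
#'   \item{two_inlet_oxygen}{normoxia inlet port at the top of the left edge;
#'     hypoxia-channel contact along the full bottom edge (the hypoxic supply
#'     channel runs along that side of the gel at zero through-gel velocity);
#'     flow outlet port at the top of the right edge; consumption influx strip
#'     along the top wall.}
#'   \item{dual_gradient}{as `two_inlet_oxygen`, plus drug-channel contact on
#'     the perpendicular edge pair: drug inlet along the left edge (below the
#'     normoxia port), drug-free blank along the right edge (below the oxygen
#'     outlet), with the bottom port-width strip of the right edge labelled as
#'     the blank-channel outlet.}
#' }
#'
#' @param geometry A [chip_geometry()].
#' @param nx,ny Cell counts in x and y; both must be >= 3.
#' @param scenario One of `"single_inlet"`, `"two_inlet_oxygen"`,
#'   `"dual_gradient"`.
#' @return An object of class `chip_grid`: cell sizes, coordinates and an
#'   `edges` data frame (`side`, `index`, `label`) with one row per boundary
#'   face.
#' @export
build_grid <- function(geometry, nx, ny, scenario) {
  if (!inherits(geometry, "chip_geometry")) {
    stop("build_grid: geometry must be a chip_geometry", call. = FALSE)
  }
  if (!is.numeric(nx) || !is.numeric(ny) || nx < 3 || ny < 3) {
    stop("build_grid: nx and ny must both be >= 3", call. = FALSE)
  }
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (!scenario %in% .grid_scenarios) {
    stop(sprintf("build_grid: unknown scenario '%s' (must be one of %s)",
                 scenario, paste(.grid_scenarios, collapse = ", ")), call. = FALSE)
  }
  dx <- geometry$width / nx
  dy <- geometry$depth / ny
  xc <- (seq_len(nx) - 0.5) * dx
  yc <- (seq_len(ny) - 0.5) * dy
  pd <- geometry$port_diameter

  edges <- rbind(
    data.frame(side = "left",   index = seq_len(ny), label = "wall"),
    data.frame(side = "right",  index = seq_len(ny), label = "wall"),
    data.frame(side = "bottom", index = seq_len(nx), label = "wall"),
    data.frame(side = "top",    index = seq_len(nx), label = "wall")
  )
  set_label <- function(edges, side, idx, label) {
    edges$label[edges$side == side & edges$index %in% idx] <- label
    edges
  }
  # port cells: boundary cells whose centers fall inside a strip; always at
  # least the cell nearest the strip center so coarse grids keep their ports
  strip_cells <- function(centers, lo, hi) {
    idx <- which(centers >= lo & centers <= hi)
    if (length(idx) == 0) idx <- which.min(abs(centers - (lo + hi) / 2))
    idx
  }

  if (scenario == "single_inlet") {
    mid <- geometry$depth / 2
    inlet <- strip_cells(yc, mid - pd / 2, mid + pd / 2)
    edges <- set_label(edges, "left", inlet, "o2_inlet_normoxia")
    edges <- set_label(edges, "right", seq_len(ny), "o2_outlet")
  } else {
    top_port <- strip_cells(yc, geometry$depth - pd, geometry$depth)
    edges <- set_label(edges, "left", top_port, "o2_inlet_normoxia")
    edges <- set_label(edges, "right", top_port, "o2_outlet")
    edges <- set_label(edges, "bottom", seq_len(nx), "o2_inlet_hypoxia")
    edges <- set_label(edges, "top", seq_len(nx), "influx_strip")
    if (scenario == "dual_gradient") {
      left_rest <- setdiff(seq_len(ny), top_port)
      right_rest <- setdiff(seq_len(ny), top_port)
      bot_port <- strip_cells(yc, 0, pd)
      edges <- set_label(edges, "left", left_rest, "drug_inlet")
      edges <- set_label(edges, "right", right_rest, "drug_inlet_blank")
      edges <- set_label(edges, "right", intersect(right_rest, bot_port), "drug_outlet")
    }
  }

  # cell regions: the normoxic supply channel is resolved in-domain as a
  # high-permeability strip along the top edge (two-inlet and dual-gradient
  # scenarios); everything else is hydrogel
  cell_region <- matrix("hydrogel", nx, ny)
  if (scenario != "single_inlet") {
    chan_rows <- strip_cells(yc, geometry$depth - pd, geometry$depth)
    cell_region[, chan_rows] <- "channel"
  }

  structure(list(nx = nx, ny = ny, dx = dx, dy = dy,
                 width = geometry$width, depth = geometry$depth,
                 thickness = geometry$thickness,
                 port_diameter = pd,
                 xc = xc, yc = yc,
                 scenario = scenario, edges = edges,
                 # open supply duct: an order above the circular-tube
                 # equivalent d^2/32, so duct conduction dominates gel seepage;
                 # results are insensitive to the exact value beyond that
                 cell_region = cell_region,
                 channel_permeability = pd^2 / 3.2,
                 geometry = geometry),
            class = "chip_grid")
}

#' @export
print.chip_grid <- function(x, ...) {
  cat(sprintf("chip_grid: %d x %d cells (%.3g x %.3g mm), scenario '%s'\n",
              x$nx, x$ny, x$width * 1e3, x$depth * 1e3, x$scenario))
  tab <- table(x$edges$label)
  cat("boundary faces:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Boundary condition constructors
#'
#' A boundary specification is a named list mapping edge labels (see
#' [build_grid()]) to conditions.  Labels present on the grid but absent from
#' the specification behave as impermeable walls.  Kinds:
#' \describe{
#'   \item{`bc_velocity_inlet(v, c)`}{prescribed normal inflow velocity
#'     (m/s, positive into the domain) carrying concentration `c` (mg/L).}
#'   \item{`bc_concentration(c)`}{zero-flow contact at fixed concentration
#'     (mg/L), e.g. a supply channel running along the gel.}
#'   \item{`bc_outflow(P)`}{outflow at reference pressure `P` (Pa, gauge);
#'     advective outflow, zero diffusive flux.}
#'   \item{`bc_no_flux()`}{impermeable wall.}
#'   \item{`bc_influx(Q_mL_s, c)`}{distributed volumetric influx over the
#'     labelled strip, `Q_mL_s` in mL/s, carrying concentration `c` (mg/L).
#'     Used to represent cellular oxygen consumption as a deoxygenated-medium
#'     influx (`c = 0`).}
#' }
#'
#' @param v Inflow velocity, m/s.
#' @param c Concentration, mg/L.
#' @param P Reference pressure, Pa.
#' @param Q_mL_s Volumetric influx, mL/s.
#' @return A boundary condition list with a `kind` element.
#' @name boundary_conditions
NULL

#' @rdname boundary_conditions
#' @export
bc_velocity_inlet <- function(v, c = 0) {
  if (v < 0) stop("bc_velocity_inlet: v must be >= 0", call. = FALSE)
  list(kind = "velocity_inlet", v = v, c = c)
}

#' @rdname boundary_conditions
#' @export
bc_concentration <- function(c) list(kind = "concentration", c = c)

#' @rdname boundary_conditions
#' @export
bc_outflow <- function(P = 0) list(kind = "outflow", P = P)

#' @rdname boundary_conditions
#' @export
bc_no_flux <- function() list(kind = "no_flux")

#' @rdname boundary_conditions
#' @export
bc_influx <- function(Q_mL_s, c = 0) {
  if (Q_mL_s < 0) stop("bc_influx: Q_mL_s must be >= 0", call. = FALSE)
  list(kind = "influx", Q_mL_s = Q_mL_s, c = c)
}

#' Default boundary specification for a scenario
#'
#' Fills in the boundary conditions the chip is operated with: normoxic
#' supply at `inlet_velocity` and `medium$inlet_O2`, hypoxic channel at 0 mg/L
#' and zero velocity, outflow at gauge pressure 0, and the consumption influx
#' (deoxygenated medium) over the influx strip.
#'
#' @param grid A [build_grid()] result.
#' @param medium A [chip_medium()].
#' @param inlet_velocity Normal velocity at the normoxia inlet, m/s.
#' @param influx_mL_s Consumption-equivalent influx, mL/s (two-inlet and dual
#'   gradient scenarios).
#' @param drug A [drug_params()] (dual-gradient scenario only); used for the
#'   drug-species boundary set returned under the drug labels.
#' @return A named list of boundary conditions keyed by edge label, for the
#'   oxygen species.  Drug-species boundaries are built separately by
#'   [solve_drug_field()].
#' @export
default_boundaries <- function(grid, medium = chip_medium(),
                               inlet_velocity = 0.1,
                               influx_mL_s = 0.007,
                               drug = NULL) {
  sc <- grid$scenario
  if (sc == "single_inlet") {
    list(
      o2_inlet_normoxia = bc_velocity_inlet(inlet_velocity, medium$inlet_O2),
      o2_outlet = bc_outflow(0)
    )
  } else {
    list(
      o2_inlet_normoxia = bc_velocity_inlet(inlet_velocity, medium$inlet_O2),
      o2_inlet_hypoxia = bc_concentration(0),
      o2_outlet = bc_outflow(0),
      influx_strip = bc_influx(influx_mL_s, 0)
    )
  }
}

# --- internal helpers shared by the solvers ---------------------------------

# linear cell index, column-major in (i, j): i fastest
.cid <- function(i, j, nx) (j - 1L) * nx + i

# per-boundary-face geometry: cell index, face area (m^2), half distance (m),
# outward axis ("x"/"y") and sign (+1 at right/top, -1 at left/bottom)
.boundary_faces <- function(grid) {
  e <- grid$edges
  n <- nrow(e)
  cell <- integer(n); area <- numeric(n); dd <- numeric(n); ax <- character(n)
  sgn <- integer(n)
  th <- grid$thickness
  for (r in seq_len(n)) {
    side <- e$side[r]; idx <- e$index[r]
    if (side == "left")   { cell[r] <- .cid(1L, idx, grid$nx);        area[r] <- grid$dy * th; dd[r] <- grid$dx / 2; ax[r] <- "x"; sgn[r] <- -1L }
    if (side == "right")  { cell[r] <- .cid(grid$nx, idx, grid$nx);   area[r] <- grid$dy * th; dd[r] <- grid$dx / 2; ax[r] <- "x"; sgn[r] <- +1L }
    if (side == "bottom") { cell[r] <- .cid(idx, 1L, grid$nx);        area[r] <- grid$dx * th; dd[r] <- grid$dy / 2; ax[r] <- "y"; sgn[r] <- -1L }
    if (side == "top")    { cell[r] <- .cid(idx, grid$ny, grid$nx);   area[r] <- grid$dx * th; dd[r] <- grid$dy / 2; ax[r] <- "y"; sgn[r] <- +1L }
  }
  data.frame(side = e$side, index = e$index, label = e$label,
             cell = cell, area = area, dd = dd, axis = ax, sgn = sgn,
             stringsAsFactors = FALSE)
}

# expand a scalar or nx-by-ny matrix to a matrix
.as_field_matrix <- function(x, grid, what) {
  if (length(x) == 1) return(matrix(x, grid$nx, grid$ny))
  if (is.matrix(x) && nrow(x) == grid$nx && ncol(x) == grid$ny) return(x)
  stop(sprintf("%s must be a scalar or an nx-by-ny matrix", what), call. = FALSE)
}

# region-aware material property fields: permeability, diffusivity, porosity.
# Channel cells (resolved supply channel) carry open-channel permeability,
# free-medium diffusivity and porosity 1; an explicit matrix argument is used
# verbatim.
.permeability_field <- function(grid, material) {
  if (is.matrix(material$permeability)) {
    return(.as_field_matrix(material$permeability, grid, "permeability"))
  }
  k <- matrix(material$permeability, grid$nx, grid$ny)
  if (!is.null(grid$cell_region)) {
    k[grid$cell_region == "channel"] <- grid$channel_permeability
  }
  k
}

.diffusivity_field <- function(grid, material, medium, D = NULL) {
  if (!is.null(D)) return(.as_field_matrix(D, grid, "diffusivity"))
  Dm <- matrix(effective_diffusivity(material, medium), grid$nx, grid$ny)
  if (!is.null(grid$cell_region)) {
    Dm[grid$cell_region == "channel"] <- medium$D_OM
  }
  Dm
}

.porosity_field <- function(grid, material) {
  phi <- matrix(material$porosity, grid$nx, grid$ny)
  if (!is.null(grid$cell_region)) {
    phi[grid$cell_region == "channel"] <- 1
  }
  phi
}
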