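#' @name cli_io
#' @title Run configuration, field I/O and provenance
#' @description YAML run configurations with strict key validation and
#'   provenance-tagged defaults; CSV (long format) and legacy-VTK structured
#'   field writers; a JSON provenance record per run.
NULL

# schema: recognized keys, defaults and the provenance tag of each default
.config_schema <- function() {
  list(
    scenario = list(default = "two_inlet_oxygen", source = "artifact default"),
    nx = list(default = 101L, source = "artifact default"),
    ny = list(default = 101L, source = "artifact default"),
    seed = list(default = 1L, source = "artifact default"),
    output_dir = list(default = "out", source = "artifact default"),
    geometry = list(
      width_m = list(default = 0.020, source = "paper"),
      depth_m = list(default = 0.020, source = "paper"),
      thickness_m = list(default = 0.005, source = "paper"),
      port_diameter_m = list(default = 0.001, source = "paper")
    ),
    material = list(
      fiber_density_mg_per_ml = list(default = 3, source = "paper"),
      viscous_resistance_per_m2 = list(default = 7.5e11, source = "paper"),
      d_ratio = list(default = 0.8, source = "artifact default"),
      porosity = list(default = NULL, source = "paper (table)")
    ),
    medium = list(
      density_kg_per_m3 = list(default = 1007, source = "paper"),
      viscosity_kg_per_m_s = list(default = 0.958e-3, source = "paper"),
      d_om_m2_per_s = list(default = 2.88e-9, source = "paper"),
      inlet_o2_mg_per_l = list(default = 5.45, source = "paper")
    ),
    boundaries = list(
      inlet_velocity_m_per_s = list(default = 0.1, source = "paper"),
      influx_ml_per_s = list(default = 0.007, source = "paper")
    ),
    consumption = list(
      n_cells = list(default = 5e6, source = "paper"),
      per_cell_rate_ug_per_s = list(default = 3.2e-9, source = "paper-implied"),
      ref_concentration_mg_per_l = list(default = 16 / 7, source = "paper-implied")
    ),
    drug = list(
      name = list(default = "doxorubicin", source = "artifact default"),
      ic50_um = list(default = 0.4, source = "artifact default"),
      inlet_concentration_um = list(default = NULL, source = "paper (3 x IC50)"),
      d_drug_m2_per_s = list(default = NULL, source = "artifact default")
    ),
    numerics = list(
      tol = list(default = 1e-6, source = "artifact default"),
      dt_s = list(default = "auto", source = "artifact default"),
      t_end_s = list(default = 300, source = "artifact default")
    )
  )
}

.is_leaf_spec <- function(x) is.list(x) && all(c("default", "source") %in% names(x))

#' Read and validate a run configuration
#'
#' Parses a YAML run configuration, rejects unknown keys (to catch typos in
#' physical parameters), fills defaults and records the provenance of every
#' resolved value (`"paper"`, `"paper-implied"` or `"artifact default"`),
#' then validates the physical invariants of every block.
#'
#' @param path Path to a YAML file.
#' @return An object of class `run_config`: the resolved nested list plus a
#'   `provenance` data frame (`key`, `value`, `source`).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("read_config: file not found: %s", path), call. = FALSE)
  }
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop(sprintf("read_config: parse error in %s: %s",
                                                   path, conditionMessage(e)), call. = FALSE))
  if (is.null(raw)) raw <- list()
  schema <- .config_schema()

  prov <- list()
  resolve <- function(spec, given, prefix) {
    out <- list()
    unknown <- setdiff(names(given), names(spec))
    if (length(unknown)) {
      stop(sprintf("read_config: unknown key '%s%s'", prefix, unknown[1]), call. = FALSE)
    }
    for (k in names(spec)) {
      if (.is_leaf_spec(spec[[k]])) {
        if (!is.null(given[[k]])) {
          out[[k]] <- given[[k]]
          prov[[paste0(prefix, k)]] <<- list(value = given[[k]], source = "user config")
        } else {
          out[k] <- list(spec[[k]]$default)
          prov[[paste0(prefix, k)]] <<- list(value = spec[[k]]$default,
                                             source = spec[[k]]$source)
        }
      } else {
        out[[k]] <- resolve(spec[[k]], given[[k]] %||% list(),
                            paste0(prefix, k, "."))
      }
    }
    out
  }
  cfg <- resolve(schema, raw, "")

  .validate_config(cfg)
  cfg$provenance <- data.frame(
    key = names(prov),
    value = vapply(prov, function(p) paste(format(p$value), collapse = ","), character(1)),
    source = vapply(prov, function(p) p$source, character(1)),
    row.names = NULL
  )
  structure(cfg, class = "run_config")
}

.validate_config <- function(cfg) {
  fail <- function(key, msg) {
    stop(sprintf("read_config: invalid value for '%s': %s", key, msg), call. = FALSE)
  }
  g <- cfg$geometry
  for (k in c("width_m", "depth_m", "thickness_m", "port_diameter_m")) {
    if (!is.numeric(g[[k]]) || g[[k]] <= 0) fail(paste0("geometry.", k), "must be > 0")
  }
  if (g$port_diameter_m >= min(g$width_m, g$depth_m)) {
    fail("geometry.port_diameter_m", "must be smaller than the chip plan dimensions")
  }
  m <- cfg$material
  if (!is.null(m$porosity) && (m$porosity <= 0 || m$porosity > 1)) {
    fail("material.porosity", "must lie in (0, 1]")
  }
  if (m$fiber_density_mg_per_ml < 0 || m$fiber_density_mg_per_ml > 3) {
    fail("material.fiber_density_mg_per_ml", "must lie in [0, 3]")
  }
  if (m$viscous_resistance_per_m2 <= 0) {
    fail("material.viscous_resistance_per_m2", "must be > 0")
  }
  if (m$d_ratio <= 0 || m$d_ratio > 1) fail("material.d_ratio", "must lie in (0, 1]")
  md <- cfg$medium
  for (k in c("density_kg_per_m3", "viscosity_kg_per_m_s", "d_om_m2_per_s")) {
    if (md[[k]] <= 0) fail(paste0("medium.", k), "must be > 0")
  }
  if (md$inlet_o2_mg_per_l < 0) fail("medium.inlet_o2_mg_per_l", "must be >= 0")
  b <- cfg$boundaries
  if (b$inlet_velocity_m_per_s < 0) fail("boundaries.inlet_velocity_m_per_s", "must be >= 0")
  if (b$influx_ml_per_s < 0) fail("boundaries.influx_ml_per_s", "must be >= 0")
  cn <- cfg$consumption
  if (cn$n_cells < 0) fail("consumption.n_cells", "must be >= 0")
  if (cn$per_cell_rate_ug_per_s < 0) fail("consumption.per_cell_rate_ug_per_s", "must be >= 0")
  if (cn$ref_concentration_mg_per_l <= 0) fail("consumption.ref_concentration_mg_per_l", "must be > 0")
  if (!cfg$scenario %in% .grid_scenarios) {
    fail("scenario", paste("must be one of", paste(.grid_scenarios, collapse = ", ")))
  }
  if (cfg$nx < 3 || cfg$ny < 3) fail("nx/ny", "must be >= 3")
  if (cfg$drug$ic50_um <= 0) fail("drug.ic50_um", "must be > 0")
  invisible(TRUE)
}

# build model objects from a validated config
.config_objects <- function(cfg) {
  geometry <- chip_geometry(width = cfg$geometry$width_m,
                            depth = cfg$geometry$depth_m,
                            thickness = cfg$geometry$thickness_m,
                            port_diameter = cfg$geometry$port_diameter_m)
  medium <- chip_medium(density = cfg$medium$density_kg_per_m3,
                        viscosity = cfg$medium$viscosity_kg_per_m_s,
                        D_OM = cfg$medium$d_om_m2_per_s,
                        inlet_O2 = cfg$medium$inlet_o2_mg_per_l)
  material <- hydrogel_material(fiber_density = cfg$material$fiber_density_mg_per_ml,
                                porosity = cfg$material$porosity,
                                viscous_resistance = cfg$material$viscous_resistance_per_m2,
                                D_ratio = cfg$material$d_ratio)
  grid <- build_grid(geometry, cfg$nx, cfg$ny, cfg$scenario)
  boundaries <- default_boundaries(grid, medium,
                                   inlet_velocity = cfg$boundaries$inlet_velocity_m_per_s,
                                   influx_mL_s = cfg$boundaries$influx_ml_per_s)
  drug <- drug_params(cfg$drug$name, ic50 = cfg$drug$ic50_um,
                      inlet_concentration = cfg$drug$inlet_concentration_um %||%
                        (3 * cfg$drug$ic50_um),
                      D_drug = cfg$drug$d_drug_m2_per_s,
                      D_OM = medium$D_OM)
  list(geometry = geometry, medium = medium, material = material,
       grid = grid, boundaries = boundaries, drug = drug)
}

#' Write a field to CSV or legacy VTK
#'
#' CSV is long format `(x_m, y_m, value)` at 9 significant digits; VTK is
#' legacy ASCII `STRUCTURED_POINTS` with one scalar per field.  Zone maps are
#' written with integer labels (CSV additionally carries the label text).
#'
#' @param x A `conc_field`, `zone_map` or `dual_gradient_map`.
#' @param path Output file path.
#' @param format `"csv"` or `"vtk"`.
#' @return `path`, invisibly.
#' @export
write_field <- function(x, path, format = c("csv", "vtk")) {
  format <- match.arg(format)
  UseMethod("write_field")
}

#' @export
write_field.conc_field <- function(x, path, format = c("csv", "vtk")) {
  format <- match.arg(format)
  g <- x$grid
  if (format == "csv") {
    df <- data.frame(x_m = rep(g$xc, times = g$ny),
                     y_m = rep(g$yc, each = g$nx),
                     value = as.vector(x$c))
    .write_csv9(df, path)
  } else {
    .write_vtk(as.vector(x$c), g, path, name = x$species, type = "double")
  }
  invisible(path)
}

#' @export
write_field.zone_map <- function(x, path, format = c("csv", "vtk")) {
  format <- match.arg(format)
  g <- x$grid
  codes <- as.vector(x$codes)
  if (format == "csv") {
    df <- data.frame(x_m = rep(g$xc, times = g$ny),
                     y_m = rep(g$yc, each = g$nx),
                     value = codes,
                     zone = as.vector(x$labels))
    .write_csv9(df, path)
  } else {
    .write_vtk(codes, g, path, name = "zone", type = "int")
  }
  invisible(path)
}

#' @export
write_field.dual_gradient_map <- function(x, path, format = c("csv", "vtk")) {
  format <- match.arg(format)
  if (format == "csv") {
    .write_csv9(as.data.frame(x), path)
  } else {
    .write_vtk(cbind(o2 = as.vector(x$c_O2), drug = as.vector(x$c_drug)),
               x$grid, path, name = c("o2", "drug"), type = "double")
  }
  invisible(path)
}

.write_csv9 <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) signif(v, 9))
  ok <- tryCatch({ utils::write.csv(df, path, row.names = FALSE, quote = FALSE); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop(sprintf("write_field: cannot write %s", path), call. = FALSE)
}

.write_vtk <- function(values, g, path, name, type = "double") {
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop(sprintf("write_field: cannot open %s", path),
                                           call. = FALSE))
  on.exit(close(con))
  n <- g$nx * g$ny
  writeLines(c("# vtk DataFile Version 3.0",
               "oxychip field export", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", g$nx, g$ny),
               sprintf("ORIGIN %.9g %.9g 0", g$dx / 2, g$dy / 2),
               sprintf("SPACING %.9g %.9g 1", g$dx, g$dy),
               sprintf("POINT_DATA %d", n)), con)
  values <- as.matrix(values)
  for (k in seq_len(ncol(values))) {
    writeLines(c(sprintf("SCALARS %s %s 1", name[k], type),
                 "LOOKUP_TABLE default",
                 format(values[, k], digits = 9, trim = TRUE, scientific = FALSE)),
               con)
  }
}

#' Read back a long-format field CSV
#'
#' @param path CSV written by [write_field()].
#' @return Data frame `(x_m, y_m, value, ...)`.
#' @export
read_field_csv <- function(path) {
  utils::read.csv(path)
}
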