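#' Closed-form Darcy pressure drop
#'
#' Pressure drop across a homogeneous porous column of length `L` and
#' cross-section `A` carrying flow `Q`:
#' \deqn{\Delta P = Q \mu L / (k A)}
#' with permeability `k` the reciprocal of the viscous resistance.
#'
#' @param Q Flow rate, m^3/s (>= 0).
#' @param k Permeability, m^2.
#' @param A Cross-sectional area, m^2.
#' @param L Column length, m.
#' @param mu Dynamic viscosity, kg/(m s).
#' @return Pressure drop, Pa.
#' @export
#' @examples
#' # the working chip at its supply-channel flow rate of 4.71 mL/min
#' darcy_pressure_drop(Q = 7.85e-8, k = 1/7.5e11, A = 1e-4, L = 0.02,
#'                     mu = 0.958e-3)
darcy_pressure_drop <- function(Q, k, A, L, mu) {
  if (any(c(k, A, L, mu) <= 0) || any(!is.finite(c(k, A, L, mu)))) {
    stop("darcy_pressure_drop: k, A, L and mu must be positive", call. = FALSE)
  }
  if (any(Q < 0)) stop("darcy_pressure_drop: Q must be >= 0", call. = FALSE)
  Q * mu * L / (k * A)
}

#' Solve the steady Darcy flow field
#'
#' Finite-volume pressure solve of the incompressible Darcy problem
#' \eqn{\nabla \cdot ((k/\mu)\nabla P) = 0} on the chip grid, with prescribed
#' inflow fluxes at velocity-inlet and influx boundaries, reference pressure
#' at outflow boundaries and no-flux walls.  Face permeabilities are harmonic
#' means, so layered media are handled exactly.
#'
#' @param grid A [build_grid()] result.
#' @param material A [hydrogel_material()]; its `permeability` may also be an
#'   `nx` x `ny` matrix for heterogeneous media.
#' @param medium A [chip_medium()].
#' @param boundaries A named boundary specification (see
#'   [boundary_conditions]); must contain at least one velocity inlet (or
#'   influx) and one outflow.
#' @return An object of class `flow_field`: cell pressures `P` (Pa), cell
#'   velocities `u`, `v` and face velocities `uf` ((nx+1) x ny) and `vf`
#'   (nx x (ny+1)), all superficial (Darcy) velocities in m/s, plus a
#'   `boundary_flux` table of outward volumetric fluxes (m^3/s) per boundary
#'   face and the relative `mass_error`.
#' @export
solve_darcy_flow <- function(grid, material, medium, boundaries) {
  nx <- grid$nx; ny <- grid$ny; N <- nx * ny
  kmat <- .permeability_field(grid, material)
  if (any(kmat <= 0)) stop("solve_darcy_flow: permeability must be positive", call. = FALSE)
  mu <- medium$viscosity
  th <- grid$thickness
  bf <- .boundary_faces(grid)
  kinds <- vapply(bf$label, function(l) {
    b <- boundaries[[l]]
    if (is.null(b)) "no_flux" else b$kind
  }, character(1))

  if (!any(kinds == "outflow")) {
    stop("solve_darcy_flow: ill-posed configuration, no outflow boundary", call. = FALSE)
  }

  # triplets for the SPD pressure system
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  diag_add <- numeric(N); b <- numeric(N)
  add <- function(i, j, v) { ii <<- c(ii, i); jj <<- c(jj, j); vv <<- c(vv, v) }

  # interior x faces
  if (nx > 1) {
    for (j in seq_len(ny)) {
      i <- seq_len(nx - 1)
      kf <- 2 * kmat[i, j] * kmat[i + 1, j] / (kmat[i, j] + kmat[i + 1, j])
      T <- kf / mu * (grid$dy * th) / grid$dx
      a <- .cid(i, j, nx); bb <- .cid(i + 1, j, nx)
      add(a, bb, -T); add(bb, a, -T)
      diag_add[a] <- diag_add[a] + T; diag_add[bb] <- diag_add[bb] + T
    }
  }
  # interior y faces
  if (ny > 1) {
    for (j in seq_len(ny - 1)) {
      i <- seq_len(nx)
      kf <- 2 * kmat[i, j] * kmat[i, j + 1] / (kmat[i, j] + kmat[i, j + 1])
      T <- kf / mu * (grid$dx * th) / grid$dy
      a <- .cid(i, j, nx); bb <- .cid(i, j + 1, nx)
      add(a, bb, -T); add(bb, a, -T)
      diag_add[a] <- diag_add[a] + T; diag_add[bb] <- diag_add[bb] + T
    }
  }

  # boundary faces: prescribed inflow and outflow reference pressure
  influx_area <- tapply(bf$area, bf$label, sum)
  face_q_in <- numeric(nrow(bf))   # prescribed volumetric inflow per face
  face_T_out <- numeric(nrow(bf))  # outflow transmissibility per face
  for (r in seq_len(nrow(bf))) {
    bc <- boundaries[[bf$label[r]]]
    if (is.null(bc)) next
    cell <- bf$cell[r]
    if (bc$kind == "velocity_inlet") {
      face_q_in[r] <- bc$v * bf$area[r]
      b[cell] <- b[cell] + face_q_in[r]
    } else if (bc$kind == "influx") {
      face_q_in[r] <- (bc$Q_mL_s * 1e-6) * bf$area[r] / influx_area[[bf$label[r]]]
      b[cell] <- b[cell] + face_q_in[r]
    } else if (bc$kind == "outflow") {
      kc <- kmat[((cell - 1) %% nx) + 1, ((cell - 1) %/% nx) + 1]
      Tb <- kc / mu * bf$area[r] / bf$dd[r]
      face_T_out[r] <- Tb
      diag_add[cell] <- diag_add[cell] + Tb
      b[cell] <- b[cell] + Tb * (bc$P %||% 0)
    }
  }

  A <- Matrix::sparseMatrix(i = c(ii, seq_len(N)), j = c(jj, seq_len(N)),
                            x = c(vv, diag_add), dims = c(N, N))
  P <- tryCatch(as.numeric(Matrix::solve(A, b)),
                error = function(e) stop("solve_darcy_flow: singular pressure system (",
                                         conditionMessage(e), ")", call. = FALSE))
  P <- matrix(P, nx, ny)

  # face velocities (superficial, m/s)
  uf <- matrix(0, nx + 1, ny)
  vf <- matrix(0, nx, ny + 1)
  if (nx > 1) {
    for (j in seq_len(ny)) {
      i <- seq_len(nx - 1)
      kf <- 2 * kmat[i, j] * kmat[i + 1, j] / (kmat[i, j] + kmat[i + 1, j])
      uf[i + 1, j] <- -(kf / mu) * (P[i + 1, j] - P[i, j]) / grid$dx
    }
  }
  if (ny > 1) {
    for (i in seq_len(nx)) {
      j <- seq_len(ny - 1)
      kf <- 2 * kmat[i, j] * kmat[i, j + 1] / (kmat[i, j] + kmat[i, j + 1])
      vf[i, j + 1] <- -(kf / mu) * (P[i, j + 1] - P[i, j]) / grid$dy
    }
  }
  q_out <- numeric(nrow(bf))
  for (r in seq_len(nrow(bf))) {
    bc <- boundaries[[bf$label[r]]]
    cell <- bf$cell[r]
    i <- ((cell - 1) %% nx) + 1; j <- ((cell - 1) %/% nx) + 1
    vn <- 0  # outward normal velocity at the face
    if (!is.null(bc)) {
      if (bc$kind %in% c("velocity_inlet", "influx")) {
        vn <- -face_q_in[r] / bf$area[r]
      } else if (bc$kind == "outflow") {
        vn <- face_T_out[r] * (P[i, j] - (bc$P %||% 0)) / bf$area[r]
      }
    }
    q_out[r] <- vn * bf$area[r]
    # write the boundary face velocity into the face arrays (sign: +x/+y)
    axial <- vn * bf$sgn[r]
    if (bf$axis[r] == "x") {
      uf[if (bf$sgn[r] < 0) 1L else nx + 1L, j] <- axial
    } else {
      vf[i, if (bf$sgn[r] < 0) 1L else ny + 1L] <- axial
    }
  }
  inflow <- -sum(q_out[q_out < 0]); outflow <- sum(q_out[q_out > 0])
  mass_error <- if (max(inflow, outflow) > 0) {
    abs(inflow - outflow) / max(inflow, outflow)
  } else 0

  u <- (uf[seq_len(nx), , drop = FALSE] + uf[2:(nx + 1), , drop = FALSE]) / 2
  v <- (vf[, seq_len(ny), drop = FALSE] + vf[, 2:(ny + 1), drop = FALSE]) / 2
  structure(list(P = P, u = u, v = v, uf = uf, vf = vf,
                 boundary_flux = cbind(bf, q_out = q_out),
                 inflow = inflow, outflow = outflow, mass_error = mass_error),
            class = "flow_field")
}

#' A zero-velocity flow field
#'
#' Used when a species enters the gel purely by diffusion from channel
#' contacts (e.g. the drug solve, or diffusion-only verification columns).
#'
#' @param grid A [build_grid()] result.
#' @return A `flow_field` with all velocities and pressures zero.
#' @export
flow_field_zero <- function(grid) {
  structure(list(P = matrix(0, grid$nx, grid$ny),
                 u = matrix(0, grid$nx, grid$ny),
                 v = matrix(0, grid$nx, grid$ny),
                 uf = matrix(0, grid$nx + 1, grid$ny),
                 vf = matrix(0, grid$nx, grid$ny + 1),
                 boundary_flux = NULL, inflow = 0, outflow = 0,
                 mass_error = 0),
            class = "flow_field")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
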