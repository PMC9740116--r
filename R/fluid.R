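# Incompressible laminar aqueous-humor solver: stabilized equal-order P1-P1
# velocity-pressure discretization (Brezzi-Pitkaranta pressure stabilization),
# implicit Euler in time, convection linearized with the previous-step
# velocity (Oseen lag, consistent with the first-order time stepping), an
# optional electric body force, a normal-traction (IOP) inlet and an open
# outlet with zero normal stress (f0 = 0).

#' Fluid properties of the aqueous humor
#'
#' Defaults are the printed values: density 1000 kg/m^3 and dynamic
#' viscosity 0.7185 mPa s; the humor is treated as homogeneous, laminar and
#' Newtonian.
#'
#' @param density Density (kg/m^3).
#' @param viscosity Dynamic viscosity (Pa s).
#' @param include_convection Keep the convective term (linearized); at the
#'   micro-scale Reynolds numbers of the outflow pathway it is negligible
#'   but retained by default.
#' @return A `fluid_properties` list.
#' @export
fluid_properties <- function(density = 1000, viscosity = 7.185e-4,
                             include_convection = TRUE) {
  stopifnot(density > 0, viscosity > 0)
  structure(list(density = density, viscosity = viscosity,
                 include_convection = include_convection),
            class = "fluid_properties")
}

#' Linear IOP load schedule
#'
#' The loading of the canonical scenarios: a linear intraocular-pressure
#' elevation from 0 to `peak_iop` mmHg over `duration` seconds with time
#' step `dt` (defaults 15 mmHg, 1 s, 0.01 s: 100 steps).
#'
#' @param peak_iop Peak IOP (mmHg).
#' @param duration Ramp duration (s).
#' @param dt Time step (s); `duration/dt` must be a whole number of steps.
#' @return A `load_schedule` list with `n_steps`.
#' @export
load_schedule <- function(peak_iop = 15, duration = 1, dt = 0.01) {
  stopifnot(duration > 0, dt > 0)
  n <- duration / dt
  if (abs(n - round(n)) > 1e-9) abort("duration/dt must be a positive integer step count")
  structure(list(peak_iop = peak_iop, duration = duration, dt = dt,
                 n_steps = as.integer(round(n))),
            class = "load_schedule")
}

#' IOP at a time point of the linear ramp
#'
#' @param t Time (s), within `[0, duration]`.
#' @param schedule A [load_schedule()].
#' @return IOP in mmHg (`peak_iop * t / duration`).
#' @export
iop_schedule <- function(t, schedule) {
  if (any(t < -1e-12 | t > schedule$duration + 1e-12))
    abort("t outside the load schedule [0, duration]")
  schedule$peak_iop * t / schedule$duration
}

#' Electric body force on the fluid
#'
#' Pointwise product `f = s * rho_f * E` (N/m^3) evaluated per element; the
#' default sign `s = +1` drives the force on positive charge along the
#' field, and `s = -1` reproduces the printed sign convention of the
#' momentum equation for sensitivity checks. An applied uniform field (e.g.
#' an inlet tangential drive) can be superposed on the quiescent field.
#'
#' @details In thermodynamic equilibrium the quiescent part of the force is
#'   an exact gradient, `rho_f E = grad(eps kappa^2 Phi^2 / 2)`, balanced by
#'   the equilibrium electrokinetic pressure rather than driving flow. With
#'   `equilibrium_correction = TRUE` (default) that gradient is subtracted
#'   (evaluated on the same interpolation), so the solver's pressure is the
#'   dynamic pressure, open boundaries behave as reservoirs in double-layer
#'   equilibrium, and the remaining force is the applied-field drive plus
#'   the discrete imbalance of the double-layer force where the geometry
#'   (e.g. pore constrictions) bends the layer. Setting it to `FALSE` keeps
#'   the raw pointwise product for sensitivity studies.
#'
#' @param charge A `charge_field` from [charge_density()].
#' @param efield An `efield` from [electric_field()].
#' @param sign `+1` (default) or `-1`.
#' @param applied_field Length-2 uniform field (V/m) added to `E`.
#' @param equilibrium_correction Subtract the equilibrium pressure gradient
#'   of the quiescent double layer (see Details).
#' @return A `body_force`: per-cell m x 2 force density with its submesh.
#' @export
body_force_field <- function(charge, efield, sign = 1, applied_field = c(0, 0),
                             equilibrium_correction = TRUE) {
  fe <- charge$fe
  if (!identical(fe$n, efield$fe$n) || !identical(fe$m, efield$fe$m))
    abort("charge and field live on different meshes")
  rho_cell <- (charge$rho[fe$tri[, 1L]] + charge$rho[fe$tri[, 2L]] +
                 charge$rho[fe$tri[, 3L]]) / 3
  f_nodal <- NULL
  if (equilibrium_correction && !is.null(charge$phi)) {
    # quiescent part minus the equilibrium pressure gradient
    # W = eps kappa^2 Phi^2 / 2 = -rho_f Phi / 2 at nodes; P1 cell gradient
    W <- -charge$rho * charge$phi / 2
    g <- fe$geom
    gwx <- gwy <- rep(0, fe$m)
    for (a in 1:3) {
      gwx <- gwx + g$bx[, a] * W[fe$tri[, a]]
      gwy <- gwy + g$by[, a] * W[fe$tri[, a]]
    }
    f <- cbind(sign * (rho_cell * efield$E[, 1L] - gwx),
               sign * (rho_cell * efield$E[, 2L] - gwy))
    # applied-field drive kept nodal (P1) so its boundary-layer load is
    # integrated exactly
    if (any(applied_field != 0)) {
      f_nodal <- cbind(sign * charge$rho * applied_field[1L],
                       sign * charge$rho * applied_field[2L])
    }
  } else {
    f <- cbind(sign * rho_cell * (efield$E[, 1L] + applied_field[1L]),
               sign * rho_cell * (efield$E[, 2L] + applied_field[2L]))
  }
  structure(list(f = f, f_nodal = f_nodal, fe = fe), class = "body_force")
}

# --- assembly ---------------------------------------------------------------

# Velocity Dirichlet dofs: no-slip (or prescribed) on glycocalyx walls, and
# the normal component on axis-aligned symmetry facets.
flow_fixed_dofs <- function(fe) {
  wall <- facet_nodes(fe, "glycocalyx_wall")
  sf <- fe$facets[fe$facets$tag == "symmetry", ]
  sx <- sort(unique(c(sf$a[abs(sf$nx) > 0.5], sf$b[abs(sf$nx) > 0.5])))
  sy <- sort(unique(c(sf$a[abs(sf$ny) > 0.5], sf$b[abs(sf$ny) > 0.5])))
  open <- any(fe$facets$tag %in% c("inlet", "outlet_open"))
  list(wall = wall, sym_x = setdiff(sx, wall), sym_y = setdiff(sy, wall),
       pin_pressure = !open)
}

assemble_flow_matrix <- function(fe, props, dt = NULL, w = NULL, alpha = 0.01) {
  g <- fe$geom; n <- fe$n; tri <- fe$tri
  mu <- props$viscosity
  val_v <- stiffness_blocks(g, tri, coef = mu)
  if (!is.null(dt) && is.finite(dt))
    val_v <- val_v + mass_blocks(g, tri, coef = props$density / dt)
  if (!is.null(w) && props$include_convection) {
    wx <- cbind(w[tri[, 1L], 1L], w[tri[, 2L], 1L], w[tri[, 3L], 1L])
    wy <- cbind(w[tri[, 1L], 2L], w[tri[, 2L], 2L], w[tri[, 3L], 2L])
    val_v <- val_v + convection_blocks(g, tri, wx, wy, props$density)
  }
  gx <- grad_blocks(g, tri, "x"); gy <- grad_blocks(g, tri, "y")
  stab <- stiffness_blocks(g, tri, coef = alpha * 2 * g$area / mu)

  tr <- new_triplets()
  for (blk in list(
    block_triplets(tri, val_v, 0L, 0L),
    block_triplets(tri, val_v, n, n),
    block_triplets(tri, -gx, 0L, 2L * n),
    block_triplets(tri, -gy, n, 2L * n),
    transpose_block(block_triplets(tri, gx, 0L, 2L * n)),
    transpose_block(block_triplets(tri, gy, n, 2L * n)),
    block_triplets(tri, stab, 2L * n, 2L * n)
  )) tr <- add_triplets(tr, blk$i, blk$j, blk$x)

  fx <- flow_fixed_dofs(fe)
  fixed <- c(fx$wall, fx$sym_x, n + fx$wall, n + fx$sym_y)
  if (fx$pin_pressure) fixed <- c(fixed, 2L * n + 1L)
  con <- constrain_rows(tr, fixed)
  A <- Matrix::sparseMatrix(i = con$i, j = con$j, x = con$x, dims = c(3L * n, 3L * n))
  list(A = A, fixed = fx, n = n)
}

flow_rhs <- function(fe, props, sysinfo, body_force, inlet_pressure, prev_u, dt,
                     wall_velocity) {
  n <- fe$n; g <- fe$geom
  rhs <- rep(0, 3L * n)
  if (!is.null(body_force)) {
    f <- if (inherits(body_force, "body_force")) body_force$f else body_force
    rhs[1:n] <- rhs[1:n] + cell_load(g, fe$tri, f[, 1L], n)
    rhs[(n + 1L):(2L * n)] <- rhs[(n + 1L):(2L * n)] + cell_load(g, fe$tri, f[, 2L], n)
    if (inherits(body_force, "body_force") && !is.null(body_force$f_nodal)) {
      mb <- mass_blocks(g, fe$tri)
      bt <- block_triplets(fe$tri, mb)
      Mc <- Matrix::sparseMatrix(i = bt$i, j = bt$j, x = bt$x, dims = c(n, n))
      rhs[1:n] <- rhs[1:n] + as.vector(Mc %*% body_force$f_nodal[, 1L])
      rhs[(n + 1L):(2L * n)] <- rhs[(n + 1L):(2L * n)] +
        as.vector(Mc %*% body_force$f_nodal[, 2L])
    }
  }
  if (!is.null(prev_u) && !is.null(dt) && is.finite(dt)) {
    mb <- mass_blocks(g, fe$tri, coef = props$density / dt)
    bt <- block_triplets(fe$tri, mb)
    Mn <- Matrix::sparseMatrix(i = bt$i, j = bt$j, x = bt$x, dims = c(n, n))
    rhs[1:n] <- rhs[1:n] + as.vector(Mn %*% prev_u[, 1L])
    rhs[(n + 1L):(2L * n)] <- rhs[(n + 1L):(2L * n)] + as.vector(Mn %*% prev_u[, 2L])
  }
  inl <- fe$facets[fe$facets$tag == "inlet", ]
  if (nrow(inl) && inlet_pressure != 0) {
    tx <- -inlet_pressure * inl$nx; ty <- -inlet_pressure * inl$ny
    for (k in seq_len(nrow(inl))) {
      for (nd in c(inl$a[k], inl$b[k])) {
        rhs[nd] <- rhs[nd] + inl$len[k] / 2 * tx[k]
        rhs[n + nd] <- rhs[n + nd] + inl$len[k] / 2 * ty[k]
      }
    }
  }
  fx <- sysinfo$fixed
  wv <- if (is.null(wall_velocity)) matrix(0, n, 2L) else wall_velocity
  rhs[fx$wall] <- wv[fx$wall, 1L]
  rhs[n + fx$wall] <- wv[fx$wall, 2L]
  rhs[fx$sym_x] <- 0
  rhs[n + fx$sym_y] <- 0
  if (fx$pin_pressure) rhs[2L * n + 1L] <- 0
  rhs
}

make_flow_state <- function(fe, props, sol, time) {
  n <- fe$n
  u <- cbind(sol[1:n], sol[(n + 1L):(2L * n)])
  p <- sol[(2L * n + 1L):(3L * n)]
  if (any(!is.finite(u)) || any(!is.finite(p)))
    abort("flow solve produced non-finite fields")
  g <- fe$geom
  div <- rep(0, fe$m)
  for (a in 1:3) {
    div <- div + g$bx[, a] * u[fe$tri[, a], 1L] + g$by[, a] * u[fe$tri[, a], 2L]
  }
  structure(list(u = u, p = p, time = time, fe = fe, props = props,
                 divergence = div),
            class = "flow_state")
}

#' Advance the fluid by one implicit time step (or solve a steady state)
#'
#' Solves the discrete momentum + incompressibility system with a
#' normal-traction inlet at `inlet_pressure`, zero normal stress on
#' `outlet_open` facets, prescribed (default no-slip) velocity on
#' `glycocalyx_wall` facets and free-slip on `symmetry` facets. With
#' `steady = TRUE` the transient term is dropped and, if convection is
#' enabled, the advecting velocity is converged by Picard iteration.
#'
#' @param mesh An [outflow_mesh] or fluid [submesh()].
#' @param props [fluid_properties()].
#' @param body_force A [body_force_field()] result, an m x 2 matrix of cell
#'   force densities (N/m^3), or `NULL`.
#' @param inlet_pressure Inlet pressure (Pa).
#' @param prev Previous `flow_state` (or `NULL` for a rest start).
#' @param dt Time step (s).
#' @param wall_velocity Optional n x 2 prescribed wall velocity (m/s).
#' @param steady Solve the steady problem instead of one transient step.
#' @param stab_alpha Pressure-stabilization constant.
#' @param picard_tol,picard_max Convergence control of the steady Picard loop.
#' @return A `flow_state` with nodal velocity `u` (m/s), pressure `p` (Pa)
#'   and the per-element divergence residual.
#' @export
solve_flow_step <- function(mesh, props, body_force = NULL, inlet_pressure = 0,
                            prev = NULL, dt = 0.01, wall_velocity = NULL,
                            steady = FALSE, stab_alpha = 0.01,
                            picard_tol = 1e-10, picard_max = 25L) {
  fe <- if (inherits(mesh, "fe_submesh")) mesh else submesh(mesh, "fluid")
  stopifnot(steady || dt > 0)
  prev_u <- if (!is.null(prev)) prev$u else NULL
  time0 <- if (!is.null(prev)) prev$time else 0

  if (steady) {
    w <- prev_u
    res_hist <- numeric(0)
    for (it in seq_len(if (props$include_convection) picard_max else 1L)) {
      sys <- assemble_flow_matrix(fe, props, dt = NULL, w = w, alpha = stab_alpha)
      rhs <- flow_rhs(fe, props, sys, body_force, inlet_pressure, NULL, NULL,
                      wall_velocity)
      sol <- solve_scaled(scaled_lu(sys$A), rhs)
      u_new <- cbind(sol[1:fe$n], sol[(fe$n + 1L):(2L * fe$n)])
      res <- if (is.null(w)) Inf else
        max(abs(u_new - w)) / max(max(abs(u_new)), 1e-300)
      res_hist <- c(res_hist, res)
      w <- u_new
      if (!props$include_convection || res < picard_tol) break
    }
    if (props$include_convection && length(res_hist) && tail(res_hist, 1L) > picard_tol &&
        tail(res_hist, 1L) > 1e-6) {
      warn(sprintf("Picard iteration stalled; residual history: %s",
                   paste(signif(res_hist, 3), collapse = ", ")))
    }
    return(make_flow_state(fe, props, sol, time0))
  }

  w <- if (props$include_convection) prev_u else NULL
  sys <- assemble_flow_matrix(fe, props, dt = dt, w = w, alpha = stab_alpha)
  rhs <- flow_rhs(fe, props, sys, body_force, inlet_pressure, prev_u, dt,
                  wall_velocity)
  sol <- solve_scaled(scaled_lu(sys$A), rhs)
  make_flow_state(fe, props, sol, time0 + dt)
}

#' Boundary flux balance of a flow state
#'
#' Integrates `u . n` over every boundary tag and reports per-tag fluxes,
#' the net flux and the gross flux (sum of absolute facet fluxes) -- the
#' conservation diagnostic for accepted solutions.
#'
#' @param state A `flow_state`.
#' @param mesh Unused; the state carries its submesh.
#' @return A `flux_report` tibble with attributes `net` and `gross`
#'   (m^2/s per unit depth).
#' @export
flux_balance <- function(state, mesh = NULL) {
  fe <- state$fe; f <- fe$facets
  un_a <- state$u[f$a, 1L] * f$nx + state$u[f$a, 2L] * f$ny
  un_b <- state$u[f$b, 1L] * f$nx + state$u[f$b, 2L] * f$ny
  flux <- f$len * (un_a + un_b) / 2
  rep <- tibble(tag = f$tag, flux = flux) %>%
    group_by(.data$tag) %>%
    summarise(flux = sum(.data$flux), .groups = "drop")
  attr(rep, "net") <- sum(flux)
  attr(rep, "gross") <- sum(abs(flux))
  class(rep) <- c("flux_report", class(rep))
  rep
}

#' Analytic plane Poiseuille profile
#'
#' Pressure-driven flow between plates at `y = +/- h`:
#' `u(y) = (-dpdx / (2 mu)) (h^2 - y^2)`; the volumetric rate per unit depth
#' is `-dpdx (2h)^3 / (12 mu)`.
#'
#' @param half_width Half-width h (m).
#' @param dpdx Axial pressure gradient (Pa/m).
#' @param viscosity Dynamic viscosity (Pa s).
#' @param n_points Sample count.
#' @return Tibble with `y` (m) and `u` (m/s).
#' @export
analytic_plane_poiseuille <- function(half_width, dpdx, viscosity, n_points = 101L) {
  stopifnot(viscosity > 0, n_points >= 2)
  y <- seq(-half_width, half_width, length.out = n_points)
  tibble(y = y, u = (-dpdx / (2 * viscosity)) * (half_width^2 - y^2))
}

#' Reynolds number of a flow state
#'
#' @param state A `flow_state`.
#' @param length_scale Characteristic length (m), e.g. the channel height.
#' @return `rho * max|u| * L / mu`.
#' @export
reynolds_number <- function(state, length_scale) {
  umax <- max(sqrt(state$u[, 1L]^2 + state$u[, 2L]^2))
  state$props$density * umax * length_scale / state$props$viscosity
}

# Viscous + pressure traction exerted by the fluid on the glycocalyx walls,
# per wall facet: t = (-p I + mu grad u) . n with n the outward fluid normal
# (the gradient form consistent with the Laplacian viscous term).
interface_traction <- function(state) {
  fe <- state$fe
  f <- fe$facets[fe$facets$tag == "glycocalyx_wall", ]
  g <- fe$geom
  cells <- f$cell
  gradc <- function(comp) {
    dx <- rep(0, fe$m); dy <- rep(0, fe$m)
    for (a in 1:3) {
      dx <- dx + g$bx[, a] * state$u[fe$tri[, a], comp]
      dy <- dy + g$by[, a] * state$u[fe$tri[, a], comp]
    }
    cbind(dx, dy)
  }
  gux <- gradc(1L); guy <- gradc(2L)
  pbar <- (state$p[f$a] + state$p[f$b]) / 2
  mu <- state$props$viscosity
  tx <- -pbar * f$nx + mu * (gux[cells, 1L] * f$nx + gux[cells, 2L] * f$ny)
  ty <- -pbar * f$ny + mu * (guy[cells, 1L] * f$nx + guy[cells, 2L] * f$ny)
  tibble(parent_a = f$parent_a, parent_b = f$parent_b, tx = tx, ty = ty,
         len = f$len, nx = f$nx, ny = f$ny)
}
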