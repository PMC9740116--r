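# Electric double layer generated by the charged glycocalyx walls: the
# quiescent potential solves the linearized (Debye-Huckel) closure of
# Poisson's equation, grad^2 Phi = kappa^2 Phi, with Phi = zeta on
# glycocalyx-tagged facets and zero normal gradient elsewhere. The free
# charge density and electric field follow as rho_f = -eps kappa^2 Phi and
# E = -grad Phi.

#' Electrical properties of the aqueous humor and outflow tissue surfaces
#'
#' Defaults are the printed constants: zeta potential -19.5 mV, relative
#' permittivity 99, electrical conductivity 179e-4 ohm^-1 cm^-1, endothelial
#' membrane potential -70 mV, reference impedance 50 ohm. The conductivity,
#' membrane potential and impedance are recorded as metadata; only the zeta
#' potential (and the Debye length, a required closure parameter not printed
#' in the source constants) enter the fluid-side field equations.
#'
#' @param zeta_potential Zeta potential at the glycocalyx slipping plane (V).
#' @param relative_permittivity Relative permittivity of the aqueous humor.
#' @param conductivity Electrical conductivity (ohm^-1 cm^-1, metadata).
#' @param membrane_potential Endothelial membrane potential (V, metadata).
#' @param reference_impedance Reference impedance (ohm, metadata).
#' @param debye_length Debye screening length kappa^-1 (nm).
#' @return An `electro_properties` list with derived absolute permittivity
#'   `eps` (F/m) and `kappa` (1/m).
#' @export
electro_properties <- function(zeta_potential = -19.5e-3,
                               relative_permittivity = 99,
                               conductivity = 179e-4,
                               membrane_potential = -70e-3,
                               reference_impedance = 50,
                               debye_length = 10) {
  if (relative_permittivity <= 0) abort("relative_permittivity must be positive")
  if (debye_length <= 0) abort("debye_length must be positive")
  structure(list(
    zeta_potential = zeta_potential,
    relative_permittivity = relative_permittivity,
    conductivity = conductivity,
    membrane_potential = membrane_potential,
    reference_impedance = reference_impedance,
    debye_length = debye_length,
    eps = relative_permittivity * .const$eps0,
    kappa = 1 / (debye_length * 1e-9)
  ), class = "electro_properties")
}

#' Quiescent electric potential of the double layer
#'
#' In `resolved` mode, solves the Debye-Huckel closure
#' `grad^2 Phi = kappa^2 Phi` on the fluid domain with `Phi = zeta` on
#' `glycocalyx_wall` facets and natural (zero normal gradient) conditions on
#' the open boundaries, using P1 finite elements. The mesh must resolve the
#' double layer: the first wall-normal element size must not exceed one
#' third of the Debye length. In `thin-EDL` mode the bulk potential is
#' identically zero and the zeta potential is recorded for slip generation.
#'
#' @param mesh An [outflow_mesh] or a fluid [submesh()].
#' @param props [electro_properties()].
#' @param mode `"resolved"` or `"thin-EDL"` (the light-weight default for
#'   generic use; the canonical scenarios run resolved).
#' @return A `potential_field`: nodal potential (V) with its submesh.
#' @export
solve_quiescent_potential <- function(mesh, props,
                                      mode = c("thin-EDL", "resolved")) {
  mode <- match.arg(mode)
  fe <- if (inherits(mesh, "fe_submesh")) mesh else submesh(mesh, "fluid")
  wall_nodes <- facet_nodes(fe, "glycocalyx_wall")
  if (!length(wall_nodes)) abort("mesh has no glycocalyx_wall facets")

  if (mode == "thin-EDL") {
    phi <- rep(0, fe$n)
  } else {
    check_edl_resolution(fe, props)
    g <- fe$geom
    tr <- new_triplets()
    k2 <- props$kappa^2
    bk <- stiffness_blocks(g, fe$tri)
    bm <- lumped_mass_blocks(g, fe$tri, coef = k2)
    t1 <- block_triplets(fe$tri, bk + bm)
    tr <- add_triplets(tr, t1$i, t1$j, t1$x)
    sys <- finalize_system(tr, wall_nodes, rep(props$zeta_potential, length(wall_nodes)),
                           rhs = rep(0, fe$n), ndof = fe$n)
    phi <- solve_scaled(scaled_lu(sys$A), sys$rhs)
  }
  structure(list(phi = phi, fe = fe, props = props, mode = mode),
            class = "potential_field")
}

# Resolved mode needs wall-adjacent elements <= kappa^-1 / 3.
check_edl_resolution <- function(fe, props) {
  need <- 1 / props$kappa / 3
  f <- fe$facets[fe$facets$tag == "glycocalyx_wall", ]
  cells <- f$cell
  # wall-normal extent of the wall-adjacent cell: 2A / facet length
  hn <- 2 * fe$geom$area[cells] / f$len
  worst <- max(hn)
  if (worst > need * (1 + 1e-9)) {
    abort(sprintf(
      "under-resolved double layer: wall-normal element size %.3g nm exceeds kappa^-1/3 = %.3g nm; refine (e.g. refine_near_wall(mesh, layer_scale = %.3g))",
      worst * 1e9, need * 1e9, props$debye_length
    ))
  }
  invisible(TRUE)
}

#' Free charge density of the double layer
#'
#' Applies the Debye-Huckel closure `rho_f = -eps kappa^2 Phi` nodewise.
#' With a negative zeta potential the mobile counter-charge near the walls
#' is positive, the physiological sign for aqueous humor against negatively
#' charged outflow tissue.
#'
#' @param potential A `potential_field`.
#' @param props [electro_properties()]; must match the solve.
#' @return Nodal charge density (C/m^3) with the submesh, class
#'   `charge_field`.
#' @export
charge_density <- function(potential, props = potential$props) {
  if (length(potential$phi) != potential$fe$n)
    abort("potential field does not match its mesh")
  rho <- -props$eps * props$kappa^2 * potential$phi
  structure(list(rho = rho, phi = potential$phi, fe = potential$fe),
            class = "charge_field")
}

#' Electric field from a potential field
#'
#' `E = -grad Phi`, evaluated per element (piecewise constant for affine
#' elements).
#'
#' @param potential A `potential_field`.
#' @return An `efield`: m x 2 matrix of per-cell field components (V/m).
#' @export
electric_field <- function(potential) {
  fe <- potential$fe; g <- fe$geom; phi <- potential$phi
  ex <- -(g$bx[, 1L] * phi[fe$tri[, 1L]] + g$bx[, 2L] * phi[fe$tri[, 2L]] +
            g$bx[, 3L] * phi[fe$tri[, 3L]])
  ey <- -(g$by[, 1L] * phi[fe$tri[, 1L]] + g$by[, 2L] * phi[fe$tri[, 2L]] +
            g$by[, 3L] * phi[fe$tri[, 3L]])
  structure(list(E = cbind(ex, ey), fe = fe), class = "efield")
}

#' Analytic plane-channel double-layer profile
#'
#' Closed-form Debye-Huckel potential between two charged plates at
#' `y = +/- h`: `Phi(y) = zeta cosh(y/lambda_D) / cosh(h/lambda_D)`.
#' Evaluated through a ratio of scaled exponentials so thin double layers
#' (`h/lambda_D` beyond ~300) do not overflow.
#'
#' @param half_width Channel half-width (m).
#' @param zeta Wall zeta potential (V).
#' @param debye_length Debye length (m).
#' @param n_points Number of sample points across the channel (>= 2).
#' @return A tibble with `y` (m) and `phi` (V).
#' @export
analytic_plane_edl <- function(half_width, zeta, debye_length, n_points = 101L) {
  stopifnot(half_width > 0, debye_length > 0, n_points >= 2)
  y <- seq(-half_width, half_width, length.out = n_points)
  tibble(y = y, phi = zeta * cosh_ratio(y / debye_length, half_width / debye_length))
}

# cosh(a)/cosh(b) for |a| <= b, overflow-safe:
# = (exp(a-b) + exp(-a-b)) / (1 + exp(-2b))
cosh_ratio <- function(a, b) {
  (exp(a - b) + exp(-a - b)) / (1 + exp(-2 * b))
}

#' Helmholtz-Smoluchowski electroosmotic slip velocity
#'
#' Thin-double-layer closure `u_slip = -eps_r eps_0 zeta E_t / mu`, the bulk
#' velocity far outside the layer for a tangential field `E_t` along a wall
#' at zeta potential `zeta`.
#'
#' @param zeta Zeta potential (V).
#' @param props [electro_properties()] (supplies the permittivity).
#' @param tangential_field Tangential electric field at the wall (V/m).
#' @param viscosity Dynamic viscosity (Pa s).
#' @return Slip velocity (m/s).
#' @examples
#' helmholtz_smoluchowski_slip(-19.5e-3, electro_properties(), 1000, 7.185e-4)
#' @export
helmholtz_smoluchowski_slip <- function(zeta, props, tangential_field, viscosity) {
  stopifnot(viscosity > 0)
  -props$relative_permittivity * .const$eps0 * zeta * tangential_field / viscosity
}
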