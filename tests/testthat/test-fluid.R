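fp_stokes <- fluid_properties(include_convection = FALSE)

test_that("the IOP ramp is linear with the printed endpoints", {
  sched <- load_schedule()
  expect_equal(sched$n_steps, 100L)
  expect_equal(iop_schedule(0, sched), 0)
  expect_equal(iop_schedule(1, sched), 15)
  expect_equal(iop_schedule(0.5, sched), 7.5)
  expect_error(iop_schedule(1.2, sched), "outside")
  expect_error(load_schedule(duration = 1, dt = 0.3), "integer")
})

test_that("pressure unit conversion uses the standard constant", {
  expect_identical(mmhg_to_pa(0), 0)
  expect_equal(mmhg_to_pa(1), 133.322)
  expect_equal(mmhg_to_pa(15), 1999.83)
  expect_equal(pa_to_mmhg(mmhg_to_pa(3.7)), 3.7)
})

test_that("the electric body force is the pointwise charge-field product", {
  mesh <- channel_mesh(2, 1, nx = 3, ny = 3)
  fe <- submesh(mesh, "fluid")
  mk_charge <- function(rho) structure(list(rho = rho, fe = fe), class = "charge_field")
  mk_field <- function(E) structure(list(E = E, fe = fe), class = "efield")
  zero <- body_force_field(mk_charge(rep(0, fe$n)), mk_field(matrix(1, fe$m, 2)))
  expect_identical(max(abs(zero$f)), 0)
  unif <- body_force_field(mk_charge(rep(1, fe$n)),
                           mk_field(cbind(rep(2, fe$m), rep(0, fe$m))))
  expect_equal(unname(unif$f), cbind(rep(2, fe$m), rep(0, fe$m)))
  # sign flag flips the force
  neg <- body_force_field(mk_charge(rep(1, fe$n)),
                          mk_field(cbind(rep(2, fe$m), rep(0, fe$m))), sign = -1)
  expect_equal(neg$f, -unif$f)
  # mismatched meshes are rejected
  fe2 <- submesh(channel_mesh(2, 1, nx = 4, ny = 3), "fluid")
  bad <- structure(list(E = matrix(0, fe2$m, 2), fe = fe2), class = "efield")
  expect_error(body_force_field(mk_charge(rep(1, fe$n)), bad), "different meshes")
})

test_that("zero forcing yields identically zero flow", {
  mesh <- channel_mesh(4, 1, nx = 4, ny = 8)
  st <- solve_flow_step(mesh, fp_stokes, inlet_pressure = 0, dt = 0.01)
  expect_identical(max(abs(st$u)), 0)
  expect_identical(max(abs(st$p)), 0)
})

test_that("pressure-driven channel flow matches the Poiseuille closed form", {
  L <- 10; h <- 1; dp <- 100 # um, um, Pa
  mesh <- channel_mesh(L, h, nx = 10, ny = 32)
  st <- solve_flow_step(mesh, fp_stokes, inlet_pressure = dp, steady = TRUE)
  dpdx <- -dp / (L * 1e-6)
  prof <- analytic_plane_poiseuille(h * 1e-6, dpdx, fp_stokes$viscosity)
  u_centre <- max(prof$u)
  expect_equal(max(st$u[, 1]), u_centre, tolerance = 5e-3)
  fb <- flux_balance(st)
  q_exact <- -dpdx * (2 * h * 1e-6)^3 / (12 * fp_stokes$viscosity)
  expect_equal(abs(fb$flux[fb$tag == "inlet"]), q_exact, tolerance = 5e-3)
  # conservation: net boundary flux far below the gross flux
  expect_lt(abs(attr(fb, "net")), 1e-6 * attr(fb, "gross"))
  # no-slip and transverse velocity are clean
  expect_lt(max(abs(st$u[, 2])), 5e-3 * u_centre)
})

test_that("the velocity error converges with order >= 1 on the Poiseuille oracle", {
  errs <- vapply(c(8, 16, 32), function(ny) {
    mesh <- channel_mesh(10, 1, nx = 8, ny = ny)
    st <- solve_flow_step(mesh, fp_stokes, inlet_pressure = 100, steady = TRUE)
    u_exact <- max(analytic_plane_poiseuille(1e-6, -100 / 1e-5, fp_stokes$viscosity)$u)
    abs(max(st$u[, 1]) - u_exact) / u_exact
  }, numeric(1))
  expect_lt(errs[2], errs[1] / 1.8)
  expect_lt(errs[3], errs[2] / 1.8)
})

test_that("the analytic Poiseuille profile has the hand-derived values", {
  h <- 1e-6; dpdx <- -1e7; mu <- 7.185e-4
  prof <- analytic_plane_poiseuille(h, dpdx, mu, n_points = 101)
  expect_equal(prof$u[c(1, 101)], c(0, 0))
  expect_equal(max(prof$u), -dpdx * h^2 / (2 * mu))
  # trapezoid integral matches -dpdx (2h)^3 / (12 mu) per unit depth
  q <- sum(diff(prof$y) * (head(prof$u, -1) + tail(prof$u, -1)) / 2)
  expect_equal(q, -dpdx * (2 * h)^3 / (12 * mu), tolerance = 1e-3)
})

test_that("resolved-layer electroosmosis reaches the Helmholtz-Smoluchowski bulk velocity", {
  ep <- electro_properties() # 10 nm Debye length
  h <- 0.5                   # kappa h = 50
  mesh <- edl_channel(h, 10, length_um = 1, h_bulk_um = 0.05)
  fe <- submesh(mesh, "fluid")
  pot <- solve_quiescent_potential(fe, ep, mode = "resolved")
  bf <- body_force_field(charge_density(pot), electric_field(pot),
                         applied_field = c(1000, 0))
  st <- solve_flow_step(fe, fp_stokes, body_force = bf, steady = TRUE)
  u_hs <- helmholtz_smoluchowski_slip(ep$zeta_potential, ep, 1000,
                                      fp_stokes$viscosity)
  ctr <- which.min(abs(fe$xy[, 2]) + abs(fe$xy[, 1] - 0.5e-6))
  expect_equal(st$u[ctr, 1], u_hs, tolerance = 0.02)
})

test_that("dropping the convective term barely changes the micro-scale flow", {
  mesh <- channel_mesh(10, 1, nx = 8, ny = 16)
  st_stokes <- solve_flow_step(mesh, fp_stokes, inlet_pressure = 100, steady = TRUE)
  st_conv <- solve_flow_step(mesh, fluid_properties(), inlet_pressure = 100,
                             steady = TRUE)
  expect_lt(abs(max(st_conv$u[, 1]) - max(st_stokes$u[, 1])) / max(st_stokes$u[, 1]),
            1e-3)
  # and the Reynolds number of this flow is far below unity
  expect_lt(reynolds_number(st_conv, 2e-6), 1)
})

test_that("a closed cavity carries no boundary flux", {
  mesh <- build_outflow_domain(tiny_geometry(pore_density = 0), resolution = 0.4)
  st <- solve_flow_step(mesh, fp_stokes, inlet_pressure = 0, dt = 0.01)
  fb <- flux_balance(st)
  expect_equal(attr(fb, "gross"), 0)
})

test_that("divergence residuals stay at solver tolerance", {
  mesh <- channel_mesh(10, 1, nx = 8, ny = 16)
  st <- solve_flow_step(mesh, fp_stokes, inlet_pressure = 100, steady = TRUE)
  scale <- max(abs(st$u)) / 1e-6
  expect_lt(max(abs(st$divergence)), 1e-1 * scale) # elementwise, O(h) weak residual
  # the integrated (weak) divergence vanishes to roundoff
  expect_lt(abs(sum(st$divergence * st$fe$geom$area)),
            1e-10 * sum(abs(st$divergence) * st$fe$geom$area))
})
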