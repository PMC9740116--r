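ep_default <- electro_properties()

test_that("the analytic plane double-layer profile matches hand-derived values", {
  # boundary values equal zeta
  prof <- analytic_plane_edl(1e-7, -19.5e-3, 1e-7, n_points = 5)
  expect_equal(prof$phi[c(1, 5)], c(-19.5e-3, -19.5e-3))
  # kappa h = 1 midplane: 1/cosh(1) = 0.648054...
  prof <- analytic_plane_edl(1e-8, 1, 1e-8, n_points = 3)
  expect_equal(prof$phi[2], 0.6480543, tolerance = 1e-6)
  # thin-layer limit: centre potential vanishes, and no overflow at kappa h = 1000
  prof <- analytic_plane_edl(1e-5, -19.5e-3, 1e-8, n_points = 3)
  expect_true(all(is.finite(prof$phi)))
  expect_equal(prof$phi[2], 0)
})

test_that("the resolved double-layer solve converges to the cosh closed form", {
  # graded layer mesh at kappa h = 10 meets the 1 % closed-form tolerance
  h <- 0.1
  mesh <- edl_channel(h, 10, h_wall_frac = 10, h_bulk_um = 0.02)
  fe <- submesh(mesh, "fluid")
  pot <- solve_quiescent_potential(fe, ep_default, mode = "resolved")
  exact <- ep_default$zeta_potential *
    outflowEFSI:::cosh_ratio(fe$xy[, 2] / 1e-8, h * 1e-6 / 1e-8)
  expect_lt(sqrt(sum((pot$phi - exact)^2) / sum(exact^2)), 0.01)
  # order >= 1 under uniform refinement (kappa h = 2 channel)
  h2 <- 0.02
  errs <- vapply(c(16L, 32L, 64L), function(ny) {
    mesh <- channel_mesh(0.02, h2, nx = 2, ny = ny)
    fe <- submesh(mesh, "fluid")
    pot <- solve_quiescent_potential(fe, ep_default, mode = "resolved")
    exact <- ep_default$zeta_potential *
      outflowEFSI:::cosh_ratio(fe$xy[, 2] / 1e-8, h2 * 1e-6 / 1e-8)
    sqrt(sum((pot$phi - exact)^2) / sum(exact^2))
  }, numeric(1))
  expect_lt(errs[2], errs[1] / 1.8)
  expect_lt(errs[3], errs[2] / 1.8)
})

test_that("the discrete maximum principle holds for charged walls", {
  mesh <- edl_channel(0.1, 10)
  pot <- solve_quiescent_potential(submesh(mesh, "fluid"), ep_default,
                                   mode = "resolved")
  z <- ep_default$zeta_potential
  expect_true(all(pot$phi >= z - 1e-15) && all(pot$phi <= 0 + 1e-15))
})

test_that("zero zeta potential and thin-EDL mode give a zero bulk field", {
  mesh <- edl_channel(0.1, 10)
  fe <- submesh(mesh, "fluid")
  p0 <- solve_quiescent_potential(fe, electro_properties(zeta_potential = 0),
                                  mode = "resolved")
  expect_identical(max(abs(p0$phi)), 0)
  pt <- solve_quiescent_potential(fe, ep_default, mode = "thin-EDL")
  expect_identical(max(abs(pt$phi)), 0)
})

test_that("under-resolved walls are rejected with the required element size", {
  coarse <- channel_mesh(0.1, 0.1, nx = 2, ny = 8)
  expect_error(
    solve_quiescent_potential(submesh(coarse, "fluid"), ep_default,
                              mode = "resolved"),
    "under-resolved")
})

test_that("charge density follows the linearized closure with the right sign", {
  mesh <- edl_channel(0.1, 10)
  fe <- submesh(mesh, "fluid")
  pot <- solve_quiescent_potential(fe, ep_default, mode = "resolved")
  rho <- charge_density(pot)
  # Phi = 0 => rho_f = 0
  pt <- solve_quiescent_potential(fe, ep_default, mode = "thin-EDL")
  expect_identical(max(abs(charge_density(pt)$rho)), 0)
  # negative zeta => positive mobile counter-charge near the walls
  wall_band <- abs(abs(fe$xy[, 2]) - 0.1e-6) < 3 * 1e-8
  expect_true(all(rho$rho[wall_band] > 0))
  # pointwise match of the closed form -eps kappa^2 zeta cosh/cosh
  exact <- -ep_default$eps * ep_default$kappa^2 * ep_default$zeta_potential *
    outflowEFSI:::cosh_ratio(fe$xy[, 2] / 1e-8, 0.1e-6 / 1e-8)
  expect_lt(max(abs(rho$rho - exact)), 5e-3 * max(abs(exact)))
})

test_that("the electric field is minus the potential gradient", {
  mesh <- channel_mesh(2, 1, nx = 4, ny = 4)
  fe <- submesh(mesh, "fluid")
  const <- list(phi = rep(3, fe$n), fe = fe)
  class(const) <- "potential_field"
  expect_equal(max(abs(electric_field(const)$E)), 0)
  lin <- list(phi = 5 * fe$xy[, 1], fe = fe)
  class(lin) <- "potential_field"
  E <- electric_field(lin)$E
  expect_equal(unname(E[, 1]), rep(-5, fe$m))
  expect_equal(max(abs(E[, 2])), 0, tolerance = 1e-20)
  # cosh profile: tangential component zero, normal follows the derivative
  edl <- edl_channel(0.1, 10)
  fes <- submesh(edl, "fluid")
  pot <- solve_quiescent_potential(fes, ep_default, mode = "resolved")
  Ee <- electric_field(pot)$E
  # the tensor-grid diagonal breaks exact x-symmetry at O(h^2); the
  # tangential component stays far below the normal one
  expect_lt(max(abs(Ee[, 1])), 1e-2 * max(abs(Ee[, 2])))
})

test_that("the Helmholtz-Smoluchowski slip has the hand-checked value and scalings", {
  u <- helmholtz_smoluchowski_slip(-19.5e-3, ep_default, 1000, 7.185e-4)
  expect_equal(u, 2.379e-5, tolerance = 1e-3)
  expect_identical(helmholtz_smoluchowski_slip(0, ep_default, 1000, 7.185e-4), 0)
  # bilinear in (zeta, E_t), inversely proportional to viscosity
  expect_equal(helmholtz_smoluchowski_slip(-19.5e-3, ep_default, 2000, 7.185e-4), 2 * u)
  expect_equal(helmholtz_smoluchowski_slip(-39e-3, ep_default, 1000, 7.185e-4),
               2 * u, tolerance = 1e-12)
  expect_equal(helmholtz_smoluchowski_slip(-19.5e-3, ep_default, 1000, 2 * 7.185e-4),
               u / 2)
})

test_that("the Poisson residual of the charge closure vanishes under refinement", {
  # || K phi + M rho/eps || -> 0: test via the weak residual on interior nodes
  h <- 0.1
  res <- vapply(c(10, 20), function(frac) {
    mesh <- edl_channel(h, 10, h_wall_frac = frac, h_bulk_um = 0.2 / frac)
    fe <- submesh(mesh, "fluid")
    pot <- solve_quiescent_potential(fe, ep_default, mode = "resolved")
    rho <- charge_density(pot)
    g <- fe$geom
    bk <- outflowEFSI:::stiffness_blocks(g, fe$tri)
    bm <- outflowEFSI:::lumped_mass_blocks(g, fe$tri)
    t1 <- outflowEFSI:::block_triplets(fe$tri, bk)
    t2 <- outflowEFSI:::block_triplets(fe$tri, bm)
    K <- Matrix::sparseMatrix(i = t1$i, j = t1$j, x = t1$x, dims = c(fe$n, fe$n))
    M <- Matrix::sparseMatrix(i = t2$i, j = t2$j, x = t2$x, dims = c(fe$n, fe$n))
    r <- as.vector(K %*% pot$phi - M %*% (rho$rho / ep_default$eps))
    wall <- outflowEFSI:::facet_nodes(fe, "glycocalyx_wall")
    interior <- setdiff(seq_len(fe$n), wall)
    sqrt(sum(r[interior]^2)) / sqrt(sum((as.vector(K %*% pot$phi))[interior]^2 + 1e-300))
  }, numeric(1))
  expect_lt(res[1], 1e-9)
  expect_lt(res[2], 1e-9)
})
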