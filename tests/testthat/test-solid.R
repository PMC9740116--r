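test_that("Lame parameters match the closed-form conversion", {
  expect_equal(lame_parameters(1000, 0), c(lambda = 0, mu = 500))
  lm <- lame_parameters(4e3, 0.495)
  expect_equal(unname(lm["mu"]), 1337.79, tolerance = 1e-5)
  expect_equal(unname(lm["lambda"]), 132441.47, tolerance = 1e-6)
  lm2 <- lame_parameters(7.48e3, 0.495)
  expect_equal(unname(lm2["mu"]), 2501.67, tolerance = 1e-5)
  expect_equal(unname(lm2["lambda"]), 247665.55, tolerance = 1e-6)
  # inverse check via the isotropic compliance: E and nu recovered
  E_back <- lm["mu"] * (3 * lm["lambda"] + 2 * lm["mu"]) / (lm["lambda"] + lm["mu"])
  expect_equal(unname(E_back), 4e3, tolerance = 1e-12)
  expect_error(lame_parameters(4e3, 0.5), "incompressible")
})

test_that("strain tensors vanish for rigid motions and match simple gradients", {
  fe <- submesh(slab_mesh(4, 4, nx = 3, ny = 3), "TM")
  # rigid translation
  st <- strain_tensor(cbind(rep(1e-6, fe$n), rep(-2e-6, fe$n)), fe)
  expect_equal(max(abs(st$strain)), 0)
  # uniaxial stretch u = (alpha x, 0)
  a <- 1e-3
  st <- strain_tensor(cbind(a * fe$xy[, 1], rep(0, fe$n)), fe)
  expect_equal(unname(st$strain[, "xx"]), rep(a, fe$m))
  expect_equal(max(abs(st$strain[, c("yy", "xy")])), 0, tolerance = 1e-18)
  expect_equal(st$e, rep(a, fe$m))
  # infinitesimal rotation u = (-theta y, theta x) is strain-free
  th <- 1e-3
  st <- strain_tensor(cbind(-th * fe$xy[, 2], th * fe$xy[, 1]), fe)
  expect_lt(max(abs(st$strain)), 1e-18)
})

test_that("the stress split is the printed constitutive decomposition", {
  props <- solid_properties()
  m <- 4
  zero <- matrix(0, m, 3, dimnames = list(NULL, c("xx", "yy", "xy")))
  dec <- stress_decomposition(zero, rep(0, m), rep(50, m), props, "TM")
  expect_equal(unname(dec$sigma_total[, "xx"]), rep(-50, m))
  expect_equal(unname(dec$sigma_total[, "yy"]), rep(-50, m))
  expect_equal(max(abs(dec$sigma_total[, "xy"])), 0)
  # pure shear: sigma_xy = mu * gamma
  gam <- 0.01
  sh <- zero; sh[, "xy"] <- gam / 2
  dec <- stress_decomposition(sh, rep(0, m), 0, props, "TM")
  expect_equal(unname(dec$sigma_t[, "xy"]), rep(props$mu[["TM"]] * gam, m))
  # uniaxial strain: sigma_xx = (lambda + 2 mu) e, hand-computed 1.351 kPa
  un <- zero; un[, "xx"] <- 0.01
  dec <- stress_decomposition(un, rep(0.01, m), 0, props, "TM")
  expect_equal(unname(dec$sigma_t[1, "xx"]), 1351, tolerance = 1e-3)
  # additivity and isotropy of sigma_i are exact
  expect_identical(dec$sigma_total, dec$sigma_t + dec$sigma_i)
  dec2 <- stress_decomposition(un, rep(0.01, m), rep(77, m), props, "TM")
  expect_identical(dec2$sigma_i[, "xx"], dec2$sigma_i[, "yy"])
  expect_identical(unname(dec2$sigma_i[1, "xx"]), -77)
})

test_that("the constrained slab matches the plane-strain closed form without locking", {
  for (nu in c(0.3, 0.495)) {
    props <- solid_properties(poisson = nu)
    mesh <- slab_mesh(10, 10, nx = 6, ny = 6)
    st <- solve_quasistatic(mesh, props, tractions = list(free = c(0, -100)))
    lam <- props$lambda[["TM"]]; mu <- props$mu[["TM"]]
    u_exact <- -100 * 10e-6 / (lam + 2 * mu)
    top <- which(abs(st$fe$xy[, 2] - 10e-6) < 1e-12)
    err <- abs(mean(st$displacement[top, 2]) / u_exact - 1)
    expect_lt(err, 0.01)
    if (nu == 0.3) err_03 <- err else expect_lt(err, 2 * err_03 + 1e-12)
    # uniform stress state recovered
    expect_equal(unname(st$sigma_t[, "yy"]), rep(-100, st$fe$m), tolerance = 1e-9)
  }
})

test_that("linear displacement fields pass the patch test exactly", {
  props <- solid_properties()
  fe <- submesh(slab_mesh(7, 5, nx = 4, ny = 3), "TM")
  bn <- sort(unique(c(fe$facets$a, fe$facets$b)))
  lin <- function(xy) cbind(2e-3 * xy[, 1] + 1e-3 * xy[, 2],
                            -5e-4 * xy[, 1] + 8e-4 * xy[, 2])
  st <- solve_quasistatic(fe, props,
                          dirichlet = list(nodes = bn, values = lin(fe$xy[bn, ])))
  expect_equal(st$displacement, lin(fe$xy), tolerance = 1e-10)
})

test_that("pre-tension is balanced by the anchor reactions", {
  mesh <- build_outflow_domain(tiny_geometry(), resolution = 0.4)
  props <- solid_properties()
  depth <- 36e-3
  st <- solve_quasistatic(mesh, props, pretension = 500e-6, depth = depth)
  # Newton's third law: reactions equal the applied resultant (per depth)
  expect_equal(st$reaction_sum[1] * depth, 500e-6, tolerance = 1e-8)
  expect_lt(abs(st$reaction_sum[2] * depth), 1e-8 * 500e-6 + 1e-20)
})

test_that("external work equals stored elastic energy", {
  props <- solid_properties()
  mesh <- slab_mesh(10, 10, nx = 6, ny = 6)
  st <- solve_quasistatic(mesh, props, tractions = list(free = c(0, -100)))
  top_f <- st$fe$facets[st$fe$facets$tag == "free", ]
  # work of the dead load: 1/2 integral t . u over the loaded face
  w_ext <- 0.5 * sum(top_f$len * (-100) *
                       (st$displacement[top_f$a, 2] + st$displacement[top_f$b, 2]) / 2)
  expect_equal(outflowEFSI:::elastic_energy(st), w_ext, tolerance = 1e-6)
})

test_that("principal values and maximum shear match an eigen-decomposition oracle", {
  pv <- principal_values(diag(c(3, 2, 1)))
  expect_equal(unlist(pv), c(p1 = 3, p2 = 2, p3 = 1))
  pv <- principal_values(matrix(c(0, 1, 1, 0), 2))
  expect_equal(unlist(pv), c(p1 = 1, p2 = 0, p3 = -1))
  expect_error(principal_values(matrix(c(0, 1, 2, 0), 2)), "symmetric")
  # field form against eigen() on random symmetric tensors
  set.seed(3)
  df <- tibble::tibble(xx = rnorm(50), yy = rnorm(50), xy = rnorm(50),
                       zz = rnorm(50))
  pv <- principal_values(df)
  for (i in c(1, 17, 50)) {
    ev <- sort(eigen(matrix(c(df$xx[i], df$xy[i], 0, df$xy[i], df$yy[i], 0,
                              0, 0, df$zz[i]), 3), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    expect_equal(c(pv$p1[i], pv$p2[i], pv$p3[i]), ev, tolerance = 1e-12)
  }
  expect_equal(max_shear(df), (pv$p1 - pv$p3) / 2)
  # hydrostatic state has zero shear; pure shear tau gives tau
  expect_equal(max_shear(tibble::tibble(xx = -5, yy = -5, xy = 0, zz = -5)), 0)
  expect_equal(max_shear(tibble::tibble(xx = 0, yy = 0, xy = 0.3)), 0.3)
})

test_that("an unanchored solid is rejected as singular", {
  # channel mesh has no anchor/symmetry facets once reinterpreted as solid
  mesh <- channel_mesh(4, 1, nx = 3, ny = 3)
  mesh$region[] <- "TM"
  mesh$facets$tag[] <- "free"
  fe <- submesh(mesh, "TM")
  expect_error(solve_quasistatic(fe, solid_properties()), "singular")
})
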