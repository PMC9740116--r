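test_that("grid pore counts follow the areal density exactly", {
  expect_equal(nrow(place_inner_wall_pores(835, 1.3, c(1, 1))), 835)
  expect_equal(nrow(place_inner_wall_pores(835, 1.3, c(0.1, 0.1))), 8)
  expect_equal(nrow(place_inner_wall_pores(835, 1.3, c(0, 0))), 0)
  # property: count = round(density * area) over random valid inputs
  set.seed(42)
  for (i in 1:20) {
    dens <- runif(1, 10, 2000)
    dims <- runif(2, 0.05, 1.5)
    n_expect <- round(dens * dims[1] * dims[2])
    spacing_ok <- 1000 * min(dims) / max(1, sqrt(n_expect)) > 3
    if (!spacing_ok) next
    layout <- place_inner_wall_pores(dens, 1.3, dims)
    expect_equal(nrow(layout), n_expect)
    expect_true(all(layout$x_um >= 0 & layout$x_um <= dims[1] * 1000))
    expect_true(all(layout$y_um >= 0 & layout$y_um <= dims[2] * 1000))
  }
})

test_that("jittered layouts are seeded, reproducible and non-overlapping", {
  a <- place_inner_wall_pores(835, 1.3, c(0.2, 0.2), mode = "jittered", seed = 7)
  b <- place_inner_wall_pores(835, 1.3, c(0.2, 0.2), mode = "jittered", seed = 7)
  expect_identical(a$x_um, b$x_um)
  expect_identical(a$y_um, b$y_um)
  c2 <- place_inner_wall_pores(835, 1.3, c(0.2, 0.2), mode = "jittered", seed = 8)
  expect_false(identical(a$x_um, c2$x_um))
  expect_error(place_inner_wall_pores(835, 1.3, c(0.2, 0.2), mode = "jittered"),
               "seed")
  # pairwise non-overlap
  d <- as.matrix(dist(cbind(a$x_um, a$y_um)))
  diag(d) <- Inf
  expect_gt(min(d), 1.3)
  # overlap-infeasible request is rejected
  expect_error(place_inner_wall_pores(1e6, 1.3, c(0.1, 0.1)), "non-overlap")
})

test_that("the 2D mapping of pore density gives the hand-checked wall spacing", {
  expect_equal(pore_spacing_2d(835), 1000 / sqrt(835))
  expect_equal(pore_spacing_2d(835), 34.61, tolerance = 1e-3)
})

test_that("the outflow domain is a tagged partition with pore outlets", {
  gp <- tiny_geometry()
  mesh <- build_outflow_domain(gp, resolution = 0.4)
  expect_setequal(unique(mesh$region), c("TM", "JCT", "SC_wall", "fluid"))
  # regions partition the cells: per-region areas sum to the domain area
  v <- mesh$vertices; tr <- mesh$triangles
  area <- abs((v[tr[, 2], 1] - v[tr[, 1], 1]) * (v[tr[, 3], 2] - v[tr[, 1], 2]) -
                (v[tr[, 3], 1] - v[tr[, 1], 1]) * (v[tr[, 2], 2] - v[tr[, 1], 2])) / 2
  total <- gp$channel_length * (gp$channel_height + 2 * gp$tissue_thickness)
  expect_equal(sum(tapply(area, mesh$region, sum)), total, tolerance = 1e-12)
  # every exterior facet carries exactly one tag; interface facets are walls
  expect_false(anyNA(mesh$facets$tag))
  expect_true(all(mesh$facets$tag %in%
                    c("inlet", "outlet_open", "glycocalyx_wall", "anchor", "free")))
  expect_gt(sum(mesh$facets$tag == "outlet_open"), 0)
  # a zero pore density closes the SC wall: no outlet facets downstream
  closed <- build_outflow_domain(tiny_geometry(pore_density = 0), resolution = 0.4)
  expect_equal(sum(closed$facets$tag == "outlet_open"), 0)
})

test_that("invalid geometry and resolution requests are rejected", {
  expect_error(geometry_params(pore_diameter = 40), "spacing")
  expect_error(geometry_params(jct_thickness = -1), "positive")
  expect_error(build_outflow_domain(tiny_geometry(), resolution = 2), "too coarse")
  expect_error(build_outflow_domain(geometry_params(dimensionality = "slab-3D")),
               "plane-2D")
})

test_that("mesh quality reports match a brute-force scan", {
  mesh <- build_outflow_domain(tiny_geometry(), resolution = 0.4)
  q <- mesh_quality(mesh)
  expect_equal(q$n_cells, nrow(mesh$triangles))
  expect_equal(q$n_vertices, nrow(mesh$vertices))
  expect_equal(q$n_inverted, 0L)
  # brute-force min edge oracle
  v <- mesh$vertices; tr <- mesh$triangles
  edges <- rbind(cbind(tr[, 1], tr[, 2]), cbind(tr[, 2], tr[, 3]), cbind(tr[, 3], tr[, 1]))
  el <- sqrt(rowSums((v[edges[, 1], ] - v[edges[, 2], ])^2))
  expect_equal(q$min_edge_um, min(el))
  expect_equal(q$max_edge_um, max(el))
  # uniform structured grid has unit cell anisotropy
  qc <- mesh_quality(channel_mesh(4, 2, nx = 4, ny = 4))
  expect_equal(qc$max_aspect, 1)
})

test_that("near-wall refinement resolves the layer and preserves tags", {
  mesh <- build_outflow_domain(tiny_geometry(), resolution = 0.4)
  ref <- refine_near_wall(mesh, layer_scale = 30, growth = 1.5)
  q <- mesh_quality(ref)
  expect_lte(q$min_edge_um, 30 / 3 / 1000 + 1e-12)
  expect_setequal(unique(ref$facets$tag), unique(mesh$facets$tag))
  # idempotent once resolved: a second call changes nothing
  ref2 <- refine_near_wall(ref, layer_scale = 30, growth = 1.5)
  expect_equal(nrow(ref2$vertices), nrow(ref$vertices))
  # element budget is enforced
  expect_error(refine_near_wall(mesh, layer_scale = 1, growth = 1.01,
                                max_cells = 500), "budget")
})

test_that("pore layouts round-trip through CSV", {
  layout <- place_inner_wall_pores(835, 1.3, c(0.1, 0.1))
  f <- tempfile(fileext = ".csv")
  write_pore_csv(layout, f)
  back <- utils::read.csv(f)
  expect_equal(back$x_um, layout$x_um)
  expect_equal(back$diameter_um, layout$diameter_um)
})
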