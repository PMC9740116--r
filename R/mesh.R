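# Tensor-product triangulated meshes with region labels and tagged boundary
# facets. Geometry coordinates are stored in micrometres; the solvers work on
# `fe_submesh` objects extracted with submesh(), whose coordinates are metres.

#' @title Tagged unstructured mesh of the outflow domain
#' @description An `outflow_mesh` is a conforming triangulation built on a
#'   tensor-product line set. It carries per-cell region labels
#'   (`TM`, `JCT`, `SC_wall`, `fluid`) and a facet table tagging every
#'   exterior facet with exactly one of `inlet`, `outlet_open`, `symmetry`,
#'   `anchor` or `free`, plus every fluid-tissue interface facet as
#'   `glycocalyx_wall`.
#' @name outflow_mesh
NULL

# Fill an interval [a, b] with lines: geometric fans growing away from either
# end (resolving boundary layers) and a uniform bulk fill in between.
fill_interval <- function(a, b, h_bulk, fan_a = NULL, fan_b = NULL) {
  gap <- b - a
  pts_a <- if (!is.null(fan_a)) a + fan_offsets(fan_a$h0, fan_a$ratio, gap / 2) else numeric(0)
  pts_b <- if (!is.null(fan_b)) b - fan_offsets(fan_b$h0, fan_b$ratio, gap / 2) else numeric(0)
  lo <- if (length(pts_a)) max(pts_a) else a
  hi <- if (length(pts_b)) min(pts_b) else b
  mid <- numeric(0)
  if (hi - lo > 1.5 * h_bulk) {
    nmid <- max(1L, ceiling((hi - lo) / h_bulk))
    mid <- seq(lo, hi, length.out = nmid + 1L)
  }
  sort(unique(c(a, pts_a, mid, pts_b, b)))
}

# Cumulative geometric offsets h0, h0(1+r), ... capped at `reach`.
fan_offsets <- function(h0, ratio, reach) {
  stopifnot(h0 > 0, ratio >= 1)
  off <- numeric(0)
  d <- h0; tot <- 0
  while (tot + d < reach && length(off) < 200L) {
    tot <- tot + d
    off <- c(off, tot)
    d <- d * ratio
  }
  off
}

# Build a triangulated mesh on x/y line sets. `classify(cx, cy)` returns the
# region label of a cell from its quad centre (NA drops the cell);
# `tagger(mx, my, nx, ny)` returns the tag of an exterior facet from its
# midpoint and outward normal.
mesh_from_grid <- function(xlines, ylines, classify, tagger, params = NULL) {
  xlines <- sort(unique(xlines)); ylines <- sort(unique(ylines))
  nx <- length(xlines); ny <- length(ylines)
  if (nx < 2L || ny < 2L) abort("mesh grid needs at least 2 lines per axis")
  node_id <- function(ix, iy) (iy - 1L) * nx + ix
  xy <- cbind(rep(xlines, ny), rep(ylines, each = nx))

  ix <- rep(seq_len(nx - 1L), ny - 1L)
  iy <- rep(seq_len(ny - 1L), each = nx - 1L)
  cx <- (xlines[ix] + xlines[ix + 1L]) / 2
  cy <- (ylines[iy] + ylines[iy + 1L]) / 2
  region_q <- classify(cx, cy)
  keep <- !is.na(region_q)
  ix <- ix[keep]; iy <- iy[keep]; region_q <- region_q[keep]

  v00 <- node_id(ix, iy);      v10 <- node_id(ix + 1L, iy)
  v11 <- node_id(ix + 1L, iy + 1L); v01 <- node_id(ix, iy + 1L)
  # two counter-clockwise triangles per quad
  tri <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  region <- c(region_q, region_q)

  used <- sort(unique(as.vector(tri)))
  remap <- integer(nrow(xy)); remap[used] <- seq_along(used)
  tri <- matrix(remap[tri], ncol = 3L)
  vertices <- xy[used, , drop = FALSE]

  facets <- build_facets(vertices, tri, region, tagger)

  structure(
    list(vertices = vertices, triangles = tri, region = region,
         facets = facets, xlines = xlines, ylines = ylines,
         classify = classify, tagger = tagger, params = params),
    class = "outflow_mesh"
  )
}

# Identify exterior facets (edges bounding one cell) and fluid-tissue
# interface facets (edges shared by a fluid and a tissue cell).
build_facets <- function(vertices, tri, region, tagger) {
  m <- nrow(tri)
  ea <- c(tri[, 1L], tri[, 2L], tri[, 3L])
  eb <- c(tri[, 2L], tri[, 3L], tri[, 1L])
  cell <- rep(seq_len(m), 3L)
  lo <- pmin(ea, eb); hi <- pmax(ea, eb)
  key <- paste(lo, hi)
  cnt <- table(key)[key]
  is_fluid <- region == "fluid"

  ext <- which(cnt == 1L)
  # interface: counted twice, the two owners differ in fluid/solid character
  dup <- which(cnt == 2L)
  ord <- dup[order(key[dup])]
  o1 <- ord[seq(1L, length(ord), by = 2L)]
  o2 <- ord[seq(2L, length(ord), by = 2L)]
  ifc <- is_fluid[cell[o1]] != is_fluid[cell[o2]]
  # keep fluid-side owner first for interface facets
  own1 <- ifelse(is_fluid[cell[o1]], o1, o2)[ifc]
  own2 <- ifelse(is_fluid[cell[o1]], o2, o1)[ifc]

  geom <- function(idx, owner) {
    a <- ea[idx]; b <- eb[idx]
    ax <- vertices[a, 1L]; ay <- vertices[a, 2L]
    bx <- vertices[b, 1L]; by <- vertices[b, 2L]
    len <- sqrt((bx - ax)^2 + (by - ay)^2)
    nxv <- (by - ay) / len; nyv <- -(bx - ax) / len
    # orient outward from owning cell
    ctr <- cbind(
      (vertices[tri[owner, 1L], 1L] + vertices[tri[owner, 2L], 1L] + vertices[tri[owner, 3L], 1L]) / 3,
      (vertices[tri[owner, 1L], 2L] + vertices[tri[owner, 2L], 2L] + vertices[tri[owner, 3L], 2L]) / 3
    )
    mx <- (ax + bx) / 2; my <- (ay + by) / 2
    flip <- (mx - ctr[, 1L]) * nxv + (my - ctr[, 2L]) * nyv < 0
    nxv[flip] <- -nxv[flip]; nyv[flip] <- -nyv[flip]
    tibble(a = a, b = b, cell = owner, mx = mx, my = my,
           nx = nxv, ny = nyv, len = len)
  }

  fe <- geom(ext, cell[ext])
  fe$tag <- tagger(fe$mx, fe$my, fe$nx, fe$ny)
  if (anyNA(fe$tag)) abort("untagged exterior facet: tagger returned NA")
  fi <- geom(own1, cell[own1])
  if (nrow(fi)) {
    fi$tag <- "glycocalyx_wall"
    fi$cell2 <- cell[own2]
  }
  fe$cell2 <- NA_integer_
  bind_rows(fe, fi)
}

#' Extract a solver submesh for a set of regions
#'
#' Returns an `fe_submesh` (coordinates in metres) carrying the cells of the
#' requested regions, their precomputed P1 geometry, and the boundary facet
#' table of the subdomain. Facets on the fluid-tissue interface keep the
#' `glycocalyx_wall` tag on both the fluid and the solid side.
#'
#' @param mesh An [outflow_mesh].
#' @param regions Character vector of region labels to keep.
#' @return An object of class `fe_submesh`.
#' @export
submesh <- function(mesh, regions) {
  keep <- which(mesh$region %in% regions)
  if (!length(keep)) abort(paste("no cells in regions:", paste(regions, collapse = ", ")))
  tri0 <- mesh$triangles[keep, , drop = FALSE]
  used <- sort(unique(as.vector(tri0)))
  remap <- integer(nrow(mesh$vertices)); remap[used] <- seq_along(used)
  tri <- matrix(remap[tri0], ncol = 3L)
  xy <- mesh$vertices[used, , drop = FALSE] * 1e-6  # micrometres -> metres

  # boundary facets of the subdomain: sub-edges appearing once
  ea <- c(tri0[, 1L], tri0[, 2L], tri0[, 3L])
  eb <- c(tri0[, 2L], tri0[, 3L], tri0[, 1L])
  cell <- rep(seq_along(keep), 3L)
  key <- paste(pmin(ea, eb), pmax(ea, eb))
  cnt <- table(key)[key]
  bnd <- which(cnt == 1L)

  pk <- paste(pmin(mesh$facets$a, mesh$facets$b), pmax(mesh$facets$a, mesh$facets$b))
  tagmap <- stats::setNames(mesh$facets$tag, pk)
  tags <- tagmap[key[bnd]]
  if (anyNA(tags)) abort("subdomain boundary facet missing from the parent facet table")

  a <- remap[ea[bnd]]; b <- remap[eb[bnd]]
  ax <- xy[a, 1L]; ay <- xy[a, 2L]; bx <- xy[b, 1L]; by <- xy[b, 2L]
  len <- sqrt((bx - ax)^2 + (by - ay)^2)
  nxv <- (by - ay) / len; nyv <- -(bx - ax) / len
  own <- cell[bnd]
  ctrx <- (xy[tri[own, 1L], 1L] + xy[tri[own, 2L], 1L] + xy[tri[own, 3L], 1L]) / 3
  ctry <- (xy[tri[own, 1L], 2L] + xy[tri[own, 2L], 2L] + xy[tri[own, 3L], 2L]) / 3
  mx <- (ax + bx) / 2; my <- (ay + by) / 2
  flip <- (mx - ctrx) * nxv + (my - ctry) * nyv < 0
  nxv[flip] <- -nxv[flip]; nyv[flip] <- -nyv[flip]

  g <- tri_geometry(xy, tri)
  if (any(g$area <= 0)) abort("inverted element in submesh")
  structure(
    list(xy = xy, tri = tri, n = nrow(xy), m = nrow(tri),
         region = mesh$region[keep], geom = g,
         node_parent = used, cell_parent = keep,
         facets = tibble(a = a, b = b, cell = own, tag = unname(tags),
                         mx = mx, my = my, nx = nxv, ny = nyv, len = len,
                         parent_a = ea[bnd], parent_b = eb[bnd])),
    class = "fe_submesh"
  )
}

facet_nodes <- function(fe, tags) {
  f <- fe$facets[fe$facets$tag %in% tags, ]
  sort(unique(c(f$a, f$b)))
}

#' Mesh quality report
#'
#' Summary statistics in the spirit of a solver's element-quality check:
#' element counts, minimum/maximum edge length, element areas, cell
#' anisotropy (bounding-box aspect ratio, 1 for square tensor cells), and a
#' count of inverted (non-positively oriented) elements, which are flagged
#' rather than silently accepted.
#'
#' @param mesh An [outflow_mesh].
#' @return A one-row tibble (`quality_report`).
#' @export
mesh_quality <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  x1 <- v[tr[, 1L], 1L]; y1 <- v[tr[, 1L], 2L]
  x2 <- v[tr[, 2L], 1L]; y2 <- v[tr[, 2L], 2L]
  x3 <- v[tr[, 3L], 1L]; y3 <- v[tr[, 3L], 2L]
  area <- ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)) / 2
  e1 <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  e2 <- sqrt((x3 - x2)^2 + (y3 - y2)^2)
  e3 <- sqrt((x1 - x3)^2 + (y1 - y3)^2)
  dx <- pmax(x1, x2, x3) - pmin(x1, x2, x3)
  dy <- pmax(y1, y2, y3) - pmin(y1, y2, y3)
  aspect <- pmax(dx / dy, dy / dx)
  n_inverted <- sum(area <= 0)
  if (n_inverted > 0) warn(sprintf("%d inverted element(s) detected", n_inverted))
  rep <- tibble(
    n_vertices = nrow(v), n_cells = nrow(tr),
    min_edge_um = min(e1, e2, e3), max_edge_um = max(e1, e2, e3),
    min_area_um2 = min(abs(area)), max_area_um2 = max(abs(area)),
    max_aspect = max(aspect), n_inverted = n_inverted
  )
  class(rep) <- c("quality_report", class(rep))
  rep
}

# Locate the glycocalyx-coated wall lines of a tensor mesh: distinct
# (axis, coordinate, fluid-side sign) triples from the interface facets.
wall_lines <- function(mesh) {
  f <- mesh$facets[mesh$facets$tag == "glycocalyx_wall", ]
  if (!nrow(f)) return(NULL)
  horiz <- abs(f$ny) > 0.5
  out <- list()
  probe <- 1e-4 * max(diff(range(mesh$xlines)), diff(range(mesh$ylines)))
  add <- function(axis, coords, mids_other) {
    for (cc in unique(round(coords, 9))) {
      sel <- abs(coords - cc) < 1e-9 + 1e-9 * abs(cc)
      mo <- mids_other[sel][1L]
      for (s in c(-1, 1)) {
        pt <- cc + s * probe
        reg <- if (axis == "y") mesh$classify(mo, pt) else mesh$classify(pt, mo)
        if (!is.na(reg) && reg == "fluid")
          out[[length(out) + 1L]] <<- list(axis = axis, at = cc, side = s)
      }
    }
  }
  add("y", f$my[horiz], f$mx[horiz])
  if (any(!horiz)) add("x", f$mx[!horiz], f$my[!horiz])
  out
}

#' Boundary-layer refinement near glycocalyx walls
#'
#' Inserts geometrically graded mesh lines on the fluid side of every
#' glycocalyx-tagged wall so the first wall-normal element is no larger than
#' `layer_scale / 3` -- the resolution needed for a resolved electric double
#' layer of thickness `layer_scale`. Region labels and the boundary tag set
#' are preserved; walls already resolved are left untouched.
#'
#' @param mesh An [outflow_mesh] built by this package (tensor-line metadata
#'   is required).
#' @param layer_scale Layer thickness to resolve, in nm (e.g. the Debye
#'   length or the glycocalyx thickness).
#' @param growth Geometric growth ratio of successive layers (>= 1).
#' @param max_cells Element budget; refinement beyond it is rejected.
#' @return A refined [outflow_mesh].
#' @export
refine_near_wall <- function(mesh, layer_scale, growth = 1.4, max_cells = 2e5) {
  stopifnot(layer_scale > 0, growth >= 1)
  h0 <- layer_scale / 3 / 1000  # nm -> um, first-layer size
  walls <- wall_lines(mesh)
  xl <- mesh$xlines; yl <- mesh$ylines
  for (w in walls) {
    lines <- if (w$axis == "x") xl else yl
    i <- which.min(abs(lines - w$at))
    nb <- i + w$side
    if (nb < 1L || nb > length(lines)) next
    gapv <- abs(lines[nb] - lines[i])
    if (gapv <= h0 * (1 + 1e-9)) next  # already resolved: no-op
    off <- fan_offsets(h0, growth, gapv)
    off <- off[off > h0 / 2 & off < gapv - h0 / 2]
    newpts <- w$at + w$side * c(h0 * 0, off)  # offsets exclude the wall itself
    newpts <- newpts[newpts != w$at]
    if (w$axis == "x") xl <- sort(unique(c(xl, newpts))) else yl <- sort(unique(c(yl, newpts)))
  }
  ncell_est <- 2 * (length(xl) - 1) * (length(yl) - 1)
  if (ncell_est > max_cells) {
    abort(sprintf(
      "refinement would build ~%d cells, exceeding the budget of %d; coarsen the bulk resolution or raise max_cells",
      ncell_est, as.integer(max_cells)
    ))
  }
  out <- mesh_from_grid(xl, yl, mesh$classify, mesh$tagger, params = mesh$params)
  stopifnot(setequal(unique(out$facets$tag), unique(mesh$facets$tag)))
  out
}

#' Plane-channel oracle mesh
#'
#' Rectangular all-fluid channel `[0, L] x [-h, h]` (micrometres) with the
#' inlet at `x = 0`, an open outlet at `x = L` and glycocalyx walls at
#' `y = +/- h`; the analytic validation geometry for the double-layer,
#' Poiseuille and electroosmotic closed forms.
#'
#' @param length_um,half_width_um Channel dimensions (um).
#' @param nx,ny Cell counts (uniform spacing).
#' @param ylines Optional explicit transverse lines (um), e.g. from
#'   [graded_channel_ylines()]; overrides `ny`.
#' @return An [outflow_mesh].
#' @export
channel_mesh <- function(length_um, half_width_um, nx = 8L, ny = 16L, ylines = NULL) {
  xl <- seq(0, length_um, length.out = nx + 1L)
  yl <- if (is.null(ylines)) seq(-half_width_um, half_width_um, length.out = ny + 1L) else ylines
  h <- half_width_um
  classify <- function(cx, cy) rep("fluid", length(cx))
  tagger <- function(mx, my, nx_, ny_) {
    ifelse(abs(ny_) > 0.5, "glycocalyx_wall",
           ifelse(nx_ < 0, "inlet", "outlet_open"))
  }
  mesh_from_grid(xl, yl, classify, tagger)
}

#' Wall-graded transverse mesh lines for a plane channel
#'
#' Geometric grading towards both walls: first element `h_wall_um`, growth
#' `ratio`, bulk spacing `h_bulk_um`. Used to resolve the electric double
#' layer in [channel_mesh()].
#'
#' @param half_width_um Channel half-width (um).
#' @param h_wall_um First wall-normal element size (um).
#' @param h_bulk_um Bulk spacing (um).
#' @param ratio Geometric growth ratio.
#' @return Sorted vector of y lines (um).
#' @export
graded_channel_ylines <- function(half_width_um, h_wall_um, h_bulk_um, ratio = 1.4) {
  fan <- list(h0 = h_wall_um, ratio = ratio)
  fill_interval(-half_width_um, half_width_um, h_bulk_um, fan_a = fan, fan_b = fan)
}

#' Rectangular solid-slab oracle mesh
#'
#' All-solid slab `[0, W] x [0, H]` with an anchored base, a loadable top
#' (tagged `free`) and symmetry (roller) sides; the constrained-slab
#' elasticity oracle geometry.
#'
#' @param width_um,height_um Slab dimensions (um).
#' @param nx,ny Cell counts.
#' @param region Region label for the moduli.
#' @return An [outflow_mesh].
#' @export
slab_mesh <- function(width_um, height_um, nx = 8L, ny = 8L, region = "TM") {
  xl <- seq(0, width_um, length.out = nx + 1L)
  yl <- seq(0, height_um, length.out = ny + 1L)
  classify <- function(cx, cy) rep(region, length(cx))
  tagger <- function(mx, my, nx_, ny_) {
    ifelse(abs(nx_) > 0.5, "symmetry", ifelse(ny_ < 0, "anchor", "free"))
  }
  mesh_from_grid(xl, yl, classify, tagger)
}
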