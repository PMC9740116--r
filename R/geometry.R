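# Synthetic idealized geometry of the conventional outflow pathway: a
# layered 2D flow domain (TM -> JCT -> SC inner wall in series along the
# flow axis) with the perforated SC inner wall and glycocalyx-tagged
# fluid-tissue interfaces. This stands in for eye-specific image-based
# reconstructions, which are out of scope.

#' Geometry parameters of the idealized outflow domain
#'
#' Defaults carry the printed anatomy: JCT thickness ~14 um, SC inner wall
#' (with basement membrane) ~2.2 um, inner-wall pores of diameter 1.3 um at
#' 835 pores/mm^2, and a ~109 nm glycocalyx coating all fluid-tissue
#' interfaces. The aqueous channel through the TM/JCT is a homogeneous
#' permeable-channel idealization of the trabecular spaces; its height sets
#' the desk-scale flow cross-section.
#'
#' @param tm_depth TM region extent along the flow axis (um).
#' @param jct_thickness JCT layer thickness along the flow axis (um).
#' @param sc_wall_thickness SC inner-wall (incl. basement membrane) thickness (um).
#' @param pore_density Inner-wall pore areal density (pores/mm^2).
#' @param pore_diameter Inner-wall pore diameter (um).
#' @param glycocalyx_thickness Glycocalyx layer thickness (nm).
#' @param channel_height Aqueous channel height across the flow axis (um).
#' @param tissue_thickness Thickness of the elastic tissue flanking the
#'   channel on each side (um), a homogenized stand-in for the beam
#'   lamellae bordering one trabecular flow space.
#' @param dimensionality `"plane-2D"` (a radial slice; the supported mode) or
#'   `"slab-3D"` (reserved; not implemented in this release).
#' @return A `geometry_params` list; `channel_length` is derived as the sum
#'   of the three layer extents.
#' @export
geometry_params <- function(tm_depth = 40, jct_thickness = 14,
                            sc_wall_thickness = 2.2, pore_density = 835,
                            pore_diameter = 1.3, glycocalyx_thickness = 109,
                            channel_height = 2, tissue_thickness = 10,
                            dimensionality = c("plane-2D", "slab-3D")) {
  dimensionality <- match.arg(dimensionality)
  p <- list(
    tm_depth = tm_depth, jct_thickness = jct_thickness,
    sc_wall_thickness = sc_wall_thickness, pore_density = pore_density,
    pore_diameter = pore_diameter, glycocalyx_thickness = glycocalyx_thickness,
    channel_height = channel_height, tissue_thickness = tissue_thickness,
    channel_length = tm_depth + jct_thickness + sc_wall_thickness,
    dimensionality = dimensionality
  )
  lengths <- c(p$tm_depth, p$jct_thickness, p$sc_wall_thickness,
               p$pore_diameter, p$channel_height, p$tissue_thickness)
  if (any(lengths <= 0)) abort("all geometry lengths must be positive")
  if (p$pore_density < 0) abort("pore_density must be >= 0")
  if (p$glycocalyx_thickness <= 0) abort("glycocalyx_thickness must be positive")
  if (p$glycocalyx_thickness / 1000 > p$channel_height / 5)
    abort("glycocalyx_thickness must be much smaller than channel_height")
  if (p$pore_density > 0 && p$pore_diameter >= pore_spacing_2d(p$pore_density))
    abort("pore_diameter must be below the mean pore spacing implied by pore_density")
  class(p) <- "geometry_params"
  p
}

#' Mean inner-wall pore spacing implied by an areal density
#'
#' In the 2D slice the 3D areal pore density maps to a wall-gap spacing of
#' `1/sqrt(density)`; at 835 pores/mm^2 this is about 34.6 um.
#'
#' @param pore_density Pores/mm^2.
#' @return Spacing in um.
#' @examples
#' pore_spacing_2d(835)
#' @export
pore_spacing_2d <- function(pore_density) {
  stopifnot(pore_density > 0)
  1000 / sqrt(pore_density)
}

#' Place pores in a planar patch of the SC inner wall
#'
#' Grid mode places exactly `round(density * area)` pores on a centred
#' rectangular lattice; jittered mode perturbs the same lattice with a seeded
#' RNG subject to non-overlap and containment. The planar patch generator is
#' defined independently of the 2D simulation slice.
#'
#' @param density Pores/mm^2.
#' @param diameter Pore diameter (um).
#' @param patch_dims Patch width and height (mm), length-2 numeric.
#' @param mode `"grid"` or `"jittered"`.
#' @param seed Integer seed; mandatory in jittered mode.
#' @return A `pore_layout` tibble with `x_um`, `y_um`, `diameter_um`.
#' @examples
#' nrow(place_inner_wall_pores(835, 1.3, c(1, 1)))   # 835
#' nrow(place_inner_wall_pores(835, 1.3, c(0.1, 0.1))) # 8
#' @export
place_inner_wall_pores <- function(density, diameter, patch_dims,
                                   mode = c("grid", "jittered"), seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(density >= 0, diameter > 0, length(patch_dims) == 2L, all(patch_dims >= 0))
  w_um <- patch_dims[1L] * 1000; h_um <- patch_dims[2L] * 1000
  n <- round(density * patch_dims[1L] * patch_dims[2L])
  if (n == 0L) {
    out <- tibble(x_um = numeric(0), y_um = numeric(0), diameter_um = numeric(0))
  } else {
    ny <- max(1L, floor(sqrt(n * h_um / max(w_um, 1e-12))))
    nx <- ceiling(n / ny)
    sx <- w_um / nx; sy <- h_um / ny
    if (min(sx, sy) <= diameter)
      abort("requested pore count incompatible with non-overlap at this diameter")
    gx <- (rep(seq_len(nx), ny) - 0.5) * sx
    gy <- (rep(seq_len(ny), each = nx) - 0.5) * sy
    gx <- gx[seq_len(n)]; gy <- gy[seq_len(n)]
    if (mode == "jittered") {
      if (is.null(seed)) abort("jittered mode requires a seed")
      amp <- pmax(0, (min(sx, sy) - diameter) / 2 * 0.9)
      old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
      set.seed(seed)
      gx <- pmin(pmax(gx + runif(n, -amp, amp), diameter / 2), w_um - diameter / 2)
      gy <- pmin(pmax(gy + runif(n, -amp, amp), diameter / 2), h_um - diameter / 2)
    }
    out <- tibble(x_um = gx, y_um = gy, diameter_um = rep(diameter, n))
  }
  attr(out, "patch_dims_mm") <- patch_dims
  attr(out, "mode") <- mode
  attr(out, "seed") <- seed
  class(out) <- c("pore_layout", class(out))
  out
}

#' Write a pore layout to CSV
#'
#' @param layout A `pore_layout`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pore_csv <- function(layout, path) {
  utils::write.csv(as.data.frame(layout)[, c("x_um", "y_um", "diameter_um")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build the idealized TM/JCT/SC outflow domain
#'
#' The 2D slice runs along the flow axis: an aqueous channel of height
#' `channel_height` bounded by elastic tissue, crossing the TM region and the
#' JCT layer, then interrupted by the SC inner wall, which is perforated by
#' pore gaps of width `pore_diameter` (their number from the 2D mapping of
#' the areal density; at least one gap when the density is positive, none
#' when it is zero, which yields a closed cavity). Every fluid-tissue facet
#' is tagged `glycocalyx_wall`; the anterior-chamber face is the `inlet`; the
#' pore exits are the `outlet_open` face; outer tissue boundaries are
#' `anchor`ed and the remaining exterior tissue facets are `free`.
#'
#' @param params A [geometry_params].
#' @param resolution Target element size controlling the channel
#'   cross-section (um); must be at most `channel_height / 4`. The bulk
#'   axial spacing is relaxed to `4 * resolution` (anisotropy a tensor mesh
#'   supports well).
#' @return An [outflow_mesh].
#' @export
build_outflow_domain <- function(params, resolution = params$channel_height / 4) {
  if (!inherits(params, "geometry_params")) abort("params must be geometry_params()")
  if (params$dimensionality == "slab-3D")
    abort("slab-3D geometry is reserved; this release supports plane-2D")
  if (resolution > params$channel_height / 4 + 1e-12)
    abort(sprintf("resolution %.3g um too coarse: must be <= channel_height/4 = %.3g um",
                  resolution, params$channel_height / 4))
  if (resolution > params$sc_wall_thickness)
    abort("resolution too coarse to resolve the SC inner wall")

  t <- params$tissue_thickness
  H <- params$channel_height
  x_tm <- params$tm_depth
  x_sc <- params$tm_depth + params$jct_thickness
  L <- params$channel_length
  y0 <- t; y1 <- t + H; Htot <- H + 2 * t

  n_gaps <- if (params$pore_density == 0) 0L else
    max(1L, round(H / pore_spacing_2d(params$pore_density)))
  if (n_gaps > 0) {
    seg <- H / n_gaps
    if (params$pore_diameter >= seg)
      abort("pore gap wider than the SC wall segment it perforates")
    gap_lo <- y0 + (seq_len(n_gaps) - 0.5) * seg - params$pore_diameter / 2
    gap_hi <- gap_lo + params$pore_diameter
  } else {
    gap_lo <- numeric(0); gap_hi <- numeric(0)
  }

  in_gap <- function(y) {
    if (!length(gap_lo)) return(rep(FALSE, length(y)))
    res <- rep(FALSE, length(y))
    for (k in seq_along(gap_lo)) res <- res | (y > gap_lo[k] & y < gap_hi[k])
    res
  }
  classify <- function(cx, cy) {
    fluid <- (cy > y0 & cy < y1 & cx < x_sc) | (cx >= x_sc & in_gap(cy))
    reg <- ifelse(cx < x_tm, "TM", ifelse(cx < x_sc, "JCT", "SC_wall"))
    ifelse(fluid, "fluid", reg)
  }
  tagger <- function(mx, my, nx_, ny_) {
    tag <- rep("free", length(mx))
    tag[abs(ny_) > 0.5 & (my < 1e-9 | my > Htot - 1e-9)] <- "anchor"
    left <- nx_ < -0.5 & mx < 1e-9
    tag[left] <- ifelse(my[left] > y0 & my[left] < y1, "inlet", "free")
    right <- nx_ > 0.5 & mx > L - 1e-9
    tag[right] <- ifelse(in_gap(my[right]), "outlet_open", "free")
    tag
  }

  hx <- 4 * resolution
  x_breaks <- c(0, x_tm, x_sc, L)
  xl <- c(
    fill_interval(0, x_tm, hx),
    fill_interval(x_tm, x_sc, hx),
    fill_interval(x_sc, L, min(resolution / 2, params$sc_wall_thickness / 4))
  )
  ybk <- sort(unique(c(0, y0, y1, Htot, gap_lo, gap_hi)))
  yl <- unlist(lapply(seq_len(length(ybk) - 1L), function(i) {
    hb <- if (ybk[i + 1L] <= y0 || ybk[i] >= y1) t / 3 else resolution
    fill_interval(ybk[i], ybk[i + 1L], hb)
  }))
  mesh <- mesh_from_grid(sort(unique(xl)), sort(unique(yl)), classify, tagger,
                         params = params)
  attr(mesh, "pore_gaps") <- if (n_gaps > 0) tibble(lo = gap_lo, hi = gap_hi) else tibble(lo = numeric(0), hi = numeric(0))
  mesh
}
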