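# Summary statistics matching the reported quantities, streamline
# extraction, and field export (legacy ASCII VTK with a matching reader for
# lossless round trips, CSV series, JSON summaries).

#' Summarize a results bundle
#'
#' One row of the scenario summary table: maxima of velocity, pressure, 1st
#' principal stress/strain and maximum shear stress/strain at the final time
#' step (peak IOP), the nodal-averaged displacement over the named tissue
#' region, and -- since the reporting time of a spatial maximum is a
#' convention -- the spatiotemporal maxima with their times as extra
#' columns.
#'
#' @param bundle An `efsi_results`.
#' @param region Tissue region for the nodal-averaged displacement
#'   (`"TM"`, the series default; other regions need stored final fields).
#' @param weighted Volume-weighted instead of unweighted nodal average
#'   (needs stored final fields).
#' @return A one-row tibble.
#' @export
summarize_bundle <- function(bundle, region = "TM", weighted = FALSE) {
  s <- bundle$series
  if (!nrow(s)) abort("empty results bundle")
  fin <- s[nrow(s), ]
  disp <- fin$tm_displacement_um
  if (region != "TM" || weighted) {
    if (is.null(bundle$final)) abort("region/weighted averages need store_fields = 'final'")
    st <- bundle$final$solid
    cells <- st$fe$region == region
    if (!any(cells)) abort(paste("empty region:", region))
    nodes <- sort(unique(as.vector(st$fe$tri[cells, ])))
    mag <- sqrt(st$displacement[nodes, 1L]^2 + st$displacement[nodes, 2L]^2)
    if (weighted) {
      w <- node_lumped_area(st$fe, cells)[nodes]
      disp <- sum(mag * w) / sum(w) * 1e6
    } else {
      disp <- mean(mag) * 1e6
    }
  }
  tibble(
    max_velocity_mm_s = fin$max_velocity_mm_s,
    max_pressure_mmhg = fin$max_pressure_mmhg,
    max_p1_stress_kpa = fin$max_p1_stress_kpa,
    max_p1_strain_pct = fin$max_p1_strain_pct,
    max_shear_stress_kpa = fin$max_shear_stress_kpa,
    max_shear_strain_pct = fin$max_shear_strain_pct,
    nodal_avg_displacement_um = disp,
    peak_velocity_mm_s = max(s$max_velocity_mm_s),
    t_peak_velocity_s = s$time[which.max(s$max_velocity_mm_s)]
  )
}

node_lumped_area <- function(fe, cells) {
  w <- rep(0, fe$n)
  tri <- fe$tri[cells, , drop = FALSE]
  A <- fe$geom$area[cells]
  for (a in 1:3) {
    acc <- Matrix::sparseMatrix(i = tri[, a], j = rep(1L, nrow(tri)),
                                x = A / 3, dims = c(fe$n, 1L))
    w <- w + as.vector(acc)
  }
  w
}

# Coarse spatial binning for point location in a submesh.
make_locator <- function(fe, nbins = 32L) {
  bb <- apply(fe$xy, 2L, range)
  dx <- max(bb[2L, 1L] - bb[1L, 1L], 1e-300) / nbins
  dy <- max(bb[2L, 2L] - bb[1L, 2L], 1e-300) / nbins
  cx <- (fe$xy[fe$tri[, 1L], ] + fe$xy[fe$tri[, 2L], ] + fe$xy[fe$tri[, 3L], ]) / 3
  bins <- vector("list", nbins * nbins)
  bx <- pmin(pmax(floor((cx[, 1L] - bb[1L, 1L]) / dx), 0), nbins - 1L)
  by <- pmin(pmax(floor((cx[, 2L] - bb[1L, 2L]) / dy), 0), nbins - 1L)
  # a triangle may span several bins: register it in a 3x3 neighbourhood
  for (k in seq_len(fe$m)) {
    for (ix in max(0, bx[k] - 1L):min(nbins - 1L, bx[k] + 1L))
      for (iy in max(0, by[k] - 1L):min(nbins - 1L, by[k] + 1L)) {
        id <- ix * nbins + iy + 1L
        bins[[id]] <- c(bins[[id]], k)
      }
  }
  list(bb = bb, dx = dx, dy = dy, nbins = nbins, bins = bins)
}

locate_point <- function(fe, loc, p) {
  ix <- floor((p[1L] - loc$bb[1L, 1L]) / loc$dx)
  iy <- floor((p[2L] - loc$bb[1L, 2L]) / loc$dy)
  if (ix < 0 || iy < 0 || ix >= loc$nbins || iy >= loc$nbins) return(NULL)
  cand <- loc$bins[[ix * loc$nbins + iy + 1L]]
  if (is.null(cand)) cand <- seq_len(fe$m)
  for (k in cand) {
    v <- fe$tri[k, ]
    x1 <- fe$xy[v[1L], ]; x2 <- fe$xy[v[2L], ]; x3 <- fe$xy[v[3L], ]
    det <- (x2[1L] - x1[1L]) * (x3[2L] - x1[2L]) - (x3[1L] - x1[1L]) * (x2[2L] - x1[2L])
    l2 <- ((p[1L] - x1[1L]) * (x3[2L] - x1[2L]) - (x3[1L] - x1[1L]) * (p[2L] - x1[2L])) / det
    l3 <- ((x2[1L] - x1[1L]) * (p[2L] - x1[2L]) - (p[1L] - x1[1L]) * (x2[2L] - x1[2L])) / det
    l1 <- 1 - l2 - l3
    eps <- -1e-10
    if (l1 >= eps && l2 >= eps && l3 >= eps) return(list(cell = k, w = c(l1, l2, l3)))
  }
  NULL
}

#' Trace velocity streamlines
#'
#' Fixed-step first-order integration of the velocity direction field from
#' each seed until the trace leaves the fluid region, stalls, or reaches
#' `max_steps`; the local speed is recorded along the arc. Seeds outside
#' the fluid region are skipped with a warning.
#'
#' @param flow A `flow_state`.
#' @param seeds Seed points, k x 2 matrix or data frame (um).
#' @param step Arc-length step (um).
#' @param max_steps Step budget per streamline.
#' @return A tibble with `id`, `s_um` (arc length), `x_um`, `y_um`,
#'   `speed_mm_s`.
#' @export
streamlines <- function(flow, seeds, step = 0.5, max_steps = 2000L) {
  fe <- flow$fe
  seeds <- as.matrix(seeds)
  loc <- make_locator(fe)
  out <- list()
  for (i in seq_len(nrow(seeds))) {
    p <- seeds[i, ] * 1e-6
    hit <- locate_point(fe, loc, p)
    if (is.null(hit)) {
      warn(sprintf("seed %d lies outside the fluid region; skipped", i))
      next
    }
    xs <- ys <- sp <- numeric(max_steps + 1L)
    ns <- 0L
    repeat {
      ux <- p1_interp(fe, flow$u[, 1L], hit$cell, matrix(hit$w, 1L))
      uy <- p1_interp(fe, flow$u[, 2L], hit$cell, matrix(hit$w, 1L))
      spd <- sqrt(ux^2 + uy^2)
      ns <- ns + 1L
      xs[ns] <- p[1L]; ys[ns] <- p[2L]; sp[ns] <- spd
      if (spd < 1e-300 || ns > max_steps) break
      p <- p + step * 1e-6 * c(ux, uy) / spd
      hit <- locate_point(fe, loc, p)
      if (is.null(hit)) break
    }
    out[[length(out) + 1L]] <- tibble(
      id = i, s_um = (seq_len(ns) - 1L) * step,
      x_um = xs[seq_len(ns)] * 1e6, y_um = ys[seq_len(ns)] * 1e6,
      speed_mm_s = sp[seq_len(ns)] * 1e3
    )
  }
  bind_rows(out)
}

# --- VTK / CSV / JSON export ------------------------------------------------

fmt17 <- function(x) formatC(x, format = "g", digits = 17)

#' Write fields on a submesh to a legacy ASCII VTK file
#'
#' @param fe An `fe_submesh`.
#' @param path Output file.
#' @param point_data Named list of nodal scalars (length n) or n x 2
#'   vectors.
#' @param cell_data Named list of per-cell scalars.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(fe, path, point_data = list(), cell_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("outflowEFSI fields")
  wl("ASCII")
  wl("DATASET UNSTRUCTURED_GRID")
  wl("POINTS ", fe$n, " double")
  writeLines(paste(fmt17(fe$xy[, 1L]), fmt17(fe$xy[, 2L]), "0"), con)
  wl("CELLS ", fe$m, " ", 4L * fe$m)
  writeLines(paste(3L, fe$tri[, 1L] - 1L, fe$tri[, 2L] - 1L, fe$tri[, 3L] - 1L), con)
  wl("CELL_TYPES ", fe$m)
  writeLines(rep("5", fe$m), con)
  if (length(point_data)) {
    wl("POINT_DATA ", fe$n)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v)) {
        wl("VECTORS ", nm, " double")
        writeLines(paste(fmt17(v[, 1L]), fmt17(v[, 2L]), "0"), con)
      } else {
        wl("SCALARS ", nm, " double 1")
        wl("LOOKUP_TABLE default")
        writeLines(fmt17(v), con)
      }
    }
  }
  if (length(cell_data)) {
    wl("CELL_DATA ", fe$m)
    for (nm in names(cell_data)) {
      v <- cell_data[[nm]]
      if (is.character(v) || is.factor(v)) v <- as.numeric(factor(v))
      wl("SCALARS ", nm, " double 1")
      wl("LOOKUP_TABLE default")
      writeLines(fmt17(v), con)
    }
  }
  invisible(path)
}

#' Read a legacy ASCII VTK unstructured-grid file
#'
#' Companion reader for [write_vtk()]: round-tripping through it reproduces
#' the written arrays exactly (17 significant digits).
#'
#' @param path VTK file.
#' @return List with `points` (n x 3), `cells` (m x 3, 1-based),
#'   `point_data`, `cell_data`.
#' @export
read_vtk <- function(path) {
  ln <- readLines(path)
  i <- grep("^POINTS", ln)[1L]
  n <- as.integer(strsplit(ln[i], "\\s+")[[1L]][2L])
  pts <- matrix(scan(text = ln[(i + 1L):(i + n)], quiet = TRUE), ncol = 3L, byrow = TRUE)
  i <- grep("^CELLS", ln)[1L]
  m <- as.integer(strsplit(ln[i], "\\s+")[[1L]][2L])
  cl <- matrix(scan(text = ln[(i + 1L):(i + m)], quiet = TRUE), ncol = 4L, byrow = TRUE)
  cells <- cl[, 2:4, drop = FALSE] + 1L
  read_block <- function(start, count) {
    res <- list()
    j <- start
    while (j <= length(ln)) {
      if (grepl("^(POINT_DATA|CELL_DATA)", ln[j])) break
      if (grepl("^SCALARS", ln[j])) {
        nm <- strsplit(ln[j], "\\s+")[[1L]][2L]
        res[[nm]] <- scan(text = ln[(j + 2L):(j + 1L + count)], quiet = TRUE)
        j <- j + 2L + count
      } else if (grepl("^VECTORS", ln[j])) {
        nm <- strsplit(ln[j], "\\s+")[[1L]][2L]
        v <- matrix(scan(text = ln[(j + 1L):(j + count)], quiet = TRUE),
                    ncol = 3L, byrow = TRUE)
        res[[nm]] <- v[, 1:2, drop = FALSE]
        j <- j + 1L + count
      } else j <- j + 1L
    }
    res
  }
  pd <- list(); cd <- list()
  ip <- grep("^POINT_DATA", ln)
  if (length(ip)) pd <- read_block(ip[1L] + 1L, n)
  ic <- grep("^CELL_DATA", ln)
  if (length(ic)) cd <- read_block(ic[1L] + 1L, m)
  list(points = pts, cells = cells, point_data = pd, cell_data = cd)
}

#' Export the fields of a results bundle
#'
#' `vtk` writes one file per subdomain (fluid and solid) with the final-step
#' fields and region/tag data; `csv` writes the scalar series; `json` writes
#' the summary row and provenance.
#'
#' @param bundle An `efsi_results` with stored final fields.
#' @param path Output path prefix (without extension).
#' @param format `"vtk"`, `"csv"` or `"json"`.
#' @return Character vector of files written, invisibly.
#' @export
export_fields <- function(bundle, path, format = c("vtk", "csv", "json")) {
  format <- match.arg(format)
  files <- character(0)
  if (format == "vtk") {
    if (is.null(bundle$final)) abort("vtk export needs store_fields = 'final'")
    fl <- bundle$final$fluid
    pd <- list(velocity = fl$u, pressure = fl$p)
    if (!is.null(bundle$final$potential) && bundle$final$potential$mode == "resolved") {
      pd$potential <- bundle$final$potential$phi
      pd$charge_density <- charge_density(bundle$final$potential)$rho
    }
    f1 <- paste0(path, "_fluid.vtk")
    write_vtk(fl$fe, f1, point_data = pd,
              cell_data = list(divergence = fl$divergence))
    so <- bundle$final$solid
    pv <- principal_values(so$sigma_total)
    f2 <- paste0(path, "_solid.vtk")
    write_vtk(so$fe, f2,
              point_data = list(displacement = so$displacement, P_i = so$P_i),
              cell_data = list(sigma_xx = so$sigma_total[, "xx"],
                               sigma_yy = so$sigma_total[, "yy"],
                               sigma_xy = so$sigma_total[, "xy"],
                               sigma_zz = so$sigma_total[, "zz"],
                               sigma_p1 = pv$p1,
                               max_shear = (pv$p1 - pv$p3) / 2))
    files <- c(f1, f2)
  } else if (format == "csv") {
    f <- paste0(path, "_series.csv")
    utils::write.csv(bundle$series, f, row.names = FALSE, quote = FALSE)
    files <- f
  } else {
    f <- paste0(path, "_summary.json")
    jsonlite::write_json(
      list(summary = summarize_bundle(bundle), provenance = bundle$provenance,
           scenario = bundle$config$name),
      f, auto_unbox = TRUE, digits = NA)
    files <- f
  }
  invisible(files)
}

#' Write a summary table to CSV
#'
#' One header row plus one row per scenario.
#'
#' @param summary Summary tibble (e.g. `canonical_suite()$summary`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(summary, path) {
  utils::write.csv(summary, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
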