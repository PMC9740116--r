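# Quasi-static near-incompressible linear elasticity of the outflow tissues
# (TM, JCT, SC inner wall) with the stress split sigma_total = sigma_t +
# sigma_i, sigma_t = lambda e I + 2 mu E, sigma_i = -P_i I. Near-
# incompressibility (nu = 0.495) is handled by a two-field mixed formulation
# (displacement + the volumetric stress phi = lambda e) with equal-order P1
# interpolation and pressure-gradient stabilization, which is free of
# volumetric locking; a pure-displacement mode exists for moderate nu.

#' Lame parameters from Young's modulus and Poisson's ratio
#'
#' @param young Young's modulus E (Pa), > 0.
#' @param poisson Poisson's ratio nu, in `[0, 0.5)`; the incompressible
#'   limit itself is not representable.
#' @return Named vector `c(lambda =, mu =)` (Pa).
#' @examples
#' lame_parameters(4e3, 0.495)
#' @export
lame_parameters <- function(young, poisson) {
  stopifnot(young > 0)
  if (poisson < 0 || poisson >= 0.5)
    abort("poisson must lie in [0, 0.5): the incompressible limit is not representable")
  mu <- young / (2 * (1 + poisson))
  lambda <- young * poisson / ((1 + poisson) * (1 - 2 * poisson))
  c(lambda = lambda, mu = mu)
}

#' Elastic properties of the outflow tissues
#'
#' Defaults carry the printed values: Young's moduli 4, 4 and 7.48 kPa for
#' TM, JCT and SC inner wall, Poisson's ratio 0.495 (nearly incompressible),
#' and a ~500 uN pre-tension representing ciliary-muscle loading. The
#' per-region volume fraction `eps_t` multiplies the equilibrium stress
#' divergence and defaults to 1 (standard equilibrium).
#'
#' @param young Named vector of Young's moduli per region (Pa).
#' @param poisson Poisson's ratio (shared).
#' @param volume_fraction Per-region tissue volume fraction `eps_t` (scalar
#'   or named vector), in (0, 1].
#' @param pretension Pre-tension resultant (N).
#' @param plane `"strain"` (default; long circumferential extent) or
#'   `"stress"`.
#' @param formulation `"mixed"` (locking-free default) or `"displacement"`.
#' @return A `solid_properties` list with derived Lame parameters per region.
#' @export
solid_properties <- function(young = c(TM = 4e3, JCT = 4e3, SC_wall = 7.48e3),
                             poisson = 0.495, volume_fraction = 1,
                             pretension = 500e-6,
                             plane = c("strain", "stress"),
                             formulation = c("mixed", "displacement")) {
  plane <- match.arg(plane)
  formulation <- match.arg(formulation)
  if (any(volume_fraction <= 0 | volume_fraction > 1))
    abort("volume_fraction must lie in (0, 1]")
  lame <- vapply(young, function(E) lame_parameters(E, poisson), numeric(2))
  structure(list(
    young = young, poisson = poisson,
    lambda = stats::setNames(lame["lambda", ], names(young)),
    mu = stats::setNames(lame["mu", ], names(young)),
    volume_fraction = volume_fraction, pretension = pretension,
    plane = plane, formulation = formulation
  ), class = "solid_properties")
}

region_value <- function(values, region) {
  if (length(values) == 1L && is.null(names(values))) return(rep(values, length(region)))
  if (is.null(names(values))) abort("per-region values must be named")
  miss <- setdiff(unique(region), names(values))
  if (length(miss)) abort(paste("missing property for region(s):", paste(miss, collapse = ", ")))
  unname(values[region])
}

# Effective lambda for the 2D reduction (plane stress softens it).
lambda_eff <- function(props, region) {
  lam <- region_value(props$lambda, region)
  mu <- region_value(props$mu, region)
  if (props$plane == "stress") 2 * lam * mu / (lam + 2 * mu) else lam
}

#' Infinitesimal strain tensor of a displacement field
#'
#' `E = (grad u + grad u^T) / 2` and its trace, the volumetric strain
#' `e = div u`, evaluated per element (piecewise constant for P1
#' displacements). Rigid translations and infinitesimal rotations give
#' exactly zero strain.
#'
#' @param displacement n x 2 nodal displacement (m).
#' @param fe The [submesh()] the displacement lives on.
#' @return List with `strain` (m x 3: xx, yy, xy tensor components) and `e`.
#' @export
strain_tensor <- function(displacement, fe) {
  g <- fe$geom
  exx <- eyy <- gxy <- rep(0, fe$m)
  for (a in 1:3) {
    ux <- displacement[fe$tri[, a], 1L]; uy <- displacement[fe$tri[, a], 2L]
    exx <- exx + g$bx[, a] * ux
    eyy <- eyy + g$by[, a] * uy
    gxy <- gxy + g$by[, a] * ux + g$bx[, a] * uy
  }
  list(strain = cbind(xx = exx, yy = eyy, xy = gxy / 2), e = exx + eyy)
}

#' Stress decomposition of the tissue
#'
#' Elastic stress `sigma_t = lambda e I + 2 mu E`, interstitial-pressure
#' stress `sigma_i = -P_i I`, and their sum `sigma_total`, per element. In
#' plane strain the out-of-plane component `sigma_zz = lambda e - P_i` is
#' carried along.
#'
#' @param strain m x 3 strain components (xx, yy, xy) as from
#'   [strain_tensor()].
#' @param e Volumetric strain per element.
#' @param P_i Interstitial (aqueous) pressure per element (Pa); scalar or
#'   length-m.
#' @param props [solid_properties()].
#' @param region Region label per element (for per-region moduli); a single
#'   label is recycled.
#' @return List of m x 4 component matrices (`xx`, `yy`, `xy`, `zz`):
#'   `sigma_t`, `sigma_i`, `sigma_total`.
#' @export
stress_decomposition <- function(strain, e, P_i, props, region = "TM") {
  m <- nrow(strain)
  region <- if (length(region) == 1L) rep(region, m) else region
  lam <- lambda_eff(props, region)
  mu <- region_value(props$mu, region)
  P_i <- rep(P_i, length.out = m)
  zz_t <- if (props$plane == "strain") lam * e else rep(0, m)
  sigma_t <- cbind(xx = lam * e + 2 * mu * strain[, "xx"],
                   yy = lam * e + 2 * mu * strain[, "yy"],
                   xy = 2 * mu * strain[, "xy"],
                   zz = zz_t)
  sigma_i <- cbind(xx = -P_i, yy = -P_i, xy = rep(0, m), zz = -P_i)
  list(sigma_t = sigma_t, sigma_i = sigma_i, sigma_total = sigma_t + sigma_i)
}

solid_fixed_dofs <- function(fe) {
  anc <- facet_nodes(fe, "anchor")
  sf <- fe$facets[fe$facets$tag == "symmetry", ]
  sx <- sort(unique(c(sf$a[abs(sf$nx) > 0.5], sf$b[abs(sf$nx) > 0.5])))
  sy <- sort(unique(c(sf$a[abs(sf$ny) > 0.5], sf$b[abs(sf$ny) > 0.5])))
  list(anchor = anc, sym_x = setdiff(sx, anc), sym_y = setdiff(sy, anc))
}

assemble_solid_matrix <- function(fe, props, stab_alpha = 0.1) {
  g <- fe$geom; n <- fe$n; tri <- fe$tri
  mu <- region_value(props$mu, fe$region)
  lam <- lambda_eff(props, fe$region)
  epst <- region_value(props$volume_fraction, fe$region)
  mixed <- props$formulation == "mixed"

  a11 <- a12 <- a22 <- matrix(0, fe$m, 9L)
  idx <- 0L
  for (a in 1:3) for (b in 1:3) {
    idx <- idx + 1L
    a11[, idx] <- epst * 2 * mu * g$area * (g$bx[, a] * g$bx[, b] + 0.5 * g$by[, a] * g$by[, b])
    a22[, idx] <- epst * 2 * mu * g$area * (g$by[, a] * g$by[, b] + 0.5 * g$bx[, a] * g$bx[, b])
    a12[, idx] <- epst * 2 * mu * g$area * 0.5 * g$by[, a] * g$bx[, b]
    if (!mixed) {
      a11[, idx] <- a11[, idx] + epst * lam * g$area * g$bx[, a] * g$bx[, b]
      a22[, idx] <- a22[, idx] + epst * lam * g$area * g$by[, a] * g$by[, b]
      a12[, idx] <- a12[, idx] + epst * lam * g$area * g$by[, a] * g$bx[, b]
    }
  }

  tr <- new_triplets()
  blocks <- list(
    block_triplets(tri, a11, 0L, 0L),
    block_triplets(tri, a22, n, n),
    block_triplets(tri, a12, 0L, n),
    transpose_block(block_triplets(tri, a12, 0L, n))
  )
  ndof <- if (mixed) 3L * n else 2L * n
  if (mixed) {
    gx <- grad_blocks(g, tri, "x"); gy <- grad_blocks(g, tri, "y")
    gx_e <- gx * epst; gy_e <- gy * epst
    stab <- stiffness_blocks(g, tri, coef = stab_alpha * 2 * g$area / (2 * mu))
    mlam <- mass_blocks(g, tri, coef = 1 / lam)
    blocks <- c(blocks, list(
      block_triplets(tri, gx_e, 0L, 2L * n),
      block_triplets(tri, gy_e, n, 2L * n),
      transpose_block(block_triplets(tri, gx, 0L, 2L * n)),
      transpose_block(block_triplets(tri, gy, n, 2L * n)),
      block_triplets(tri, -mlam - stab, 2L * n, 2L * n)
    ))
  }
  for (blk in blocks) tr <- add_triplets(tr, blk$i, blk$j, blk$x)
  list(tr = tr, ndof = ndof, mixed = mixed)
}

# Nodal load from facet tractions: each facet endpoint receives len/2 * t.
facet_traction_load <- function(rhs, n, facets, tx, ty) {
  for (k in seq_len(nrow(facets))) {
    for (nd in c(facets$a[k], facets$b[k])) {
      rhs[nd] <- rhs[nd] + facets$len[k] / 2 * tx[k]
      rhs[n + nd] <- rhs[n + nd] + facets$len[k] / 2 * ty[k]
    }
  }
  rhs
}

# Pre-tension as a statically equivalent distributed traction over the TM
# anchoring boundary (the anterior TM face), pulling along the outward
# normal; `depth` converts the 3D resultant to a 2D line load.
pretension_facets <- function(fe) {
  f <- fe$facets[fe$facets$tag == "free", ]
  if (!nrow(f)) return(f)
  tm_cells <- fe$region[f$cell] == "TM"
  xmin <- min(fe$xy[, 1L])
  front <- abs(f$mx - xmin) < 1e-12 + 1e-9 * abs(xmin) & abs(f$nx) > 0.5
  f[tm_cells & front, ]
}

#' Quasi-static tissue equilibrium
#'
#' Solves the mixed near-incompressible equilibrium with the total stress of
#' [stress_decomposition()]: anchored facets are fixed, symmetry facets
#' roll, interface facets carry the fluid traction, the interstitial
#' pressure enters as a volumetric load, and the pre-tension resultant is
#' spread as a uniform traction along the anterior TM face.
#'
#' @param mesh An [outflow_mesh] (its tissue regions are extracted) or a
#'   solid [submesh()].
#' @param props [solid_properties()].
#' @param interface_traction Per-facet traction table as produced by the
#'   fluid solver (columns `parent_a`, `parent_b`, `tx`, `ty`), or `NULL`.
#' @param P_i Nodal interstitial pressure on the solid submesh (Pa), a
#'   scalar, or `NULL` for zero.
#' @param pretension Pre-tension resultant (N); 0 disables it.
#' @param depth Out-of-plane extent (m) the plane-strain slice represents,
#'   converting 3D force resultants to 2D line loads; the default is the
#'   ~36 mm circumference of the TM annulus.
#' @param tractions Named list `tag = c(tx, ty)` of constant tractions on
#'   additional facet tags (Pa).
#' @param dirichlet Optional list `list(nodes =, values =)` prescribing
#'   displacements (n x 2 rows matching `nodes`) instead of the anchors --
#'   used e.g. by patch tests.
#' @param cache Optional environment reusing the assembled/factorized system
#'   across repeated solves on the same mesh (the transient pipeline).
#' @return A `mechanical_state` with displacement, strain, volumetric
#'   strain, the stress split, and anchor reaction forces.
#' @export
solve_quasistatic <- function(mesh, props, interface_traction = NULL,
                              P_i = NULL, pretension = 0, depth = 36e-3,
                              tractions = list(), dirichlet = NULL,
                              cache = NULL) {
  fe <- if (inherits(mesh, "fe_submesh")) mesh else
    submesh(mesh, c("TM", "JCT", "SC_wall"))
  n <- fe$n
  sys <- if (!is.null(cache) && !is.null(cache$sys)) cache$sys else
    assemble_solid_matrix(fe, props)

  fx <- solid_fixed_dofs(fe)
  if (is.null(dirichlet) && !length(fx$anchor) && !length(fx$sym_x) && !length(fx$sym_y))
    abort("no anchor or symmetry facets: the system is singular")

  rhs <- rep(0, sys$ndof)
  # interstitial pressure load: int P_i div v
  if (!is.null(P_i)) {
    Pn <- rep(P_i, length.out = n)
    g <- fe$geom
    pbar <- (Pn[fe$tri[, 1L]] + Pn[fe$tri[, 2L]] + Pn[fe$tri[, 3L]]) / 3
    epst <- region_value(props$volume_fraction, fe$region)
    for (a in 1:3) {
      load <- epst * g$area * pbar
      rhs[1:n] <- rhs[1:n] + as.vector(Matrix::sparseMatrix(
        i = fe$tri[, a], j = rep(1L, fe$m), x = load * g$bx[, a], dims = c(n, 1L)))
      rhs[(n + 1L):(2L * n)] <- rhs[(n + 1L):(2L * n)] + as.vector(Matrix::sparseMatrix(
        i = fe$tri[, a], j = rep(1L, fe$m), x = load * g$by[, a], dims = c(n, 1L)))
    }
  } else {
    Pn <- rep(0, n)
  }
  if (!is.null(interface_traction) && nrow(interface_traction)) {
    f <- fe$facets[fe$facets$tag == "glycocalyx_wall", ]
    key_fe <- paste(pmin(f$parent_a, f$parent_b), pmax(f$parent_a, f$parent_b))
    key_tr <- paste(pmin(interface_traction$parent_a, interface_traction$parent_b),
                    pmax(interface_traction$parent_a, interface_traction$parent_b))
    idx <- match(key_fe, key_tr)
    if (anyNA(idx)) abort("interface traction does not cover all glycocalyx facets")
    rhs <- facet_traction_load(rhs, n, f,
                               interface_traction$tx[idx], interface_traction$ty[idx])
  }
  for (tg in names(tractions)) {
    f <- fe$facets[fe$facets$tag == tg, ]
    if (nrow(f))
      rhs <- facet_traction_load(rhs, n, f, rep(tractions[[tg]][1L], nrow(f)),
                                 rep(tractions[[tg]][2L], nrow(f)))
  }
  if (pretension != 0) {
    f <- pretension_facets(fe)
    if (!nrow(f)) abort("pretension requested but no anterior TM facets found")
    mag <- pretension / (depth * sum(f$len))
    rhs <- facet_traction_load(rhs, n, f, mag * f$nx, mag * f$ny)
  }
  rhs_free <- rhs  # unconstrained copy for reaction recovery

  if (is.null(dirichlet)) {
    fixed <- c(fx$anchor, fx$sym_x, n + fx$anchor, n + fx$sym_y)
    values <- rep(0, length(fixed))
  } else {
    fixed <- c(dirichlet$nodes, n + dirichlet$nodes)
    values <- c(dirichlet$values[, 1L], dirichlet$values[, 2L])
  }
  if (!is.null(cache) && !is.null(cache$lu) && is.null(dirichlet)) {
    fact <- cache$lu
    Afree <- cache$Afree
  } else {
    con <- constrain_rows(sys$tr, fixed)
    A <- Matrix::sparseMatrix(i = con$i, j = con$j, x = con$x,
                              dims = c(sys$ndof, sys$ndof))
    fact <- scaled_lu(A)
    Afree <- triplets_matrix(sys$tr, sys$ndof)
    if (!is.null(cache) && is.null(dirichlet)) {
      cache$sys <- sys; cache$lu <- fact; cache$Afree <- Afree
    }
  }
  rhs[fixed] <- values
  sol <- solve_scaled(fact, rhs)
  if (any(!is.finite(sol))) abort("elastic solve produced non-finite fields")

  u <- cbind(sol[1:n], sol[(n + 1L):(2L * n)])
  phi <- if (sys$mixed) sol[(2L * n + 1L):(3L * n)] else NULL

  # reactions: residual of the unconstrained equations at fixed dofs
  resid <- as.vector(Afree %*% sol) - rhs_free
  reactions <- matrix(0, n, 2L)
  reactions[fx$anchor, 1L] <- resid[fx$anchor]
  reactions[fx$anchor, 2L] <- resid[n + fx$anchor]

  st <- strain_tensor(u, fe)
  P_cell <- (Pn[fe$tri[, 1L]] + Pn[fe$tri[, 2L]] + Pn[fe$tri[, 3L]]) / 3
  dec <- stress_decomposition(st$strain, st$e, P_cell, props, fe$region)
  if (sys$mixed) {
    # volumetric part from the stable mixed variable phi = lambda e
    phibar <- (phi[fe$tri[, 1L]] + phi[fe$tri[, 2L]] + phi[fe$tri[, 3L]]) / 3
    lam <- lambda_eff(props, fe$region)
    corr <- phibar - lam * st$e
    for (cmp in c("xx", "yy", "zz")) {
      dec$sigma_t[, cmp] <- dec$sigma_t[, cmp] + corr * (cmp != "zz" | props$plane == "strain")
    }
    dec$sigma_total <- dec$sigma_t + dec$sigma_i
  }

  structure(list(
    displacement = u, velocity = NULL, phi = phi,
    strain = st$strain, vol_strain = st$e,
    sigma_t = dec$sigma_t, sigma_i = dec$sigma_i, sigma_total = dec$sigma_total,
    P_i = Pn, fe = fe, props = props, reactions = reactions,
    reaction_sum = colSums(reactions)
  ), class = "mechanical_state")
}

#' Principal values of a symmetric tensor field
#'
#' Eigenvalues sorted descending per point. For 2D plane-strain stress
#' fields the out-of-plane component (`zz` column, `nu (sxx + syy)`) is
#' included as the third value; if no `zz` column is present 0 is used
#' (plane-strain strain tensors and plane-stress stress tensors).
#'
#' @param tensor Either one symmetric 2x2/3x3 matrix, or an m x k matrix /
#'   data frame with columns `xx`, `yy`, `xy` and optionally `zz`.
#' @return A tibble with `p1 >= p2 >= p3`.
#' @export
principal_values <- function(tensor) {
  if (is.matrix(tensor) && nrow(tensor) == ncol(tensor) &&
      !all(c("xx", "yy", "xy") %in% colnames(tensor))) {
    if (max(abs(tensor - t(tensor))) > 1e-12 * max(1, max(abs(tensor))))
      abort("tensor must be symmetric")
    ev <- sort(eigen(tensor, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    if (length(ev) == 2L) ev <- sort(c(ev, 0), decreasing = TRUE)
    return(tibble(p1 = ev[1L], p2 = ev[2L], p3 = ev[3L]))
  }
  tensor <- as.data.frame(tensor)
  if (!all(c("xx", "yy", "xy") %in% names(tensor)))
    abort("tensor field needs columns xx, yy, xy (and optionally zz)")
  avg <- (tensor$xx + tensor$yy) / 2
  rad <- sqrt(((tensor$xx - tensor$yy) / 2)^2 + tensor$xy^2)
  zz <- if ("zz" %in% names(tensor)) tensor$zz else rep(0, nrow(tensor))
  vals <- cbind(avg + rad, avg - rad, zz)
  ord <- t(apply(vals, 1L, sort, decreasing = TRUE))
  tibble(p1 = ord[, 1L], p2 = ord[, 2L], p3 = ord[, 3L])
}

#' Maximum shear of a symmetric tensor field
#'
#' `(p1 - p3) / 2` per point; zero for hydrostatic states.
#'
#' @inheritParams principal_values
#' @return Numeric vector.
#' @export
max_shear <- function(tensor) {
  pv <- principal_values(tensor)
  as.numeric((pv$p1 - pv$p3) / 2)
}

# Stored elastic energy 1/2 int sigma_t : E (per unit depth).
elastic_energy <- function(state) {
  A <- state$fe$geom$area
  s <- state$sigma_t; e <- state$strain
  sum(A * 0.5 * (s[, "xx"] * e[, "xx"] + s[, "yy"] * e[, "yy"] +
                   2 * s[, "xy"] * e[, "xy"]))
}
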