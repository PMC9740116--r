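# Linear (P1) triangular finite-element kernels shared by the potential,
# flow and elasticity solvers. All kernels work on an `fe_submesh` whose
# coordinates are in metres; assembly is fully vectorised over elements and
# accumulated as (i, j, x) triplets so duplicate entries sum on construction.

# Geometric precomputation: signed areas and the constant gradients of the
# three barycentric basis functions on every triangle.
tri_geometry <- function(xy, tri) {
  x1 <- xy[tri[, 1L], 1L]; y1 <- xy[tri[, 1L], 2L]
  x2 <- xy[tri[, 2L], 1L]; y2 <- xy[tri[, 2L], 2L]
  x3 <- xy[tri[, 3L], 1L]; y3 <- xy[tri[, 3L], 2L]
  area2 <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  area <- area2 / 2
  # grad(lambda_i) = (b_i, c_i)
  bx <- cbind(y2 - y3, y3 - y1, y1 - y2) / area2
  by <- cbind(x3 - x2, x1 - x3, x2 - x1) / area2
  list(area = area, bx = bx, by = by)
}

# Triplet accumulator ---------------------------------------------------------

new_triplets <- function() list(i = list(), j = list(), x = list())

add_triplets <- function(tr, i, j, x) {
  k <- length(tr$i) + 1L
  tr$i[[k]] <- i; tr$j[[k]] <- j; tr$x[[k]] <- x
  tr
}

triplets_matrix <- function(tr, n, m = n) {
  Matrix::sparseMatrix(
    i = unlist(tr$i, use.names = FALSE),
    j = unlist(tr$j, use.names = FALSE),
    x = unlist(tr$x, use.names = FALSE),
    dims = c(n, m)
  )
}

# Elementwise 3x3 block triplets. `val` is an m x 9 matrix ordered
# (i1j1, i1j2, i1j3, i2j1, ...), rows/cols offset into a larger system.
block_triplets <- function(tri, val, row_off = 0L, col_off = 0L) {
  ii <- tri[, c(1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L)] + row_off
  jj <- tri[, c(1L, 2L, 3L, 1L, 2L, 3L, 1L, 2L, 3L)] + col_off
  list(i = as.vector(ii), j = as.vector(jj), x = as.vector(val))
}

# Transposed block entries (swap rows and columns, offsets included).
transpose_block <- function(blk) list(i = blk$j, j = blk$i, x = blk$x)

# Stiffness: coef_K * A_K * (grad l_i . grad l_j); `coef` per element.
stiffness_blocks <- function(g, tri, coef = 1) {
  v <- matrix(0, nrow(tri), 9L)
  idx <- 0L
  for (a in 1:3) for (b in 1:3) {
    idx <- idx + 1L
    v[, idx] <- coef * g$area * (g$bx[, a] * g$bx[, b] + g$by[, a] * g$by[, b])
  }
  v
}

# Consistent mass: coef_K * A_K / 12 * (1 + delta_ij).
mass_blocks <- function(g, tri, coef = 1) {
  v <- matrix(0, nrow(tri), 9L)
  idx <- 0L
  for (a in 1:3) for (b in 1:3) {
    idx <- idx + 1L
    v[, idx] <- coef * g$area / 12 * (1 + (a == b))
  }
  v
}

# Lumped mass (diagonal, A/3 per vertex): used where an M-matrix structure
# matters (the Helmholtz closure keeps its discrete maximum principle).
lumped_mass_blocks <- function(g, tri, coef = 1) {
  v <- matrix(0, nrow(tri), 9L)
  for (a in 1:3) v[, (a - 1L) * 3L + a] <- coef * g$area / 3
  v
}

# Pressure-gradient coupling C[i, j] = int lambda_j d(lambda_i)/dx dx
# (entry is independent of j): used as -C %*% p in the momentum rows and
# t(C) %*% u in the continuity row.
grad_blocks <- function(g, tri, deriv = c("x", "y")) {
  deriv <- match.arg(deriv)
  d <- if (deriv == "x") g$bx else g$by
  v <- matrix(0, nrow(tri), 9L)
  idx <- 0L
  for (a in 1:3) for (b in 1:3) {
    idx <- idx + 1L
    v[, idx] <- g$area / 3 * d[, a]
  }
  v
}

# Convection N[i, j] = rho * int lambda_i (w . grad lambda_j) dx with w the
# P1 advecting field (m x 3 nodal values per element and component).
convection_blocks <- function(g, tri, wx, wy, rho) {
  sx <- wx[, 1L] + wx[, 2L] + wx[, 3L]
  sy <- wy[, 1L] + wy[, 2L] + wy[, 3L]
  v <- matrix(0, nrow(tri), 9L)
  idx <- 0L
  for (a in 1:3) for (b in 1:3) {
    idx <- idx + 1L
    ix <- g$area / 12 * (sx + wx[, a])
    iy <- g$area / 12 * (sy + wy[, a])
    v[, idx] <- rho * (g$bx[, b] * ix + g$by[, b] * iy)
  }
  v
}

# Nodal load vector from a per-element force density (m x 1): int f lambda_i.
cell_load <- function(g, tri, f, n) {
  contrib <- g$area / 3 * f
  as.vector(Matrix::sparseMatrix(
    i = as.vector(tri), j = rep(1L, 3L * nrow(tri)),
    x = rep(contrib, 3L), dims = c(n, 1L)
  ))
}

# Replace rows of a triplet set by identity rows for Dirichlet dofs.
# Columns are kept, so pinned unknowns propagate consistently and changing
# only the boundary values changes only the right-hand side.
constrain_rows <- function(tr, fixed) {
  i <- unlist(tr$i, use.names = FALSE)
  j <- unlist(tr$j, use.names = FALSE)
  x <- unlist(tr$x, use.names = FALSE)
  keep <- !(i %in% fixed)
  list(
    i = c(i[keep], fixed),
    j = c(j[keep], fixed),
    x = c(x[keep], rep(1, length(fixed)))
  )
}

finalize_system <- function(tr, fixed, values, rhs, ndof) {
  con <- constrain_rows(tr, fixed)
  A <- Matrix::sparseMatrix(i = con$i, j = con$j, x = con$x, dims = c(ndof, ndof))
  rhs[fixed] <- values
  list(A = A, rhs = rhs)
}

# Symmetric diagonal equilibration + sparse LU: the systems mix O(1)
# Dirichlet identity rows with FE entries many orders smaller (SI units at
# micrometre scale), which trips naive conditioning checks.
scaled_lu <- function(A) {
  d <- abs(Matrix::diag(A))
  d[d == 0 | !is.finite(d)] <- 1
  s <- 1 / sqrt(d)
  D <- Matrix::Diagonal(x = s)
  list(lu = Matrix::lu(D %*% A %*% D), s = s)
}

solve_scaled <- function(fact, rhs) {
  fact$s * as.vector(Matrix::solve(fact$lu, fact$s * rhs))
}

# Linear interpolation of a nodal field to arbitrary points given containing
# triangles (bary weights); used by streamline tracing.
p1_interp <- function(fe, field, cells, w) {
  f <- cbind(field[fe$tri[cells, 1L]], field[fe$tri[cells, 2L]], field[fe$tri[cells, 3L]])
  rowSums(f * w)
}
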