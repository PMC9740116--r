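# Partitioned (Dirichlet-Neumann) fluid-solid coupling: a fixed-point
# sub-iteration over the interface displacement, optionally accelerated by
# Aitken under-relaxation. The operators are passed as closures so the same
# scheme drives both the production pipeline and small manufactured test
# problems (where a monolithic assembly is available as an oracle).

#' One coupled sub-iteration cycle to convergence
#'
#' Iterates `traction = fluid_solve(d)`, `d_new = solid_solve(traction)`
#' until the relative interface-displacement increment drops below `tol`.
#' `relaxation = "aitken"` applies dynamic Aitken under-relaxation to the
#' increment; `"fixed"` uses plain (unrelaxed) substitution, which is
#' adequate in the viscous-dominated, quasi-static regime of the outflow
#' pathway.
#'
#' @param fluid_solve Function of the interface displacement vector
#'   returning the interface traction (any numeric object accepted by
#'   `solid_solve`).
#' @param solid_solve Function of that traction returning the new interface
#'   displacement vector.
#' @param d0 Starting interface displacement.
#' @param tol Relative convergence tolerance on the displacement increment.
#' @param max_iters Iteration budget; exceeding it aborts with the residual
#'   history.
#' @param relaxation `"fixed"` or `"aitken"`.
#' @return List with `d`, `traction`, `iterations`, `residuals`.
#' @export
couple_step <- function(fluid_solve, solid_solve, d0, tol = 1e-6,
                        max_iters = 50L, relaxation = c("fixed", "aitken")) {
  relaxation <- match.arg(relaxation)
  d <- d0
  omega <- 1
  r_prev <- NULL
  residuals <- numeric(0)
  for (it in seq_len(max_iters)) {
    traction <- fluid_solve(d)
    d_tilde <- solid_solve(traction)
    r <- d_tilde - d
    res <- sqrt(sum(r^2)) / max(sqrt(sum(d_tilde^2)), 1e-300)
    residuals <- c(residuals, res)
    if (res < tol) {
      return(list(d = d_tilde, traction = traction, iterations = it,
                  residuals = residuals))
    }
    if (relaxation == "aitken" && !is.null(r_prev)) {
      dr <- r - r_prev
      denom <- sum(dr^2)
      if (denom > 0) omega <- -omega * sum(r_prev * dr) / denom
      omega <- min(max(omega, 0.05), 2)
    }
    d <- d + omega * r
    r_prev <- r
  }
  abort(paste0("coupling failed to converge in ", max_iters,
               " iterations; residual history: ",
               paste(signif(residuals, 3), collapse = ", ")))
}
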