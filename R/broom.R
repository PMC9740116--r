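# broom-style accessors for result objects.

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the scalar series of a scenario run
#'
#' @param x An `efsi_results`.
#' @param ... Unused.
#' @return Long tibble with `step`, `time`, `quantity`, `value`.
#' @export
tidy.efsi_results <- function(x, ...) {
  tidyr::pivot_longer(x$series, -c("step", "time", "iop_mmhg", "coupling_iters"),
                      names_to = "quantity", values_to = "value")
}

#' One-row summary of a scenario run
#'
#' @param x An `efsi_results`.
#' @param ... Unused.
#' @return One-row tibble with the scenario name, step count, final maxima
#'   and provenance hashes.
#' @export
glance.efsi_results <- function(x, ...) {
  summarize_bundle(x) %>%
    mutate(scenario = x$config$name, n_steps = x$provenance$n_steps,
           mesh_hash = x$provenance$mesh_hash,
           wall_time_s = x$provenance$wall_time_s, .before = 1L)
}

#' Tidy a scenario delta report
#'
#' @param x A `delta_report`.
#' @param ... Unused.
#' @return The final-time delta table (quantity, a, b, delta, relative).
#' @export
tidy.delta_report <- function(x, ...) attr(x, "final")
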