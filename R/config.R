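# Minimal TOML-subset configuration reader: [section] headers, `key = value`
# pairs with numbers, booleans, quoted strings and flat numeric arrays.
# Covers the [geometry], [electro], [fluid], [solid] and [scenario]
# sections used by the command-line driver.

#' Read a TOML-style configuration file
#'
#' @param path Config file.
#' @return Named list of sections, each a named list of values.
#' @export
read_config <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- sub("#.*$", "", ln)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln)]
  out <- list()
  section <- NULL
  for (l in ln) {
    if (grepl("^\\[.*\\]$", l)) {
      section <- gsub("^\\[|\\]$", "", l)
      out[[section]] <- list()
    } else if (grepl("=", l, fixed = TRUE)) {
      if (is.null(section)) abort("key outside of a [section]")
      kv <- strsplit(l, "=", fixed = TRUE)[[1L]]
      key <- trimws(kv[1L])
      val <- trimws(paste(kv[-1L], collapse = "="))
      out[[section]][[key]] <- parse_config_value(val)
    } else {
      abort(paste("cannot parse config line:", l))
    }
  }
  out
}

parse_config_value <- function(val) {
  if (val %in% c("true", "false")) return(val == "true")
  if (grepl('^".*"$', val)) return(gsub('^"|"$', "", val))
  if (grepl("^\\[.*\\]$", val)) {
    items <- trimws(strsplit(gsub("^\\[|\\]$", "", val), ",")[[1L]])
    return(vapply(items, function(x) as.numeric(x), numeric(1), USE.NAMES = FALSE))
  }
  num <- suppressWarnings(as.numeric(val))
  if (!is.na(num)) return(num)
  val
}

apply_args <- function(fn, defaults, overrides) {
  if (is.null(overrides)) overrides <- list()
  known <- names(formals(fn))
  unknown <- setdiff(names(overrides), known)
  if (length(unknown))
    abort(paste("unknown config keys:", paste(unknown, collapse = ", ")))
  do.call(fn, overrides)
}

#' Build a scenario configuration from a config file
#'
#' Maps the `[geometry]`, `[electro]`, `[fluid]`, `[solid]` and
#' `[scenario]` sections onto the corresponding parameter constructors.
#' In `[solid]`, Young's moduli are given as `young_tm`, `young_jct`,
#' `young_sc_wall` (Pa).
#'
#' @param path Config file path.
#' @return A [scenario_config()].
#' @export
scenario_from_config <- function(path) {
  cfg <- read_config(path)
  geometry <- apply_args(geometry_params, NULL, cfg$geometry)
  electro <- apply_args(electro_properties, NULL, cfg$electro)
  fluid <- apply_args(fluid_properties, NULL, cfg$fluid)
  sargs <- cfg$solid
  if (!is.null(sargs)) {
    ym <- c(TM = sargs$young_tm %||% 4e3, JCT = sargs$young_jct %||% 4e3,
            SC_wall = sargs$young_sc_wall %||% 7.48e3)
    sargs$young_tm <- sargs$young_jct <- sargs$young_sc_wall <- NULL
    sargs$young <- ym
  }
  solid <- apply_args(solid_properties, NULL, sargs)
  sc <- cfg$scenario %||% list()
  sched <- load_schedule(peak_iop = sc$peak_iop %||% 15,
                         duration = sc$duration %||% 1,
                         dt = sc$dt %||% 0.01)
  scenario_config(
    name = sc$name %||% "scenario",
    electric_enabled = sc$electric_enabled %||% TRUE,
    peak_iop = sched$peak_iop, schedule = sched,
    geometry = geometry, fluid = fluid, electro = electro, solid = solid,
    edl_mode = sc$edl_mode %||% "resolved",
    resolution = sc$resolution %||% (geometry$channel_height / 4),
    coupling_tol = sc$coupling_tol %||% 1e-6,
    relaxation = sc$relaxation %||% "fixed",
    electric_sign = sc$electric_sign %||% 1,
    inlet_field = sc$inlet_field %||% 0,
    seed = sc$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
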