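# Orchestration of the segregated electrical-fluid-structure solution:
# quiescent potential once (the geometry is fixed), then a time loop over
# the IOP ramp with a partitioned two-way fluid-solid sub-iteration per
# step. Scenarios differ only in their physics toggles so that the
# zero-charge limit runs through identical solver code.

#' Scenario configuration
#'
#' The three canonical scenarios of the study design are
#' `FSI @ 15 mmHg` (no electric force), `EFSI @ 0 mmHg` and
#' `EFSI @ 15 mmHg`, all on the same mesh; see [canonical_suite()].
#'
#' @param name Scenario label.
#' @param electric_enabled Include the double-layer body force.
#' @param peak_iop Peak IOP of the linear ramp (mmHg).
#' @param schedule [load_schedule()]; built from `peak_iop` by default.
#' @param geometry [geometry_params()].
#' @param fluid [fluid_properties()].
#' @param electro [electro_properties()].
#' @param solid [solid_properties()].
#' @param edl_mode `"resolved"` (canonical default: the double layer is
#'   meshed) or `"thin-EDL"`.
#' @param resolution Mesh resolution (um) passed to [build_outflow_domain()].
#' @param edl_growth Growth ratio of the boundary-layer grading.
#' @param coupling_tol,max_coupling_iters,relaxation Coupling controls for
#'   [couple_step()].
#' @param electric_sign Sign convention of the electric body force in the
#'   momentum equation. The scenario default `-1` follows the printed form
#'   of the source momentum equation (`... = mu grad^2 u - rho_f E`); `+1`
#'   is the textbook electrokinetic convention used by
#'   [body_force_field()]'s own default. At the canonical conditions the
#'   conservative part of the force is balanced either way and only the
#'   discrete imbalance, whose direction follows this sign, remains.
#' @param inlet_field Applied tangential field at the inlet (V/m); 0 by
#'   default, so flow at zero IOP arises only from the double-layer force.
#' @param pretension_on Apply the pre-tension traction.
#' @param anchor_extent Height (um) of the physical TM anchoring
#'   cross-section per unit circumference; the slice carries its
#'   area-proportional share of the pre-tension resultant so the anterior
#'   face sees the physiological pre-tension stress.
#' @param depth Out-of-plane extent (m) the slice represents (the TM
#'   annulus circumference), converting force resultants to line loads.
#' @param store_fields `"final"` keeps the last-step fields, `"none"` only
#'   the scalar series.
#' @param seed Integer seed recorded for provenance (the pipeline itself is
#'   deterministic; the seed feeds jittered pore layouts if requested).
#' @return A `scenario_config`.
#' @export
scenario_config <- function(name = "EFSI", electric_enabled = TRUE,
                            peak_iop = 15,
                            schedule = load_schedule(peak_iop = peak_iop),
                            geometry = geometry_params(),
                            fluid = fluid_properties(),
                            electro = electro_properties(),
                            solid = solid_properties(),
                            edl_mode = c("resolved", "thin-EDL"),
                            resolution = geometry$channel_height / 4,
                            edl_growth = 1.5,
                            coupling_tol = 1e-6, max_coupling_iters = 50L,
                            relaxation = c("fixed", "aitken"),
                            electric_sign = -1, inlet_field = 0,
                            pretension_on = TRUE, anchor_extent = 150, depth = 36e-3,
                            store_fields = c("final", "none"), seed = 1L) {
  edl_mode <- match.arg(edl_mode)
  relaxation <- match.arg(relaxation)
  store_fields <- match.arg(store_fields)
  if (abs(schedule$peak_iop - peak_iop) > 1e-12)
    abort("peak_iop and schedule$peak_iop disagree")
  structure(list(
    name = name, electric_enabled = electric_enabled, peak_iop = peak_iop,
    schedule = schedule, geometry = geometry, fluid = fluid,
    electro = electro, solid = solid, edl_mode = edl_mode,
    resolution = resolution, edl_growth = edl_growth,
    coupling_tol = coupling_tol, max_coupling_iters = as.integer(max_coupling_iters),
    relaxation = relaxation, electric_sign = electric_sign,
    inlet_field = inlet_field, pretension_on = pretension_on,
    anchor_extent = anchor_extent, depth = depth,
    store_fields = store_fields, seed = as.integer(seed)
  ), class = "scenario_config")
}

mesh_hash <- function(mesh) {
  rlang::hash(list(mesh$vertices, mesh$triangles, mesh$region,
                   mesh$facets$tag))
}

# Build (and, in resolved mode, boundary-layer-refine) the scenario mesh.
scenario_mesh <- function(config) {
  mesh <- build_outflow_domain(config$geometry, config$resolution)
  if (config$edl_mode == "resolved") {
    mesh <- refine_near_wall(mesh, layer_scale = config$electro$debye_length,
                             growth = config$edl_growth)
  }
  mesh
}

#' Run one scenario of the outflow pipeline
#'
#' Executes the segregated solution: geometry build (unless a prebuilt mesh
#' is supplied), quiescent-potential/charge/field solve when the electric
#' force is enabled, then the time loop over the IOP ramp with a
#' Dirichlet-Neumann fluid-solid sub-iteration per step.
#'
#' @param config A [scenario_config()].
#' @param mesh Optional prebuilt [outflow_mesh] (shared across scenarios by
#'   [canonical_suite()]).
#' @param progress Print per-step progress.
#' @return An `efsi_results` bundle: per-step scalar series, final fields,
#'   mesh and provenance.
#' @export
run_scenario <- function(config, mesh = NULL, progress = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  if (is.null(mesh)) mesh <- scenario_mesh(config)
  fe_f <- submesh(mesh, "fluid")
  fe_s <- submesh(mesh, c("TM", "JCT", "SC_wall"))
  sched <- config$schedule
  dt <- sched$dt

  potential <- NULL
  body_force <- NULL
  if (config$electric_enabled) {
    potential <- solve_quiescent_potential(fe_f, config$electro,
                                           mode = config$edl_mode)
    if (config$edl_mode == "resolved") {
      rho <- charge_density(potential)
      ef <- electric_field(potential)
      body_force <- body_force_field(rho, ef, sign = config$electric_sign,
                                     applied_field = c(config$inlet_field, 0))
    }
  }

  # interface bookkeeping: shared parent nodes of the two submeshes
  ifc_parent <- intersect(
    unique(c(fe_f$facets$parent_a[fe_f$facets$tag == "glycocalyx_wall"],
             fe_f$facets$parent_b[fe_f$facets$tag == "glycocalyx_wall"])),
    fe_s$node_parent
  )
  ifc_f <- match(ifc_parent, fe_f$node_parent)
  ifc_s <- match(ifc_parent, fe_s$node_parent)

  # interstitial pressure: constant extension inward from the nearest
  # interface node
  xs <- fe_s$xy; xi <- fe_s$xy[ifc_s, , drop = FALSE]
  nearest_ifc <- vapply(seq_len(fe_s$n), function(i) {
    which.min((xi[, 1L] - xs[i, 1L])^2 + (xi[, 2L] - xs[i, 2L])^2)
  }, integer(1))

  tm_nodes <- sort(unique(as.vector(fe_s$tri[fe_s$region == "TM", ])))

  solid_cache <- new.env(parent = emptyenv())
  # the slice's share of the pre-tension: physiological anchoring stress
  # (resultant / (depth x anchoring height)) times the modelled face area
  pret <- 0
  if (config$pretension_on) {
    front_len <- sum(pretension_facets(fe_s)$len)
    tau <- config$solid$pretension / (config$depth * config$anchor_extent * 1e-6)
    pret <- tau * config$depth * front_len
  }

  n <- fe_f$n
  prev <- make_flow_state(fe_f, config$fluid, rep(0, 3L * n), 0)
  # start from the pre-tensioned static equilibrium (the reference state;
  # reported displacements are measured from it)
  u_ref <- matrix(0, fe_s$n, 2L)
  if (pret > 0) {
    st0 <- solve_quasistatic(fe_s, config$solid, pretension = pret,
                             depth = config$depth, cache = solid_cache)
    u_ref <- st0$displacement
  }
  d_step <- as.vector(u_ref[ifc_s, ])
  u_solid_prev <- u_ref
  flow_lu <- NULL
  flow_sys <- NULL

  series <- vector("list", sched$n_steps)
  last_fluid <- NULL; last_solid <- NULL

  for (k in seq_len(sched$n_steps)) {
    tk <- k * dt
    p_in <- mmhg_to_pa(iop_schedule(tk, sched))

    w <- if (config$fluid$include_convection) prev$u else NULL
    flow_sys <- assemble_flow_matrix(fe_f, config$fluid, dt = dt, w = w)
    flow_lu <- scaled_lu(flow_sys$A)

    env <- new.env(parent = emptyenv())
    fluid_solve <- function(d) {
      wv <- matrix(0, n, 2L)
      dd <- matrix(d, ncol = 2L)
      wv[ifc_f, ] <- (dd - matrix(d_step, ncol = 2L)) / dt
      rhs <- flow_rhs(fe_f, config$fluid, flow_sys, body_force, p_in,
                      prev$u, dt, wv)
      sol <- solve_scaled(flow_lu, rhs)
      st <- make_flow_state(fe_f, config$fluid, sol, tk)
      env$fluid <- st
      interface_traction(st)
    }
    solid_solve <- function(traction) {
      P_nodal_ifc <- env$fluid$p[ifc_f]
      Pn <- P_nodal_ifc[nearest_ifc]
      st <- solve_quasistatic(fe_s, config$solid,
                              interface_traction = traction, P_i = Pn,
                              pretension = pret, depth = config$depth,
                              cache = solid_cache)
      env$solid <- st
      as.vector(st$displacement[ifc_s, ])
    }

    cs <- couple_step(fluid_solve, solid_solve, d_step,
                      tol = config$coupling_tol,
                      max_iters = config$max_coupling_iters,
                      relaxation = config$relaxation)
    d_step <- cs$d
    fluid_state <- env$fluid
    solid_state <- env$solid
    solid_state$velocity <- (solid_state$displacement - u_solid_prev) / dt
    u_solid_prev <- solid_state$displacement
    prev <- fluid_state

    series[[k]] <- step_scalars(fluid_state, solid_state, tm_nodes, u_ref) %>%
      mutate(step = k, time = tk, iop_mmhg = iop_schedule(tk, sched),
             coupling_iters = cs$iterations, .before = 1L)
    last_fluid <- fluid_state; last_solid <- solid_state
    if (progress) message(sprintf("step %d/%d: max |u| = %.4g mm/s, %d coupling iter(s)",
                                  k, sched$n_steps,
                                  series[[k]]$max_velocity_mm_s, cs$iterations))
  }

  series <- bind_rows(series)
  final <- if (config$store_fields == "final") {
    list(fluid = last_fluid, solid = last_solid, potential = potential,
         body_force = body_force)
  } else NULL

  structure(list(
    series = series, final = final, mesh = mesh, config = config,
    provenance = list(
      config_hash = rlang::hash(unclass(config)),
      mesh_hash = mesh_hash(mesh),
      series_hash = rlang::hash(series),
      package_version = as.character(utils::packageVersion("outflowEFSI")),
      wall_time_s = proc.time()[["elapsed"]] - t0,
      n_steps = sched$n_steps
    )
  ), class = "efsi_results")
}

step_scalars <- function(fluid_state, solid_state, tm_nodes, u_ref = 0) {
  speed <- sqrt(fluid_state$u[, 1L]^2 + fluid_state$u[, 2L]^2)
  pv_s <- principal_values(solid_state$sigma_total)
  pv_e <- principal_values(solid_state$strain)
  du <- solid_state$displacement - u_ref
  disp <- sqrt(du[, 1L]^2 + du[, 2L]^2)
  tibble(
    max_velocity_mm_s = max(speed) * 1e3,
    max_pressure_mmhg = pa_to_mmhg(max(fluid_state$p)),
    max_p1_stress_kpa = max(pv_s$p1) / 1e3,
    max_p1_strain_pct = max(pv_e$p1) * 100,
    max_shear_stress_kpa = max((pv_s$p1 - pv_s$p3) / 2) / 1e3,
    max_shear_strain_pct = max((pv_e$p1 - pv_e$p3) / 2) * 100,
    tm_displacement_um = mean(disp[tm_nodes]) * 1e6
  )
}

#' Compare two scenario results
#'
#' Elementwise differences (`b - a`) and relative differences of the scalar
#' series and of the final-time row; antisymmetric under swapping the
#' arguments. Results must share the mesh and schedule.
#'
#' @param a,b `efsi_results` bundles.
#' @return A `delta_report` tibble (per-step deltas) with attribute
#'   `final` (final-time deltas and relative deltas).
#' @export
compare_scenarios <- function(a, b) {
  if (!identical(a$provenance$mesh_hash, b$provenance$mesh_hash))
    abort("scenario results were computed on different meshes")
  if (a$config$schedule$duration != b$config$schedule$duration ||
      a$config$schedule$dt != b$config$schedule$dt)
    abort("scenario results use different time discretizations")
  cols <- c("max_velocity_mm_s", "max_pressure_mmhg", "max_p1_stress_kpa",
            "max_p1_strain_pct", "max_shear_stress_kpa",
            "max_shear_strain_pct", "tm_displacement_um")
  d <- a$series[, c("step", "time")]
  for (cc in cols) d[[cc]] <- b$series[[cc]] - a$series[[cc]]
  fin_a <- a$series[nrow(a$series), cols]
  fin_b <- b$series[nrow(b$series), cols]
  final <- tibble(
    quantity = cols,
    a = as.numeric(fin_a[1, ]), b = as.numeric(fin_b[1, ]),
    delta = as.numeric(fin_b[1, ]) - as.numeric(fin_a[1, ])
  ) %>% mutate(relative = ifelse(.data$a != 0, .data$delta / .data$a, NA_real_))
  attr(d, "final") <- final
  attr(d, "names_ab") <- c(a$config$name, b$config$name)
  class(d) <- c("delta_report", class(d))
  d
}

#' Run the canonical three-scenario suite
#'
#' Runs FSI @ 15 mmHg, EFSI @ 0 mmHg and EFSI @ 15 mmHg on one shared mesh
#' (identical structure, density and distribution across models) and
#' returns the bundles, all pairwise delta reports, and a summary table.
#'
#' @param config Base [scenario_config()] supplying geometry, properties,
#'   resolution and coupling controls.
#' @param progress Print per-step progress.
#' @return List with `bundles` (named list), `deltas` (named list of
#'   [compare_scenarios()] reports) and `summary` (one row per scenario).
#' @export
canonical_suite <- function(config = scenario_config(), progress = FALSE) {
  mesh <- scenario_mesh(config)
  mk <- function(name, electric, iop) {
    cfg <- config
    cfg$name <- name
    cfg$electric_enabled <- electric
    cfg$peak_iop <- iop
    cfg$schedule <- load_schedule(peak_iop = iop,
                                  duration = config$schedule$duration,
                                  dt = config$schedule$dt)
    cfg
  }
  configs <- list(
    FSI_15  = mk("FSI @ 15 mmHg", FALSE, config$peak_iop),
    EFSI_0  = mk("EFSI @ 0 mmHg", TRUE, 0),
    EFSI_15 = mk("EFSI @ 15 mmHg", TRUE, config$peak_iop)
  )
  bundles <- lapply(configs, run_scenario, mesh = mesh, progress = progress)
  stopifnot(length(unique(vapply(bundles, function(b) b$provenance$mesh_hash,
                                 character(1)))) == 1L)
  deltas <- list(
    EFSI15_vs_FSI15 = compare_scenarios(bundles$FSI_15, bundles$EFSI_15),
    EFSI0_vs_FSI15 = compare_scenarios(bundles$FSI_15, bundles$EFSI_0),
    EFSI0_vs_EFSI15 = compare_scenarios(bundles$EFSI_15, bundles$EFSI_0)
  )
  summary <- bind_rows(lapply(names(bundles), function(nm) {
    summarize_bundle(bundles[[nm]]) %>% mutate(scenario = nm, .before = 1L)
  }))
  list(bundles = bundles, deltas = deltas, summary = summary)
}
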