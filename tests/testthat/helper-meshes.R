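# Shared small fixtures, built in code.

# A tiny outflow geometry for fast pipeline tests (same topology as the
# default, ~10x fewer cells).
tiny_geometry <- function(...) {
  geometry_params(tm_depth = 8, jct_thickness = 4, sc_wall_thickness = 1.5,
                  channel_height = 1.6, tissue_thickness = 3,
                  pore_diameter = 0.8, ...)
}

tiny_config <- function(n_steps = 5, peak_iop = 15, ...) {
  scenario_config(
    peak_iop = peak_iop,
    schedule = load_schedule(peak_iop = peak_iop, duration = 1, dt = 1 / n_steps),
    geometry = tiny_geometry(),
    resolution = 0.4,
    ...
  )
}

# Plane channel with wall-graded transverse lines resolving a Debye layer.
edl_channel <- function(half_width_um, debye_nm, length_um = half_width_um,
                        nx = 3L, h_wall_frac = 10, ratio = 1.1,
                        h_bulk_um = half_width_um / 10) {
  yl <- graded_channel_ylines(half_width_um,
                              h_wall_um = debye_nm / 1000 / h_wall_frac,
                              h_bulk_um = h_bulk_um, ratio = ratio)
  channel_mesh(length_um, half_width_um, nx = nx, ylines = yl)
}
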