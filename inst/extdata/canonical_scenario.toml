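# Canonical study conditions: idealized TM/JCT/SC slice, printed material
# and electrical constants, 0 -> 15 mmHg ramp in 100 steps.

[geometry]
tm_depth = 40
jct_thickness = 14
sc_wall_thickness = 2.2
pore_density = 835
pore_diameter = 1.3
glycocalyx_thickness = 109
channel_height = 2
tissue_thickness = 10

[electro]
zeta_potential = -19.5e-3
relative_permittivity = 99
conductivity = 179e-4
membrane_potential = -70e-3
reference_impedance = 50
debye_length = 10

[fluid]
density = 1000
viscosity = 7.185e-4
include_convection = true

[solid]
young_tm = 4000
young_jct = 4000
young_sc_wall = 7480
poisson = 0.495
pretension = 500e-6

[scenario]
name = "EFSI @ 15 mmHg"
electric_enabled = true
peak_iop = 15
duration = 1
dt = 0.01
edl_mode = "resolved"
resolution = 0.5
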