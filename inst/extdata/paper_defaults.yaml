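# Reference trapping-experiment configuration (laboratory units).
# Values match the package defaults exactly; loading this file is
# equivalent to load_config(NULL).
geometry:
  ring_inner_radius_um: 20.0
  ring_outer_radius_um: 40.0
  counter_inner_radius_um: 60.0
  domain_radius_um: 125.0
  channel_height_um: 40.0
  channel_width_um: 250.0
  channel_length_mm: 30.0
drive:
  vpp: 8.0
  frequency_mhz: 10.0
medium:
  permittivity_f_per_m: 7.1e-10
  conductivity_s_per_m: 1.5
  viscosity_pa_s: 1.0e-3
  density_kg_per_m3: 1000.0
cell:
  model: shelled
  radius_um: 5.0
  membrane_thickness_nm: 5.0
  membrane_permittivity_f_per_m: 1.8e-12
  membrane_conductivity_s_per_m: 1.0e-7
  cytoplasm_permittivity_f_per_m: 7.1e-10
  cytoplasm_conductivity_s_per_m: 0.75
  relative_permittivity: 80.0
  conductivity_s_per_m: 0.5
  density_kg_per_m3: 1050.0
flow:
  enabled: false
  volumetric_rate_ul_min: 2.5
grid:
  spacing_um: 0.5
  solver_tolerance: 1.0e-8
  max_iterations: 50
integration:
  dt_s: 1.0e-4
  t_end_s: 2.0
  snapshot_times_s: [0.3, 1.0, 2.0]
  record_every: 10
ensemble:
  count: 50
  seed: 42
  x_range_um: [-120.0, 120.0]
  y_range_um: [0.0, 0.0]
  z_range_um: [5.0, 35.0]
gravity:
  enabled: false
  g_m_per_s2: 9.81
require_ndep: true
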