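# stenoflow pipeline configuration (all quantities carry their unit in the
# field name). NULL-able fields fall back to the packaged resting renal
# waveform averages.
geometry:
  reference_diameter_mm: 5.0
  length_mm: 40.0
  bend_angle_deg: 30.0          # total planar bend over the vessel length
  seed: null                    # integer: adds seeded tortuosity
  stenoses:
    - center_mm: 5.0            # ostial lesion
      length_mm: 6.0
      severity: 72.0            # percent diameter reduction
mesh:
  target_density_per_mm3: 200.0 # average elements per cubic millimetre
  n_wall_layers: 5
  growth_ratio: 1.2
fluid:
  viscosity_pa_s: 0.0035
  density_kg_m3: 1066.0
boundary_conditions:
  inlet_flow_ml_min: null       # null: cycle average of packaged waveform
  outlet:
    mode: resistance            # resistance | fixed_pressure
    reference_pressure_pa: 0.0
    resistance_pa_s_m3: null    # null: packaged mean pressure / mean flow
solver:
  nonlinear_tolerance: 1.0e-5
  max_nonlinear_iterations: 200
extraction:
  downstream_offsets_mm: [10.0, 15.0, 20.0]
  threshold: 0.9
seed: 1
output_dir: stenoflow-out
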