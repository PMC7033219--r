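# Benchmark configuration (mirrors default_config()). Tissue material
# values are literature-typical placeholders for articular cartilage, not
# subject-specific measurements.
seed: 1
gait:
  n_grid: 101
  bodyweight_n: 765
  peak_flexion_deg: 22
  peak_load_bw: 0.95
  extension_demand_nm: 40
  flexion_demand_nm: 30
  adduction_peak_nm: 12
  rotation_peak_nm: 1.5
  noise_sd: 0.02
  emg_band_hz: [20, 450]
  emg_lp_hz: 6
  emg_norm: trial-max
muscles:
  band: 0.1
  floor: 0.02
ligaments:
  ACL: {K_l: 10.0, prestrain_pct: 8.0, n_elements: 60}
  PCL: {K_l: 18.0, prestrain_pct: -13.5, n_elements: 100}
  LCL: {K_l: 6.0, prestrain_pct: -7.33, n_elements: 15}
  MCL: {K_l: 8.25, prestrain_pct: 3.66, n_elements: 20}
material:
  E_m: 0.5        # MPa, non-fibrillar matrix modulus
  nu_m: 0.15
  E_0: 2.0        # MPa, initial fibril modulus
  E_eps: 500.0    # MPa, strain-dependent fibril modulus
  eta: 0.0        # MPa s (0 = elastic fibrils)
  k_0: 2.0e-15    # m^4/(N s)
  M_k: 5.0
  e_0: 4.0
  n_nodes: 8
  chi: 0.9
geometry:
  plateau_x: 45
  plateau_z: 80
  cell_mm: 2
  condyle_offset_z: 22
  ax: 28
  ay: 24
  az: 18
  thickness_mm: 6
  dish_radius_mm: 80
  meniscus_r_in: 7
  meniscus_r_out: 14
  meniscus_wedge_tan: 0.5
  hoop_stiffness: 150
  horn_stiffness: 200
solver:
  stance_duration_s: 0.6
  tol_rel: 1.0e-9
sweep:
  offsets_pct: [-10, -5, 0, 5, 10]
  ligaments: [ACL, PCL, LCL, MCL]
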