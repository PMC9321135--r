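{
  "case": "droplet",
  "geometry": {
    "length_um": 500,
    "branch_length_um": 250,
    "width_um": 100,
    "height_um": 100,
    "p_top_pa": 0,
    "p_bot_pa": 0.00288,
    "branch_measure": "edge"
  },
  "fluid": {
    "density_kg_m3": 1,
    "kinematic_viscosity_m2_s": 1.004e-06,
    "surface_tension_n_m": 0.005
  },
  "driving": {
    "u_in_mm_s": 10
  },
  "shan_chen": {
    "G": 1.1,
    "minority_floor": 0.083,
    "rho0": 2
  },
  "droplet": {
    "length_um": 200,
    "slip_factor": 1.28,
    "gap_cells": 7,
    "start_um": 50
  },
  "solver": {
    "dx_um": 2.5,
    "u_lat": 0.01,
    "tolerance": 1e-05,
    "window": 500,
    "max_steps": 80000
  }
}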