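{
  "case": "mix",
  "geometry": {
    "length_um": 600,
    "width_um": 40,
    "measurement_line_um": 500
  },
  "fluid": {
    "density_kg_m3": 1,
    "viscosity_pas": 1.004e-06,
    "diffusivity_um2_s": 90
  },
  "driving": {
    "u_in_mm_s": 10,
    "p_out_pa": 0
  },
  "shan_chen": {
    "G": 0.8,
    "minority_floor": 0.01
  },
  "mixing": {
    "convention": "table"
  },
  "solver": {
    "dx_um": 1,
    "u_lat": 0.01,
    "tolerance": 1e-05,
    "window": 1000,
    "max_steps": 160000
  }
}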