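{
  "case": "flow",
  "geometry": {
    "length_um": 500,
    "width_um": 100,
    "height_um": 100,
    "measurement_line_um": 400
  },
  "fluid": {
    "density_kg_m3": 1060,
    "carreau_yasuda": {
      "mu0_pas": 0.022,
      "mu_inf_pas": 0.0022,
      "lambda_s": 0.110,
      "a": 0.644,
      "n": 0.392
    }
  },
  "driving": { "u_in_mm_s": 10, "p_out_pa": 0 },
  "solver": { "dx_um": 1, "u_lat": 0.05, "tolerance": 1e-5, "window": 1000, "max_steps": 120000 }
}
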