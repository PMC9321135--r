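Package: mfsim
Title: Multi-Level Simulation of Pressure-Driven Channel Microfluidics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates pressure-driven, channel-based microfluidic (Lab-on-a-Chip)
    devices at three abstraction levels. Provides 1D analytic and semi-analytic
    models (rectangular-duct Hagen-Poiseuille series, Carreau-Yasuda
    shear-thinning profiles, hydraulic-resistance network analysis,
    advection-diffusion mixing series, slip-factor droplet trajectories) and a
    2D/3D Lattice-Boltzmann solver (D2Q9/D3Q19, BGK collision, halfway
    bounce-back family boundaries, Shan-Chen two-component coupling) for three
    use cases: non-Newtonian blood flow in a channel, two-fluid mixing, and
    droplet transport through a bifurcation. Includes comparison metrics
    (velocity and concentration profiles, the Absolute Mixing Index, droplet
    tracking), CSV/JSON/VTK writers and declarative JSON/YAML configuration.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
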