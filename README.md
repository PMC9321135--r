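# mfsim

Multi-level simulation of pressure-driven, channel-based microfluidic
(Lab-on-a-Chip) devices in R. Chip designers trade accuracy against compute
time when choosing a simulation level; `mfsim` implements the three levels
side by side, with shared geometry, fluid and unit-conversion types, so the
trade-off can be measured instead of guessed:

* **1D** — analytic and semi-analytic models: the rectangular-duct
  Hagen–Poiseuille series
  `Q = w h³ Δp / (12 µ l) · [1 − (h/w)(192/π⁵) Σ n⁻⁵ tanh(nπw/2h)]`,
  Carreau–Yasuda shear-thinning profiles
  `µ_eff(γ̇) = µ∞ + (µ0 − µ∞)[1 + (λγ̇)^a]^{(n−1)/a}` solved by
  Newton/bisection root finding plus Simpson quadrature, hydraulic-resistance
  networks (`R_H = Δp/Q`, Kirchhoff nodal analysis), the advection–diffusion
  mixing series for two co-flowing streams, and slip-factor droplet
  trajectories `u_d = α Q / A`.
* **2D/3D** — a lattice-Boltzmann solver (D2Q9/D3Q19, BGK collision,
  halfway bounce-back walls, velocity-inlet and anti-bounce-back pressure
  outlets, local strain-rate readout with per-cell Carreau–Yasuda coupling)
  with Shan–Chen two-component forcing for miscible mixing and immiscible
  droplets. The hot loop is compiled (Rcpp); a pure-R reference step defines
  the update rule and the two are held equal to machine precision in the
  tests.

Three shipped use cases (blood flow in a channel, two-fluid mixing, droplet
transport through a bifurcation) are configured by JSON/YAML files with
SI-unit-suffixed keys. Comparison metrics — velocity/concentration profiles,
the Absolute Mixing Index `AMI = (1/N) Σ |αᵢ − ⟨α⟩| / ⟨α⟩`, droplet
trailing-edge tracking — plus CSV/JSON/VTK writers and a small CLI complete
the toolchain. The methods vignette (`vignettes/methods.Rmd`) documents the
models, conventions and numerical choices.

## Worked example

```r
library(mfsim)

# blood in a 500 x 100 um channel at 10 mm/s: semi-analytic profile
cfg <- load_config(example_config("flow_blood"))
res <- run_flow_case(cfg, "1d")
res$report$dp_pa      # 23.78  -- pressure difference driving 10 mm/s
res$report$flatness   # 1.420  -- u_max/u_mean; 1.5 would be a Newtonian parabola

# two-fluid mixing: concentration profile 500 um downstream and its AMI
mix <- load_config(example_config("mix_straight"))
m1 <- run_mix_case(mix, "1d")
m1$report$ami         # 0.6617 -- mostly unmixed (1 = unmixed step, 0 = mixed)

# droplet through the bifurcation, 1D level: branch choice and arrival
drp <- load_config(example_config("droplet_bifurcation"))
d1 <- run_droplet(drp, "1d")
d1$report$branch        # "top"  -- branch with the larger flow
d1$report$t_arrive_ms   # 65.15  -- trailing edge reaches the branch outlet
```

The flatness 1.42 (against the Newtonian 1.5) is the shear-thinning
signature: blood's viscosity drops where shear is high (near the walls),
flattening the centre of the profile relative to the parabola. The mixing AMI of 0.66 says the two
streams are still largely segregated 500 µm downstream at this Péclet
number. Field-level runs of the same configurations
(`run_flow_case(cfg, "2d")`, `run_mix_case(mix, "2d")`,
`run_droplet(drp, "2d")`) take minutes instead of milliseconds and add what
the 1D level cannot represent: wall development, concentration-dependent
diffusion, droplet shape and integrity.

A command-line wrapper is installed with the package:

```sh
$(Rscript -e 'cat(system.file("exec", "mfsim", package = "mfsim"))') \
    mix --level 1d --config $(Rscript -e 'cat(mfsim::example_config("mix_straight"))') \
    --out /tmp/mix_out
```

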