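# pvsflow

Lumped-parameter hydraulic network models of pulsatile fluid motion in
cortical **perivascular spaces (PVS)** and brain **parenchyma**.

Dissolved compounds move through the perivascular spaces of cortical
arterioles faster than diffusion can explain, and the effect tracks
vascular pulsatility.  `pvsflow` models the fluid mechanics behind this
observation for physiologists and modellers who want a transparent,
desk-scale alternative to CFD: every compartment is a hydraulic resistor
obeying `Δp = R q`, and the only drivers are volumetric sources equal to
the fluid displaced by sinusoidal vessel wall motion
(`q ≈ 4π² l f b R_i sin(2πft)` for a full vessel, halved with a phase
shift `θ` and amplitude ratio `ξ` for the venous side of the planar
two-vessel model).  Element resistances come from closed forms: annular
Poiseuille flow `R = 8μl / {πR_o⁴[1 − E⁴ + (E²−1)²/ln E]}` for the
free-fluid PVS, Darcy reductions for porous PVS
(`l/[π(R_o²−R_i²)K_PVS]`), radial parenchyma shells
(`ln(R_o/R_i)/(2πhK)`) and rectangular parenchyma slabs (`l/(Khd)`).
Solving one pulse period yields pressures, superficial velocities, net
volumes (zero: the motion is purely oscillatory), Womersley and Péclet
regime diagnostics, and parameter sweeps over amplitude, radii,
conductivities, pulsatility ratio and pulse timing.

## Worked example

```r
library(pvsflow)

p  <- pvs_parameters()                 # baseline rat-cortex parameters, SI
s1 <- solve_period(build_one_vessel(p))
s1
#> Solved hydraulic network over one period (0.2 s, 256 samples)
#>   peak |pressure|: 0.06494 Pa
#>   peak |velocity|: 2.942e-05 m/s (R4)
#>   max |net volume|: 1.53e-31 m^3

# parenchyma superficial velocity next to the PVS and 50 um further out
element_velocity(s1, "R6") * 1e9                    # 3.58 nm/s
element_velocity(s1, "R6", distance = 50e-6) * 1e9  # 1.34 nm/s

# two-vessel model: arteriole + vein, 200 um apart
s2 <- solve_period(build_two_vessel(pvs_parameters(model = "two_vessel")))
max(s2$peaks$peak_velocity[s2$peaks$label %in% c("R1","R8","R15","R22")])
#> 1.470258e-05    # arterial PVS peak ~15 um/s, half the one-vessel value

peclet_table(s1)[, c("region", "D_star", "length_mode", "Pe")]
#>       region D_star  length_mode           Pe
#> 1        PVS  1e-11      segment 8.826860e+02
#> 2 parenchyma  1e-11         pore 1.074945e-04
#> 3        PVS  1e-10      segment 8.826860e+01
#> 4 parenchyma  1e-10 inter_vessel 3.583149e-02
#> 5        PVS  1e-09      segment 8.826860e+00
#> 6 parenchyma  1e-09 inter_vessel 3.583149e-03
```

Reading: the wall pulse moves PVS fluid at tens of µm/s under ~65 mPa
pressure peaks — enough for Péclet numbers of 10–10³, so oscillatory
dispersion can matter there — while parenchyma fluid creeps at a few
nm/s (Pe ≤ 10⁻¹): solute transport in tissue is diffusion-dominated, and
no element carries net flow over a cycle.

Sweeps and reports:

```r
sw <- run_sweep("b", seq(0, 0.37e-6, length.out = 11))  # amplitude sweep
write_report(s1, "out/")     # summary.json + timeseries.csv + topology.txt
```

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/pvsflow.R run   --model two_vessel --out out/
Rscript inst/cli/pvsflow.R sweep --name K_PVS --porous-pvs --out out/
Rscript inst/cli/pvsflow.R check
```

## Output schema

`summary.json`: model tag, SI parameter echo, per-resistor topology
digest (kind, length, resistance), per-node/-element peaks, net volumes,
Péclet table, validity diagnostics (Womersley number, wavelength ratio,
`b/R_i`, resistance variation).  `timeseries.csv`: `t`, `p_<node>`,
`q_<resistor>`, `v_<resistor>` (RFC-4180, 9 significant digits,
byte-stable across reruns).  Sweep CSVs: one row per grid point ×
element with peak flow, velocity and pressure.
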