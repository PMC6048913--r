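---
title: "Hydraulic network models of pulsatile perivascular and parenchymal flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydraulic network models of pulsatile perivascular and parenchymal flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsflow)
```

## The physical problem

Tracers injected into cerebrospinal fluid move along the perivascular
spaces (PVS) of cortical arterioles much faster than diffusion alone
allows, and the effect correlates with vascular pulsatility.  Whether that
motion amounts to *net* convective flow through the PVS and brain
parenchyma, or merely *oscillatory* fluid motion that enhances dispersion,
is a central question for glymphatic physiology.  `pvsflow` addresses it
with the simplest mechanistic tool that can hold PVS and parenchyma in one
model: a lumped-parameter hydraulic resistance network in which volumetric
fluid sources represent the fluid displaced by sinusoidal vessel wall
motion, and every tissue compartment is a hydraulic resistor obeying

$$\Delta p = R\,q,$$

the fluid analogue of Ohm's law.  No pressure difference is imposed
anywhere; wall motion is the only driver.

Two model variants are provided:

* **one-vessel** — a 300 µm segment of a single penetrating arteriole, its
  annular PVS, and the surrounding parenchyma treated as a cylindrical
  shell (7 resistors, 3 sources);
* **two-vessel** — a planar slice of cortex holding an arteriole and a
  vein 200 µm apart, their half-PVS channels, and a parenchyma grid
  between them (25 resistors, 3 arterial + 3 venous sources).

## Element resistances

Each resistor's value follows from a closed-form reduction of the
momentum equation for its geometry:

* **Free-fluid PVS annulus** (`annular_poiseuille_resistance`): the
  Navier–Stokes solution for steady axial flow in a concentric annulus,
  $R = 8\mu l / \{\pi R_o^4\,[\,1 - E^4 + (E^2-1)^2/\ln E\,]\}$ with
  $E = R_i/R_o$.  Oscillatory flow may use the steady profile because the
  Womersley number of the gap, $\alpha = 2(R_o-R_i)\sqrt{2\pi f\rho/\mu}
  \approx 0.24$ at baseline, is small, and the 20 cm pulse wavelength
  dwarfs the segment.
* **Porous PVS annulus** (`porous_annulus_resistance`): Darcy flow,
  $R = l/[\pi(R_o^2 - R_i^2) K_{PVS}]$, for exploring solid-filled
  perivascular spaces.
* **Parenchyma radial shell** (`radial_shell_resistance`): 1-D radial
  Darcy flow, $R = \ln(R_o^{PCY}/R_i^{PCY})/(2\pi h K_{PCY})$.
* **Parenchyma slab** (`darcy_slab_resistance`): plane Darcy flow,
  $R = l/(K_{PCY} h d)$, the natural element for the rectangular
  two-vessel grid.

Resistances are held constant over the cycle.  This is legitimate only
while the wall excursion barely changes the annular resistance; the
baseline amplitude keeps the variation under 5%, and
`max_amplitude_for_resistance_tolerance()` computes, by bracketing root
search on the exact annular formula, the largest amplitude honouring any
given tolerance (16.2 nm for a 1 µm gap at 5%).  The radii sweep applies
this cap automatically.

## Volumetric sources

The inner wall moves as $r_i(t) = R_i - b\cos(2\pi f t - \theta)$,
uniformly along the segment.  Differentiating the contained volume
$\pi l r_i^2$ gives the displaced flow rate; since $b/R_i \le 0.037$ over
the simulated amplitude range, the linearized waveform

$$q \approx g\,l f b R_i \sin(2\pi f t - \theta), \qquad
  g = \begin{cases} 4\pi^2 & \text{full radial outflow (one-vessel)}\\
                    2\pi^2 & \text{half outflow (two-vessel plane)}\end{cases}$$

is used in the solves; the exact derivative is retained (`mode =
"exact"`) to bound the linearization error, which is at most $b/R_i$ in
relative terms.  Venous amplitude is set from the venous:arterial
pulsatility ratio $\xi$, which at shared frequency reduces to the
amplitude ratio.  Pulsatility itself,
$\Pi = 2\int_0^T |r_i - R_i|\,dt$, is evaluated by quadrature; for a full
period it equals $4b/(\pi f)$.  (A commonly quoted closed form $b/\pi f$
differs by a constant factor; only ratios of pulsatility enter the
models, so the factor is immaterial and the integral as defined is kept.)
The measurement interval $T$ defaults to one pulse period, to which the
ratio $\xi$ is insensitive.

## Network topologies

**One-vessel.**  The axial PVS chain R1(50 µm)–R2(100)–R3(100)–R4(50) is
grounded at both ends; each interior node carries one source (l = 100 µm)
and one radial shell resistor (R5–R7) to ground.  This
chain-with-radial-shunts arrangement is the unique 7-resistor/3-source
layout consistent with the published element lengths, and it reproduces
the published peak velocity and pressure.

**Two-vessel.**  The published figure is described but not fully wired in
text, so the topology was reconstructed from its constraints: 25
resistors, eleven of them 100 µm long (R6, R8–R11, R13, R15–R18, R20),
boundaries open at top and bottom for PVS *and* parenchyma, and the
parenchyma elements R12/R13 at increasing distance from the arteriole.  A
4-column grid satisfies every constraint label-for-label when numbered
row-wise: grounded-top-and-bottom columns at x = 0 (arterial half-PVS),
50 µm and 150 µm (parenchyma), and 200 µm (venous half-PVS), each of
lengths 50/100/100/50 µm, bridged at the three source rows by horizontal
parenchyma runs of 50 + 100 + 50 µm.  The layout is written out by
`write_topology()` so alternative reconstructions can be reviewed or
substituted.

Because the planar model carries only half of each vessel's annulus, its
PVS elements have exactly twice the one-vessel resistance and half the
geometric section, and its arterial sources emit exactly half the flow.

## Velocity conventions

All reported velocities are superficial (Darcy) velocities — volumetric
flow per total cross-section — consistent with the porosity-bearing
parenchyma Péclet formulations below.  Conversion sections are: full
annulus $\pi(R_o^2 - R_i^2)$ for one-vessel PVS elements; $h\,d$ for
slabs; $2\pi r h$ for radial shells, where the evaluation radius $r$ is a
caller choice (`element_velocity(sol, "R6", distance = 50e-6)`) so the
decay of parenchyma velocity with distance from the PVS outer boundary
can be profiled — it defaults to the PVS outer radius, the shell's
upstream face.  Half-annulus PVS elements report velocity through the
*full* annular section: the planar model represents half of a radially
symmetric vessel, and referring its flows to the full section keeps one-
and two-vessel velocities directly comparable (the halved source then
halves the reported PVS velocity, as published).  The geometric half
section is retained on the element for flow-area calculations.

## Solving and transport metrics

`solve_period()` samples one period at `n_samples + 1` instants
(endpoints included so period integrals close), assembles the reduced
nodal conductance matrix over non-grounded nodes — symmetric positive
definite by construction — and solves all instants through one Cholesky
factorization.  Grounded boundaries sit at relative pressure zero, the
far-field CSF/ISF reference.  Per-element peak metrics, net displaced
volumes (trapezoidal rule) and the Kirchhoff residual are derived from
the sampled series.  The default 256 samples leave peak metrics stable to
better than 0.1% under doubling, which the test suite asserts.

Transport regime is summarized by Péclet numbers:
$Pe = L_{PVS} v / D^*$ in the PVS, and in the parenchyma either
$Pe = L_{PCY} v / (\phi D^*)$ (inter-vessel distance as length scale) or
$Pe = \eta v / (\phi D^*)$ (pore size, the porous-media convention,
applied by `peclet_table()` to the smallest diffusivity in a span).  The
PVS Péclet uses the time-peak of the section-averaged velocity of the
fastest PVS element — a deliberately conservative choice: if even that
velocity leaves $Pe \ll 1$ the diffusion-dominated verdict is safe, and
where it is large the oscillatory (zero-net) nature of the flow means the
proper interpretation is dispersion, not convection.

## Parameters

| symbol | meaning | default (SI) | origin |
|---|---|---|---|
| `R_i`, `R_o` | PVS inner/outer radius | 10, 30 µm | arteriole morphometry |
| `L_PVS` | vessel segment length | 300 µm | mean penetrating-segment length |
| `L_PCY` | inter-vessel distance | 200 µm | arteriole–venule spacing |
| `b`, `f` | pulse amplitude, frequency | 0.25 µm, 5 Hz | in-vivo wall imaging |
| `wave_speed` | arterial pulse wave speed | 1 m/s | gives 20 cm wavelength |
| `K_PCY` | parenchyma conductivity | 5.63e-12 m²/(Pa·s) | interstitium estimates |
| `K_PVS` | porous-PVS conductivity | free-fluid equivalent | see below |
| `mu`, `rho` | ISF viscosity, density | 0.9 mPa·s, 993.2 kg/m³ | water at body temperature |
| `phi`, `eta` | porosity, pore size | 0.2, 60 nm | extracellular-space probes |
| `xi`, `theta` | venous pulsatility ratio, phase | 0.80, 0 | venous imaging |
| `h`, `d` | element height, depth | 100, 200 µm | grid discretization |
| `R_i_PCY`, `R_o_PCY` | parenchyma shell radii | 10, 300 µm | see note |

Values are entered in any supported unit (`"10 um"`,
`"5.63e6 um3.s/kg"`, `"0.9 mPa.s"`) and converted once at the boundary;
everything internal is SI.  Two genuinely open choices deserve note.
First, the parenchyma shell inner radius is 10 µm (the vessel wall) even
though the PVS outer boundary sits at 30 µm; the published table prints
10 µm and that value is used as-is — the shell resistance changes by only
the ratio $\ln(300/10)/\ln(300/30)$ (≈ 1.48×) between the two readings, and
neither alters any regime conclusion.  Second, no baseline porous-PVS
conductivity is published, only a sweep range, so the default `K_PVS` is
solved from equality of the porous and free-fluid annulus resistances at
baseline geometry (≈ 3.8e-8 m³ s/kg, the "free fluid cavity" order of
magnitude); the porous variant at defaults therefore matches the
free-fluid baseline exactly, and sweeps perturb it from there.

## Sweeps

`run_sweep()` rebuilds and re-solves the network at every grid point with
all other parameters at baseline.  Conductivity grids are logarithmic
(the physiological ranges span nine decades), amplitude/radius/ratio/phase
grids linear.  Invalid grid points (e.g. $R_i \ge R_o$ in a radii grid)
are skipped and recorded in the result's `skipped` attribute rather than
aborting the sweep.  `phase_sweep()` reports signed velocities a quarter
period into the arterial waveform, where the arterial sources peak, so
direction reversals between arterial and venous PVS are visible.

```{r}
sol <- solve_period(build_one_vessel(pvs_parameters()))
sol
round(element_velocity(sol, "R6", distance = 50e-6) * 1e9, 2)  # nm/s
```

## What the model does and does not capture

The defaults above *are* the study conditions: a rigid-tissue, linear,
constant-resistance network driven by a single-harmonic wall motion.
Within those conditions the model reproduces the published magnitudes
(peak PVS velocity ≈ 29 µm/s and pressure ≈ 65 mPa in the one-vessel
baseline; ≈ 15 µm/s arterial PVS velocity in the two-vessel baseline;
parenchyma velocities of a few nm/s; an arterial–venous pressure gradient
of order 10⁻³ mmHg/mm) — all recomputed, not stored, by the test suite
and `scripts/acceptance.R`.  Passing those checks shows the network
physics and topology are right; it does not show that real perivascular
flow is sinusoidal, that tissue is rigid, or that no net-flow mechanism
exists.  Specifically out of scope: fluid–structure interaction and
viscoelastic tissue deformation; time-varying PVS conductivity and CSF
pressure transients (both candidate net-flow drivers); explicit
AQP4/astrocyte modelling (their effect enters only through `K_PCY`);
branching PVS trees; and quantitative shear-dispersion coefficients — the
Péclet numbers flag where dispersion matters, they do not quantify it.

By construction the linear network with zero-mean sources can produce no
net flow; the zero-net-volume checks therefore validate the integrator,
not a biological discovery.

## Numerical choices

* 256 time samples per period (tests assert < 0.1% peak drift on
  doubling); test-suite solves mostly use 64–128 samples to stay quick.
* Cholesky solve of the reduced conductance system; assembly refuses
  networks with nodes not connected to ground, naming the offenders.
* Pulsatility quadrature splits the integral at half-period kinks of
  |cos| before adaptive integration (rel. tol 1e-10).
* The amplitude-cap root search brackets on $[0, \min(R_o - R_i, R_i))$
  and exploits monotonicity of the resistance deviation in $b$.
* Degenerate inputs: zero-length axial elements have zero resistance and
  are valid as formulas but rejected inside networks; equal shell radii
  give zero radial resistance; `b = 0` yields an exactly quiescent
  solution.
* Reports serialize at 9 significant digits, which makes repeated runs
  byte-identical while keeping round-trip error (~1e-9 relative) far
  below physical uncertainty.

## Reproducing the published magnitudes

`Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json`
re-solves both baseline models at 256 samples and writes the headline
metrics (velocities, pressures, parenchyma bounds, amplitude cap) as
JSON.  The model is deterministic; the seed flag exists for interface
uniformity.  A command-line front end with `run`, `sweep` and `check`
subcommands lives at `inst/cli/pvsflow.R`.
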