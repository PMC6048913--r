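Package: pvsflow
Title: Hydraulic Network Models of Pulsatile Perivascular and Parenchymal Flow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lumped-parameter hydraulic resistance network models of
    oscillatory fluid motion driven by blood-vessel pulsation in cortical
    perivascular spaces (PVS) and brain parenchyma.  Builds one-vessel
    (arteriole) and two-vessel (arteriole + vein) networks from validated
    physiological parameters, computes element resistances (annular
    Poiseuille, porous-media annulus, radial Darcy shell, Darcy slab),
    drives them with sinusoidal volumetric sources derived from vessel wall
    motion, solves nodal pressures and flows over a pulse period, and
    derives velocities, Peclet numbers, Womersley number and parameter
    sweeps over pulse amplitude, PVS radii, hydraulic conductivities,
    pulsatility ratio and pulse timing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: jsonlite, stats, utils, yaml
Suggests: knitr, testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
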