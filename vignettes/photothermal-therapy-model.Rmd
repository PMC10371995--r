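---
title: "Modeling gold-nanoparticle photothermal therapy: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling gold-nanoparticle photothermal therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pttsim)
```

# The model

`pttsim` simulates laser photothermal therapy (PTT) of a superficial skin
tumor loaded with gold nanoparticles (GNPs). The pipeline has five stages,
each exposed as ordinary R functions:

1. **Nanoparticle optics.** The discrete dipole approximation (DDA)
   computes absorption/scattering cross sections of the photothermal
   converter; a Lorenz--Mie implementation serves as the oracle for
   spherical targets.
2. **Effective medium.** Particle efficiencies and a loading fraction
   become additions to the tissue's absorption and reduced-scattering
   coefficients: `mu_abs_np = 0.75 f_v Q_abs / r_eff`, reduced scattering
   scaled by `(1 - g)`, summed onto the host coefficients.
3. **Photon transport.** A voxelized Monte Carlo walk deposits
   `Delta W = W mu_abs / mu_ext` per interaction, with Henyey--Greenstein
   scattering, Russian roulette, and step-splitting across voxel
   boundaries.
4. **Heat diffusion.** An explicit finite-difference solver with
   harmonic-mean interface conductivities integrates
   `rho c_v dT/dt = q + div(k grad T)` on the same grid.
5. **Dosimetry and sweep.** Snapshot temperatures become the apoptosis
   retention ratio `theta_A*` (time-averaged tumor fraction strictly
   between 43 and 50 degrees C), the thermal-hazard retention value
   `theta_H*` (time-averaged, hazard-weighted band occupancy of a 1 mm
   normal-tissue shell), and their ratio `theta_eff*`; a parametric sweep
   scans GNP distribution radius ratio (0.2--1.0), injection count (1--7)
   and laser power (0--100 mW).

# Scenario and parameters

The treatment scene is a skin cylinder, 20 mm diameter by 10 mm deep, of
four layers (epidermis 0.08 mm, papillary dermis 0.5 mm, reticular dermis
0.6 mm, subcutaneous fat 8.82 mm) with a squamous-cell-carcinoma cylinder
of 4 mm diameter and 2 mm length centered laterally. Thermal and optical
properties sit in `skinLayerTable()`; that table is the single source of
truth for material constants. A 1064 nm continuous-wave Gaussian beam of
4 mm diameter illuminates the surface at normal incidence for 600 s.

Choices the scenario statement leaves open, and what this package does:

* **Tumor depth anchor.** The tumor is anchored at the irradiated surface
  (depth 0--2 mm). Squamous-cell carcinoma originates in the epidermis,
  and anchoring at the surface is the only choice consistent with a
  surface-visible lesion; `tumor_depth_offset` makes it configurable.
* **Sub-pitch epidermis.** At the default 0.2 mm pitch the 0.08 mm
  epidermis is thinner than a voxel; voxel centers take the label of the
  layer they fall in, merging the epidermis into its neighbors with a
  warning. Within the tumor footprint (the heated region) this has no
  effect because the tumor occupies the surface there.
* **Injection layout.** One sphere at the tumor centroid plus the rest on
  a maximal ring at mid-depth, equally spaced. For n = 2 and 3 at large
  radius ratios the center + ring layout cannot satisfy pairwise
  non-overlap, so all n spheres go on the ring; layouts are checked
  against the inside-tumor and non-overlap constraints and fail loudly
  when infeasible.
* **Initial and boundary temperatures.** 37 C everywhere initially; the
  distal and lateral faces are clamped at 37 C (far-field body
  temperature) and the irradiated surface is adiabatic. The distal faces
  sit at least 8 mm from the heated region, so this choice is weakly
  felt; all faces are selectable through `boundarySpec()`.

# The photothermal converter is an assumption

The scenario specifies a 1064 nm laser but no particle geometry, size or
dielectric data, and absolute temperatures depend on all three. The
package fixes a **default converter** and keeps it visible and
replaceable everywhere (every pipeline function takes an
`OpticalEfficiencies` argument):

* a square-section gold nanorod, effective radius 11 nm, aspect ratio 10,
  chosen once by `calibrateNanorod()` so the longitudinal absorption
  efficiency peaks at the laser line (Q_abs about 12 at 1064 nm in the
  packaged gold dielectric table, vacuum-host convention, polarization
  along the rod axis -- the orientation that maximizes plasmonic
  absorption, matching the intent of using 1064 nm converters);
* gold optical constants over 400--1400 nm transcribed from published
  thin-film measurements, interpolated log-linearly in wavelength
  (`goldDielectric()`).

A key mitigating fact: with the loading definition below, particle-laden
voxels are optically thick at any plausible Q_abs, so tumor heating is
governed by how much beam the spheres intercept, not by the exact Q_abs.
The sweep conclusions are therefore robust to the converter assumption
even though point temperatures are not.

# Loading semantics

The loading fraction is defined literally as the ratio of one injection's
distribution-sphere volume to the whole tumor volume (per injection,
identical spheres). This is a *distribution* volume fraction, not a
gold-volume fraction, and it makes `mu_abs` inside the spheres of order
10^4 mm^-1 -- the spheres absorb essentially all light that enters them.
Because this is physically unusual, `volumeFraction()` and
`applyInjections()` also offer a dose-conserving mode (`fv_mode = "dose"`)
in which a fixed total particle volume is split across the spheres.
The default remains the literal definition. When several spheres
overlapped a voxel their coefficients would sum; the packing constraints
prevent overlap in all supported layouts.

# Transport conventions

The stepping attenuation follows the stated bookkeeping: `mu_ext =
mu_abs + mu_sca (1 - g)` (absorption plus *reduced* scattering), while
direction sampling still uses the tabulated anisotropy g. These two
choices are mutually inconsistent in radiative-transfer terms (a
similarity-reduced walk should scatter isotropically), so
`runPhotons(mode = "full")` offers the standard convention
`mu_ext = mu_abs + mu_sca` as an escape hatch; the default reproduces the
stated model. Boundaries are refractive-index matched (no Fresnel
reflection); packets leaving the domain or entering the inert
outside-cylinder region count as escaped. Roulette uses threshold 1e-4
and survival multiplier 10, preserving expected weight.

# Heat solver numerics

The explicit scheme's time step is `safety x min_m rho_m c_m /
(2 k_m (1/dx^2 + 1/dy^2 + 1/dz^2))` with safety 0.5; `runHeat()` rounds
it down so the snapshot stride (default 5 s at desk preset) is an exact
multiple. Face conductances are harmonic means, which reduce to k for
uniform material and to zero against inert voxels (so the embedded
cylinder's side walls are automatically adiabatic). Fixed-temperature
domain faces use a same-material ghost cell one pitch away. The point
release test against the analytic 3-D heat kernel holds to RMSE < 2% of
the peak; an adiabatic constant-source run conserves energy to machine
precision.

Because conduction with temperature-independent properties is linear in
the source, one unit-power run per (radius ratio, injection count) gives
the temperature rise at every laser power by scaling -- this is how the
will-be-1785-case sweep collapses to 35 transport + heat runs. A direct
cross-check (`52 mW` run vs `26 x 2 mW` scaling) is part of the test
suite.

# Dosimetry

Apoptosis is scored strictly inside (43, 50) C; temperatures at or above
50 C count as necrosis. The hazard weights for the normal-tissue shell
are a package assumption (the damage-grading weights are not uniquely
fixed by the damage phenomena they grade): below 43 C weight 0,
43--50 C weight 0.5, 50--60 C weight 0.75, at/above 60 C weight 1. All
headline metrics carry the band table used; `hazardWeights()` accepts any
ascending band set. Time integration is a rectangle rule over uniformly
spaced snapshots. The normal shell is all non-tumor tissue within 1 mm
(half the tumor length) of the tumor boundary. `theta_eff* =
theta_A*/theta_H*`, with 0/0 resolved to 0 and a positive apoptosis score
over zero hazard reported as `Inf` with a `degenerate` flag (it can occur
at very low power).

Plane-vs-volume fractions: instantaneous apoptosis coverage can be
evaluated over the tumor volume or over a single depth plane
(`bandFractions()` on any mask); both are reported where results are
quoted at a fixed depth.

Hazard-weight sensitivity, stated plainly: with the default table's zero
weight below 43 C, `theta_H*` is essentially zero until the shell first
crosses 43 C, so the ratio `theta_eff*` is largest at the *low-power*
edge of any sweep window and decreases from there -- it has no interior
maximum in laser power. Comparative statements about `theta_eff*` maxima
(for instance, that one injection scores below seven) therefore hold
near the therapeutic optimum but can reverse at low powers, where
concentrated single-injection heating reaches the apoptosis band before
the shell registers any hazard. Any weighting that assigns a small
nonzero hazard to sub-43 C heating restores an interior maximum; since
the grading weights are an acknowledged assumption, conclusions that
depend on the low-power shape of `theta_eff*` should be checked against
the user's own band table.

# DDA numerics and the metal-sphere regime

The coupled-dipole system `P_i = alpha_i (E_inc,i - sum A_ij P_j)` is
solved matrix-free with displacement-indexed interaction tables (all
dipoles sit on a cubic lattice, so pairwise tensors are precomputed per
integer displacement); small systems use a dense direct solve, larger
ones COCG (uniform scalar polarizability; the scaled system is complex
symmetric) or block-preconditioned BiCGSTAB (tensor polarizabilities),
to relative residual 1e-6 with an iteration cap of 1e4.

Three polarizability prescriptions are available:

* `"fcd"` (default): filtered coupled dipoles. The interaction tensor is
  the low-pass filtered Green tensor (cutoff pi/d) and the self term is
  derived from the same filter, which makes an infinite lattice reproduce
  the exact bulk dispersion for |m| k < pi/d. Accurate for dielectrics
  and for compact exact-fill shapes (rods); well conditioned for metals.
* `"ldr"` / `"cm-rr"`: the classical lattice-dispersion-relation and
  Clausius--Mossotti + radiative-reaction forms.
* `"rcb"`: shape-adapted (prescribed) tensor polarizabilities that make
  the static uniform-field solution of the discretized target exact,
  after Rahmani, Chaumet and Bryant. This is the accurate choice for
  *staircased* metal targets (spheres) in the near infrared.

Why the extra machinery: for gold at 1064 nm the relative permittivity is
about -49 + 3.6i, and a staircase-discretized sphere supports spurious
corner/surface plasmon modes spanning exactly this range. With the
classical prescriptions the absorption then overshoots the Mie value by
factors of 2--7 at 10^3--10^4 dipoles and barely improves with
refinement -- a documented failure regime of the DDA for strongly
negative permittivity. The shape-adapted prescription combined with the
filtered kernel removes the artifact: scattering matches Mie almost
exactly, and the extinction discrepancy falls to a few percent at about
5 x 10^3 dipoles (it decreases non-monotonically with refinement, since
the staircase surface changes discretely with the spacing). Large
prescribed-polarizability solves use an FFT-accelerated matvec (the
cubic lattice makes the interaction a 3-D circular convolution). For the
default *rod* converter the lattice fills the cuboid exactly (no
staircase), so the plain filtered prescription suffices; the calibrated
rod behaves like a textbook longitudinal plasmon resonator, and
`calibrateNanorod()` reproduces the aspect-ratio scan that placed its
absorption peak at the laser line.

# Problem sizes

Two presets bundle the grid settings: `"desk"` (0.2 mm pitch, 1e5 photon
packets, 5 s snapshot stride) and `"paper"` (0.1 mm pitch, 1e6 packets,
1 s stride). All shipped tests and the acceptance script use the desk
preset: one distribution case (transport + 600 s of heat) takes roughly
two minutes, and a restricted sweep over {0.8, 1.0} x {1, 3, 7}
injections stays within a coffee break. The full 5 x 7 grid at paper
settings is a batch job, not an interactive one, and is left to the user.

Monte Carlo uses R's RNG throughout (`set.seed` gives bit-identical
absorption grids); every sweep case derives its seed from the base seed
plus the case index.

# What the synthetic scenes do and do not capture

The scene builder produces idealized geometry: perfectly layered planar
skin, a cylindrical tumor, spherical injection regions with sharp
boundaries, and uniform optical properties per material. Real lesions
have irregular margins, vasculature and perfusion (no Pennes perfusion
term is included here -- the governing equation is plain conduction),
temperature-dependent properties, and GNP distributions that diffuse
after injection. Passing tests on these scenes validate the numerics and
the stated model, not the biology; absolute temperatures in vivo would
differ. The validation phantom (30 mm cylinder, 5 mm spherical tumor,
805 nm top-hat beam at 1 W/cm^2, initial temperature 0 C) is included as
a qualitative fixture with synthetic water-like material constants; the
original phantom study's property values and measured curve are not
packaged, so only the monotone heating shape is asserted.
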