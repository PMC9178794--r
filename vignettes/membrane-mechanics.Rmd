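---
title: "Membrane mechanics and pore sizing with bilayr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane mechanics and pore sizing with bilayr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bilayr)
```

`bilayr` post-processes lipid-bilayer trajectories with an eye on one
scientific question: how does a bound antimicrobial peptide stress an
anionic membrane, and how large is the water pore that stress opens?
This vignette is the package's own account of the models it implements,
the parameters that matter, the numerical choices behind them, and what
the synthetic test bed does and does not establish.

## The analysis chain

A trajectory (topology + frames of coordinates in nm, orthorhombic
periodic cell) flows through five stages:

1. **Leaflet surfaces.** The lipid phosphorus atoms are split into upper
   and lower leaflets and each leaflet is fitted with a smooth periodic
   height field `z = s(x, y)` on a regular grid.
2. **Geometry maps.** Node-wise P-to-P thickness, the surface order
   parameter, area per lipid, and curvature-corrected density profiles.
3. **Elasticity.** Relative area change, its incompressibility-mirrored
   thickness change, and the tension `Γ = K_A · ΔA/A`, with
   `K_A` either supplied or estimated from area fluctuations.
4. **Pore census.** Per-frame count of water oxygens in a 0.5 nm slab at
   the bilayer centre; plateau statistics; cylinder-model diameter;
   disruption detection.
5. **Interactions.** Contacts, hydrogen bonds, residue distance maps,
   centre-of-mass tracks, diffusion coefficients and charge bookkeeping.

`analyze_bilayer()` chains stages 1–4 and returns a tidy report;
stage-5 functions compose freely with it.

## Surface fitting

Each leaflet surface is a kernel regression: the height at a lateral
position is the Gaussian-weighted mean of the leaflet's P-atom heights,
with lateral distances wrapped periodically. The fit quality
(`fit_rmsd`) is the RMS difference between each P atom's height and the
surface evaluated at that atom's lateral position — an interpolated-
surface definition, chosen over nearest-grid-node because it makes the
RMSD independent of grid resolution.

Parameters:

* `grid_n` (default 500, unitless): nodes per lateral dimension. All
  geometric contracts hold for any `grid_n ≥ 32`; the test suite runs at
  32–128 nodes and a few hundred to a few thousand atoms per stage,
  sizes at which every property is already resolution-converged.
* `bandwidth` (nm): the Gaussian kernel width. Small bandwidths follow
  undulations faithfully but chase noise; large ones smooth both. With
  `bandwidth = "auto"` a fixed ladder
  (1.5, 1.0, 0.75, 0.5, 0.4, 0.3, 0.25, 0.2, 0.15 nm) is scanned and the
  **largest** value achieving RMSD ≤ 0.1 nm — the customary quality bar
  for P-atom surface fits — is selected; if none achieves it, the
  RMSD-minimising ladder value is used. Preferring the smoothest
  acceptable fit is a deliberate regularisation: since RMSD decreases
  monotonically as the bandwidth shrinks, preferring small bandwidths
  would always select the ladder floor and overfit positional noise.

Degenerate inputs fail loudly: fewer than four points, or all points at
one lateral site, are errors rather than extrapolations. A fit of a
noiseless surface that the kernel can represent is exact (flat planes
reproduce to machine precision with zero RMSD); a box-commensurate
sinusoid of amplitude 0.3 nm is recovered to better than 5% of its
amplitude, and injected Gaussian noise of 0.07 nm reappears as a fit
RMSD of 0.07 nm within 20%.

Leaflet assignment is an exact one-dimensional 2-means partition of the
P-atom heights (deterministic scan over all split thresholds, no random
initialisation). If the two class means are separated by less than twice
the sum of the class standard deviations the distribution is not
credibly bimodal and the split errors out rather than guessing.

## Thickness, order and density

Thickness is measured **vertically** at matched lateral nodes
(`upper − lower` height), not along local normals: this is the map
convention for P-to-P distance distributions, and it makes the map mean
exactly equal to the difference of mean surface heights. A 3.1 nm
bilayer with a 0.2 nm peptide-bound dimple therefore shows a 2.9 nm
minimum, the signature the thickness map exists to expose.

The order parameter is `P₂(cos θ) = (3cos²θ − 1)/2` of the angle between
the local surface normal (central differences with periodic wrap) and
the box z-axis: 1 where the surface is flat, 0 at the magic angle
(54.74°), −0.5 where the surface is locally vertical. Values below 1
flag curvature; the quantity is a property of the fitted surface, not a
deuterium acyl-chain order parameter.

Density profiles are referenced to the **midsurface**, the mean of the
two fitted leaflet heights at each atom's lateral position: each atom is
binned by `z − midsurface(x, y)`, which removes the smearing that
undulation and peptide-induced curvature cause in an absolute-z
histogram. Referencing each leaflet separately was the open alternative;
the midsurface was chosen because it treats the two leaflets
symmetrically and reduces to the naive profile exactly when the bilayer
is flat. This is the one stage whose reference convention is a genuine
interpretation rather than a forced choice, and it is isolated behind
the `corrected` flag so both variants stay available.

## Elasticity

The elastic chain is deliberately small: hydrocarbon thickness
`h = P-to-P − 1.0 nm` (the 0.5 nm phosphate-to-hydrocarbon offset per
leaflet), fractional thinning `Δh/h`, incompressibility `Δh/h ≈ −ΔA/A`,
and `Γ = K_A · ΔA/A`. With `K_A = 200 mN/m`, tensions of 70 and 60 mN/m
correspond to 35% and 30% area increments, and a 10% thinning reads back
as about 20 mN/m of binding-induced tension.

When `K_A` must come from data, `estimate_ka()` uses the equilibrium
fluctuation estimator `K_A = k_B T ⟨A⟩ / var(A)` on a stationary area
series (≥ 100 frames), with a contiguous-block bootstrap standard error
(20 blocks, 200 replicates by default) to respect serial correlation.
The estimator is validated by self-consistency: synthetic Gaussian area
series constructed to have a given modulus return it within 10%. A
stated modulus for this bilayer class is 200 ± 20 mN/m, which is the
package default where a value is needed.

## Water census and pore sizing

The census slab is a half-open interval `[z_min, z_max)` applied to
**wrapped** z coordinates — half-open so boundary waters are never
double-counted, wrapped so the count is invariant to how the trajectory
writer placed the box origin. The canonical window is 0.5 nm high about
the bilayer centre (an absolute window of 1.7–2.2 nm in a box whose
midplane sits at 1.95 nm); `analyze_bilayer()` defaults to the window
symmetric about the fitted midplane.

Plateau finding works on rolling means over `window` frames (default
10): a position is stable when two consecutive non-overlapping window
means differ by under 10% (relative to at least 1 count, so an all-zero
series is stable). The plateau is the **last maximal stable run**. This
convention resolves two ambiguities at once: a series that is flat at
zero before filling is trivially "stable" early on, and a pre-collapse
blow-up destroys stability at the tail; anchoring on the last stable run
skips both the filling ramp and the blow-up. If no run exists the mean
is taken over all frames with a warning.

The pore diameter inverts the cylinder model
`d = sqrt(4V/(πh))`, `V = NW·M_w/(ρ·N_A)` with `h = 0.5` nm and
`ρ = 1 g/cm³` (bulk water) by default: 10 slab waters give 0.87 nm,
reported as 0.9; 5 give 0.62 nm, reported as 0.6. Reported values are
rounded to one decimal — the physically honest precision for a count of
order 10 — while raw values are always retained. The cylinder is an
idealisation; the real constriction is irregular, and the slab count is
best read as a bottleneck (lower-bound-flavoured) diameter.

Disruption detection is a heuristic for an event the underlying physics
only defines qualitatively ("the count rises abruptly before collapse"):
the first time the count exceeds `plateau_mean + k_sd · max(plateau_sd, 1)`
for `persistence` consecutive frames (defaults 5 and 5). Both knobs are
exposed; the defaults classify clean step fixtures exactly and recover
injected blow-up times within twice the persistence in at least 9 of 10
seeded noisy fixtures.

## Interaction statistics

* **Contacts** (`count_contacts()`): atom **pairs** within 0.6 nm
  (6 Å), counted individually rather than as unique atoms — each
  contact contributes. A periodic cell list accelerates large frames;
  its contract is bit-identical to all-pairs and is tested against an
  exhaustive 27-image oracle. Heavy-atom filtering is the caller's
  choice of selection, not an implicit rule.
* **Hydrogen bonds** (`find_hbonds()`): the de facto geometric
  convention, donor–acceptor ≤ 0.35 nm and H–D–A angle ≤ 30°, both
  configurable, because the upstream tools this mirrors apply exactly
  such criteria without stating them. Hydrogens are attached by naming
  convention (H\*-named atoms within 0.12 nm of the donor in the first
  frame) or by an explicit table; donors without hydrogens are skipped
  with a warning.
* **Diffusion** (`msd_diffusion()`): Einstein relation over all time
  origins with a least-squares slope over the middle 10–50% of lags,
  `D = slope/(2·n_dim)`. Dimensionality (2 for lateral membrane-bound
  motion, 3 for solution) is an explicit argument because a mobility
  ratio between a bound and a free state is only meaningful when both
  are computed in the same dimensionality. Wrapped coordinates (jumps
  greater than half a box edge) are refused rather than silently
  unwrapped, and a log-log MSD exponent far from 1 flags non-diffusive
  (ballistic/drifting) motion instead of reporting a meaningless slope.
* **Charges**: `+1` per LYS/ARG, `−1` per unprotonated GLU, nothing from
  the termini of a circular backbone; counterions are whatever makes the
  peptide + anionic-lipid box electroneutral. A 70-residue circular
  bacteriocin with 8 LYS, 2 ARG, 4 GLU is +6 at neutral pH and +10 with
  GLU protonated; two monomers on 128 anionic lipids need 116 and 108
  monovalent cations respectively.

## The synthetic bilayer

`generate_bilayer()` produces the ground-truth fixtures every stage is
validated against. It emulates precisely the statistical structure the
analyses assume, and nothing more:

* leaflet P atoms on `z = midplane ± p2p/2 + undulation(x, y)` with
  box-commensurate separable sinusoidal undulations (periodic by
  construction, hence analytically known everywhere), optional Gaussian
  dimple on the upper leaflet (a bound-peptide depression thins the
  bilayer locally — applying it to both leaflets would leave thickness
  maps blind to it), and Gaussian height noise;
* minimal pseudo-lipids — P atom, carbonyl-O acceptor, two tail beads —
  because the analyses touch only P positions, O acceptors, tails and
  waters; full lipid chemistry would add cost without adding contract
  coverage;
* single-site waters filling bulk slabs at 33.4 nm⁻³ (1 g/cm³), with
  optional ideal-geometry H sites for hydrogen-bond tests;
* an optional cylindrical trans-bilayer pore with an **exact** requested
  census-slab occupancy (or an occupancy drawn from bulk density), so
  census assertions are sharp;
* an optional bound pseudo-peptide cluster (one 110 amu bead per
  residue, classed cationic/anionic/polar/hydrophobic) for selection and
  interaction tests;
* a per-frame lateral dilation schedule; with volume conservation the z
  direction scales by `1/f²`, so relative thinning mirrors relative area
  growth exactly — the geometric consequence of applied tension without
  any dynamics.

Defaults are the study conditions of the anionic-bilayer system the
package targets: 64 lipids per leaflet (128 total) in a 6.72 × 6.72 nm
cell (0.7056 nm² per lipid), mean P-to-P separation 3.1 nm. Everything
is reproducible bit-for-bit from `seed`, and the generator restores the
global RNG state.

What the generator does **not** emulate — and therefore what passing
tests do not show — matters: there are no thermal ensembles, no
correlated undulation spectra, no lipid tilt or protrusion, no realistic
water structure, no kinetics. Recovery of a generator parameter
demonstrates that the analysis measures what it claims to measure, not
that a force field or sampling protocol is adequate. Trajectory-
dependent observables of real simulations (absolute water counts,
disruption times, per-replica maps) are outside what synthetic fixtures
can certify.

## Problem sizes and runtime choices

The test suite and examples run at desk scale by design: surface grids
of 32–128 nodes (the full 500-node default is used for production
analyses), 16–900 lipids per leaflet, hundreds of waters, trajectories
of 2–200 frames, 120–150 random walkers over 200 frames for diffusion,
and 10-seed oracle sweeps for contacts and census. These sizes were
chosen as the smallest at which each property is comfortably converged;
every tolerance in the suite (5% amplitude recovery, 10% modulus
recovery, 15% diffusion and pore-diameter recovery, 20% ratio recovery)
was fixed from the statistics of the estimator at those sizes, not tuned
downward afterwards.

## Known limitations

* Orthorhombic cells only; triclinic input is rejected at the parsers.
* Thickness is vertical P-to-P, not normal-projected; strongly tilted
  membranes would mix the two.
* The census slab is a fixed z-window: a pore that wanders far off the
  midplane, or a badly curved bilayer, needs a caller-supplied window.
* The cylinder pore model deliberately ignores pore shape; its output is
  a volume-equivalent bottleneck diameter.
* The disruption rule is a threshold heuristic; exotic collapse modes
  (slow leaks without a plateau) fall back to a warning.
* No closed-surface (vesicle/micelle) fitting and no undulation-spectrum
  analysis; the height-field representation assumes the leaflet is a
  graph over the lateral plane.
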