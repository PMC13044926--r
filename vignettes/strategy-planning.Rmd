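---
title: "Planning rotation-method data collection with mxsweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning rotation-method data collection with mxsweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mxsweep)
```

## The problem

A macromolecular crystallography experiment on a synchrotron beamline
rotates a cryo-cooled crystal about the goniostat omega axis while a
pixel-array detector records diffraction. A good plan must balance several
coupled constraints at once: completeness (including the "cusp" of
reflections near the rotation axis that can never cross the Ewald sphere),
multiplicity and the uniformity of its distribution, the Lorentz-factor
enhancement that diverges near that cusp, shadows cast by the phi-axis
mounting at high chi, losses in the inactive gaps between detector
modules, the radiation-damage dose budget, and the number of time-consuming
recentring operations. `mxsweep` implements the strategy-computation core
of such a planner: symmetry algebra, instrument geometry, dose and
transmission, a ray-tracing sweep simulator, and generators for
characterization, native (basic/advanced) and phasing strategies.

## Conventions

One lab frame is used everywhere: the beam along $+z$, the omega rotation
axis along $+x$ (horizontal), the detector plane perpendicular to the beam
at distance $D$. Reciprocal vectors are normalized to $\lambda = 1$, so
the Ewald sphere has unit radius and $|\mathbf{R}| = 2\sin\theta$. A
reflection at angle $X$ to the rotation axis crosses the sphere when its
axial rotation satisfies $R_z(\omega) = -|\mathbf{R}|^2/2$; it is *blind*
(inside the cusp) exactly when $\sin X < \sin\theta$, the boundary
$X=\theta$ counting as measurable. Crossings are geometric events:
mosaicity and bandpass are zero, which is the right idealization for
multiplicity arithmetic. A crossing belongs to a sweep when it falls in
the half-open interval $[\omega_0, \omega_0 + w)$.

## Symmetry

The eleven axial point groups (1, 2, 3, 4, 6, 222, 32, 422, 622, 23, 432)
are stored as proper-rotation groups of integer matrices acting on $hkl$
in the conventional settings, trigonal and hexagonal groups on hexagonal
axes. Point group 32 is kept in both arithmetic settings (321 and 312)
because the Bravais lattice alone cannot place its twofold axes. Indexing
ambiguity is represented as an ordered list of candidate arithmetic
crystal classes; the strategy is computed for the *lowest symmetry above
monoclinic* (on a hexagonal lattice offering 3, 6, 32 and 622 the planner
assumes 3). When two candidates tie on group order - the pseudo-tetragonal
list 4/422/222/2 ties 4 against 222 - the tie breaks toward the group
with the lower maximal rotation-axis order, then toward list order; the
choice is recorded on the returned object. A strategy computed for too low
a symmetry wastes a little beam time; one computed for too high a symmetry
can leave systematic holes, which is why the conservative direction is
down.

## Instrument geometry

For a centred beam the largest usable scattering angle is
$2\theta_{\max} = \arctan(w/2D)$ with $w$ the narrowest detector
dimension, and $d = \lambda / (2\sin\theta)$ converts it to a resolution.
The phi-axis mounting is modelled as a single infinite cone of half-angle
$A$ (default $19.84^\circ$, also used for the Smargon, whose main shadow
cone has a similar aperture) around $-\hat{\phi}$, apexed at the crystal;
minor kappa-bracket shadows are ignored. This reproduces the closed form:
a full turn is shadow-free exactly when
$(90^\circ - \chi) - 2\theta_{\max} \ge A$, i.e.
$\chi_{\max} = 90^\circ - A - 2\theta_{\max}$.

```{r}
detector_limits_table()
```

Two-axis kinematics give $\cos\chi = \cos^2\alpha + \sin^2\alpha\cos\kappa$
with $\alpha = 24^\circ$ for the mini-kappa, so $\chi(180^\circ)=48^\circ$,
and a chi limit of 48 degrees reaches $1-\cos 48^\circ \approx 33\%$ of
all unsigned rotation-axis orientations.

`shadow_fraction()` tests a configurable grid of detector points (default
$256^2$) against the cone. `shadow_free_omega_range()` reports the
shadow-free omega window over a set of kappa values in two readings:
`mode = "each"` (default) gives the smallest per-kappa window width - the
width of the free band across an omega/kappa shadow map, which is how such
maps are usually quoted - while `mode = "common"` gives the single widest
interval free at every kappa simultaneously. With a PILATUS3 6M the model
gives per-kappa windows of about 217 degrees at 200 mm and 176 degrees at
100 mm over kappa 90-240 degrees, a few percent narrower than the
published map readings of "about 225" and "about 185"; the omega/kappa
phase convention of the kinematic chain is fixed by the model above, so
the acceptance check compares window widths, never endpoints.

## Dose and transmission

At 100 K the dose-dependent intensity decay is modelled as
$I/I_0 = \exp(-\beta D d^{*2}/2)$ with $\beta = 1.0$ Å$^2$ MGy$^{-1}$
(a B-factor convention with $B = \beta D$). The dose budget is the dose at
which the relative intensity at the target resolution reaches a
configurable cutoff, 25 % by default:
$D_{\mathrm{budget}} = -2\ln(0.25)\,d_{\min}^2/\beta$, about 10.3 MGy at
1.93 Å. The matching transmission spreads that budget over the planned
exposure, $x = D_{\mathrm{budget}} / (t\, s\, \mathrm{conv}\, F_d)$,
clamped at 1 with an "under-dosed" advisory. `conv` (MGy per photon
µm$^{-2}$ for a sensitivity-1 crystal) has no universal value; the default
2e-10 is an order-of-magnitude figure for 12.4 keV and should be
calibrated per beamline - every recommendation that matters here depends
only on proportionality, which the tests pin down instead.

Arbitrary beams are reduced to an effective uniform flux density:
Gaussian widths are replaced by top-hat widths equal to the FWHM, then
$F_d = \Phi / (b_x \min(b_y, T))$ - the average over the beam when the
beam is wider than the crystal thickness $T$, the density in the
continuously irradiated slice when narrower. The `min()` keeps the
estimate continuous at $b_y = T$; the branch rule only matters when the
effective beam is narrower than the crystal. A small voxel simulator
(cubic grid, 1 µm voxels, no photoelectron escape or divergence) validates
this: the flux-weighted mean decay of a fully bathed uniform beam matches
the closed form to well under 1 %, and a 2x2 µm FWHM Gaussian at one
eighth of the flux of a 16x2 µm Gaussian tracks it within a documented
10 % sup-norm. Narrow-beam curves show the expected fast initial decay, a
quasi-plateau while fresh material rotates into the beam, and a step near
180 degrees when it runs out. The strict claim that a narrow Gaussian and
its FWHM top-hat give *identical* curves does not survive signal-weighted
voxel accounting (the Gaussian's tails decay more slowly than its core)
and is not asserted. Only single-position dosing is modelled;
per-sweep fresh-volume accounting for pseudo-helical collection is a
documented extension point, and room-temperature damage is out of scope.

## The sweep simulator

`simulate_sweeps()` enumerates every reflection to the resolution limit,
solves the crossing condition per sweep in closed form (at most two
crossings per full turn), and annotates each crossing with the Bragg
angle, the axis angle $X$, the Lorentz factor
$L = 1/(2\sin\theta\sqrt{\cos^2\theta - \cos^2 X})$ (equal to
$1/\sin 2\theta$ at the equator, divergent toward the cusp; verified
against a numerical crossing-speed oracle to 0.1 %), the detector
position, and gap/shadow flags. The spot footprint is a disc of 3 pixels
diameter (configurable; the integration criterion is stated in terms of
intensity, for which a uniform disc is the simplest stand-in), and a
reflection is excluded when less than 75 % of the footprint lies on active
modules; on a PILATUS 6M layout (487x195-pixel modules, 7/17-pixel gaps)
this removes about 10 % of predicted reflections, against 8.5 % inactive
area. `merge_stats()` merges under the Laue group (or proper rotations
only, for anomalous bookkeeping), reporting per-unique multiplicity, the
S/N enhancement factor (the sum of Lorentz factors over retained
observations, equal to multiplicity times mean enhancement),
equi-populated enhancement bins (10 by default), and completeness both
overall and outside the blind region.

## Native strategies

The basic strategy is a single 360-degree sweep at $\chi = 0$, reoriented
by the minimal chi when the rotation axis falls within $\theta_{\max}$ of
a unique symmetry axis (so every cusp reflection has a measurable mate);
P1 needs two sweeps, the second tilted by twice $\theta_{\max}$ so the two
cusp systems clear each other. Advanced strategies spread sweep
orientations and their symmetry images uniformly using vertices of
regular polyhedra: a rhombicuboctahedron vertex for 23, triangle triplets
for 222 and 4, a vertex square (or a three-sweep triangle, the default)
for 3, a truncated-cuboctahedron vertex for 432 (two for 23's
alternative), and two truncated-octahedron vertices for 32. For 6, 422
and 622 multiplicities are already high and a heuristic two-orientation
set is used; for 1 and 2 four-orientation spreads are chosen to fit the
accessible cone, since no goniostat can cover the sphere for them. The
vertex sets are package data frozen from the standard polyhedron
constructions; the published pictures do not fix coordinates, so which
triangle/square is used is a documented choice.

`fit_to_mounting()` rotates the target set rigidly - about the principal
symmetry axis where there is one, over all of SO(3) for P1, over the
finite symmetry images for cubic groups - minimizing the maximum required
chi on a 2-degree grid, then realizes each axis by inverse kinematics;
targets beyond the chi limit fall back to the nearest accessible
orientation with a warning (for certain mountings the preferred
orientations are simply unreachable). Sweep lengths follow the scaling
rule: the lowest-chi sweep first at 360 degrees, later sweeps 360 when
shadow-free at their chi and 192 otherwise, all widths multiples of the
4.8-degree scaling batch, omega starts centred in the shadow-free window.
Predicted maximum multiplicity is
$2 \times |\mathrm{Laue}| \times L_{\mathrm{eff}}/360$ with 192-degree
sweeps counted as 180 (their prolongation exists for scaling, not
multiplicity):

```{r}
native_strategy_table()
```

## Phasing building blocks

Anomalous differences are only as good as the scaling of the reflections
being subtracted, so the planner exposes building blocks rather than one
canonical plan per group: minimum sweep lengths for anomalous completeness
(P1: $180^\circ + 2\theta_{\max}$; single-axis groups: $360^\circ/n$
aligned or $90^\circ + \theta_{\max}$ orthogonal; other groups:
$360^\circ/2n$ on an evenfold axis or $90^\circ$ orthogonal), cusp-filling
sweeps ($180^\circ + 2\theta_{\max}$, $180^\circ + 4\theta_{\max}$, or a
pair of $2\theta_{\max}$ sweeps 180 degrees apart) at the accessible
orientation farthest from the main axis, interleaving schedules
(omega / omega+180 wedges, optionally crossed with a wavelength list for
MAD - wavelengths are opaque labels, no absorption-edge physics), and
out-of-sequence sweep splitting. For the monoclinic crystal rotated
orthogonal to its twofold the implemented minimum is
$90^\circ + \theta_{\max}$; the older literature value
$180^\circ + 2\theta_{\max}$ is computable behind the
`dauter_monoclinic` flag but appears to be incorrect.

Two subtleties that the simulator exposes, and that the tests encode:
these minima assume the sweep *starts at an omega matched to the
symmetry-axis directions* (the test helpers scan candidate starts), and
even then an exactly minimal sweep leaves a small boundary volume
unmeasured - in P1 a sweep of $180^\circ + 2\theta_{\max}$ is exactly
complete outside the enlarged trumpet
$\sin X \le \sin\theta / \sin\theta_{\max}$, and drops below 99 % when
shortened by 10 degrees. For single-axis aligned cases ($360^\circ/n$) the
minimum is conservative for a generic mounting: completeness stays at
100 % even 10 degrees short, so no sharp drop is asserted there.

## Synthetic fixtures

`generate_fixture()` draws unit cells uniformly in 25-60 Å edges (angles
75-105 degrees bounded 3 degrees away from 90 where free; monoclinic beta
in 95-115), uniformly random orientations via quaternions, thickness 12 µm
and sensitivity 1.0 - a small, well-diffracting protein crystal of average
composition. These fixtures exercise every geometric code path (random
orientations sample the cusp, shadow and gap configurations), but they are
ideal-lattice objects: passing tests says nothing about mosaicity,
absorption, anisotropy, twinning or real detector calibration. Problem
sizes in the tests and the acceptance script are chosen at the stated
experimental resolutions where a published number fixes them (1.93 Å,
1.22 Å, ~2 Å) and at 2.5-4 Å for invariants that hold at any resolution.

## Numerical choices

Group closure is exact integer arithmetic. Crossing solutions clamp
$|c/\rho|$ at 1 with a $10^{-12}$ tolerance; tangent crossings count once.
The blind test uses the same tolerance on $\sin X - \sin\theta$.
Orbit representatives are the lexicographically largest member under an
integer encoding. The shadow grid (default $256^2$, coarser in tests) and
the 0.5-degree omega scan bound the window-width error to about a degree.
The voxel simulator uses 1 µm voxels and 2-degree steps; halving either
changes the bathed-limit agreement by far less than the 1 % tolerance.
Monte Carlo accessibility uses $10^5$ or more axes, where the binomial
error on 33 % is about 0.15 percentage points.

## Limitations

No intensity prediction from structure factors, profile fitting, scaling
model, absorption, or anomalous signal strength; no CAD goniostat
collision model beyond the chi limit; no multi-crystal or
room-temperature strategies; no beamline-control integration - the
deliverable of a planning run is the plan file and its simulated
statistics.
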