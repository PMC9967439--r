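---
title: "Gradient bundle analysis: model, numerics and design choices"
author: "bondbundles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gradient bundle analysis: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

The quantum theory of atoms in molecules (QTAIM) partitions real space by
the topology of the electron density $\rho(\mathbf r)$: gradient paths of
$\nabla\rho$ terminate at nuclear maxima, and the set of paths sharing a
terminus is an atomic basin, bounded by zero-flux surfaces (ZFS). Over a
ZFS-bounded region the ambiguity between the gradient and Laplacian
kinetic-energy densities vanishes, so such regions have well-defined
kinetic and (through the virial theorem) total energies.

Gradient bundle analysis refines this partition below the atomic level.
Around each nucleus $i$ a small reference sphere $S_i$ of radius
$\mathrm{d}r$ indexes every gradient path of the atom by the point
$(\theta,\phi)$ where it crosses the sphere. A surface element
$\mathrm{d}A$ of $S_i$ generates a *differential gradient bundle* — the
tube of gradient paths through it — which is ZFS-bounded by construction.
Any 3D scalar field $f$ then condenses to a 2D field on the sphere,

$$F_i[f](\theta,\phi) = \int_{G_i(\theta,\phi)} f(s)\, \mathrm{d}A(s)\,
\mathrm{d}s,$$

the integral of $f$ over the bundle: the charge density gives the
condensed charge density $P$, a kinetic-energy density gives $T$, and
$f\equiv 1$ gives the bundle volume $V$. Watershed basins of $P$ on the
sphere are *bond wedges*; wedges on different atoms whose bundles share an
interatomic surface form a *bond bundle*, the real-space analogue of a
chemical bond. A wedge's *solid angle* $\alpha$ is the fraction of the
sphere it covers; per atom the $\alpha$ sum to 1 exactly.

Energetics follow from the regional virial theorem for force-free nuclei,
$E_\Omega = -T_\Omega$, applied to the condensed kinetic energy (the
non-interacting form; no exchange-correlation kinetic correction is
applied). Core/valence splits use the solid-angle share of the isolated
atom's core count, $N_\mathrm{val} = P_w - \alpha N_\mathrm{core}$, and
bond energies subtract the solid-angle share of the isolated-atom energy,
$BE = \sum_w (T_w - \alpha_w T_\mathrm{atom})$, converted at
1 Ha = 2625.4996 kJ/mol = 27.2114 eV.

## Density sources

Fields are evaluable objects with value, gradient and Hessian. Two
realizations ship:

* **Promolecular densities** — superpositions of spherically symmetric
  neutral-atom densities built from Slater-type shells
  ($\rho_\mathrm{at}(r) = \sum_k c_k r^{p_k} e^{-a_k r}$) with exponents
  from Slater's screening rules and shell occupations from the aufbau
  ground states (with the usual d-block exceptions; Ag is
  [Kr]4d$^{10}$5s$^1$). Each atom is normalized to its electron count
  exactly. Derivatives are analytic. Periodic systems sum lattice images
  until every shell falls below an absolute tail tolerance
  ($10^{-14}$ a.u.).
* **Grid fields** — Gaussian cube input with C1 tricubic (Catmull-Rom)
  interpolation, periodic or not. Grids reproduce node values exactly and
  give continuous gradients, which path tracing requires. A 0.1 bohr
  pitch resolves valence regions but *not* heavy-atom cores: reference
  spheres on grid densities need either fine grids or analytic densities.

The promolecular model is the package's test bed: it has the correct
topology (nuclear cusp maxima, bond/ring/cage saddles, interatomic
surfaces) and closed-form integrals, but no self-consistent charge
rearrangement — no bonding accumulation, no polarization. Consequences
observed throughout the package's checks, and worth stating bluntly:

* condensed-density watersheds sit closer to the geometric midpoints than
  in self-consistent densities. For acetylene the promolecular triple-bond
  wedge has $\alpha \approx 0.26$ where all-electron GGA analyses report
  0.62; benzene and cyclobutadiene behave similarly. Passing conservation
  and symmetry tests on promolecular fixtures therefore validates the
  *machinery*, not the published wedge sizes, which require
  self-consistent densities as input (e.g. via cube files).
* FCC silver: the promolecular condensed density is metallic-flat (about
  1% relief) and peaks toward the twelve nearest neighbors, giving twelve
  symmetry-equivalent wedges, not the six octahedral-hole wedges of the
  self-consistent metal. The equipartition property (energy share equal to
  solid-angle share) holds either way.

## Numerical scheme

**Topology.** Nuclei are density cusps, so they are recorded directly as
nuclear critical points; smooth stationary points are refined by damped
Newton iteration from nuclei, pair midpoints, triple centroids, random
scatter and (for periodic cells) a uniform fractional grid, then
deduplicated (minimum-image metric in periodic systems) and classified by
Hessian eigenvalue signs, with a density floor (`rho_min`, default
$10^{-4}$) suppressing far-field noise where $|\nabla\rho|$ is numerically
zero. Molecular CP sets are checked against the Poincare–Hopf relation
(index sum 1; 0 on the torus).

**Path tracing.** Adaptive RK4 on the unit gradient field with a per-step
monotonicity guard on $\rho$, step clamping to a quarter of the distance
to the nearest known CP (prevents jumps across interatomic surfaces near
saddles), and *separatrix continuation*: a descent path that stalls at a
bond or ring CP continues along the projection of its incoming direction
onto the downhill Hessian eigenspace. Without this continuation, paths
pinned at saddles make the quadrature sweep the interatomic-surface
region and overcount populations by tens of percent. Descent terminates
at the truncation isovalue, at a minimum (cage CP), or at an aperiodic
grid boundary; ascent terminates at nuclear maxima.

**Condensation.** The three vertex paths of each mesh element are
re-parameterized at common $\rho$ levels (geometric spacing, default 48
stations per decade; matching by $\rho$ level rather than arc length keeps
stations aligned when path lengths differ). The cell between consecutive
station triangles is integrated as an exact triangular prism volume
(three-tetrahedron decomposition, signed so that numerical folds cancel);
an earlier area-times-mean-step rule overcounted divergently wherever
bundles flatten onto interatomic surfaces, because the three bounding
paths have local step lengths differing by orders of magnitude. Flat
station triangles are corrected by the spherical/flat area ratio of the
element. Elements whose stations spread much further than the radial
expectation (`fan_threshold`, default 3) are adaptively subdivided with
freshly traced, cached midpoint paths up to `max_depth` (default 4),
children being accepted against the parent value at tolerance `tol`
(default $10^{-3}$) — every element is subdivided at least once. The
sphere interior ($r<\mathrm{d}r$) is added per element as the radial cone
integral (41-point Simpson), exact for the nearly spherical core.

**Separatrix caps.** The elements at a bond-path direction own a full
annular neighborhood of the interatomic-surface rim; flat station
triangles there sweep the curved surface and accumulate a fixed phantom
mass of order 0.1 e per strong bond (for the flat interatomic surface of a
homonuclear diatomic the sweep degenerates and the error vanishes, which
is why only curved surfaces reveal it). Where the separatrix opens onto
the truncation surface — molecular fans — the cap of elements within a
fixed angular radius (0.15 rad) of the bond direction is therefore
integrated as a single surface of revolution about the bond axis: at each
$\rho$ level the cross-section is the Pappus ring swept between the cap's
perimeter stations and a traced separatrix path, degenerating to the
polar-cap disc before the bond CP. The cap total is shared among its
elements by area; since these elements sit at the interior (peak) of
their wedge, neither solid angles nor wedge sums are affected by the
sharing. Caged crystal fans, whose separatrices end at ring or cage
critical points, keep the standard quadrature, which is well behaved
there. With this treatment, basin populations agree with the gradient-flow
ground truth (ascent assignment of every grid voxel) to 0.05–1.7% across
the fixture suite, and with the voxel-watershed oracle to 0.2–0.6%.

**Truncation.** The display convention for bundle surfaces is the
$\rho = 10^{-3}$ isosurface, but condensation descends to $10^{-6}$ by
default: the tail between the two holds several percent of a hydrogen
basin, and electron-count conservation at the 1% level requires it.

**Watershed.** Elements link to their steepest-ascent neighbor by
per-area condensed density (ties to the lowest index, recorded as
plateaus; an all-equal field returns a single basin flagged degenerate).
Basin hygiene uses two merges: (i) basins smaller than `min_elements`
(default 8) are mesh-noise — condensed densities have integrable
$\sim 1/\theta$ singularities along bond-path directions, where per-element
quadrature noise exceeds any fixed fraction of the field range, and such
noise basins are always a few elements; (ii) in maxima mode, basins whose
peak rises less than `prominence` (default 0.25, relative) above their
highest connecting saddle merge across it. The relative form is
scale-free (a range-normalized threshold is meaningless under the ridge
singularities), and the default sits in a wide observed gap: every
genuine bond wedge examined rises at least 42% above its saddle, while
the only shallower structures are truncation-sensitive far-field bumps
behind hydrogens (3–18%), which the published convention folds into the
single H wedge ($\alpha_\mathrm{H} = 1$). Metallic condensed fields are
nearly flat; for those, pass `smooth` (one or two area-weighted neighbor
averagings, used only for the watershed ordering) and a small
`prominence` such as 0.002.

**Bundles.** Each wedge is matched to the bond CP whose bond path pierces
its interior (piercing by nearest element centroid; interior means all
edge-neighbors share the wedge); two wedges on one bond CP form a
two-center bundle. Unpierced wedges try the ring/cage CP nearest (within
60 degrees) to their area centroid direction under the minimum-image
convention; wedges sharing such a CP form a multi-center bundle, and the
rest are flagged unassigned (lone-pair-like).

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `dr` | 0.2 | bohr | reference sphere radius; results are insensitive because bundles span nucleus to terminus (halving `dr` moves acetylene wedge $\alpha$ by $6\times10^{-4}$) |
| `level` | 4 | — | icosphere subdivision; 2562 vertices / 5120 elements |
| `trunc` | $10^{-6}$ | e/bohr$^3$ | descent truncation isovalue |
| `levels_per_decade` | 48 | — | station density along paths |
| `max_depth`, `tol` | 4, $10^{-3}$ | — | adaptive element subdivision |
| `prominence`, `min_elements` | 0.25, 8 | — | watershed hygiene |
| `gtol`, `capture`, `nudge` | $10^{-8}$, $10^{-4}$, $5\times10^{-3}$ | a.u., bohr | stationarity, CP capture, separatrix continuation step |

## What the fixtures emulate

`generate_fixture()` provides deterministic, closed-form systems chosen
to exercise every code path: a single atom (exact uniform condensation),
homo- and heteronuclear diatomics (one bond CP, mirror symmetry, unequal
basins), tetrahedral methane (four equivalent wedges), staggered ethane
(C–C plus six C–H bundles), a periodic FCC silver cell (interstitial
ring/cage topology, lattice-image summation), and a synthetic two-bump
condensed field (segmentation in isolation). Companion kinetic-energy
densities use the Thomas–Fermi form plus one ninth von Weizsaecker — a
standard semilocal approximation that is exact in the uniform limit and
has the right cusp-region growth; over ZFS-bounded regions the gradient
and Laplacian forms agree, so any positive KED with the system's symmetry
exercises the energetics identically. What the fixtures do **not**
emulate is self-consistency (see above), so agreement on fixtures does
not certify published wedge sizes for real densities.

The reference wedge and bundle tables for cyclobutadiene
(`cyclobutadiene_reference()`) come from a published all-electron GGA
analysis and drive the worked-example arithmetic: the D4h C–H bundle
valence count (2.291 e), the per-fragment and per-molecule distortion
energies (0.009 and 0.036 Ha), and the back-solved isolated-H reference
(the D4h and D2h rows are mutually consistent only within the rounding of
the printed solid angles, about 6 kJ/mol).

## Verification strategy and known limitations

Independent oracles back every stage: radial quadrature for promolecular
normalization; finite differences for gradients and Hessians; a 1D scan
for diatomic bond CPs; a voxel steepest-ascent (grid-native Bader)
labeling for basin assignment and populations; brute-force hill climbing
for condensed ascent links; exhaustive boundary matching for segmentation
comparison; and closed-form arithmetic for the energetics. Conservation
(population and energy) holds to better than 1% at mesh level 3–4 with
the default quadrature.

Known limitations, measured rather than assumed:

* Mesh-level aggregation of condensed values (children summing to their
  parent element) agrees to about 1% in L1, not better, independent of
  subdivision depth: the discrepancy concentrates in the separatrix caps,
  whose element membership quantizes differently at different mesh levels,
  and in the ridge elements where mass attribution is resolution-limited.
  Totals and wedge sums converge much faster (0.4% between levels 3
  and 4).
* Watershed boundaries on nearly flat (metallic) condensed fields are
  noise-limited at coarse mesh levels; solid angles of
  symmetry-equivalent metallic wedges scatter by tens of percent at
  level 2–3 even though their energy shares track their areas closely.
* Whether P-basin and E-basin boundaries coincide in general is left
  open; `compare_P_E_boundaries()` measures their distance and never
  assumes coincidence (where symmetry forces it, the measured distance is
  zero by construction).
* Non-nuclear maxima are treated as attractors of their own pseudo-atom
  basins and flagged in reports.

## A worked example

```{r, eval = FALSE}
library(bondbundles)

fx  <- generate_fixture("methane_td")
cps <- find_critical_points(fx$field)
s   <- build_reference_sphere(fx$field, atom = 1, dr = 0.2, level = 3,
                              cps = cps)
P   <- condense_field(s, fx$field)
b   <- segment_condensed_basins(P)
solid_angle(b)          # four wedges of ~0.25 each
sum(b$values)           # the carbon basin population

res <- run_analysis(analysis_config(mesh_level = 3), fx$field,
                    ked = fx$ked, outdir = "methane_out")
res$wedge_table
```

The analysis sizes used in the package's own checks (mesh levels 2–4,
voxel oracles at 0.15–0.18 bohr pitch, the FCC cell at level 2) were
chosen as the coarsest settings at which the conservation and symmetry
properties above are clearly resolved.
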