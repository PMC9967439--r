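# bondbundles

Chemical bonds, as objects with an energy, an electron count and a
boundary, are not directly observable in quantum mechanics — but the
topology of the electron charge density gets remarkably close. The quantum
theory of atoms in molecules (QTAIM) partitions space into atomic basins
bounded by zero-flux surfaces of the density gradient; over such regions
the kinetic (and hence, by the virial theorem, total) energy is
well-defined. `bondbundles` implements the sub-atomic refinement of this
idea: every gradient path of an atom is indexed by the point where it
crosses a small *reference sphere* around the nucleus, each sphere surface
element generates a zero-flux-bounded *differential gradient bundle*, and
any 3D scalar field `f` condenses onto the sphere as

    F[f](theta, phi) = integral of f over the bundle through (theta, phi).

The condensed charge density `P` segments (by watershed on the sphere)
into **bond wedges**; wedges on neighboring atoms sharing an interatomic
surface form **bond bundles** — the real-space analogue of chemical bonds,
with well-defined solid angles (`alpha`, the sphere-area fraction),
electron counts, virial energies (`E = -T`), core/valence splits
(`N_val = P_w - alpha * N_core`) and bond energies relative to isolated
atoms (`BE = sum_w (T_w - alpha_w * T_atom)`, 1 Ha = 2625.4996 kJ/mol).

The package is for computational chemists who want these quantities from
densities on Gaussian cube grids or from the built-in analytic
promolecular model (Slater-type atomic shells, exact derivatives,
molecular or periodic). It provides the full supporting toolkit: critical
point location/classification, gradient path tracing, Bader basin
assignment, icosphere condensation with adaptive quadrature, watershed
segmentation, bundle assembly, and virial energetics, plus a grid-native
(voxel steepest-ascent) Bader oracle for validation.

## A worked example

```r
library(bondbundles)

fx  <- generate_fixture("methane_td")         # Td CH4, analytic density
cps <- find_critical_points(fx$field)
table(cps$class)
#>    bond nuclear
#>       4       5

s <- build_reference_sphere(fx$field, atom = 1, dr = 0.2, level = 3,
                            cps = cps)
P <- condense_field(s, fx$field)              # condensed charge density
b <- segment_condensed_basins(P)
round(solid_angle(b), 4)
#> [1] 0.2513 0.2522 0.2507 0.2458
round(sum(P$values), 3)                       # carbon basin population
#> [1] 6.758
```

The four equal solid angles are the four C–H bond wedges of the methane
carbon; their populations sum to the carbon Bader basin population. The
published wedge tables for cyclobutadiene ship as reference data and
drive the energetics arithmetic:

```r
ref <- atomic_reference(c("C", "H"))          # cores: C 2, H 0; E_C shipped
w   <- cyclobutadiene_reference("wedges")
ch  <- subset(w, config == "D4h" & wedge %in% c("C of C-H", "H of C-H"))
sum(core_valence_split(ch$P, ch$alpha, ch$symbol, ref))
#> [1] 2.291                                   # C-H bundle valence electrons
```

`run_analysis()` chains the whole pipeline (topology, spheres,
condensation, segmentation, bundles, energetics) and writes CSV/JSON
reports stamped with a configuration hash; see the methods vignette
(`vignettes/gradient-bundle-analysis.Rmd`) for the model, the numerical
scheme, parameter guidance and measured limitations — in particular what
the analytic promolecular model can and cannot reproduce of
self-consistent-density results.

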