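---
title: "Whole-aerosol morphology analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-aerosol morphology analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aeromorph)
```

Submicrometer sea-spray aerosol (SSA) particles are droplets ejected by
bubble bursting at the ocean surface. At 30–50 nm diameter they are
organics-rich: roughly half water by mass, with an organic fraction
dominated by saturated fatty acids plus proteins and saccharides, and a
concentrated electrolyte core. This package analyses droplet-in-vacuum
molecular models of such particles — their overall shape, the organisation
of surfactants into surface rafts, the radial layering of the components,
water transport, and the chemistry of the air/particle interface — and
ships a coarse-grained synthetic generator that reproduces the published
composition designs and provides exact ground truth for every analysis
stage.

## The composition designs

Three systems of increasing chemical complexity are built as 40-nm
droplets:

* **A** — fatty acids (lauric : myristic : palmitic : stearic in a 1:2:4:3
  molar ratio) plus *Burkholderia cepacia* lipase (BCL), in 0.4 M NaCl.
* **B** — adds a rough lipopolysaccharide (LPS) construct and the minor
  seawater cations (110 mM Mg²⁺, 25 mM Ca²⁺, 20 mM K⁺).
* **C** — further adds free glucose and a 15-mer branched laminarin.

The published design states a total inorganic : organic : water mass ratio
of 0.09 : 0.40 : 0.51 and per-system fatty-acid shares of the organic mass
of 93 % (A), 80 % (B) and 63 % (C), with a constant lipase load of
"approximately 3 %". These numbers pin the remaining degrees of freedom:

* In system A the organic phase contains only fatty acids and lipase, so a
  93 % fatty-acid share forces the lipase to 7 % of organic mass — which is
  3 % of *total* particle mass (organic being 40 % of the total). We
  therefore read the 3 % as a total-mass figure and hold the lipase at 7 %
  of organic mass in every system, consistent with a constant lipase count.
* The LPS share is held at 13 % of organic mass in both B and C (a constant
  LPS load), leaving 17 % for the saccharides in C, split evenly between
  glucose and laminarin. The per-system saccharide split is not published;
  an even split is the least-informative choice.
* A 0.4 M NaCl solution contributes only ~2 % of the particle mass — far
  less than the nominal 9 % inorganic fraction, which describes a dried
  seawater-derived particle rather than a 0.4 M solution. The two published
  numbers cannot both be realised. The builder honours the *molarities*
  (ion counts follow the stated concentrations against the aqueous volume,
  at 30 Å³ per water molecule, with Cl⁻ adjusted last for
  electroneutrality) and the *water fraction* (water is fixed at 0.51 of
  the realized total mass); the organic phase absorbs the remainder, ending
  near 0.47–0.48 rather than 0.40. The achieved fractions are recorded in
  every `build_composition()` result.

Molecule counts are discretized by largest-remainder rounding, with at
least one molecule for any component with a nonzero target, and molar
masses from standard chemistry (LPS and laminarin construct masses are
configurable because no canonical single-molecule mass exists; defaults are
14 kDa and 2.45 kDa). The particle mass budget comes from the design
diameter at an overall density of 1.2 g/cm³, typical of an aqueous
organic–salt particle near 70 % relative humidity; this choice only scales
the molecule counts and cancels from every reported ratio.

```{r composition}
comp <- build_composition("A", diameter = 400)
comp
round(comp$achieved$mass_fractions, 4)
```

## The synthetic particle and trajectory generator

The generator is deliberately coarse-grained: one bead per water, ion and
glucose; two-bead head–tail rods for fatty acids; bead rods for LPS and
laminarin; a Gaussian bead blob for the lipase. Every downstream analysis
consumes only positions, masses, molecule ids, classes and head→tail
vectors, so this is the minimal faithful representation. Beads are placed
by rejection sampling inside the design sphere, with molecule centers kept
clear of the boundary so the rods stay contained. Identical seeds give
bit-identical particles.

`generate_raft_fixture()` plants what the real simulations develop
spontaneously: monolayer patches of lipids on the sphere surface with a
per-patch tilt (at zero tilt the tail bead points outward, toward the
atmosphere, so the head→tail vector aligns with the outward normal — the
orientation convention used by the surface-raft test), plus an optional
randomly oriented aggregate near the center. Because patches are planted,
their labels are exact ground truth for the clustering analysis; the rafts
are *not* emergent physics.

`generate_brownian_trajectory()` propagates the waters as an overdamped
random walk with per-axis step variance 2·D(r)·dt, where D depends on the
radial shell occupied at the step start, inside a reflecting spherical
wall. It is the parameter-recovery oracle for the transport module: the
analysis must read back the D values that generated the data.

What the generator does **not** emulate: force-field energetics, lipid
self-assembly kinetics, ion–macromolecule bridging, evaporation, and the
anisotropic particle deformation seen in the real trajectories. Passing
tests therefore certify the *analysis machinery* — not any claim about real
aerosol behaviour.

## Shape descriptors

The gyration tensor is the second moment of (mass-weighted) bead positions
about the centroid. With eigenvalues λ₁ ≥ λ₂ ≥ λ₃ (Å²):

* asphericity φ = λ₁ − (λ₂ + λ₃)/2 — zero for a sphere, growing with
  elongation; reported in Å² without normalisation, which matches the
  magnitude of published whole-aerosol values (φ ≈ 500–1000 Å² for 40-nm
  particles);
* relative shape anisotropy κ² = 1 − 3(λ₁λ₂ + λ₂λ₃ + λ₃λ₁)/(λ₁+λ₂+λ₃)² —
  dimensionless in [0, 1]; 1 for a line, 0 for isotropic symmetry (sphere,
  regular tetrahedron), ¼ for a planar isotropic set.

Mass weighting is the default (mass fractions being the currency of every
other analysis); an unweighted tensor is a flag away. Both closed forms of
κ² are evaluated on every call and must agree to 10⁻¹²; an all-zero tensor
is an error, never a silent NaN.

## Raft clustering

Each surfactant is reduced to a 6-vector: its centroid concatenated with
its unit head→tail orientation scaled by a weight *w* (Å). Euclidean
DBSCAN on these features clusters lipids that are both close and
co-oriented; points in no dense neighborhood stay "unclustered" (label
−1), which is the property that motivated DBSCAN here — no predetermined
cluster count, and a meaningful noise class. The implementation is
deterministic: neighborhoods include the point itself (`min_samples`
counts it) and expansion proceeds in index order.

Defaults (the published analysis states none): `eps` = 12 Å spans two to
three surfactant spacings at condensed packing; `min_samples` = 5;
*w* = 10 Å makes a head-to-tail flip cost 2*w* = 20 Å, about two neighbor
spacings, so oppositely tilted rafts in contact split into separate
clusters while `w = 0` recovers position-only clustering. The orientation
enters the *metric* as a scaled concatenation rather than as an angle so
that standard Euclidean DBSCAN reachability semantics apply unchanged.
No periodic imaging is used anywhere: the droplet sits in vacuum.

A cluster counts as a **surface raft** when its centroid's ellipsoidal
coordinate u reaches the outermost equal-volume shell (u ≥ (2/3)^(1/3))
and its lipids point outward on average (mean cosine against the outward
ellipsoid normal ≥ 0.5). This is where "orientation with respect to the
surface normal" is evaluated — after clustering, once a surface exists —
keeping the clustering itself well-defined on any configuration.

## Bounding ellipsoid and equal-volume shells

The particle surface is approximated by the minimum-volume enclosing
ellipsoid (MVEE) of the bead positions, computed by Khachiyan's algorithm
(tolerance 10⁻³) on an active set of extreme points — the convex-hull
vertices reachable along a dense fan of directions — with violators added
and the fit repeated until every bead satisfies u ≤ 1 (a final minimal
rescale guarantees containment). An enclosing fit, rather than a
least-squares surface fit, is what "bounding ellipsoid" implies, and the
MVEE's uniqueness gives fit idempotence under rigid rotation. Stray vapor
beads far outside the droplet would inflate any enclosing fit; an
`exclude_vapor` filter (drop beads beyond 1.8× the median radius) is
provided.

Concentric similar ellipsoids scaled by s_k = (k/N)^(1/3) bound equal
volumes; with the default N = 3 the regions are named core, bulk and
surface. A bead with u > 1 (outside the fitted surface, possible only
within the containment tolerance or for unfitted selections) belongs to
the surface region — the only assignment consistent with the shell
construction. Per component class, the package reports the percentage of
that class's mass in each region; rows sum to 100 by construction.

## Water transport

MSD curves use consecutive time slices from the trajectory tail with the
slice start as the single time origin, mirroring the sliced analysis
convention of the source data; multiple-origin averaging is available by
flag and is used in the tests where maximal statistics at fixed cost
matter. The diffusion coefficient comes from an OLS fit of MSD = 6Dτ over
a window defaulting to 10–80 % of the slice, skipping the short-time
region; the intercept is reported, not constrained. Shell-resolved
profiles freeze each water's shell membership at the slice start — beads
crossing shells mid-slice keep their label, trading a small boundary-mixing
bias for freedom from exchange artifacts. Units are Å²/ns with a 10⁻⁵
conversion to cm²/s.

Problem sizes in the tests were chosen for statistical headroom at desk
scale: the single-shell recovery uses 10⁴ bead-steps arranged as 1000 beads
× 10 steps (many short-lag samples beat few long-lag ones for slope
precision), and the two-shell recovery uses 600 beads × 2000 frames over a
200 Å sphere with the band edge at 140 Å, keeping the boundary mixing
layer a small fraction of each shell.

## Interfacial metrics

The ellipsoid surface area uses the Thomsen approximation (p = 1.6075,
accurate to ~1 %). With an area per lipid a_lipid — default 21 Å², a
condensed-phase fatty-acid monolayer value; the published analysis never
prints its site area — the surface offers N_sites = A/a_lipid sites.
Coverage is 100 · N_surface · a_lipid / A; predicted surface excess is
N_total/N_sites and measured excess N_surface/N_sites, so coverage = 100 ·
measured excess is an exact internal identity that `surface_report()`
asserts. Raft curvature is evaluated analytically: each member lipid is
projected radially onto the fitted ellipsoid and the mean curvature H of
the implicit surface is taken at the footpoint (sphere: H = 1/R; prolate
pole: H = a/b²); a raft's value is the member mean and the system value
the raft-size-weighted mean. Atmospheric exposure is distance-based rather
than ray-based: a bead is exposed when it lies within d_exp (default 3 Å)
of the ellipsoid surface along its ray, a molecule is exposed when any of
its beads is, and the frequency is the fraction of frames exposed. The
distance rule is exactly testable and matches the intuition of "at the
interface" without a solvent probe.

## Worked example

```{r pipeline}
cfg <- pipeline_config(system_id = "A", diameter = 150, seed = 1,
                       n_frames = 21, dt = 0.1,
                       slice_length = 0.5, n_slices = 2, min_samples = 3)
report <- run_pipeline(cfg)
report$stages
head(report$shape, 3)
report$surface$coverage_percent
```

## Numerical choices and limitations

* Khachiyan tolerance 10⁻³ bounds semi-axis error well under 1 % for the
  fixtures used; tighten for near-degenerate clouds.
* Largest-remainder rounding breaks ties by index; compositions are fully
  deterministic.
* Exactly antipodal orientations and exactly tied DBSCAN distances resolve
  by bead index order.
* The generators are oracles, not physics: raft recovery and diffusion
  recovery certify the estimators under the generating model only.
* Trajectory-dependent published quantities (the φ time courses, cluster
  kinetics percentages, per-system D values) require the original
  multi-million-atom trajectories, which are not deposited; the package
  reproduces the *design* quantities and the analytic limits, and validates
  the estimators by parameter recovery.
* Supported formats: PDB/GRO/XYZ coordinates, DCD and multi-frame XYZ
  trajectories. XTC is not supported (no reader available in the R
  ecosystem used here); convert with standard MD tooling first.
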