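---
title: "Membrane metrics in memflex: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane metrics in memflex: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memflex)
```

# The scientific problem

A cellular membrane has to satisfy two conflicting demands: it must be
deformable enough to be bent, tubulated and finally divided by fission
machinery (dynamin, BAR-domain proteins), yet tight enough that water, ions
and metabolites do not leak across. The fatty-acyl profile of the membrane
phospholipids tunes this trade-off. Phospholipids with **two**
polyunsaturated chains make membranes extremely deformable but also very
permeable; the natural **asymmetric** combination — saturated at *sn1*,
polyunsaturated at *sn2* — buys most of the deformability at little cost in
permeability, because the flexible *sn2* chain absorbs curvature stress
while the straight *sn1* chain keeps the hydrophobic core packed.

`memflex` implements the measurements with which this picture is
established: water-permeation statistics, acyl-chain dynamics and packing
defects on all-atom-style planar trajectories; tube geometry and relative
bending rigidity on coarse-grained pulled membranes; and the quantification
formulas of the accompanying wet assays. This vignette records the models,
their assumptions, the tunable parameters, and the places where the design
was genuinely open and a choice had to be made.

# Bilayer reference geometry

All planar-membrane metrics are defined relative to a per-frame reference:

* **Leaflets** are found by a deterministic two-means split of the
  phosphate z coordinates, initialised at the range extremes so the result
  is independent of atom order. A split whose centres separate by less than
  1 nm is rejected as *not a planar bilayer* — tube or micellar
  configurations fail loudly rather than silently.
* **Thickness** is the distance between the two leaflets' mean phosphate
  heights. The thickness entering the hydrophobic-slab definition is not
  standardised in the literature; phosphate-to-phosphate means are the most
  common operational choice and are available identically in all-atom and
  coarse-grained templates, which is why this package uses them. The choice
  is visible and configurable through the template (any atom can play the
  "phosphate" role).
* The **midplane** is the midpoint of the two phosphate means (not the
  centre of mass), which makes it robust to asymmetric water boxes.
* The **hydrophobic slab** is the band centred on the midplane spanning
  `slab_fraction` of the thickness. The default 0.65 defines "the centre of
  the membrane" for water-visit scoring. Slab bounds are computed **per
  frame**, not trajectory-averaged: permeation events span many frames, and
  per-frame bounds track membrane drift and undulation instead of smearing
  the slab. A lipid whose phosphate falls exactly on the midplane (a tie)
  is assigned by its glycerol z, with a warning.

Density profiles histogram any role selection (sn1 carbons, sn2 carbons,
water, ...) in midplane-relative z, averaged over frames, normalised so the
integral equals the mean selected-atom count per frame. Defaults: 100 bins
over ±thickness. In natural (sn1-saturated) bilayers the sn1 density peaks
at the bilayer centre while the sn2 density dips there — the saturated tail
fills the space the mobile polyunsaturated chain vacates — and the
generator reproduces exactly this contrast for testing.

# Water permeation

A **visit** is a maximal contiguous run of frames in which a water oxygen
lies strictly inside the slab (`slab_lo < z < slab_hi`). One frame inside
suffices; no minimum dwell time is imposed, because the underlying
measurement counts visits without a dwell criterion. Each visit is
classified by the sides occupied immediately before entry and after exit:

* *crossing* — exit side ≠ entry side;
* *rebound* — exit on the entry side;
* *unresolved* — the trajectory ends while the water is inside.

Re-entrant waters produce one record per maximal run; this keeps the
bookkeeping deterministic and order-independent. A water already inside the
slab at frame 1 has no observable entry side: if it later exits, the event
is scored as a rebound on its exit side (the most conservative,
"rebound-consistent" inference); otherwise it is unresolved.

Side bookkeeping under periodic boundaries uses per-frame minimum-image
corrected paths (`unwrap_z`). A corrected per-frame step of a quarter box
or more means the motion genuinely cannot be tracked at this frame spacing
— after wrapping, the true displacement is no longer distinguishable from
its periodic images — and the atom is flagged untrackable with a warning.

Summaries assign events to consecutive blocks (default 100 ns) by entry
time. Two normalisations are reported side by side because the headline
phrase "% of water molecules visiting" is ambiguous between them:
`percent_visiting` counts **distinct molecules** per block (the default
headline), while the crossing/rebound tallies count **events**. The
high-level `permeation_analysis()` wrapper defaults to 100 ns blocks after
a 100 ns equilibration discard, mirroring the standard protocol of
analysing 400 ns production runs as 3 × 100 ns blocks after discarding the
first 100 ns; short synthetic trajectories pass explicit values.

# Chain dynamics

**Terminal velocity.** The speed of the terminal CH3 carbon is the summed
per-step distance divided by total time, sampled every `step_ps` (default
10 ps, the trajectory-saving interval of the underlying data), with
minimum-image correction per axis. Two projections are reported: along the
membrane normal (`velocity_z = Σ|Δz|/T`) and in-plane. The in-plane number
is the per-step Euclidean displacement `Σ√(Δx²+Δy²)/T`: descriptions of
this quantity oscillate between "x velocity" and "x–y velocity", and the
in-plane Euclidean form is the rotation-invariant reading; per-axis sums
(`velocity_x`, `velocity_y`) are also emitted so either convention can be
recovered. Units nm/ns.

**Torsions.** A torsion here is *not* a 4-atom dihedral: it is a 3-point
bend — the angle at carbon *n* subtended by carbons *n−2* and *n+2* of the
same chain, scored in every frame for every interior carbon
(3 ≤ n ≤ L−2). An angle strictly below 100° counts; the boundary is
exclusive, and the scanner treats an angle of exactly the threshold as not
bent. Chains shorter than 5 carbons have no interior triplet and are
excluded with a warning. Frequencies are averaged within frame over chains,
then over frames, with SDs over blocks.

**Protrusions.** A chain is protruded when its terminal carbon is outward
of its own lipid's central glycerol carbon along the leaflet's outward
normal (upper: `z_CH3 > z_gly`; lower: `z_CH3 < z_gly`). An **event** is
the transition from non-protruded to protruded between consecutive frames —
transition counting is the only definition that makes "number of events"
finite for a continuous trajectory; no minimum duration is applied because
none is stated for the underlying measurement. A configurable hysteresis
band (default 0) is available for noisy all-atom data, where thermal jitter
around the glycerol level would otherwise double-count.

# Packing defects

The interfacial scanner reconstructs a classic membrane "packing defect"
analysis as a deterministic, oracle-checkable geometry problem: over each
leaflet, a 0.1 nm x-y grid is laid and a ray is cast from the solvent side
along the inward normal at every grid point. The first lipid **heavy** atom
whose van der Waals sphere the ray intersects is the contact; if it belongs
to the template's aliphatic set (acyl carbons minus the two carbonyl
carbons), the cell is a defect. The defect depth is the vertical distance
of the contact point below the *nearest glycerol* — the glycerol central
carbon with the smallest periodic lateral distance within a 1 nm
neighbourhood (configurable; the nearest overall is used if none is that
close). Depths up to 1 Å are *shallow*, beyond 1 Å *deep*. The stated
thresholds ("< 1 Å", "> 1 Å") leave exactly 1 Å unassigned; this package
assigns the boundary to *shallow* (with a 1e-9 nm numerical guard so an
exact boundary is not split by floating-point rounding). Cells no atom
covers at all are voids, counted separately and never as defects.

Contiguous defect cells merge by 4-connectivity, periodic in x-y, within
each class. Default vdW radii: C 0.17, N 0.155, O 0.152, P 0.18, S 0.18,
H 0.12, generic coarse-grained bead 0.26 nm. The exact prior scanning
procedure (probe radius, merging rule) is not restated in the sources this
reconstruction follows, so ray-cast-first-contact with 4-connectivity
merging is this package's documented interpretation; halving the grid
spacing changes measured areas by less than one perimeter-cell band, which
bounds the discretisation error.

# Tube analysis and relative rigidity

The bending energy stored in a membrane tube of length `L` and radius `R`
is `E_b = π K_b L/R`. Tubes pulled from different compositions by the same
force to the same elapsed time have stored the same curvature energy, so
their `L/R` ratios read out the **inverse** of their relative bending
moduli: `relative_Kb(c) = 100 × LR(ref)/LR(c)` %. The function demands that
force and time labels match across rows — comparing tubes at different
forces is meaningless — and is scale-free in `L/R`. Note one arithmetic
subtlety: applied to a printed table `L/R = 6, 12, 16, 20`, the formula
yields 50%, **37.5%** and 30% relative to the first entry; a published 35%
for the third composition traces to rounding of the underlying `L/R`
values before tabulation, and `relative_rigidity()` reports the formula
value without forcing agreement.

How `L` and `R` are measured on a bead model is itself a choice, since no
standard exists. `fit_tube()` takes: base level = median headgroup height
of the flat region (identified from the two dominant peaks of the
headgroup height histogram); tube beads = lipid beads above the base plus
twice its roughness; `L` = maximal tube-bead height above the base (a
configurable `base_offset` can subtract a bulge allowance);
`R` = midsurface radius, the average of the inner- and outer-leaflet mean
radial distances from the tube's own axis, excluding 1 nm at either tube
end where the cap and the junction distort the radius. A protrusion
shorter than 1.5 nm (one monolayer) is reported as *flat* rather than as a
degenerate tube. The alternative — least-squares cylinder fit to tail
beads — gives indistinguishable answers on synthetic cylinders but is less
robust when a base bulge is present.

**Scission calls.** Single-linkage connected components over all lipid
beads at a 1.2 nm cutoff (the standard coarse-grained neighbour distance),
periodic in x-y, classify severing outcomes. One component: *intact*. With
multiple components, the component holding the majority of the
pulled-patch lipids decides: if it contains at most `margin` (default 10)
non-patch lipids, the rupture happened at the point of force application —
*breakage*; if it also carries tube-body lipids, the tube separated at the
neck — *fission*, the productive, vesicle-releasing outcome. The component
search delegates to igraph after cell-binned neighbour enumeration; tests
verify it against a brute-force all-pairs search.

# Assay formulas

* **NBD quenching**: `(F_i − F_0)/(F_T − F_0) × 100`, with `F_0` the mean
  over the pre-dithionite window (default 0–30 s, configurable) and `F_T`
  either supplied or taken as the post-detergent mean. Dithionite cannot
  cross an intact membrane quickly, so the fast phase quenches only the
  externally oriented probe fraction — 50% for an even transbilayer
  distribution — and the slow phase reports quencher permeation. The
  percentage is invariant under gain/offset changes of the fluorimeter.
* **GUV permeability**: `I_in/I_ex × 100`; 100% = fully equilibrated probe.
* **GUV shrinkage**: implemented exactly as the printed formula
  `100 × A_0/A_i`, which *increases above 100%* as vesicles shrink. Because
  that reads oddly, the bounded alternative `100 × (1 − A_i/A_0)` is
  provided under `ratio = "consumed"`; whether the printed form was
  intended as written cannot be resolved from the text, so both are
  emitted and the printed one is the default.
* **Apparent radius**: `R = √(A/π)` for projected profiles on micrographs.
* **GTPase rate**: absorbances at 650 nm are calibrated to µM phosphate by
  a least-squares line through the standards **with intercept** (no
  constraint to the origin is stated, and the intercept absorbs the
  reagent background); the calibrated early time course is fitted linearly
  over `fit_window` (default 15–120 s — the sampling grid is 15, 45, 75,
  120, 180, 240, 360 s but the fitted window is not stated, so the early
  linear phase before substrate depletion is used) and the slope divided
  by the enzyme concentration, giving s⁻¹. Rates on good membrane
  templates fall in the 2–5 s⁻¹ range, which the defaults reproduce.

# The synthetic-data generator

The generator is a **fixture factory, not a simulator**: no forces are
computed, lipids are rigid idealised conformers except where scripted, and
every output is a pure function of (config, seed). Its defaults are the
study conditions of the data it emulates: 2 × 144 phospholipids in two
leaflets, an 18-carbon sn1 chain and a 22-carbon sn2 chain, frames every
10 ps, a 3.8 nm phosphate-to-phosphate thickness (typical of these
bilayers), 0.65 nm² of area per lipid, and roughly 30 waters per lipid.
The scaled-down preset used throughout the tests is 2 × 16 lipids with
1000 frames (10 ns), which keeps the full suite under two minutes while
exercising every code path.

Planted features are scripted, not emergent:

* **Permeation** — planted waters follow deterministic z paths realising
  exactly `n_cross` crossings and `n_rebound` rebounds (linear transits and
  mid-plane touch-and-return excursions in non-overlapping 30-frame
  windows); background waters jitter inside the bulk bands and never
  approach the slab. Exact event counts beat physical realism for testing:
  recovery can be asserted record-for-record.
* **Chain motion** — per chain label, one of: Gaussian-step random walk of
  the terminal carbon (velocity recovery; the half-normal step mean gives
  the expected velocity `σ√(2/π)/Δt`); a mid-chain fold toggled on a
  Bernoulli schedule whose geometry plants exactly one sub-threshold
  3-point angle per folded frame (the fold's neighbouring vertices sit at
  (180°+θ)/2 = 120° for θ = 60°, safely above threshold); or a square wave
  of the terminal carbon across its glycerol with per-chain random phase
  (protrusion events = rising edges, known exactly).
* **Tubes** — an open cylinder of inner/outer leaflet bead strings on a
  flat base, with the planted midsurface radius and height; *severed*
  removes a > 1.5 nm axial band at mid-height, *patch detached* displaces
  only the pulled patch beyond the linkage cutoff.
* **Assays** — two-phase quench traces (instantaneous outer-leaflet phase
  by default), per-vesicle intensity/area records, and linear phosphate
  accrual with Gaussian concentration noise on the standard 7-point grid.

What the generator does **not** emulate — thermal roughness of the
midplane, water diffusion, chain entanglement, realistic area fluctuations,
finite-temperature disorder in defect structure — bounds what passing
tests show: they certify the *bookkeeping and geometry* of the metrics
(event segmentation, classification, normalisation, thresholds,
connectivity), not the statistical mechanics of real membranes. On real
trajectories the same code paths run, but parameters with no effect on
fixtures (the protrusion hysteresis, the untrackability guard, the
nearest-glycerol neighbourhood) become load-bearing.

# Numerical choices and degenerate inputs

* Trajectory times must be strictly increasing and uniformly spaced to a
  relative 1e-6; a single frame is a valid degenerate trajectory with
  undefined `dt` (flagged).
* The two-means leaflet split is seeded at the range extremes, making it
  deterministic and order-independent; ties at the midplane fall back to
  glycerol z.
* Angles are computed from position vectors with the cosine clamped to
  [−1, 1] before `acos`, so collinear chains cannot produce NaN.
* The shallow/deep boundary carries a 1e-9 nm guard (boundary to shallow).
* The untrackability guard for wrapped paths triggers at a quarter box per
  step: minimum-image correction bounds apparent steps at half a box, so
  half-box can never be observed and a quarter box is the conservative
  observable criterion.
* `percent_visiting` uses distinct-molecule counting; event tallies are
  reported alongside.
* Random-number use is confined to `with_seed()`, which restores the
  caller's RNG state, so generators never perturb user code.

# Problem sizes

The shipped tests run the permeation recovery grid on 2 × 16-lipid,
1000-frame fixtures (16 combinations of planted counts), the tube recovery
grid over R ∈ {2, 3, 5} nm × L ∈ {10, 20, 40} nm, torsion oracles on
10-frame fixtures, and 100-seed GTPase recovery; the whole suite completes
in well under five minutes on a single core. These sizes are the package's
own choice of a thorough-but-quick regression net; all generators scale to
the full 2 × 144 default when more realistic occupancy is wanted.

# Known limitations

* Planar-bilayer metrics assume an approximately flat membrane in x-y;
  curved or undulating midplane surfaces (local-patch fitting) are out of
  scope, as are area-per-lipid and deuterium order parameters.
* Binary trajectory formats (XTC/TRR/DCD) are not parsed; convert to
  multi-GRO, multi-model PDB or frame-text first, or adapt an external
  reader behind `md_trajectory()`.
* Permeability is reported as normalised visit percentages, not as a
  physical permeability coefficient (cm/s); computing the latter requires
  an inhomogeneous solubility-diffusion treatment outside this package's
  scope.
* `fit_tube()` supports the +z pulling axis; rotate configurations first
  if pulled along another direction.
* Atom-naming conventions for custom lipids vary; templates are
  user-supplied and never inferred from residue names.
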