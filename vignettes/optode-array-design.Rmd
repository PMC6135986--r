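---
title: "Designing fNIRS optode arrays by combined sensitivity and coverage maximization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing fNIRS optode arrays by combined sensitivity and coverage maximization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Functional near-infrared spectroscopy (fNIRS) measures cortical
hemodynamics through pairs of scalp-mounted light sources and detectors.
A source and a detector close enough for a usable measurement form a
*channel*; the separation of the pair governs both how deeply the
channel probes (larger separations reach deeper) and its signal-to-noise
ratio (intensity falls roughly exponentially with separation). Given a
cortical region of interest (ROI) and a device with `nS` sources and
`nD` detectors, the array design problem is to choose scalp positions
for every optode so that the resulting channel set samples the ROI as
well as possible. The problem is combinatorial — the best array is not
the union of the best individual channels — and this package solves it
with a multistart randomized greedy metaheuristic (GRASP) over a
standardized scalp position inventory.

## Solution space: the extended 10-20 family

Optode positions are drawn from the 10-20 positioning family on
landmark-anchored scalp contours (nasion, inion, left/right
preauricular), following the extended-system convention of Oostenveld
and Praamstra. `build_contours()` realises the contours as
plane/surface intersection polylines — the midline sagittal arc, the
central coronal arc, an upper circumferential ring through Fpz/T7/Oz/T8,
a lower ring through the nasion, preauricular points and inion, fifteen
transverse contours at 5% sagittal levels, and short frontal/occipital
stubs — and all positions are placed by fractional arc length along
them. On convex head surfaces these planar slices follow the great-arc
paths that positioning practice assumes.

Which contour carries which labelled position, and which pairs of
10-5 positions receive an interleaved 10-2.5 position halfway between
them, is a fixed combinatorial blueprint of the package
(`interleave_pairs()`): contour-arc midpoints in both the transverse and
longitudinal directions, lateral connectors at the frontal and occipital
poles, and cell-diagonal midpoints in the paramedian and polar cells.
The segment adjacent to the nasion carries no interleaved position (no
optode can sit on the nasion notch). The blueprint reproduces the
canonical inventory sizes of the extended family — 345 positions at the
10-5 density and 1092 at 10-2.5 — on *every* valid head, because the
counts are properties of the blueprint, not of the mesh. Published
10-2.5 inventories derived from individual atlas heads involve
geometry-dependent deduplication of near-coincident points; a
mirror-symmetric, geometry-independent construction cannot reproduce
such a set point-for-point, so the blueprint fixes one defensible
convention and holds it everywhere. Inter-optode distances are 3-D
chord distances between scalp positions, the standard fNIRS separation
convention.

## Channel sensitivity: PMDFs

The sensitivity of a channel to an absorption change at a cortical
location is its photon measurement density function (PMDF). Following
the adjoint method, `compute_pmdf()` forms the product of the source
and detector fluence fields on the cortical surface, multiplies by the
per-node cortical volume, and normalises by the larger of the two
cross-probed volumetric fluence values (the source fluence at the
detector position or vice versa; `pmdf_norm`). Values below 1e-6 of the
channel maximum are set to exactly zero to keep the store sparse.

Fluence fields enter through a provider contract: any function mapping
a scalp origin to cortex-node values plus a volumetric probe plugs in.
The built-in provider is the analytic field
`phi(r) = exp(-mu_eff * r) / max(r, r0)`, a spherically symmetric
diffusion-like solution with effective attenuation `mu_eff` (default
0.1 per mm, a softened head-tissue value chosen so that sensitivity
extends over the full 15-60 mm separation range on the coarse synthetic
cortex) and a 1 mm singularity floor. Finite-element or Monte-Carlo
transport solvers can replace it without touching any PMDF code; the
per-node volume correction is deliberately isolated in `compute_pmdf()`
(one multiplication) so the quadrature convention can be revised in one
place.

Because relative brain sensitivity rises with separation while SNR
falls, raw PMDFs would push any maximizer toward the largest allowed
separations. `fit_snr_decay()` therefore measures how the channel
normalisation factor decays beyond the separation the user trusts
(`maxGoodRho`): it takes the ratio of each longer channel's `pmdf_norm`
to the mean `pmdf_norm` of channels *at* `maxGoodRho`, and fits a line
to the natural log of these ratios against separation. On an irregular
position grid no channel sits exactly at `maxGoodRho`, so a tolerance
band (default ±1 mm; widen it on sparse position sets) defines the
reference group. The fitted slope `a` (negative) parameterises the
weighting

```
W(SD) = 1                      SD <= maxGoodRho
        exp(a*(SD-maxGoodRho)) maxGoodRho < SD <= maxRho
        0                      SD >  maxRho
```

applied once per store (`apply_weights()`; double application is an
error). Both boundaries belong to the closed branch on their left:
`W(maxGoodRho) = 1` and `W(maxRho) = exp(a*(maxRho-maxGoodRho))`.

## The objective

For an array `A` with viable channels (separations in
`[minRho, maxRho]`), the package maximizes

```
SA + cW * CA
```

where `SA` is the total weighted sensitivity summed over ROI nodes,
normalised by `Smax` (the best total sensitivity achievable when
sensitivity is the sole objective), and `CA` is the fraction of ROI
nodes whose summed sensitivity strictly exceeds a coverage threshold
`Cthresh`. Strict inequality is deliberate: boundary-valued nodes occur
on synthetic data and must not count as covered. `cW = 0` reproduces
pure sensitivity maximization, which clusters channels over the
shallowest part of the ROI; increasing `cW` forces the array to spread.

The threshold is physical: a node is covered when an absorption change
`delta_mua` (default 0.001 per mm, about a 10% change) in a tissue
block of `actvol` (default 1 cm^3) would change the measured intensity
by at least `pthresh` percent (default 1%):

```
Cthresh = ln((100 + pthresh)/100) * vhat / (actvol * delta_mua)
```

with `vhat` the median per-node cortical volume. The typeset form of
this expression is ambiguous about the placement of `actvol` and
`vhat`; this arrangement is the only one with units of mm that matches
the stated physical reading, and it reproduces the conventional
reference value 0.1528 mm at `vhat = 15.36 mm^3`. Per-node volumes are
barycentric node areas (one third of incident triangle area) times a
nominal 3 mm cortical thickness — the standard surface analogue of a
per-node Voronoi volume; `vhat` is overridable wherever it is consumed.
On synthetic heads always compute `Cthresh` from the head's own `vhat`
(`coverage_threshold(vhat = node_volumes(cortex)$vhat)`): thresholds
tuned to a different mesh resolution make coverage trivially easy or
impossible.

Distance parameters (defaults: `minRho` 15, `minRhoOpt` 10,
`maxGoodRho` 30, `maxRho` 60, all mm) have distinct roles: `minRhoOpt`
is the physical packing limit between any two optodes, while `minRho`
is the shortest *usable* channel — two detectors may legally sit 12 mm
apart even when no 12 mm channel is viable.

## The GRASP solver

`solve_array()` runs two phases. Phase 1 maximizes raw ROI sensitivity
only, to obtain the normalisation `Smax`; phase 2 maximizes the
combined objective. Each restart of either phase builds a greedy
randomized solution — the initial source-detector pair and every
subsequent optode are drawn uniformly from the restricted candidate
list of the five best-scoring feasible options under the active
objective, with the feasible set re-pruned after every placement — and
then polishes it by local search: single-optode relocation (1-opt) in
both phases; a flip-float neighbourhood in phase 1 (for each candidate
relocation of one source, the whole detector set is rebuilt greedily,
and symmetrically — exact only without distance constraints, extended
heuristically with them); and a 2-opt neighbourhood in phase 2 (joint
reinsertion of a removed source-detector pair; exhaustive over small
candidate sets, otherwise over a top-`k` marginal-gain shortlist per
role, `k = 12` by default, always including the removed positions).
Candidate positions whose best viable channel contributes zero ROI
sensitivity are excluded throughout — solution-neutral because all
contributions are non-negative. All rankings break ties by ascending
position index, and one seeded generator drives each solve, so equal
seeds give identical solutions. The default is 20 restarts with an
optional wall-clock budget; when the budget binds, determinism is no
longer guaranteed across machines, which is why the default budget is
infinite.

`exhaustive_oracle()` enumerates every feasible layout under the
identical evaluation contract and is the exactness reference in the
test suite; it refuses instances beyond a configurable enumeration cap.
`manual_grid_array()` reproduces the traditional hand-designed
baseline: an alternating grid (or a star with central sources when
`nD >= 4 nS`) with first-neighbour spacing as close as possible to
30 mm, laid out in the tangent plane at the scalp projection of the ROI
centre of mass and snapped to solution-space positions. The tangent
frame is oriented by the global vertical, a fixed convention standing
in for the unspecified rotation a human designer would choose.

## The synthetic head generator

`synth_head()` builds closed ellipsoidal scalp and cortex meshes
(subdivided icosahedra; default scalp semi-axes 75/95/70 mm,
approximating an adult head) with four fiducials at the axis extremes
of the scalp mid-plane. The cortex radius is modulated by a smooth,
seed-deterministic harmonic field of amplitude 3 mm, so ROIs defined by
volumetric shapes contain both shallow ("gyral") and deep ("sulcal")
nodes — the feature that makes coverage a genuine constraint. What the
generator does *not* emulate: realistic cortical folding with
centimetre-deep sulci, tissue-specific optics (skull, CSF), hemispheric
asymmetry, and realistic scalp-cortex distance variation. Tests passing
on these heads therefore validate the algorithmic contracts
(feasibility, monotonicity, optimality against enumeration,
reproducibility) and the geometry-independent inventory counts, not
absolute sensitivity magnitudes on real anatomy.

## Benchmark harness and problem sizes

`bench_setup()`/`make_grid()`/`run_bench()` reproduce the design of a
simulation study at desk scale: three ROI shape classes (a focal
sphere, an extended ellipsoid, a noncontiguous two-sphere region),
optode counts {1, 2, 4} with `nD >= nS` (six combinations), and
coverage weights {0, 1, 10} — 54 cells, each solved by GRASP and the
manual baseline with the default 20 restarts, about three to four
minutes on one core. The full grid (five ROIs, counts up to 16, six cW
values, 450 cells) remains available by configuration. The bench uses
the 10-5 solution space: the dominance of optimized arrays over manual
single-distance arrays is a property of a solution space dense relative
to the optode spacing, and a coarser space can genuinely force the
optimizer below the manual array's sensitivity when full coverage is
demanded. The sensitivity-only phase is shared across coverage weights
of the same cell family, since `Smax` does not depend on `cW`. The test
suite's oracle comparisons use instances of at most 20 candidate
positions and at most two sources and two detectors, where exhaustive
enumeration is exact and fast. Elapsed times are recorded but never
asserted.

## Numerical conventions

* Sparsification threshold 1e-6 of the channel maximum; entries equal
  to the threshold are retained.
* Coverage uses strict `>` against `Cthresh`.
* Local search accepts a move only if it improves the objective by more
  than 1e-12, so searches terminate despite floating-point noise.
* `SA` can marginally exceed 1 when `Smax` comes from the heuristic
  phase rather than the oracle; it is reported, never clamped.
* Landmarks must lie on the scalp surface within 0.5 mm (or 5% of the
  head radius on coarse meshes); mesh units are mm by contract and are
  never inferred.
* Degenerate inputs fail loudly: empty ROIs, zero-area faces, stores
  weighted twice, layouts violating `minRhoOpt`, unreachable ROIs
  (`Smax = 0`), and oracle instances beyond the enumeration cap are all
  errors, not warnings.

## Known limitations

Surface PMDFs only — depth information is collapsed onto the cortical
surface, so the package designs fNIRS arrays, not tomographic (DOT)
arrays. Short-separation regressor channels are not placed; add them to
the returned layout per device requirements. GRASP carries no
optimality certificate; the oracle provides one only at toy scale. The
manual baseline encodes one fixed convention for grid orientation. The
analytic fluence provider ignores tissue heterogeneity; it is a
contract stand-in, not a transport model.
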