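---
title: "Measuring interobserver variation in radiotherapy delineations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring interobserver variation in radiotherapy delineations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contourIOV)
```

## The problem

Radiotherapy planning starts from hand-drawn outlines: each planning
target volume (PTV) and organ at risk (OAR) is delineated slice by slice
on the planning CT. Different radiation oncologists contouring the same
patient produce systematically different structures — different margins,
different anatomical interpretations, different craniocaudal extents —
and this interobserver variation (IOV) propagates directly into dose.
`contourIOV` quantifies that variation for a cohort of observers who all
contoured the same case on the same CT grid.

The package deliberately separates three concerns: a geometric data model
(contours, grids, binary masks), the agreement statistics themselves, and
a synthetic cohort generator that stands in for real multi-observer
structure sets, which are rarely shareable.

## Data model and rasterization

All analysis happens on one regular voxel lattice (`ImageGrid`): origin at
the center of voxel (0,0,0), per-axis spacing in mm (the default
1 × 1 × 4 mm matches a typical head-and-neck planning CT with 4 mm
slices), x to the patient's left, y posterior, z cranial. Observers'
structures arrive as stacks of closed planar polygons
(`PlanarContour`) or as pre-rasterized masks on the declared grid;
resampling between heterogeneous grids is intentionally unsupported and
raises an error, because silent resampling would change voxel counts and
therefore every statistic downstream.

Rasterization follows two conventions that planning systems commonly use
and that admit an exact brute-force oracle:

* a voxel belongs to a structure iff its **center** lies inside the union
  of the slice's outer polygons minus its holes, decided by the even–odd
  (crossing-number) rule;
* a contoured slice occupies the **full slice thickness** dz (the slab
  model). Volume is then simply (set voxels) × dx·dy·dz. We adopt the
  slab model over inter-slice interpolation because it is the only
  volume definition that is exactly reproducible from the contours alone;
  on 4 mm slices the two differ mainly at the caudal/cranial caps.

Contour z positions must match a slice center within dz/2; an exact tie
between two slices resolves to the lower slice index. Points exactly on a
polygon edge follow the half-open convention of the crossing test — an
axis-aligned 10 mm square on a 1 mm grid rasterizes to exactly 100 voxels
per slice rather than 81 or 121.

## Agreement statistics

For each structure, statistics run over exactly the observers who
delineated it (the per-structure N); omissions are recorded, never
imputed as empty volumes, because an empty volume would be a statement
about the anatomy rather than about participation.

* **Volume statistics**: mean, sample SD (n − 1 denominator — the paper
  trail of most clinical reports; printed CoV values cannot discriminate
  the denominator, so this is a documented convention), CoV = SD/mean,
  and range. SD is defined 0 for n = 1, and report tables render CoV and
  conformity blank (not 0) for single-observer structures.
* **DSC / Jaccard** on voxel counts, with the identity DSC = 2J/(1 + J)
  checked property-style in the tests.
* **CIpairs**: the sum over unordered observer pairs of pairwise
  intersection volumes divided by the sum of pairwise union volumes. It
  is permutation-invariant, equals Jaccard at n = 2, and is 1 iff all
  masks are identical — all three are tested invariants.
* **MASD**: surface voxels are set voxels with a face-adjacent unset (or
  out-of-grid) neighbour; the metric is the symmetric mean over both
  surfaces of each surface-voxel center's distance to the nearest
  surface-voxel center of the other mask, in physical mm. Distances come
  from an exact separable Euclidean distance transform (the
  parabola-envelope algorithm, implemented in C++ with per-axis spacing,
  so the 1 × 1 × 4 mm anisotropy is handled exactly); an exhaustive
  all-pairs oracle verifies it in the tests. Voxel-center surfaces, not
  sub-voxel meshes, are used: the discretization is a documented
  convention chosen for exact reproducibility.

## Nodal-level inclusion

A lymph node level — supplied as a mask; the package never constructs
level anatomy from CT — counts as included in an observer's PTV iff
|level ∩ PTV| / |level| is **strictly greater** than the threshold
(default 0.70, "more than 70 %"), evaluated on voxel counts to avoid
double rounding through cm³. A fraction of exactly 0.70 is therefore not
included. Per level the package reports each observer's fraction, the
count of including observers, and covered-by-all / covered-by-none flags.
When one observer split the PTV into two same-named structures they are
merged by union (with a logged warning) before analysis, so bilateral
target volumes are evaluated as one PTV.

## Landmark-referenced borders and width

Cranial and caudal borders are the z centers of the extreme occupied
slices — with the slab model on a 4 mm CT all border positions, and hence
all offsets, are multiples of 4 mm, matching how observers pick whole CT
slices. Offsets are signed in the clinical phrasing: "4 mm **below** the
sphenoid-sinus floor" is `landmark_z − border_z = +4`; "12 mm **above**
the sternoclavicular joint" is `border_z − landmark_z = +12`. Axial width
at a reference slice is the occupied extent along x (left–right;
configurable to y, since published "width" rarely states the axis) plus
one voxel size — the outer-edge convention, so a single voxel is dx wide,
not zero. Landmarks are user-declared z positions; automatic detection on
CT is out of scope.

## The synthetic cohort generator

Real multi-observer structure sets are seldom deposited, so the generator
is a first-class, tested module, not a fixture. Observer error is
decomposed into the three effects contouring studies repeatedly identify:

1. **Systematic margin**: observer i dilates every structure by
   δ_i ~ Normal(marginMean, marginSD) mm (clamped at minus half the
   smallest shape radius so structures cannot invert);
2. **Smooth boundary noise**: a per-(observer, structure) radial field of
   three low-order angular harmonics with random amplitudes and slowly
   z-drifting phases, pointwise sd ≈ boundaryNoiseSD — smooth by
   construction, like a hand wavering around an ambiguous boundary, not
   voxel noise;
3. **Caudal truncation**: designated structures (the elective PTV) are
   cut below a per-observer plane, offsets in multiples of dz —
   emulating observers choosing different caudal CT slices.

Structures can additionally be omitted with a per-structure probability,
reproducing the familiar "only 7 of 10 contoured the pituitary" pattern.
Generation is deterministic given the seed (bit-identical JSON output),
and the ground truth (realized margins, truncations, omissions, analytic
volumes) is returned alongside the cohort, which is what makes parameter
recovery testable: on a 1 mm grid the configured mean margin is recovered
from voxelized volumes within 0.5 mm, and dz-aligned truncation offsets
are recovered exactly in the craniocaudal extents.

`defaultCohortSpec()` fixes the packaged study-scale conditions: 10
observers, a 512 × 512 × 80 grid at 1 × 1 × 4 mm, 18 structures whose
true volumes span the published head-and-neck range (a ~850 cm³ PTV1
tube down to ~0.27 cm³ eye lenses), margin 2 ± 1 mm (clinical margins of
up to ~6 mm are reported for small OARs), boundary noise 1.5 mm, caudal
truncation offsets spanning 20 mm (the reported scale of caudal border
disagreement) with the caudal landmark placed so the cohort mean border
sits 12 mm above it, the cranial landmark 4 mm above the PTV top, and six
box-shaped nodal-level stand-ins around the PTV tube, the caudal pair
dipping below its caudal border so truncation degrades their coverage.
Box levels are adequate to exercise the 70 % rule; the generator makes no
attempt at real anatomy, HU texture or registration effects, so passing
tests demonstrate metric correctness, not segmentation realism.

## Numerical choices

* Even–odd voxel-center rasterization with half-open edge handling;
  fixtures avoid voxel centers exactly on polygon edges.
* Slab-model volumes; slice matching tolerance dz/2, ties to the lower
  slice.
* Contour polygons in the generator use 72 vertices per ring (a 72-gon
  underestimates a circle's area by ~0.13 %, far inside the 2 %
  volume-convergence tolerance verified against analytic spheres and
  ellipsoids on a 1 mm grid).
* Report rounding: volumes to 3 significant figures, CoV and fractions to
  2 decimals, half away from zero (base R's round-half-even would turn
  0.125 into 0.12); undefined cells are blank, not 0.
* Table rows sort by descending CoV, ties alphabetically; identical
  inputs give byte-identical CSVs.
* Degenerate inputs fail loudly: polygons with < 3 vertices or zero area,
  empty masks in Dice/MASD/overlap fractions, thresholds outside (0, 1),
  mismatched grids, contours outside the grid extent.

## Problem sizes

The test suite validates the metrics on small grids (≲ 60³ voxels) where
exhaustive oracles — brute-force point-in-polygon scans, all-pairs
surface distances — are feasible, and runs the full study-scale pipeline
(10 observers × 18 structures on 512 × 512 × 80, with the complete MASD
matrix per structure) once end to end; that run takes on the order of
half a minute on one CPU. Margin recovery uses 20 seeds of two-observer
sphere cohorts on a 1 mm grid.

## Limitations

* DICOM-RT STRUCT files are not read directly; export to the JSON contour
  dialect first. NIfTI masks are supported.
* No resampling between grids, no consensus-volume (STAPLE-style)
  estimation, no dose objects, no statistical testing across observer
  subgroups.
* MASD is defined on voxel-center surfaces; values on coarse grids are
  resolution-dependent (as they are in any discretized implementation).
* The synthetic generator emulates error structure, not anatomy: results
  on it validate the metrics, not the clinical difficulty of any real
  delineation task.
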