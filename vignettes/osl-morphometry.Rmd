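---
title: "Quantifying osseous spiral lamina morphology from microCT volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying osseous spiral lamina morphology from microCT volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

The osseous spiral lamina (OSL) is the thin bony shelf that spirals from
the base to the apex of the cochlea, projecting from the modiolus and
separating the scala vestibuli from the scala tympani. It consists of
two plates of compact bone — the vestibular plate (VP) above and the
tympanic plate (TP) below — joined by sparse bony pillars across an
inter-plate gap and perforated by the habenular openings along its
lateral rim. Three quantities summarise its mechanics-relevant
morphology:

* **porosity** of each plate, defined through a *filled envelope*:
  if $V_o$ is the volume of the porous plate and $V_f$ the volume of its
  pore-free (filled) counterpart, then
  $p = \dfrac{V_f - V_o}{V_f}\cdot 100\,\%$;
* **radial width**, the extent from the modiolar (inner) wall to the
  lateral edge at a given spiral angle;
* **thickness**, the transverse height of the plate assembly — outer VP
  surface to outer TP surface — at the lateral, middle, and medial
  radial points.

`oslmorph` implements this analysis as a reproducible pipeline over 3D
image stacks: global thresholding, artifact removal, geometric
separation of the plates, angle-based partitioning into basal, middle,
and apical turns, mesh-volume porosity per plate and region, spiral
width/thickness profiles, and a radial pore-distribution map. Because
no public microCT dataset of the OSL is available, the package ships a
synthetic phantom generator whose voxel-level ground truth is exact by
construction; every stage of the pipeline is validated against it.

## The phantom

The phantom sweeps a two-plate ribbon along a conical spiral: the
modiolar radius and the radial width both vary linearly with the spiral
angle $\theta$, and the mid-surface drifts axially at a constant pitch.
Defaults model the adult anatomy: a sweep of 990° (two and three
quarter turns), width tapering from 1800 µm at the base to 200 µm at
the apex, and a 100 µm plate assembly (two 25 µm plates around a 50 µm
gap). The remaining geometric parameters are not reported anywhere and
were fixed once at anatomically plausible values: modiolar wall radius
300 → 150 µm, pitch 600 µm per turn, pore radii 12–24 µm, one pillar
per 50° of sweep (radius 20 µm), habenular openings of 50 µm diameter
every 20°, bone/soft-tissue gray levels 200/50 (16-bit DNs) with
Gaussian noise of SD 10 and a handful of bright speck artifacts.

Three modelling choices deserve explanation:

* **Pores sit on a jittered hexagonal lattice**, carved in random order
  with live voxel counting until the plate's pore fraction is within a
  percentage point of target (a short rejection-sampling top-up runs if
  the lattice is exhausted). Poisson-placed discs percolate at the
  pore fractions observed in this bone (50–70%): their unions form
  lakes wider than any structuring element, which no shape-following
  envelope could close. The real plates are lace-like — bounded
  windows separated by bone strands — and the lattice reproduces
  exactly that. By default centres stay half a pore radius inside the
  plate edges; the rim itself is perforated only by the habenular
  openings, which are modelled as cylinders tangent to the lateral
  edge from inside (the "claw"-like rim openings seen in the anatomy).
  Setting `pore_edge_bleed = TRUE` lets uniform-bias centres overhang
  the edges instead, which makes the pore-volume density strictly
  uniform out to the rim — the right condition for studying radial
  pore distributions — at the cost of rim scallops that no
  shape-following envelope can restore, so porosity-recovery
  experiments keep it off.
* **Openings count as pore space.** The constructed pore-free envelope
  is the full ribbon, so pores and habenular openings both contribute
  to ground-truth porosity, which is what the filled-envelope statistic
  measures on real data.
* **The ground truth is exhaustive**: per-voxel material labels
  (VP/TP/pillar), the pore-free envelope, region and turn labels, the
  construction frame (with pitch and base offset), per plate × region
  voxel-count porosity, and the width/thickness profiles. The
  brute-force oracle `oracle_porosity()` is plain voxel arithmetic,
  `100 (N_{env} - N_{mat}) / N_{env}`, fully independent of the mesh
  pipeline it judges.

What the phantom does *not* emulate: partial-volume blur, beam
hardening, ring artifacts, soft tissue (basilar membrane, nerve
fibres), or anatomic irregularity of real bone. Passing recovery tests
therefore demonstrates the correctness of the measurement chain, not
the segmentability of arbitrary clinical scans.

## Segmentation and the spiral frame

Bone is separated from soft tissue by a global threshold — Otsu's
two-class criterion by default, a numeric override for expert use —
followed by removal of 26-connected components smaller than a
configurable voxel count (speck artifacts). Plates are separated
geometrically: per 1° angular bin, the gap mid-surface is the midpoint
of the local axial extent, and voxels above it are vestibular. Regions
are cut at fixed spiral angles (defaults 360° and 630°), replacing the
manual turn separation of interactive workflows.

All angle-indexed measurements live in a *spiral frame*: the
helicotrema centre point, the central axis, a zero-angle ray anchored
at the basal start, and a handedness. The angular coordinate is
unwrapped across turns using the pitch (axial drift per turn), which
`estimate_pitch()` recovers from the mask by clustering axial positions
within azimuth bins. `fit_spiral_frame()` estimates the frame from the
mask alone: the axis starts from the smallest principal direction of
the second-moment tensor and is refined by averaging local sheet
normals sampled evenly in azimuth — the raw moment axis leans by
several degrees when the tapering width makes the mass azimuthally
asymmetric, while sheet normals are immune to that. The in-plane
centre comes from an Archimedean-spiral fit to the modiolar edge of the
apical turn. Degenerate inputs (planar slabs, sub-turn sweeps,
near-isotropic moments) raise errors demanding landmarks rather than
guessing; supplying landmarks mirrors the manual frame definition used
in practice, and the validation suite does exactly that.

## Meshing and volumes

Surfaces are extracted as the exact boundary-face surface of the
binary mask (the 0.5 iso-surface under nearest-neighbour
interpolation): every face between material and background becomes two
consistently oriented triangles, vertices are deduplicated per
face-connected voxel cluster around each lattice corner, and
configurations in which material voxels touch only along a lattice
edge are first resolved by carving one voxel per 2×2 checkerboard
(monotone, hence always terminating). The result is guaranteed
watertight and edge-manifold, and its divergence-theorem volume equals
the voxel count times the voxel volume — which keeps the mesh route
and the voxel-count cross-check structurally comparable at every
scale. A marching-cubes-style interpolating surface would be smoother
but offers no accuracy advantage for volume ratios of binary masks.

`mesh_volume()` evaluates the signed-tetrahedra sum about the mesh
centroid (translation invariant to first order in floating point) and
refuses open or non-manifold input, reporting boundary and
non-manifold edge counts. `simplify_mesh()` provides quadric-error
edge-collapse decimation with a link-condition and orientation guard,
and backs off if the decimated volume departs from the input by more
than 1%; decimation is off by default and exists for export and
compute-cost control, exactly as in mesh-software workflows.

## The filled envelope

Two envelope constructions are provided:

* `method = "ball"` — morphological closing with a Euclidean ball (or
  an oblate ellipsoid via `axial_radius_um`), computed exactly through
  the weighted squared distance transform. This is the textbook
  reading of "shrink-wrapping" a porous solid, and it retains the
  textbook limitation: the ball dips into each pore mouth by
  $r-\sqrt{r^2-a^2}$, so on plates whose thickness is comparable to
  the pore size the filled volume is biased low.
* `method = "plate"` — a height-field shrink-wrap built for thin
  plates: the in-plane support map is closed with a flat disc (filling
  pore columns while following the plate outline), and the top and
  bottom surface height maps are extended over the filled columns by
  breadth-first neighbour-mean infill. For a tilted, tapering,
  stair-quantized sheet this reconstructs the envelope essentially
  flush; it requires each image column to cross the sheet once, so
  pieces sweeping ≥ 180° are split into angular sub-sectors about the
  spiral frame and their envelopes unioned.

The pipeline defaults to the plate wrap with an in-plane radius of
three times the largest expected pore radius (the radius must exceed
the largest pore cluster but stay below the modiolar radius; for real
data it is a required user choice, since no universal default is
defensible). Both methods are extensive, idempotent at fixed radius,
and monotone in the radius, and both are exercised against constructed
slabs in the test suite. `porosity()` evaluates the defining formula
exactly, clamping sub-0.5% violations of $V_o \le V_f$ (mesh noise) to
zero with a warning and treating anything larger as a pipeline fault.

## Width, thickness, and the pore map

Width at angle $\theta$ intersects the mask with the angular slab
$|\theta_v-\theta|\le\Delta\theta/2$ (default 2°, never narrower than
one voxel of tangential extent near the modiolus, and always on the
correct turn). The cross-section of a porous plate fragments, so
components whose radial intervals lie within `bridge_gap_um` (default
8 voxels) of each other are chained into one lamina; stray specks and
distant structures fall outside the chain. Width is the radial extent
of the chain; thickness is the axial extent of a narrow radial column
(±2 voxels, widened once to ±4 on an empty hit, then flagged
undefined) at radial fractions 0.9/0.5/0.1 of the local span for the
lateral/middle/medial points. `spiral_profile()` samples every
`step_deg` (default 45°, the four-dissection-plane scheme) and reports
mean and SD per region; undefined samples are flagged and counted,
never imputed. With a single synthetic specimen the SD axis is the
angular sample spread within a region, not the specimen-wise spread of
a cohort.

The pore map divides each plate's pore space (envelope minus material,
26-connected components as individual pores) into radial bands —
medial/middle/lateral thirds of the *local* radial span, estimated per
fine angular bin so the taper does not smear the bands — and reports
voxel-based pore fractions per band and angular sector. It is
deliberately voxel-based: the map is a spatial distribution, while the
mesh-based statistic remains the headline porosity.

## Validation conditions and problem sizes

The acceptance suite (in `tests/testthat/test-acceptance.R`, recomputed
by `scripts/acceptance.R`) runs at sizes chosen for a single CPU:

* porosity recovery: 990° phantoms at 7 µm voxels (~9M voxels,
  roughly 243×243×153) with pore fractions 0.50/0.60/0.69 on both
  plates, pore radii 36–44 µm, full pipeline from the noisy grayscale
  volume; recovered porosity must stay within 2 percentage points of
  the voxel-count oracle in every plate × region cell, with ordering
  across the three phantoms preserved;
* geometry recovery: the reported real-scale geometry (width
  1800 → 200 µm across 720°, 100 µm assembly) at 12 µm voxels
  (~363×363×105), pore-free — isolating shape recovery the way a
  human expert would place calipers on bone rather than into a pore;
* label recovery: plate split and region partition agreement ≥ 99%
  against construction labels, measured over the voxels the
  segmentation retained (segmentation recall is reported separately,
  so the two error sources are not conflated);
* pore-distribution properties: a middle-heavy phantom must show its
  largest basal pore fraction in the middle band, and uniform phantoms
  must keep band fractions within 5 points of each other across ten
  seeds.

The porosity phantoms scale the radial dimensions down (width
560 → 280 µm) to keep the volume within a single-CPU budget while
preserving every structural feature at the anatomical plate-assembly scale;
the porosity statistic is a ratio and does not depend on the absolute
plate size.

## Numerical choices and degenerate inputs

* Connectivity is 26-neighbour everywhere components are formed.
* Coordinates: voxel centres at `(i-1) * voxel_size_um` relative to
  the origin; all physical lengths in µm; masks written as 0/255 8-bit
  multi-page TIFF, volumes as 16-bit TIFF, meshes as binary STL,
  tables as CSV with JSON sidecars.
* Thresholding a constant volume, fitting a frame to a planar mask,
  unwrapping a sub-turn sweep without a pitch, computing volumes of
  open meshes, and envelopes that would bridge onto an exclusion mask
  are all errors with actionable messages, never silent guesses.
* Determinism: a single integer seed drives every stochastic draw in
  the generator; pipeline reports carry no timestamps, so identical
  configurations produce byte-identical JSON.

## Known limitations

* The boundary-face surface over-estimates *areas* (staircase effect)
  even though volumes are exact; curvature- or surface-area-based
  metrics should not be derived from it.
* The plate envelope assumes a locally single-sheet geometry; it is
  not applicable to bulk trabecular solids (use the ball closing
  there).
* `fit_spiral_frame()` needs more than a full turn of sweep and a
  recognisable sheet; pathological segmentations should use landmark
  input, which is also how real specimens are typically anchored.
* Porosity recovery degrades gracefully but measurably when pore
  clusters approach the closing radius or the modiolar radius;
  the envelope radius must be chosen from the observed pore sizes.
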