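# oslmorph

Quantitative 3D morphometry of the human **osseous spiral lamina
(OSL)** from microCT-style image volumes.

The OSL is the thin bony shelf spiraling from the base to the apex of
the cochlea. It consists of two plates of compact bone — the
vestibular plate (VP) and the tympanic plate (TP) — joined by sparse
bony pillars and perforated like lace. Its porosity, radial width, and
thickness shape the mechanics of hearing, and quantifying them from
microCT volumes requires a chain of image-analysis steps that this
package makes explicit and reproducible:

1. **Segmentation** — global (Otsu or manual) thresholding of the
   bone/soft-tissue contrast, removal of small-component artifacts.
2. **Plate separation** — each voxel assigned to VP or TP by its side
   of the inter-plate gap mid-surface; **region partition** into
   basal / middle / apical turns by spiral angle (defaults 360°/630°).
3. **Porosity** — per plate and region, through the filled-envelope
   statistic: mesh the porous plate (volume `V_o`), construct its
   pore-free envelope (volume `V_f`), and evaluate

   `p = (V_f − V_o) / V_f · 100 %`.

   Surfaces are exact watertight voxel-boundary meshes with
   divergence-theorem volumes; the envelope is a morphological
   closing (Euclidean ball / oblate ellipsoid via distance
   transforms) or a height-field shrink-wrap designed for thin plates.
4. **Width/thickness profiling** in a helicotrema-centred spiral
   coordinate frame: radial width and the assembly thickness (outer VP
   face to outer TP face) at the lateral / middle / medial radial
   points, sampled every 45° by default, with mean ± SD per region.
5. **Pore distribution** — pore fraction per radial band
   (medial / middle / lateral) and angular sector.

Because no microCT dataset of the OSL is publicly deposited, the
package includes a **synthetic phantom generator**: a conical-spiral,
two-plate lamina with through-plate pores, bony pillars, habenular
openings, imaging noise, and speck artifacts — with exact voxel-level
ground truth (material/plate/region labels, pore-free envelopes, the
construction frame, and voxel-count porosity). Every pipeline stage is
validated against it.

## Worked example

Generate a small phantom, run the full pipeline, and compare with the
built-in ground truth:

```r
library(oslmorph)

cfg <- run_config(
  phantom = phantom_config(
    voxel_size_um = 8, turns_deg = 720,
    width_base_um = 400, width_apex_um = 200,
    r_inner_base_um = 180, r_inner_apex_um = 140,
    pitch_um_per_turn = 360,
    pore_fraction_vp = 0.35, pore_fraction_tp = 0.45,
    pore_radius_um_range = c(20, 28), speck_count = 5, seed = 5),
  min_component_voxels = 40, seed = 5)

report <- run_pipeline(cfg)
report
```

```
<osl_report> oslmorph 0.1.0, seed 5
Porosity (mesh-based, percent):
 plate region p_percent p_voxel_percent
    vp  basal      34.4            34.2
    vp middle      33.7            33.6
    vp   apex      30.3            29.9
    tp  basal      44.9            44.6
    tp middle      41.7            41.6
    tp   apex      42.1            41.9
Profile summary:
 region n_samples n_defined n_undefined width_um_mean width_um_sd
   apex         3         3           0         195.9       18.18
  basal         8         8           0         342.8       45.35
 middle         6         6           0         263.8       30.28
 ...
Ground-truth comparison (porosity, percentage points):
 plate region porosity_percent pipeline_percent error_pp
    vp  basal             34.5             34.4  -0.0732
    vp middle             36.3             33.7  -2.5445
    vp   apex             32.5             30.3  -2.2772
    tp  basal             45.5             44.9  -0.6665
    tp middle             43.3             41.7  -1.5859
    tp   apex             46.8             42.1  -4.7055
Plate label agreement: 100.00%; region label agreement: 100.00%
```

Reading the output: the VP was built with a 35% target pore fraction
and the TP with 45%; the mesh-based filled-envelope porosity recovers
the realized ground truth to within a fraction of a point in the basal
turn, with larger deviations toward the apex of this miniature phantom
(its apex region is a tiny 90° wedge where edge effects dominate), and
the geometric plate/region assignment reproduces the construction
labels exactly. The width summary tracks the configured 400 → 200 µm
taper. At study scale (the acceptance phantoms below) porosity
recovery is within 2 points in every plate × region cell.

Real volumes enter the same way via `run_config(input = "scan.tif",
voxel_size_um = ..., threshold = ..., closing_radius_um = ...)`, and a
thin command-line wrapper is installed at
`system.file("cli", "oslmorph.R", package = "oslmorph")` with
subcommands `phantom`, `segment`, `porosity`, `profile`, `poremap`,
and `run`.

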