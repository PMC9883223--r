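---
title: "Terraced marching cubes and computer-calculated soft-tissue landmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Terraced marching cubes and computer-calculated soft-tissue landmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccmark)
```

## The problem

Digitizing facial soft-tissue landmarks on volume-rendered CBCT is
subjective: the rendered skin surface shifts with brightness and
contrast settings, and repeated clicks by the same or different
examiners scatter by millimetres, especially on the cheeks, where there
is no sharp anatomical feature. `ccmark` implements an alternative
surface-based workflow in which the reconstruction itself supplies the
feature to click on, and a deterministic rule turns any nearby click
into one reproducible point.

The pipeline is:

1. **Binarization** (`binarize_soft_tissue`): a single global Otsu
   threshold over the whole-volume histogram separates tissue from air;
   the largest 26-connected component is kept.
2. **Surface reconstruction** (`extract_isosurface`): binary marching
   cubes at isovalue 0.5.  With binary data, linear edge interpolation
   degenerates to edge midpoints, so the mesh is *terraced*: flat
   "mountain tabletop" plateaus appear at each locally most protruded
   region.  At 0.3 mm voxels these terraces are exactly the contour
   features a clinician can see and click.
3. **CC points** (`find_tabletop`, `compute_cc_point`): from a seeded
   click, collect mesh vertices within 50 pixels, keep those within one
   pixel of the click along the landmark's fixed anatomical normal,
   restrict to the edge-connected patch containing the click, and
   average.  The centroid is the computer-calculated (CC) point.
4. **Consistency** (`consistency_check`) and **reliability statistics**
   (`cronbach_alpha`, `rater_differences`, `paired_t_test`,
   `required_sample_size_paired_t`).

## The landmark model

Six convex landmarks are supported, each with a fixed unit normal
describing its protrusion axis (axis convention: +x subject-left, +y
subject-backward, +z up):

```{r}
t(vapply(landmark_catalog(), function(l) l$normal_raw, numeric(3)))
```

The anterior landmarks (pronasale, both lips) face −y; the columella
faces 45° down-forward and the cheeks 45° laterally-forward.  These
raw vectors are presentation notation; only their direction is used
(`normal_unit`).  The normals are *fixed per landmark*, not taken from
the mesh: the band filter must slice the surface the same way for every
patient, which is what makes the CC point reproducible.  Per-vertex
mesh normals are used only to reject a seed on a back-facing surface.

## Why the tabletop makes the CC point a fixed point

On an axis-aligned plateau every vertex shares the same coordinate
along the landmark normal, so the one-pixel band selects the same
member set no matter where on the plateau the seed lands; the centroid
— and hence the CC point — is therefore *identical* for every seed on
the plateau, and re-seeding from the CC point moved by up to 4 px in
the tangent plane returns it exactly.

A less obvious fact drives the 45° landmarks: the marching-cubes
contour of a voxelized 45° half-space is a zigzag staircase whose
vertices all lie **exactly on one plane** perpendicular to the 45°
direction (each zig changes one coordinate by +0.5 and the other by
−0.5).  A 45°-oriented facet therefore behaves as a perfect tabletop
for the columella and cheek normals, with the same fixed-point property
as the flat plateau.  Away from such a facet the band filter on a
generically curved staircase selects a set that depends on the seed's
quantized level, and sub-pixel inconsistencies appear — which is why
landmarks are defined on protrusion apices in the first place.

## Tunable parameters

| parameter   | default             | units  | meaning                                   |
|-------------|---------------------|--------|-------------------------------------------|
| `radius_px` | 50                  | voxels | seed neighbourhood (15 mm at 0.3 mm)      |
| `band_px`   | 1                   | voxels | half-thickness of the normal-band slab    |
| `offsets_px`| 0.5–4.0 step 0.5    | voxels | consistency-examination displacements     |
| `center`    | (266.5, 266.5, 266) | voxels | reference origin of the mm conversion     |
| `scale`     | 0.3                 | mm/vox | voxel pitch of the emulated acquisition   |
| `bins`      | 256                 | —      | Otsu histogram bins over the value range  |

"Pixel" always means voxel unit; the 0.3 mm isotropic acquisition makes
the two interchangeable.  The band test is `|(v − s)·n̂| ≤ 1`, a slab of
thickness 2 px centred on the seed: the natural symmetric reading, and
the one under which a plateau is a fixed point regardless of seeding
side.  `convert_voxel_to_mm` is an exact affine bijection; distances
`d` are plain Euclidean norms of the converted coordinates.

## The case dictionaries

The 2D dictionary has 16 entries and the 3D dictionary 256, which fall
into 15 equivalence classes under the 24 cube rotations plus
inside/outside complementation (23 under rotations alone);
`count_cube_equivalence_classes` verifies this by brute-force
canonicalization and `burnside_cube_classes` independently by
orbit-counting arithmetic.

The 3D triangle table is *generated*, not hand-typed: each cell face
contributes its marching-squares segments, the directed segments are
chained into closed loops on the cell boundary, and each loop is
fan-triangulated from its lowest-numbered edge.  Two numerical choices
matter:

* **Saddle rule.** An ambiguous face (two diagonal corners inside) is
  resolved *geometrically*: the separated diagonal is always the one
  through the face's minimum-coordinate corner, whichever class it
  belongs to.  Both cells sharing a face therefore agree, every closed
  component meshes watertight by construction, and complementing the
  mask returns the same vertices with flipped normals.  The price is
  that the 14 configurations with two saddle faces triangulate with 6
  triangles (hexagonal tunnel loops) instead of the classic table's
  maximum of 5 — the classic expansion of 15 base patterns under
  complementation is exactly what reopens face-ambiguity holes.
* **Fan anchoring.** Loops are fan-triangulated from their smallest
  edge id so complementary configurations pick the same diagonals.

Normals are area-weighted vertex averages of outward-oriented face
normals.  `smooth_preserving_plateaus` optionally relaxes staircase
noise in the *normal field* by repeated 1-ring averaging; vertex
positions — the terraces the CC algorithm depends on — are never moved.
That is the full extent of surface simplification implemented: stronger
mesh simplification is deliberately out of scope, since the landmark
computation only needs stable terraces and a tamed normal field.

## The synthetic phantom

`generate_phantom` emulates the study conditions without patient data:
a two-intensity head ellipsoid (tissue 180, air 5, Gaussian noise
SD 10) in a 160³ grid at 0.3 mm — a desk-scale stand-in for the
533-voxel, 16 cm field of view, which is available via `shape = 533`
for stress runs.  Six bumps carry the landmarks; each is a sphere of
radius 8 truncated by a plane perpendicular to the landmark's normal
at depth 2.5, giving an apex facet of radius ≈ 5.8 voxels — a tabletop
that spans well over 5 vertices and contains every 4 px consistency
offset with margin.  Three placement rules keep each tabletop's slab
from leaking onto other structures:

* the 45° landmarks are anchored at the ellipsoid's tangent points of
  their own normals, mirroring the anatomical fact that these landmarks
  *are* the most prominent points along those directions (elsewhere the
  45° band filter follows the constant-projection contour of the head
  indefinitely);
* midline protrusion heights differ (Pn 8, ULP 6, LLP 10, Co 6 voxels),
  so every anterior facet sits clear of the head's anterior pole band
  and of neighbouring bumps;
* subject-level variation (head position and size, drawn
  deterministically from the seed) moves the true landmark positions
  between subjects without disturbing those separations.

The phantom reproduces the *geometric regime* of the method — terraced
protrusion tops — not CBCT physics: no beam hardening, scatter, metal
artifacts, soft-tissue texture, or anatomical shape variability.
Passing tests therefore demonstrate the algorithmic properties
(determinism, fixed-point consistency, apex recovery to within a voxel)
and not clinical segmentation accuracy on real scans.  One discrete
artifact is worth knowing: the union of head and bumps is watertight in
every seed, but in some seeds a shallow-angle bump/head tangency adds a
voxel-level genus-1 handle, so the Euler-characteristic-2 check applies
to the genus-0 fixtures (ball, single bumps).

Simulated raters (`generate_rater_series`) add a constant per-rater
bias and isotropic Gaussian per-click jitter to true coordinates;
0.5 mm jitter emulates careful manual digitization.

## Statistical conventions

* Two-item Cronbach's alpha from the variance formula,
  `2 (1 − (s₁² + s₂²) / s²_sum)`, sample variances with divisor n − 1;
  identical non-constant series give exactly 1 in floating point.
* Intra-examiner agreement treats session 1 vs session 2 as the items;
  inter-examiner agreement uses each examiner's two-session mean as the
  representative value.
* Rater differences Δx, Δy, Δz, Δd are *absolute* values, summarized by
  their mean and SD across subjects (the SD of the absolute values).
* The paired t test is the classical one on per-subject differences;
  degenerate (zero-variance) inputs raise errors rather than returning
  NaN.
* `required_sample_size_paired_t` scans n upward using the exact
  noncentral-t power function (never the normal approximation): at
  dz = 0.5, two-sided α = 0.05, power 0.80 the minimum is n = 34.

## Problem sizes and determinism

The test suite and the reproduction script run phantoms at 160³ with
10-subject cohorts — sizes chosen so the complete pipeline stays in the
seconds-to-a-minute range on a single CPU while every tabletop still
spans dozens of vertices.  All randomness (phantom geometry, noise,
clicks, rater jitter) flows from explicit integer seeds; pipelines
re-run bit-identically from their manifest.

## Known limitations

* Only convex landmarks: a concave landmark (e.g. soft-tissue gonion)
  has no protruding tabletop and the band filter cannot isolate it.
* Landmarks whose normals are neither axis-aligned nor at 45° in a
  coordinate plane would sit on staircases without a constant-level
  crown, and the CC point would wobble at sub-pixel scale.
* Automatic seeding is out of scope: the pipeline starts from a manual
  (or phantom-truth) click near the landmark.
* The DICOM reader covers uncompressed little-endian single-frame
  series only — enough for CBCT slice stacks, not the full standard.
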