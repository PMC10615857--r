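---
title: "Methods: organelle morphometry from EM label maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: organelle morphometry from EM label maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitomorph)
```

`mitomorph` turns segmented electron-microscopy label maps into physical
measurements of mitochondrial architecture: 2D profile morphometrics,
cristae composition, mitochondria–ER contacts (MERCs) and 3D skeleton
statistics. This vignette is the package's own account of the models and
numerical choices behind those numbers — what each estimator assumes,
where its defaults come from, and what a passing test does and does not
establish.

## The measurement model

The input is an integer label map — a 2D section or a 3D stack where 0 is
background and each positive integer is one object — plus a mandatory
calibration in nanometres per pixel (x, y) and per slice (z). There is no
default scale: every downstream quantity is physical, and a silently
assumed 1 px = 1 nm is the classic way such pipelines go wrong. Volume-EM
stacks are commonly anisotropic (e.g. 10 nm × 10 nm in-plane with 50 nm
slices); the anisotropy ratio is recorded on the calibration and every
distance-based computation uses physically weighted transforms.

Segmentation itself is upstream and out of scope: raw micrographs never
enter the package. Object identity follows the mask as labelled; for
binary exports, `relabel_components()` applies the package-wide identity
convention (8-connectivity in 2D, 26 in 3D).

## 2D morphometrics

**Area** is exactly the pixel count times the pixel area — integer
arithmetic before unit conversion, so the value is reproducible to the
last digit. Holes inside a profile (cristae lumens) are filled first:
"mitochondrial area" means the organelle outline, and cristae are measured
separately.

**Perimeter** is the interesting estimator choice. The two textbook
options both fail a basic sanity pair: the 4-direction Cauchy–Crofton
estimate is accurate on discs (±0.3%) but systematically ~5–6% low on
long axis-aligned edges (direction averaging under-weights straight
runs), while weighted pixel-edge counting is near-exact on rectangles but
~5% high on discs, dragging the circularity of an ideal circle to 0.90.
The default here is therefore a sub-pixel contour: the 0.5-level boundary
polygon of the binary mask (crack midpoints, equivalent to marching
squares on binary data), simplified with Douglas–Peucker at a 1 px
tolerance so staircases collapse to their underlying straight or smoothly
curved runs while true corners survive. Measured against analytic shapes
this gives −1.0% on a 50 px square, +0.2% on a 100 px-radius disc and
+1.4% on a 45°-rotated square. The Crofton estimator remains available
(`perimeter_2d(method = "crofton")`) for comparison with stereological
conventions; its axis-aligned bias is asserted in the test suite rather
than hidden. ImageJ's (unnamed) estimator differs from both; numeric
parity with ImageJ-derived figures is explicitly not claimed.

**Circularity** is 4πA/P², reported as computed even when discretization
pushes it above 1 (a warning fires above 1.05 — e.g. the one-pixel object,
whose sub-pixel contour is a diamond). **Length** of a 2D profile is the
maximum Feret (caliper) diameter over the convex hull of pixel corners;
**aspect ratio** comes from the second-moment (inertia-equivalent)
ellipse, with a 1/12-pixel variance term so one-pixel-wide shapes remain
well defined.

## Cristae

Each 8-connected component of the cristae map is one crista, assigned to
the mitochondrion with which it shares the most pixels and clipped to that
support (so areal density cannot exceed 1); components overlapping no
mitochondrion are reported and excluded. Because a 2D section cannot
measure 3D cristae volume or membrane area, the package reports the
standard stereological surrogates under honest names: `volume_density`
(areal fraction, the unbiased estimator of volume fraction) and
`surface_proxy_um` (total crista membrane length; an optional ×Δz
conversion to an area is available but off by default, since it adds an
assumption rather than information).

Lamellar (sheet) versus tubular cristae are separated by the profile's
moment-ellipse aspect ratio with an inclusive threshold of 3.0. No
consensus numeric threshold exists in the literature, so the value is
explicit, CLI-exposed, and chosen to sit well clear of both constructed
classes in the phantom tests (sheets rendered at aspect ≥ 4, tubes ≤ 1.5).
Classification is scale-invariant by construction. The 0–4 cristae score
is validated and aggregated but never computed: it is a subjective human
judgment, and the report metadata says so.

## MERC detection

The gap field assigns every ER boundary element the Euclidean distance
(nm) to the nearest mitochondrial boundary element, computed by an exact
anisotropic distance transform (Felzenszwalb–Huttenlocher, per-axis
physical spacing) and verified in the tests against a brute-force
all-pairs minimum — exact agreement, not approximate. Distances are
between boundary-element *centers*: no half-pixel membrane offset is
applied. This convention is simple, oracle-checkable, and recorded in the
output metadata because tools with sub-pixel membrane models will differ
by up to one pixel pitch. One consequence is worth spelling out: when two
membranes rasterize with their boundary centers G apart, the physical
void between them is G minus one pitch. The slab phantoms therefore carry
their cleft-volume truth as area × (G − Δz), and the acceptance slab uses
a 1 nm z-pitch so the conventional "area × gap" figure agrees with the
void within 3.3%.

A contact is an ER boundary element with gap ≤ 50 nm — inclusive, reading
"within 50 nm" as a closed bound — with the threshold configurable.
In 2D, contact runs tolerate breaks up to `merge_gap_px` (default 2 px,
absorbing segmentation speckle) before splitting into separate sites; a
site's contact length is its element count times the pixel pitch. An
earlier design used the run's geodesic diameter, but sums of diameters
shrink when two runs merge into a loop as the threshold rises, violating
monotonicity — the count-based arc length is additive, monotone, and
exact on straight runs. In 3D, contact patches use face (6-)adjacency
(no diagonal leakage between distinct patches), areas are sums of
exposed voxel-face areas, gap statistics are area-weighted, and the
contact length is the patch's geodesic diameter (longest shortest path,
26-neighbor metric, estimated by the standard double-sweep) — for a flat
square patch this recovers the diagonal. The cleft volume is the physical
volume of background voxels within the threshold of both organelles,
assigned to the nearest patch: the geometrically unambiguous reading of
"MERC volume", and phantom-verifiable.

Coverage is the fraction of an organelle's boundary elements (2D) or
exposed surface area (3D) in contact, as a percentage — guaranteed ≤ 100
and exactly 100 for a fully wrapping sheath. In a 2D section the
denominator is dimensionally a perimeter even where figure axes say
"per surface area"; the output metadata records that reading. Boundary
extraction is truncation-aware: out-of-canvas is treated as foreground,
so an organelle cut by the field of view exposes no fictitious membrane
at the image edge — without this, slab-like geometries acquire ~10%
phantom surface. Sites whose mean gap falls in the inclusive 15–30 nm
band are flagged as candidates for efficient ER→mitochondrion calcium
transfer.

## 3D architecture

**Volume** is exact: voxel count × physical voxel volume. **Surface
area** meshes the 0.5 level of the object's binary mask with marching
tetrahedra (a 6-tetrahedron cube split — no 256-entry case table to
transcribe) after Gaussian smoothing at σ = 1 voxel. The smoothing is not
cosmetic: the level set of the raw binary mask overestimates a sphere's
area by ~9% at any radius, while the smoothed surface is −2.4% at r = 10
voxels, −0.5% at 20 and −0.04% at 40 — inside the 5% target with the
error shrinking as resolution grows, which the tests assert as a
monotonicity property. Objects too small to survive smoothing fall back
to the raw level set.

**Skeletons** come from distance-ordered homotopic thinning: boundary
voxels are removed innermost-distance-first whenever the removal is
topology-preserving (Malandain–Bertrand simple-point test) and the voxel
is not a curve endpoint. Anisotropic stacks are first resampled
(nearest-neighbor) to an isotropic grid at the finest pitch, since 3D
thinning assumes isotropy; lengths map back to physical units. Each
skeleton voxel carries a local radius: the interior distance-transform
value minus half a voxel (the membrane sits at the voxel edge, not the
background voxel's center).

**Length** is the longest geodesic through the skeleton graph with two
corrections, both forced by phantom calibration rather than taste. The
voxel chain is boxcar-smoothed (window 5) before summation, because raw
26-neighbor chains overestimate oblique arcs by up to ~5–8% — enough to
break the quarter-torus target on its own. And the endpoint interior
radii are added back, because thinning retracts a tube's centerline by
about one tube radius from each flat end — without this an r = 8 voxel
tube loses 8% of its length and the radius-invariance property fails.
With both, straight tubes of radius 2–8 voxels and a quarter torus
recover their analytic lengths within 1%. Blobs whose skeleton collapses
to a radius-dominated remnant fall back to the 3D Feret diameter with an
explicit flag (a 400 nm sphere reports ~0.4 µm, flagged).

**Branching**: junctions are skeleton nodes of degree ≥ 3 after pruning
spurs shorter than 3 voxels (thinning artifacts otherwise inflate the
count), with adjacent junction voxels clustered and counted once;
hyperbranched means ≥ 3 junctions by default. **MOAS / nanotunnels** are
segmented from the radius profile along the main geodesic: bulbs are runs
with radius ≥ 100 nm; between two bulbs, a candidate tunnel is a maximal
sub-run with radius ≤ 0.35 × the median flanking-bulb radius and physical
length ≥ 200 nm; MOAS requires ≥ 2 bulbs joined by ≥ 1 tunnel. The
literature describes the morphology (bulbous bodies on thin membranous
strings) without numeric bounds, so all four parameters are explicit and
CLI-exposed; the defaults were fixed once, before measurement, to
separate the described morphology, and the acceptance grid then checks
that the *pipeline* — rasterize, resample, thin, profile, segment —
recovers the constructed labels perfectly, including the deliberately
borderline negative (60 nm tunnels on 150 nm bulbs, ratio 0.4).

## The phantom world, and what green tests establish

Phantoms are rendered by pixel-center inclusion, so pixel-count oracles
are exact and rendering is deterministic across platforms; seeds move the
scene by sub-pixel offsets (never along a controlled gap axis) to probe
rasterization variability. The boundary jitter harness flips shell pixels
with probability 0.25 × amplitude, each flip gated by a local topology
check and the result re-verified globally.

What the phantoms emulate is geometry: sizes, gaps, radii, branching.
What they do not emulate is everything that makes real EM segmentation
hard — membrane blur, staining variability, segmentation errors beyond
speckle-scale jitter, touching organelles, cristae whose 3D obliqueness
defeats 2D classification. A green recovery suite therefore establishes
that the estimators are correct on known geometry at stated tolerances;
it does not certify accuracy on any particular real dataset, and the
blinded-workflow metadata exists precisely because the human part of the
pipeline still matters.

Default tolerances mirror the estimator calibrations above: 1–2% for
areas/perimeters at the tested radii, 2%/5% for sphere volume/surface,
5% for skeleton lengths, exactness for the distance-field oracle and for
integer-valued outcomes (counts, junctions, classifications).

## Statistics

Group comparisons are two-sided Welch t or Mann–Whitney, chosen by an
explicit flag — the package never auto-switches tests, since "use the
non-parametric equivalent if applicable" is a judgment call that belongs
to the analyst and the methods section. The Mann–Whitney p-value is exact
(via the null rank-sum distribution) for combined n ≤ 20 without ties,
and a tie-corrected normal approximation otherwise; the test suite checks
it against a complete enumeration oracle and its null calibration over
2,000 simulations. Identical constant groups make the t statistic
undefined; that case returns p = 1 with a `degenerate` flag rather than
an error, so batch pipelines survive pathological metrics. Stars follow
the strict-inequality convention (`*` p < 0.05 … `****` p < 0.0001,
`ns` at p = 0.05 exactly). More than two groups raises a deliberate
not-implemented error directing users to pairwise comparisons; omnibus
ANOVA adds surface area without serving any figure this package
reproduces.

## Known limitations

- TIFF support is uncompressed baseline grayscale (the label-map export
  subset); compressed TIFFs and OME-XML metadata are not parsed. PNG
  output is 8-bit (≤ 255 labels).
- HDF5 datasets are read in the axis order the R HDF5 layer reports;
  files from C-order writers need `reverse_dims = TRUE`.
- The geodesic diameter uses the double-sweep heuristic (exact on trees,
  a lower bound ≥ half the true diameter in general).
- Thin structures (≤ 2 px) have sub-pixel contour perimeters a few
  percent below 2×length; the surface proxy inherits that bias
  symmetrically across groups.
- MOAS segmentation inspects the main geodesic path; tunnels on side
  branches of a hyperbranched network are not counted.
- 2D coverage attribution distributes the mitochondrial side of a
  multi-site pair proportionally to site extent; per-site values are
  estimates, pair-level totals are exact.
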