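---
title: "Converting planar lung-nodule contour annotations to DICOM SEG and SR"
author: "noduleSEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Converting planar lung-nodule contour annotations to DICOM SEG and SR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noduleSEG)
```

# The problem

Large multi-reader lung-CT annotation efforts produced, for every nodule
with greatest in-plane dimension of 3–30 mm, per-slice planar contours and
nine subjective characteristic ratings, stored in a project-specific XML
dialect.  Those files encode two conventions that are easy to get wrong:

1. **Contour-exterior convention.**  The contour points are the pixels just
   *outside* the nodule.  A converter that includes contour pixels in the
   nodule inflates every downstream mask and measurement; this is a known
   error mode of ad hoc conversions.
2. **Include/exclude semantics.**  A nodule region on one slice is the
   union of the strict interiors of its "included" polygons minus the
   strict interiors of its "excluded" polygons (cavities, vessels).

`noduleSEG` converts such annotations into standard, self-describing DICOM
objects — one Segmentation object (SEG) and one SR measurement report
(template TID 1500) per annotation — so that generic DICOM tooling can
archive, query, visualize and recompute from them without project-specific
documentation.

# Pipeline and conventions

## Geometry binding

`buildGeometry()` reads the per-slice DICOM CT headers, verifies that they
form a single consistent axial series, and sorts slices by patient-space
position along the slice normal — never by file name or instance number.
The voxel index convention is fixed once: `(i = column, j = row, k =
slice)`, 0-based, with the patient mapping
`P = IPP(k) + i·Δc·X + j·Δr·Y`, where `X` and `Y` are the direction cosines
of increasing column and row index.  Mixed series, inconsistent spacing,
duplicate slice positions, a non-uniform slice step (default tolerance
0.01 mm — a missing slice shifts every contour above it, so gaps are
refused rather than bridged) and non-axial or gantry-tilted orientations
are all hard errors: silent mis-binding of a contour to the wrong slice is
strictly worse than refusal.

## Rasterization

`rasterizeRoi()` operationalizes "strict interior" as: *pixel center inside
the closed polygon through the contour pixel centers (even-odd rule), and
pixel not on the contour path*.  The path is the vertex set plus the
Bresenham digitization of each edge (closure included), so a contour that
skips pixels still never leaks onto its own outline.  Consequences that the
test suite asserts: a ring tracing the border of a 5×5 block fills exactly
the 3×3 interior; the smallest closed ring (3×3) fills one pixel; no
contour pixel is ever foreground; the fill is invariant to point-order
reversal and cyclic rotation.  Self-intersecting polygons are filled with
the even-odd rule after a warning — deterministic and orientation-free.
Excluded polygons remove only their strict interiors, mirroring the
inclusion convention (the exclusion contour itself lies outside the
excluded region); the source documentation does not pin this down, so it is
a documented package choice.  An excluded contour on a slice with no
included contour contributes nothing, permissively.

## Clustering into nodules

The source data intentionally does not say which annotations describe the
same physical nodule, nor who read what.  `clusterAnnotations()` groups the
annotations of a scan by single-linkage connected components of the
minimum patient-space Euclidean distance between contour point sets, with
tolerance defaulting to one slice step — the natural proximity scale, since
annotations of one nodule are stacks of per-slice contours that touch or
interleave in z.  The published tooling this emulates did not print its
threshold, so equivalence with the original grouping on real data is not
claimed; the tolerance is an explicit CLI parameter.  Clusters are numbered
consecutively by first member appearance in document order, each receives a
fresh tracking UID shared by all of its members' SEG and SR objects, and
clusters larger than four members (possible when distinct nodules nearly
touch) are flagged in the conversion manifest, never split automatically.

## Measurements

Three measurements accompany every annotation, chosen to match the coded
concepts carried in the SR:

* **Diameter** (mm): maximal in-plane extent — the maximum over slices of
  the largest pairwise distance between foreground *boundary* pixel
  centers (equivalent to using all foreground pixels for the maximum, and
  cheaper).  Values above the 30 mm in-scope range warn but do not error.
* **Volume** (mm³): foreground voxel count × voxel volume.  The simplest
  defensible estimator; on digitized spheres of radius 5–12 mm at 1 mm
  voxels it is within 2 % of the analytic value.
* **Surface area** (mm²): summed triangle area of an isosurface extracted
  at level 0.5 by marching tetrahedra (six tetrahedra per grid cube,
  vertices linearly interpolated along sign-changing edges) with voxel
  spacing applied.  Meshing the raw binary staircase overestimates the
  area of smooth objects substantially (≈ +25 % on digitized spheres, an
  expected artifact of jagged binary isosurfaces), so the binary volume is
  first regularized with a separable three-voxel mean filter *clamped so
  that every foreground voxel stays above and every background voxel below
  the iso-level*.  The clamp preserves the mask's voxel membership and
  topology exactly (a single voxel still yields a small positive mesh)
  while the relaxed gradient lets the interpolated surface track the
  underlying smooth shape: sphere-area errors are −5.9 % (r = 5 mm),
  −3.3 % (r = 8 mm) and −1.4 % (r = 12 mm), shrinking with radius, and the
  similarity law (doubling the spacing quadruples the area) holds exactly.

Numeric agreement with any previously published measurement values is not
claimed: the measurement *codes* are fixed, the estimators are this
package's documented choices.

## Coding

All semantics travel as `(CodeValue, CodingSchemeDesignator, CodeMeaning)`
triplets.  Segment semantics are constant: category *Morphologically
altered structure* (SCTID 49755003, CID 7150), type *Nodule* (SCTID
27925004, CID 7151), anatomy *Lung* (SCTID 39607008, CID 4), emitted with
SRT-style identifiers by default (matching collections published before the
move to numeric SNOMED CT codes; `sct = TRUE` switches to numeric codes).
Measurements use (`M-02550`, SRT) / mm, (`C0JK`, IBSI) / mm², (`G-D705`,
SRT) / mm³, units always UCUM.  The nine characteristics are coded through
a human-editable JSON dictionary shipped with the package: per attribute
one concept and an ordered value set whose meanings embed the scale
semantics (e.g. malignancy 3 → "3 out of 5 (Indeterminate Likelihood)"), so
a score can never be reversed by losing an external legend.  The private
codes use a `99`-prefixed nonstandard scheme designator (`99LIDCQIICR`);
their *values* are this package's own synthetic assignments — semantically
faithful to the documented rating scales but not byte-identical to any
previously published dictionary.  Ratings present but outside the
documented range warn and are treated as unset rather than aborting a
batch.

One naming discrepancy is deliberate: prose descriptions of the nine
characteristics sometimes list "shape" and "solidity"; the XML attribute
names are `sphericity` and `texture`.  The package follows the XML
attribute names throughout.

## SEG encoding

One SEG per annotation (never per nodule): reader identity is withheld in
the source data, so merging annotations possibly made by different readers
into one object would fabricate structure.  Objects are binary,
single-segment, with frames only for non-empty slices (slices above and
below the nodule are omitted; the further cuboid bounding-box optimization
is deliberately not performed, keeping full-slice frames).  Each frame
carries its plane position and a derivation reference to the source CT
slice.  `SeriesDescription`, `SegmentLabel`, `SegmentDescription` and the
tracking label all follow `"Nodule <n> - Annotation <id>"`.  Display colors
come from a fixed cycle of eight high-saturation RGB values indexed by the
annotation's ordinal within its cluster — pairwise distinct within a
nodule, and carrying no semantics whatsoever.  Colors are stored as 16-bit
scaled CIELab under D50 reference white; the sRGB→Lab conversion uses the
Bradford adaptation derived in code from the cone-response matrix and the
two white points, so white maps to `(0xFFFF, 0x8080, 0x8080)` exactly.
Each SEG is a new series with fresh UIDs; patient and study composite
context is copied verbatim from the CT so the objects file correctly
alongside the images.

## SR encoding

One TID 1500 report per annotation: a single measurement group carrying the
tracking pair (identical to the SEG's), finding type *Nodule*, an explicit
reference to the SEG instance and segment number, the source CT series UID,
every present characteristic as a coded name–value pair, and the three
measurements as numeric items with UCUM units (serialized to 6 significant
digits).  The finding type is set on the group itself — the group is
self-contained even without dereferencing the SEG's anatomy code.  An
annotation missing a rating simply yields fewer evaluation entries (8
instead of 9), matching the one such case known in the source collection.
`flattenEvaluations()` inverts the encoding into one table row per
annotation with the ratings recovered through the dictionary.

## DICOM codec

No R DICOM implementation was available to build on, so the package
includes a deliberately minimal Part-10 codec: explicit VR little endian
only, defined-length writing, sequence recursion, and refusal (never
mis-parsing) of any other transfer syntax.  Conformance of the emitted
objects is not self-certified: the validation suite re-parses every SEG and
SR with *pydicom* — an entirely independent implementation — and asserts
the IOD-required attributes, frame-count/pixel-length consistency and the
SR content-tree structure (`inst/py/validate_dicom.py`).

# The synthetic phantom

`generateCtSeries()` / `generateAnnotations()` emulate the two inputs the
converter consumes.  The CT series is geometrically faithful — consistent
UIDs, axial orientation, positions advancing by the slice step, 16-bit
pixel data with a uniform −1000 HU background and +1000 HU spheres — but
makes no attempt at anatomical realism: conversion correctness depends on
geometry and contours, not on intensity content.  Annotations trace, per
slice, the one-pixel exterior shell of the digitized sphere cross-section
(exactly the contour-exterior convention), with per-reader radius jitter
(default ±0.5 mm, a plausible inter-reader delineation scale) and
characteristics either specified or sampled uniformly over each attribute's
value set.  Center-only marks (single-point ROIs) can be added to exercise
the volumetric-selection filter.  Everything is driven by one integer seed;
a fixed seed reproduces the series byte-for-byte.

Default phantom conditions used throughout the tests and the acceptance
script: 96×96 pixels at (0.7, 0.7) mm, 20 slices at 2.5 mm — a realistic
thorax-CT resolution at a desk-scale matrix — with two nodules (radius 6
and 8 mm, centers > 30 mm apart) read by three readers each plus one
center-only mark.  Measurement-recovery checks use digitized spheres of
radius 5, 8 and 12 mm at 1 mm isotropic voxels.

What passing on the phantom does **not** show: robustness to the
irregular, lobulated, cavitated shapes of real nodules beyond what the
include/exclude and randomized-polygon tests cover; agreement with any
specific historical clustering of real data (the threshold of the original
tooling is unpublished); or handling of malformed real-world DICOM
variants beyond the explicit error paths.

# Numerical choices and degenerate inputs

* Slice-step uniformity tolerance 0.01 mm; contour z-position fallback
  matches within half a slice step.
* Contours with fewer than three distinct points, or all-collinear points,
  are degenerate-contour errors; two-point "outlines" are dropped by the
  volumetric filter before rasterization.
* An annotation whose contours enclose no pixel is an error (a volumetric
  annotation is expected to have a non-empty mask).
* Polygon closure is implicit: the last point connects to the first if not
  repeated.
* Tie-breaks: cluster numbering by first appearance in document order;
  z-matching of SEG frames to slices by nearest position within half a
  slice step.
* Measurement serialization at 6 significant digits; `voxel ↔ patient`
  round trips are exact to < 1e-6 mm.
* UID generation is hierarchical under a configurable root, fed by the
  session RNG plus a process counter, so a seeded run is reproducible while
  parallel runs under distinct seeds collide with negligible probability.

# Limitations

* Only axial, single-frame-per-file CT with explicit-VR-little-endian
  encoding is read; other transfer syntaxes and enhanced multiframe CT are
  refused.
* Non-nodule marks and center-only marks are parsed but never converted,
  by design.
* Clusters of more than four annotations are flagged, not resolved; the
  package offers no manual regrouping interface.
* The characteristic code dictionary is semantically faithful but private;
  collections encoded with a different dictionary will not be
  byte-compatible at the code-value level (meanings and scales are).
* Fractional (probability-map) segmentations and compressed pixel
  encodings are out of scope.
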