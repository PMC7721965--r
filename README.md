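# noduleSEG

Standard DICOM re-encoding of planar lung-nodule contour annotations.

Multi-reader lung-nodule annotation projects historically shipped their
contours in project-specific XML: per reading session, per nodule, a list of
per-slice polygons of image-relative `(x, y)` pixel coordinates with an
inclusion flag, plus nine subjective characteristic ratings (subtlety,
internal structure, calcification, sphericity, margin, lobulation,
spiculation, texture, malignancy).  Two conventions make naive conversion
wrong: the contour traces the pixels *just outside* the nodule (so contour
pixels must never be counted as nodule), and a region is the union of
"included" polygon interiors minus the "excluded" ones.  `noduleSEG`
re-encodes such annotations as self-describing standard objects:

* one **DICOM Segmentation (SEG)** object per annotation — binary,
  single-segment, one frame per non-empty slice only, with segment semantics
  coded as category *Morphologically altered structure* (SCTID 49755003),
  type *Nodule* (SCTID 27925004) and anatomy *Lung* (SCTID 39607008), a
  per-nodule tracking UID, and a recommended display color stored as 16-bit
  CIELab;
* one **DICOM SR measurement report (template TID 1500)** per annotation —
  the coded qualitative evaluations plus three quantitative measurements:
  diameter (`M-02550`, SRT; mm), mesh surface area (`C0JK`, IBSI; mm²) and
  volume (`G-D705`, SRT; mm³), all with UCUM units, referencing the SEG and
  the source CT series and carrying the same tracking pair.

Annotations of one scan are grouped into physical nodules by single-linkage
clustering of the minimum patient-space distance between contour point
sets (tolerance = one slice step by default); every object of a nodule
shares one tracking UID, and objects are labelled
`"Nodule <n> - Annotation <id>"`.

The measurements are: maximal in-plane diameter (largest pairwise distance
between boundary pixel centers on any one slice), volume by voxel counting
(foreground count × voxel volume), and surface area of a triangulated
isosurface extracted at level 0.5 by marching tetrahedra from a
topology-preserving regularization of the binary mask.

The package is written for researchers converting or validating
contour-annotated CT collections, and is fully testable offline: a synthetic
phantom generator emits a geometrically faithful DICOM CT series plus
dialect-conformant XML annotations of analytic spheres with known volume,
area and diameter.  It includes its own minimal DICOM Part-10
explicit-VR-little-endian codec for the CT, SEG and SR objects it exchanges.

## Worked example

```r
library(noduleSEG)

## a synthetic chest-CT phantom: two spherical nodules (radius 6 and 8 mm),
## three readers each, plus one center-only mark
spec <- phantomSpec(
  imageShape   = c(96L, 96L), pixelSpacing = c(0.7, 0.7),
  sliceStep    = 2.5, nSlices = 20L,
  nodules = list(
    list(center = c(20, 20, 20), radius = 6, nReaders = 3, jitter = 0.4),
    list(center = c(45, 45, 30), radius = 8, nReaders = 3, jitter = 0.4)),
  centerMarks = 1L, seed = 7L)
generateCtSeries(spec, "phantom/ct")
geom <- buildGeometry("phantom/ct")
generateAnnotations(spec, geom, "phantom/annotations.xml")

manifest <- convertScan("phantom/ct", "phantom/annotations.xml", "phantom/dicom")
manifest
#> ConversionManifest (noduleSEG 0.1.0 )
#>   annotations_parsed       7
#>   volumetric_annotations   6
#>   clusters                 2
#>   segs_written             6
#>   srs_written              6
#>   excluded_marks           1
#>   warnings                 0
```

Seven annotations parse; the center-only mark is excluded (non-volumetric),
the six polygon stacks cluster into the two physical nodules, and each
yields one SEG + one SR.  Validation re-reads everything, checks count
parity, dictionary closure, tracking consistency, the decode round trip,
and runs the independent pydicom conformance script:

```r
validateCollection("phantom/dicom", ctDir = "phantom/ct",
                   xmlPath = "phantom/annotations.xml")
#>             check pass                     detail
#> 1  correspondence TRUE 6 annotations, 6 SEG, 6 SR
#> 2 code_dictionary TRUE
#> 3        tracking TRUE
#> 4   seg_roundtrip TRUE
#> 5 iod_conformance TRUE       12 objects validated
```

The SR collection flattens into one row per annotation:

```r
srs <- list.files("phantom/dicom", pattern = "^SR_", recursive = TRUE,
                  full.names = TRUE)
flattenEvaluations(srs)[1:3, c("nodule", "annotation", "malignancy",
                               "diameter_mm", "volume_mm3")]
#>   nodule annotation malignancy diameter_mm volume_mm3
#> 1      1        101          3     11.9206     911.40
#> 2      1        102          5     11.0680     788.90
#> 3      1        103          4     11.6503     879.55
```

The diameters and volumes are consistent with the 6 mm-radius sphere the
phantom placed (analytic diameter 12 mm, volume 904.8 mm³) up to the
per-reader contour jitter and voxelization.

A thin command-line driver with `convert`, `validate` and `phantom`
subcommands is installed at
`system.file("cli", "noduleSEG.R", package = "noduleSEG")`.

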