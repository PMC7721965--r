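Package: noduleSEG
Title: DICOM SEG and SR TID 1500 Re-Encoding of Planar Lung-Nodule
    Contour Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Converts per-reader planar-contour lung-nodule annotations in
    the LIDC XML dialect into standard DICOM Segmentation (SEG) objects and
    DICOM Structured Reporting (SR) measurement reports following template
    TID 1500. Reconstructs filled binary mask volumes from included and
    excluded contours under the convention that contour pixels lie just
    outside the nodule, clusters per-reader annotations into physical
    nodules by spatial proximity with shared tracking identifiers, computes
    coded quantitative measurements (maximal in-plane diameter, mesh surface
    area, voxel volume) and coded qualitative evaluations, and validates the
    emitted collection for count parity, code-dictionary closure, tracking
    consistency and round-trip fidelity. Includes a synthetic CT phantom and
    annotation generator with analytic ground truth so the whole pipeline is
    testable without any external image collection, and a minimal DICOM
    Part-10 explicit-VR-little-endian codec for the CT, SEG and SR objects
    it exchanges.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    xml2,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
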