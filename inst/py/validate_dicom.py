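#!/usr/bin/env python
"""Independent structural conformance check for emitted SEG / SR objects.

Re-parses each file with pydicom (a DICOM implementation entirely separate
from the encoder) and asserts the attributes the respective IOD requires.
Exit status 0 iff every file passes; failures are printed one per line.
"""
import sys

import pydicom

SEG_CLASS = "1.2.840.10008.5.1.4.1.1.66.4"
SR_CLASSES = {"1.2.840.10008.5.1.4.1.1.88.33", "1.2.840.10008.5.1.4.1.1.88.22"}


def req(ds, name, errs):
    if name not in ds:
        errs.append(f"missing {name}")


def check_seg(ds):
    errs = []
    for name in ("SeriesInstanceUID", "SOPInstanceUID", "StudyInstanceUID",
                 "FrameOfReferenceUID", "Rows", "Columns", "NumberOfFrames",
                 "SegmentSequence", "SharedFunctionalGroupsSequence",
                 "PerFrameFunctionalGroupsSequence", "PixelData",
                 "SegmentationType", "ReferencedSeriesSequence"):
        req(ds, name, errs)
    if errs:
        return errs
    if ds.Modality != "SEG":
        errs.append(f"Modality {ds.Modality} != SEG")
    if ds.SegmentationType != "BINARY" or ds.BitsAllocated != 1:
        errs.append("not a binary segmentation")
    n = int(ds.NumberOfFrames)
    if len(ds.PerFrameFunctionalGroupsSequence) != n:
        errs.append("per-frame group count != NumberOfFrames")
    expected = (n * ds.Rows * ds.Columns + 7) // 8
    if len(ds.PixelData) not in (expected, expected + 1):
        errs.append(f"PixelData length {len(ds.PixelData)} != {expected}")
    seg = ds.SegmentSequence[0]
    for name in ("SegmentNumber", "SegmentLabel", "SegmentAlgorithmType",
                 "SegmentedPropertyCategoryCodeSequence",
                 "SegmentedPropertyTypeCodeSequence", "TrackingID",
                 "TrackingUID", "RecommendedDisplayCIELabValue"):
        req(seg, name, errs)
    for frame in ds.PerFrameFunctionalGroupsSequence:
        if "PlanePositionSequence" not in frame:
            errs.append("frame without PlanePositionSequence")
            break
        if "SegmentIdentificationSequence" not in frame:
            errs.append("frame without SegmentIdentificationSequence")
            break
    # frames must reference existing source CT instances
    refs = {inst.ReferencedSOPInstanceUID
            for s in ds.ReferencedSeriesSequence
            for inst in s.ReferencedInstanceSequence}
    for frame in ds.PerFrameFunctionalGroupsSequence:
        src = frame.DerivationImageSequence[0].SourceImageSequence[0]
        if src.ReferencedSOPInstanceUID not in refs:
            errs.append("frame references a CT instance outside "
                        "ReferencedSeriesSequence")
            break
    return errs


def walk(item, found):
    name = item.ConceptNameCodeSequence[0].CodeValue if \
        "ConceptNameCodeSequence" in item else None
    found.setdefault(name, []).append(item)
    for child in item.get("ContentSequence", []):
        walk(child, found)


def check_sr(ds):
    errs = []
    for name in ("SeriesInstanceUID", "SOPInstanceUID", "StudyInstanceUID",
                 "ConceptNameCodeSequence", "ContentSequence",
                 "ContentTemplateSequence", "CompletionFlag",
                 "VerificationFlag"):
        req(ds, name, errs)
    if errs:
        return errs
    if ds.Modality != "SR":
        errs.append(f"Modality {ds.Modality} != SR")
    tmpl = ds.ContentTemplateSequence[0]
    if tmpl.TemplateIdentifier != "1500" or tmpl.MappingResource != "DCMR":
        errs.append("root template is not DCMR TID 1500")
    if ds.ConceptNameCodeSequence[0].CodeValue != "126000":
        errs.append("root concept is not Imaging Measurement Report")
    found = {}
    walk(ds, found)
    if "126010" not in found:
        errs.append("no Imaging Measurements container")
    if "125007" not in found:
        errs.append("no Measurement Group")
    if "112040" not in found:
        errs.append("no Tracking Unique Identifier")
    for num in found.get("G-D705", []) + found.get("M-02550", []) + \
            found.get("C0JK", []):
        mv = num.MeasuredValueSequence[0]
        if mv.MeasurementUnitsCodeSequence[0].CodingSchemeDesignator != "UCUM":
            errs.append("measurement with non-UCUM units")
        float(mv.NumericValue)
    return errs


def main(paths):
    n_err = 0
    for path in paths:
        try:
            ds = pydicom.dcmread(path)
            cls = ds.SOPClassUID
            if cls == SEG_CLASS:
                errs = check_seg(ds)
            elif cls in SR_CLASSES:
                errs = check_sr(ds)
            else:
                errs = [f"unexpected SOP class {cls}"]
        except Exception as exc:  # unparseable file is a hard failure
            errs = [f"parse error: {exc}"]
        for e in errs:
            print(f"{path}: {e}")
        n_err += len(errs)
    return 0 if n_err == 0 else 1


if __name__ == "__main__":
    sys.exit(main(sys.argv[1:]))
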