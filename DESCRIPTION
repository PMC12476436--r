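Package: panodent
Title: Tooth Instance Post-Processing and Kennedy Classification for Panoramic Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Post-processing of raw tooth instance-segmentation output from panoramic
    dental radiographs and rule-based Kennedy classification of partially edentulous
    jaws. Provides FDI two-digit tooth numbering utilities, mask-overlap measures,
    a three-stage duplicate-suppression filter (score threshold, duplicate FDI label
    suppression, geometric novel-pixel check), a rule engine assigning Kennedy classes
    I-IV or "full" per jaw, an IoU-based evaluation protocol with tooth-level and
    Kennedy-level confusion matrices, an ablation harness for the filter stages, and a
    seeded synthetic detection generator emulating the characteristic error modes of
    instance-segmentation detectors so the whole pipeline is testable without clinical
    data. COCO-style instance JSON (RLE or polygon masks) is the interchange format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
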