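Package: toothchart
Title: Tooth Numbering and Full-Mouth-Series Charting from Dental Radiograph Masks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Pipeline for automated dental charting from segmentation masks of
    panoramic, periapical and bitewing radiographs. Extracts individual teeth
    from tooth and cementoenamel-junction (CEJ) masks, assigns FDI tooth
    numbers by multi-scale normalized cross-correlation matching against a
    labeled tooth repository or against the patient's own panoramic
    radiograph with top-k majority voting, determines each intraoral
    radiograph's position (maxilla, mandible, bitewing) from bone and CEJ
    geometry, arranges a radiograph set into the three-row full-mouth-series
    template, and computes radiographic bone loss percentages with
    periodontal staging. Includes a seeded phantom generator producing
    radiograph-like images with gold-standard annotations so every stage is
    testable without clinical data, plus the full evaluation metric suite
    (Dice, Jaccard, detection and numbering precision/recall, position
    accuracy).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
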