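Package: hep2cad
Title: Synthetic HEp-2 Immunofluorescence Workbench with Classifier
    Fusion and Reader Agreement Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for developing and evaluating computer-aided reading of
    HEp-2 indirect immunofluorescence (IIF) wells. Provides a seeded
    synthetic image generator covering seven antinuclear-antibody staining
    patterns, three fluorescence intensity classes and mitotic cells with
    ground-truth masks; classical cell segmentation (Otsu thresholding and
    watershed splitting); a 108-value cell descriptor computed at four
    gray-level quantizations; a multi-classifier pipeline (SVM intensity
    triage, seven one-vs-all pattern classifiers, two mitosis networks and
    a K-nearest-neighbour fusion stage) with well-level reporting and the
    mitosis-based well discard rule; and inter-rater agreement statistics
    (per-class correct classification rate, accuracy, mean class accuracy,
    Cohen's kappa, chi-square and McNemar tests) with packaged reference
    concordance tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    nnet,
    png,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
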