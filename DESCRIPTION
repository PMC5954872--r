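Package: gestaltCAD
Title: Gestalt-Inspired Detection of Breast Masses in Digitized Mammograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-stage computer-aided detection (CAD) pipeline for breast
    masses in digitized screening mammograms, modeled on how radiologists read
    film: a sensation stage that isolates the breast, enhances mass-like
    structure and finds salient foci by grayscale morphology, then groups
    pixels into homogeneous "visual patches" (superpixels) on joint intensity
    and spatial similarity; a semantic stage that prunes candidate patches by
    gray-level co-occurrence homogeneity ("densification") and by the
    eccentricity of a least-squares ellipse fitted to each patch boundary; and
    a verification stage that merges surviving patches into regions of
    interest, averages a 12-dimensional texture feature vector per region and
    classifies regions with a kernel extreme learning machine.  Ships a
    seeded synthetic mammographic phantom generator with full ground truth,
    region-based scoring (sensitivity, false positives per image), FROC curve
    construction and per-stage candidate accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
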