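Package: mammoseg
Title: Mammogram Mass Segmentation by Fuzzy Enhancement and Dynamic
    Graph-Cut Region Merging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Segmentation of masses in digital mammograms and tools to
    evaluate it. Implements fuzzy histogram-based contrast enhancement
    (S-function intensification of the gray-level histogram), Otsu's
    between-class-variance thresholding, and a sorted-edge graph
    region-merging segmenter whose merge threshold adapts dynamically to
    region size and homogeneity, with region-of-interest extraction and
    pectoral-muscle flagging. Ships a full segmentation-evaluation metric
    suite (PSNR, MSE, NSD, ENL, fuzziness measures, target-to-background
    contrast, local refinement error, region-overlap acceptance,
    bipartite edgel matching F-measure, confusion statistics, ROC AUC)
    and a deterministic synthetic mammogram phantom generator with exact
    ground-truth masks, so the whole pipeline is testable without access
    to clinical image databases. Reads and writes PGM (P2/P5) and
    grayscale PNG images, and provides a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
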