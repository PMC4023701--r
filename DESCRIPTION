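Package: crctalk
Title: Tri-Tissue Transcriptomics and Tumor-Adjacent Mucosa Crosstalk Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for tri-tissue (healthy mucosa, tumor-adjacent
    mucosa, tumor) expression cohorts in colorectal cancer field
    cancerization studies. Provides differential expression calling with
    Storey q-values, three-way expression-pattern classification
    (tumor-like, trend, adjacent-specific), mutual-information
    transcriptional network inference with data-processing-inequality
    pruning, transcription-factor rank scoring with resampling p-values,
    and classification of secreted-protein to membrane-receptor crosstalk
    (afferent, efferent, autocrine) over a protein-protein interaction
    network. Includes a synthetic cohort generator with planted ground
    truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
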