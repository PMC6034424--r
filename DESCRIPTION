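Package: clonescape
Title: Clone-Size Metrics and Sampling Analysis for Bulk Antibody Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating B-cell clone sizes in bulk antibody
    heavy-chain sequencing data. Implements read-level quality control
    (sliding-window trimming, low-quality masking, N-count and length
    filters), subject-wide N-tolerant sequence collapsing, clonal inference
    by V gene, J gene, CDR3 length and CDR3 amino-acid similarity, three
    clone-size metrics (copies, instances, unique sequences), Hill-number
    diversity profiles, Shannon/Simpson/Pielou/clonality summaries,
    individual- and sample-based rarefaction for sampling-sufficiency
    analysis, cosine clonal overlap, and Boolean presence matrices for
    clone tracking. Ships a multi-replicate synthetic-repertoire simulator
    with ground truth so every stage of the pipeline can be validated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
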