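Package: crmp2screen
Title: SILAC Phosphoproteomics and High-Content p-CRMP2 Screen Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for lithium-mimetic discovery screens built on
    GSK3 signaling readouts in human neurons. One arm consumes searched SILAC
    phosphopeptide quantification tables and performs post-search filtering
    (experiment coverage, decoy removal, site localization, replicate
    quantification), per-channel median normalization of log2 ratios,
    one-sample regulation testing with Benjamini-Hochberg correction,
    per-protein regulated-peptide summaries with accession-group merging,
    GSK3 phospho-motif position-frequency matrices, and protein-protein
    interaction network component summaries. The other arm quantifies
    high-content fluorescence images of neuronal cultures: nuclear
    segmentation, four-criterion collar-ring cell classification, MAP2-based
    neurite tracing by skeletonization, per-well percent p-CRMP2(T514)/MAP2
    and MAP2-positive neuron counts, plate normalization to reference wells,
    Z-prime quality control, banded hit calling with a toxicity counter-screen,
    and unpaired t-tests with star bands. Seeded synthetic generators produce
    phosphopeptide tables, three-channel plate images with per-object ground
    truth, and plate layouts so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    limma,
    igraph,
    EBImage,
    tiff,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
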