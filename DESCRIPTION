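Package: methylEMT
Title: DNA-Methylation-Driven EMT Scoring and cfDNA Methylome Deconvolution
Version: 0.1.0
Authors@R:
    person("Maarten", "Devries", email = "maarten.devries@example.org",
           role = c("aut", "cre"))
Description: Tools for studying epithelial-to-mesenchymal transition (EMT)
    driven by DNA methylation in therapy-resistant cancer. Implements EMT
    signature scoring from expression (CPM log2 fold changes, delta-delta-Ct
    with housekeeper selection) and from promoter methylation; differential
    CpG calling with a shared-overlap binomial test; 5mC-decile 5hmC bin
    analysis for TET-activity inference; design of low-methylation capture
    panels for cell-free DNA; and longitudinal liquid-biopsy deconvolution
    (ctDNA fraction estimation, tumor methylome reconstruction, EMT
    trajectories). A seeded synthetic-data generator emulates methylation
    arrays, TAB-assay 5hmC data, expression tables and serial cfDNA samples
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
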