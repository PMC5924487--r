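Package: promoterforge
Title: Design and Evaluation of Tumor-Specific Synthetic Mini-Promoters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for designing tumor-specific synthetic
    mini-promoters. Screens transcription factors against tumor-vs-normal
    expression cohorts (quantile normalization, log2 fold change, Gene
    Ontology membership, hypergeometric gene-set enrichment, literature
    evidence ranking), assembles a multi-copy transcription-factor
    binding-site construct with restriction-site-tailed cloning primers,
    and implements the reporter and stain quantification formulas used to
    evaluate such constructs (fluorescence expression index,
    intensity-by-area scoring, tumor volume, two-group comparison).
    A seeded synthetic-cohort generator provides multi-cancer,
    multi-dataset expression matrices with planted overexpressed
    transcription factors so every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    limma,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
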