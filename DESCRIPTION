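Package: regusearch
Title: Tissue-Specific Regulatory Region Search and Noncoding Variant Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies tissue-specific regulatory regions (promoters,
    enhancers and other transcription-factor binding sites, accessible
    chromatin, and miRNA loci) linked to target genes by intersecting
    regulatory tracks with windows around transcription start sites, with
    active-in-any / active-in-all tissue semantics and full dataset/tissue
    provenance. Filters patient VCF files against the discovered regions to
    prioritise candidate regulatory variants, and provides an evaluation
    harness (promoter/intragenic/distal variant categories, recall, and
    span-based specificity of tissue-restricted searches) together with a
    seeded synthetic-data generator and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    BiocGenerics,
    IRanges,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
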