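Package: staygreenBSA
Title: Bulk Segregant Mapping of Delayed-Senescence (Staygreen) Mutations in Wheat
Version: 0.2.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping EMS-induced staygreen (delayed monocarpic
    senescence) mutations in recombinant inbred wheat populations by
    exome-capture bulk segregant analysis. Derives senescence phenology
    metrics (thermal time to score thresholds, onset, termination,
    duration) from visual 0-100 score time courses, classifies lines into
    phenotypic extremes and selects sequencing bulks, computes per-bulk
    SNP indices (DV/DP) and the delta SNP index from multi-sample VCFs,
    removes varietal variants, filters EMS-characteristic G:A / C:T
    transitions, detects candidate genomic regions, annotates coding
    consequences against gene models, and builds small genetic maps with
    Kosambi distances, single-marker association and Holm correction.
    Includes a synthetic-data generator that simulates the full
    experimental design (EMS mutagenesis spectrum, single-seed-descent
    RIL populations, bulk pooling, read sampling) with ground truth for
    parameter-recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    graphics,
    vcfR,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr, optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
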