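Package: spliceotope
Title: Splicing-Derived Neoantigen Discovery from Proteomic and Splicing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a phosphoproteomics-to-neoantigen
    analysis pipeline for phosphatase-inhibitor perturbations of the
    spliceosome. Provides Perseus-style differential intensity analysis
    (valid-value filtering, downshifted-normal imputation, SAM/S0 moderated
    t statistics with permutation FDR), rMATS-dialect splicing event
    filtering on PSI and FDR, branch-point and sequence-feature statistics,
    RNA-binding-protein motif RNA maps, reconstruction and translation of
    altered transcripts into candidate 8-14mer MHC-I neopeptides with a
    novelty filter against the canonical proteome, and hypergeometric
    set-overlap statistics. A synthetic-data module generates every input
    with planted ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
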