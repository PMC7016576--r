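Package: clonetag
Title: Identify Functional Clones by Coupling Sanger Tag Reads with Pooled Full-Length CCS Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the informatics side of functional screening of
    high-GC genomic libraries: restriction-site scanning on circular
    plasmids, single-cutter selection and minimal enzyme-panel choice,
    vector trimming and insert extraction from circular consensus (CCS)
    reads, Smith-Waterman assignment of short Sanger "tag" reads to
    pooled full-length reads, deduplication to unique inserts,
    back-verification against the source genome, and six-frame ORF
    prediction. Includes a full in-silico counterpart of the wet-lab
    workflow (high-GC genome, Sau3AI partial digestion with size
    selection, ligation into a BamHI-cut pUC118-like vector, CCS and
    GC-sensitive Sanger read simulation) so the whole pipeline can be
    exercised and scored against a ground-truth manifest with no
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
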