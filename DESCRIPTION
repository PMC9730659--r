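Package: kistat
Title: Design and Fragment-Analysis Screening of CRISPR ssODN Knock-Ins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An in-silico toolkit for single-stranded oligodeoxynucleotide
    (ssODN) mediated knock-in experiments in zebrafish and other models.
    Designs frame-preserving repair templates for epitope-tag insertion and
    point mutations with asymmetric homology arms, silent PAM-blocking
    mutations and engineered diagnostic restriction sites; predicts
    fluorescent-PCR fragment sizes for capillary-electrophoresis screening
    with and without restriction digest; classifies fragment-analysis peak
    tables as knock-in positive or negative; and simulates mosaic F0 embryos
    and pooled-embryo founder screens so that every screening step can be
    exercised without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
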