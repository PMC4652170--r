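Package: bivalscan
Title: Consensus Classification and Characterisation of Bivalent Promoters
    from Multi-Sample ChIP-Seq Peak Calls
Version: 0.1.0
Authors@R:
    person("bivalscan", "developers", email = "bivalscan@example.org",
           role = c("aut", "cre"))
Description: Tools for meta-analysis of promoter chromatin states in
    embryonic stem cells from multiple H3K4me3/H3K27me3 ChIP-seq peak
    sets: strand-aware promoter windows, per-sample state calls
    (active, repressed, bivalent, latent), high-confidence consensus
    classes under a strict >70 percent agreement rule, detection
    curves and sample QC, CpG observed/expected density profiles and
    CpG-island overlap by class, TSS-centred read-density matrices
    with k-means clustering, hypergeometric factor and
    perturbation-set enrichment, transcription-factor density,
    expression summaries by class, cross-species chromatin-state
    conservation over one-to-one orthologs, fixed k-mer motif
    statistics, and a fully deterministic synthetic-study generator
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
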