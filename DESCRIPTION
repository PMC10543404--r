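Package: abcquant
Title: Digital PCR Drop-Off Quantification and Amplicon Indel Profiling
    at AID Break Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify genome instability at AID break clusters
    (ABCs) from multiplexed digital PCR drop-off assays and amplicon
    sequencing. Implements Poisson-corrected per-channel concentration
    estimation from partition-level fluorescence data, mutant (drop-off)
    allele fraction estimation with a co-encapsulation-aware joint
    estimator, copy-number ratio inference from probe concentration
    ratios, per-position indel profiling of amplicon alignments with
    CpG/RCG/WGCW motif scanning and permutation-based proximity
    enrichment, and an ordered-alternative (Jonckheere-Terpstra) trend
    test for dose-response experiments. A synthetic-data module simulates
    Poisson-loaded multi-dye partition chips and amplicon reads with
    CpG-focused indels, with ground truth for end-to-end recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
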