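Package: fetalhap
Title: Haplotype-Assisted Non-Invasive Fetal Genome Recovery from Maternal Plasma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Recovers a fetal genome non-invasively from maternal plasma
    sequencing allele counts, assisted by phased parental haplotypes.
    Implements cell-free fetal DNA (cff-DNA) fraction estimation from
    discordant homozygous sites, a hidden Markov model over parentally
    transmitted haplotypes with binomial read-count emissions and Haldane
    recombination transitions (Viterbi decoding, forward-backward
    log-odds, recombination-breakpoint extraction), trio-based parental
    phasing with a panel-assisted resolver, a site-by-site baseline with
    a naive de-novo scan, a synthetic pedigree and plasma simulator, and
    evaluation utilities (accuracy by site class, error taxonomy,
    depth-downsampling curves).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
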