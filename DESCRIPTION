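Package: noisySplice
Title: De Novo Splice Junction Discovery and Quantification of Noisy Splicing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Discovers splice junctions de novo from short RNA-seq reads by
    split-read mapping against a k-mer seed index, and quantifies "noisy"
    (erroneous) splicing: a control-dinucleotide false discovery rate for
    junction calls, reading-frame periodicity of rarely used splice sites,
    conservation-stratified per-intron splicing error rates and their
    correlates (intron length, gene expression), and hexamer enrichment near
    unconserved splice sites versus matched decoy sites. A synthetic-data
    module generates miniature genomes, annotations, conservation tracks,
    variant sets, error-bearing transcript pools, and FASTQ reads with the
    statistical structure the downstream analyses assume, so the whole
    pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
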