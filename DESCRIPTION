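Package: dipscan
Title: Windowed Enrichment Analysis and Simulation for DIP-seq Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis toolkit for DNA-immunoprecipitation
    sequencing (DIP-seq) of cytosine modifications such as
    5-hydroxymethylcytosine. Provides read-length quality control with the
    50 bp exclusion filter used on semiconductor platforms, sliding-window
    read quantification, counts-per-million depth normalization, IP-versus-
    input log2 ratio tracks, window-level Poisson enrichment peak calling
    with Benjamini-Hochberg correction, five-compartment genomic annotation
    of peaks relative to transcription start sites, metagene profiling over
    scaled gene bodies, replicate and cross-platform concordance analysis,
    and a generative simulator of the immunoprecipitation protocol
    (fragmentation, antibody capture, whole-genome amplification, size
    selection) that emits aligned reads together with ground truth so that
    every stage can be validated against closed-form expectations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Rsamtools,
    GenomicAlignments,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
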