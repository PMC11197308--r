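Package: TEdynamics
Title: LTR Retrotransposon Dating, Transposition Dynamics, and
    TE-Proximal Gene Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for transposable-element (TE) centric comparative
    genomics. Estimates insertion ages of intact LTR retrotransposons
    from the divergence of their two long terminal repeats (Jukes-Cantor
    corrected, T = K/(2*mu)), profiles transposition and accumulation
    rates in 0.1-million-year bins, computes solo-LTR to intact-element
    ratios, classifies elements by protein-domain completeness (GAG, AP,
    INT, RT, RH) and expression behaviour across tissues and timepoints,
    assigns TEs to genes within a 5-kb flanking radius, calls period- and
    cultivar-specific differentially expressed gene pairs between two
    genotypes through synteny anchors, and classifies each pair into
    three main types and sixteen positional subtypes. A synthetic-data
    generator produces annotation sets, age-encoding LTR pairs, gene/TE
    landscapes, and two-genotype expression time courses with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
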