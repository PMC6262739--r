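Package: ssrseq
Title: Microsatellite Genotyping from Multiplexed Amplicon Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sequence-based genotyping of microsatellite (SSR) loci from
    dual-tagged, multiplexed amplicon sequencing reads. Merges read pairs,
    demultiplexes by 10-nt tag plus primer prefix with cross-tag chimera
    quarantine, collapses reads into alleles with abundance-based error
    absorption and PCR-chimera detection, estimates polyploid allele dosage
    from read-depth ratios, and codes alleles by repeat-region length, total
    fragment length, or full sequence identity. Quantifies size homoplasy,
    replicate genotyping error, and population-genetic diversity and
    differentiation (NA, He, Ho, ANOVA-based FST and RST with an allele-size
    permutation test). Includes a synthetic amplicon-read simulator with
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
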