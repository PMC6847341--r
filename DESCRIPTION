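Package: m7gmap
Title: Detection of Internal m7G RNA Modifications from Mutational
    Profiling Sequencing Pileups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects internal N7-methylguanosine (m7G) RNA modifications
    from multi-sample samtools-mpileup data produced by mutational
    profiling sequencing (MaP-seq). NaBH4 reduction converts m7G to abasic
    sites that are recorded as cDNA mutations during reverse
    transcription; the package parses the full mpileup base-string
    grammar, estimates per-position mutation frequencies by maximum
    likelihood with an EM algorithm that accounts for per-base
    sequencing/alignment error, tests treated-versus-control rate
    differences and within-replicate consistency with log-likelihood-ratio
    tests, and calls modified positions with depth, control-rate and
    replicate-consistency filters. A pileup simulator with planted
    modifications, a statistical power module, and barcode-based PCR
    duplicate collapsing are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
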