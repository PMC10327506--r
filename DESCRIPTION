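Package: panstrep
Title: Comparative Pan-Genomics of Streptomyces-Like Strain Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for stratified bacterial pan-genome analysis in the style
    used for the genus Streptomyces: species demarcation from average
    nucleotide identity (ANI) with Markov clustering, orthogroup construction
    from semi-global protein alignment, genus- and species-level hard/soft
    core and accessory proteomes, species fingerprint detection, chromosomal
    arm/centre enrichment by exact hypergeometric tests, rare TTA-codon
    scanning and orthogroup-level conservation, species-saturation curve
    fitting, and intra-species feature variability. Includes a synthetic
    pan-genome generator with planted ground truth (species partition,
    core/accessory/fingerprint family structure, positional bias, TTA plants)
    so every stage can be validated end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    Biostrings,
    ape,
    rtracklayer,
    GenomicRanges,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
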