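Package: barcodegap
Title: Four-Criteria Evaluation of DNA Barcoding Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates candidate DNA barcoding loci for species identification
    using four complementary criteria: sequence characterization (variable and
    parsimony-informative sites, GC content), barcoding-gap analysis on Kimura
    two-parameter (K2P) distances, neighbour-joining tree monophyly with
    bootstrap support, and distance-based identification (best match, best
    close match with an intraspecific-distance threshold, and leave-one-out
    top-hit discrimination). Includes a multi-locus sequence simulator with
    controlled intra- and inter-specific divergence so every stage of the
    pipeline can be exercised on synthetic data, plus an orchestration layer
    that evaluates single loci and all their concatenated combinations.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
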