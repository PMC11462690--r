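Package: methylogo
Title: Methylation-Aware Sequence Logos for Transcription Factor Binding Sites
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes and renders DNA-methylation-aware sequence logos for
    aligned transcription factor binding sites. Three information tracks are
    derived from Kullback-Leibler relative entropy against background models
    estimated from a genome or promoter regions: a classical sequence logo
    track against a zero-order Markov background, a dimer track showing the
    extra information gained from a first-order background (highlighting
    CpG depletion), and a methylation track decomposing binary relative
    entropy over the six strand-specific cytosine contexts (CG, CHG, CHH on
    either strand) measured from whole-genome bisulfite sequencing calls.
    A companion flanking-window profile summarises context probability,
    methylation level and methylation relative entropy around binding sites.
    Figures are written as deterministic SVG (or PDF/PNG); a simulation
    module generates genomes, methylomes and planted binding sites with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    jsonlite,
    optparse,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    xml2,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
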