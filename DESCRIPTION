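Package: dropedit
Title: Droplet Digital PCR Quantification of HDR and NHEJ Genome-Editing Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Toolkit for droplet digital PCR (ddPCR) assays that measure
    homology-directed repair (HDR) and nonhomologous end-joining (NHEJ)
    allele frequencies simultaneously at endogenous loci. Simulates
    two-channel droplet amplitude data under Poisson template loading with
    known ground truth, gates droplets into the empty/NHEJ/WT+/HDR+
    clusters, recovers per-class concentrations and allelic frequencies
    with subset-based Poisson estimators, determines limits of detection by
    95% confidence-interval non-overlap against a wild-type-only
    background, validates probe/primer/amplicon layouts (including
    nearest-neighbor melting temperatures with SantaLucia 1998 parameters),
    and summarizes multi-condition editing experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
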