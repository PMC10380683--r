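Package: dualAAVquant
Title: Quantification of Dual-AAV Transgene Reconstitution by Droplet Digital PCR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and estimation toolkit for dual adeno-associated
    virus (AAV) gene-therapy vectors that reconstitute a large transgene by
    homologous recombination of an overlapping region. Models the 5' and 3'
    vector architecture and its restriction landscape, generates synthetic
    molecule populations (recombined genomes, ITR concatemer chains, free
    monomers, host reference loci) with full ground-truth bookkeeping,
    performs in-silico SmaI/AleI digestion and droplet digital PCR
    (Poisson partitioning, amplitude multiplexing, gating), and implements
    estimators for vector copy number, homologous-recombination efficiency,
    ITR-concatemer fraction and expression specificity, with delta-method
    confidence intervals. Includes the small phenotype metrics used in
    murine efficacy studies (escape force, grip force, fiber percentages)
    and an end-to-end scenario runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
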