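Package: oxalotrace
Title: Phylogenetics, Key-Residue Conservation and Bioenergetics of Bacterial Oxalotrophy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for surveying the bacterial oxalate-degradation
    genes oxc, frc, oxdC and oxlT. Provides curation of BLAST tabular hits
    under E-value and percent-identity retention rules, UniProt-numbered
    key-residue conservation scoring on gapped protein alignments (occupancy,
    percent identity, substitution spectra and sequence-logo information
    content), neighbor-joining tree construction with column-bootstrap
    supports and clade-metadata concordance statistics, iTOL annotation
    export, and a revised-HKF aqueous thermodynamics engine that computes
    standard-state and activity-corrected Gibbs energies of oxalotrophic and
    methanotrophic catabolic reactions across marine temperature-pressure
    conditions. A seeded synthetic-data module generates protein families,
    hit tables and additive distance matrices with known truth for testing
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
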