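Package: hetprofile
Title: Heterochromatin Enrichment Profiling from ChIP Tiling Arrays and
    Fly Reporter Assays
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies heterochromatin protein enrichment from two-channel
    ChIP tiling-array signal in Drosophila: per-probe M values (log2
    ChIP/input), median normalization over uniquely mapping probes,
    fixed-width genomic binning, assignment of bins to overlapping feature
    classes (pericentric heterochromatin, chromosome 4, transposable-element
    families, piRNA clusters, subtelomeric windows), and wild-type versus
    mutant differential class profiles with per-family direction counts and
    cross-condition correlations.  Companion wet-lab assay computations are
    included: dilution-curve ChIP-qPCR relative enrichment, delta-delta-Ct
    expression, beta-galactosidase reporter kinetics, eye-pigment scores and
    genotype-class fold changes.  A seeded synthetic-data generator with
    planted truth makes every stage testable without array downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
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
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'assays.R'
    'enrichment.R'
    'hetprofile-package.R'
    'io.R'
    'partition.R'
    'profiles.R'
    'sim-config.R'
    'simulate.R'
    'pipeline.R'
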