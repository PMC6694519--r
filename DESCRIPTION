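Package: nifhact
Title: Total and Active Diazotroph Communities from Paired nifH DNA/RNA
    Amplicon Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of paired DNA- and RNA-derived nifH amplicon libraries
    to contrast total (gene-based) and transcriptionally active (transcript-
    based) diazotroph communities. Implements repeated-rarefaction
    normalization of uneven library depths, alpha-diversity indices (Shannon,
    Simpson, Pielou evenness, Chao1) with total-versus-active contrasts,
    Bray-Curtis dissimilarity with non-metric multidimensional scaling and
    multivariate beta-dispersion permutation tests, abundance ranking of
    operational taxonomic units, DNA:RNA frequency proportionality
    classification, and qPCR-anchored bulk and group-level nifH expression
    ratios (R_bulk = E^dCt; R_group = R_bulk * f_RNA / f_DNA). A synthetic
    community generator with known per-taxon activity multipliers provides
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    vegan,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
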