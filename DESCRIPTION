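Package: amdtox
Title: Metal Toxicity and Metal Resistance Gene Profiling for Acidic Pit Lakes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative analysis chain for metagenomic and metatranscriptomic
    surveys of metal-rich acidic waters. Computes equilibrium aqueous speciation
    of metal(loid)s with a Davies activity model, dimensionless toxic potency
    factors from USEPA water-quality criteria together with per-layer toxicity
    rankings, curates a KEGG-Orthology-keyed catalog of metal resistance genes,
    derives TPM-normalized gene and transcript functional profiles and RNA:DNA
    expression ratios, applies genome-quality and dereplication filters to
    metagenome-assembled genomes, and simulates gene catalogs and read-count
    matrices with known ground truth so every stage is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
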