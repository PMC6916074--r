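Package: phenonet
Title: Shared Genetic Architecture Networks Across Quantitative Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovers shared genetic structure among many quantitative
    biochemical traits. Provides per-trait association scans with
    principal-component and age adjustment, genomic-control diagnostics,
    three complementary trait-trait correlation measures (phenotypic
    correlation, a molecular comorbidity index over protein-protein
    interaction networks, and cross-trait LD score regression), their
    integration into a trait network with hub tiers, and SNP- and
    gene-level pleiotropy tables. Ships a synthetic cohort generator with
    LD-blocked genotypes, sparse pleiotropic architectures and known
    ground truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    yaml
Config/testthat/edition: 3
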