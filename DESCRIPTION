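Package: asnvkit
Title: Archaic Variant Carrier Discovery and Phenotype Comparison for
    Biobank Exome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for studying carriers of archaic
    single-nucleotide variants (aSNVs) in biobank-scale exome data:
    curation of an aSNV catalog, carrier discovery from VCF genotypes
    under explicit genotype quality control with sex-aware chromosome-X
    zygosity, ancestry supercluster assignment from self-report harmonized
    with genetic principal components, carrier-prioritized relatedness
    pruning, matched noncarrier cohort construction under exact
    constraints and calipers, phenotype summaries with Wilson binomial
    intervals and frontal-lobe composites, and rare-variant association
    power under the additive one-degree-of-freedom chi-square model. A
    seeded synthetic-cohort generator emulates the statistical structure
    of restricted biobank holdings so that every stage is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
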