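Package: mitosomatic
Title: Somatic Mitochondrial DNA Mutation Profiling for Matched
    Tumor, Normal and Extracellular-Vesicle Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for profiling somatic mitochondrial DNA (mtDNA)
    mutations from deep-coverage variant calls in matched normal, tumor
    and circulating extracellular-vesicle (EV) samples. Provides an
    embedded rCRS (NC_012920.1) gene map with respiratory-complex
    assignments, read-support filtering and matched-normal somatic
    calling with haplogroup-marker exclusion, heteroplasmy/homoplasmy
    classification, transition-transversion spectrum and hotspot-panel
    statistics, per-group mutational loads, tumor-EV concordance
    measures, and a seeded synthetic cohort generator with a
    ground-truth ledger for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
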