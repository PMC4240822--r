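Package: trioprior
Title: Trio-Based Candidate-Gene Variant Prioritization for Dominant
    Mendelian Disease
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Variant prioritization for nuclear families segregating an
    autosomal dominant trait with a curated candidate-gene panel, as used in
    trio exome studies of inherited cataract. Implements panel intersection,
    dominant co-segregation filtering against a pedigree, population
    minor-allele-frequency exclusion, HGVS cDNA/protein consequence
    annotation with mature-protein renumbering, cross-species conservation
    scoring, and threshold classification of external predictor scores, with
    an auditable per-variant filter trail. Includes a synthetic family
    generator (Hardy-Weinberg founders, Mendelian transmission, one planted
    fully-penetrant causal variant) for verifying the cascade, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
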