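Package: Ylineage
Title: Y-Chromosome Lineage Reconstruction from Targeted Capture Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building high-resolution Y-chromosomal haplogroup
    phylogenies from haploid sequencing evidence. Implements strict
    base-majority variant calling on per-position pileup evidence, pairwise
    compatibility classification of binary Y-SNPs under missing data with
    contradiction and ambiguity filtering, assembly of the surviving variants
    into a rooted branch hierarchy, anchoring of the inferred hierarchy to a
    named reference tree with lineage-based nomenclature, per-sample haplogroup
    assignment, and capture-enrichment quality statistics. A synthetic lineage
    and sequencing simulator with ground truth supports recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    BiocGenerics,
    SummarizedExperiment,
    VariantAnnotation,
    ape
Suggests:
    withr,
    jsonlite,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
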