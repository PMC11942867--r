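Package: sarcOGM
Title: Interpretation of Optical Genome Mapping Structural Variant Calls in Sarcomas
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Interpretation pipeline for optical genome mapping (OGM) call sets
    from soft-tissue and bone sarcomas. Provides readers for SV/CNV call tables
    (BEDPE, SMAP-like TSV, VCF breakends), sample quality and evaluability
    gating, gene-panel prioritization of structural and copy-number variants,
    gene-fusion inference with breakend-orientation compatibility, detection of
    chromoplexy chains and chromothripsis regions, ISCN-style nomenclature for
    reported events, expected-alteration matching against sarcoma subtype rules,
    and a deterministic synthetic-cohort generator with ground-truth labels for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    BiocGenerics,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    optparse
Config/testthat/edition: 3
biocViews: StructuralVariation, CopyNumberVariation, Sequencing, Software
RoxygenNote: 7.3.3
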