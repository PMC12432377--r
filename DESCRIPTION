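Package: tcrtrack
Title: Tracking Tumor-Reactive T-Cell Receptor Repertoires from Blood to Tumor
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies tumor-reactive CD8 T-cell repertoires from bulk TCR
    sequencing. Reads clonotype tables (AIRR rearrangement or MiXCR-export
    TSV), applies abundance filtering, and computes repertoire descriptive
    statistics (unique clonotypes, Shannon diversity, V-J gene usage, top-N
    clonal occupancy, pairwise shared-CDR3 overlap). Re-implements
    GLIPH2-style specificity grouping of CDR3 sequences (enriched local
    motifs plus same-length one-mismatch global similarity) and uses the
    resulting clusters to track blood-derived tumor-reactive clonotypes into
    tumor-infiltrating lymphocyte repertoires, exactly and by cluster
    extension. Annotates pathogen-specific clonotypes against a VDJdb-format
    epitope table under patient HLA restriction. Includes the accompanying
    assay formulas (relative proliferation, percent cytotoxicity, Poisson
    sampling adequacy, antigen-expression cutoffs), a binned-control
    gene-signature module score for single-cell expression matrices, a
    ground-truth synthetic cohort generator, and an end-to-end pipeline
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    Matrix,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    Seurat
Config/testthat/edition: 3
RoxygenNote: 7.3.3
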