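Package: cnatrace
Title: Copy-Number-Aberrant Cell Identification and Progression
    Signatures from Single-Cell Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers per-cell copy-number-aberration (CNA) profiles from
    single-cell RNA-seq expression by reference-centered, genome-ordered
    window smoothing, and designates CNA-high malignant cells with a
    dual-correlation rule against averaged aberrant and normal reference
    profiles. Also provides QC filtering, log-normalization and scaling,
    variable-gene selection, marker-based cell typing, gene-signature
    scoring, Wilcoxon rank-sum differential expression with
    Benjamini-Hochberg correction, conserved-marker detection across
    disease states, per-cluster binomial regression of cell-type
    composition shifts with batch covariates, upper-quartile bulk
    normalization, nearest-centroid intrinsic subtyping, cross-species
    signature translation through ortholog tables, and a seeded
    negative-binomial simulator with planted arm-level CNA segments and
    expression programs that supplies ground truth for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3), SummarizedExperiment, SingleCellExperiment
Imports: methods, stats, utils, Matrix, S4Vectors, IRanges,
    GenomicRanges, withr
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'simulate.R'
    'simulate-bulk.R'
    'io.R'
    'preprocess.R'
    'cna.R'
    'classify.R'
    'signatures.R'
    'composition.R'
    'subtyping.R'
    'cnatrace-package.R'
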