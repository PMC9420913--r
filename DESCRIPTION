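Package: tfscout
Title: Cluster-Specific Transcription Factor Discovery from Single-Cell UMI Counts
Version: 0.1.0
Authors@R:
    person("MEC", "Transcriptomics Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline that takes a gene-by-cell UMI count matrix to
    ranked cluster-specific transcription-factor candidates: empty-droplet and
    ambient-gene quality control, log-normalization, variance-decomposition
    selection of highly variable genes, PCA, mutual-nearest-neighbor batch
    correction, shared-nearest-neighbor Louvain clustering, cell-cycle phase
    scoring, detection-based F1 marker ranking, Wilcoxon rank-sum differential
    expression with detection-fraction filtering, and checklist-based
    transcription-factor candidate selection.  Also provides centroid-consensus
    projection of query cells onto an annotated reference, lentiviral titering
    by the Xo method (standard curve, VPD, titer), and 2^-ddCt relative
    expression analysis with Welch's t-test.  A synthetic-data module generates
    multi-batch negative-binomial counts with planted clusters, markers,
    transcription factors, ambient contamination and cell-cycle programs, plus
    log-linear qPCR Ct tables, so the whole pipeline is testable offline with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    graphics,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
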