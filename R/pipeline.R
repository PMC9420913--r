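#' Assemble a pipeline configuration
#'
#' Collects the inputs and per-stage parameters of the end-to-end analysis:
#' quality control, normalization, HVG selection, PCA, MNN batch correction,
#' SNN-Louvain clustering, cell-cycle scoring, F1 marker ranking, Wilcoxon
#' differential expression and TF-candidate selection.  Inputs may be given
#' in memory (a `CountMatrix`, character vectors) or as paths (a 10x triplet
#' directory, one-symbol-per-line gene lists).
#'
#' @param counts a [count_matrix()] or a path to a 10x-style MTX directory.
#' @param tf_checklist character vector of TF symbols or a gene-list path.
#' @param s_genes,g2m_genes cell-cycle program symbols or gene-list paths;
#'   `NULL` skips cell-cycle scoring.
#' @param exclusion_sets named list of marker gene sets used to gate out
#'   unwanted cells (e.g. hemoglobin genes for red blood cells); `NULL`
#'   skips gating.
#' @param qc a [qc_params()] object.
#' @param mnn an [mnn_params()] object.
#' @param clustering a [cluster_params()] object (its seed is overridden by
#'   the pipeline seed fan-out).
#' @param n_pcs number of principal components (default 50).
#' @param min_pct,top_n,pseudocount differential-expression and TF-selection
#'   knobs (defaults 0.25, 20, 1).
#' @param min_detected marker-gating threshold (default 1 detected gene).
#' @param seed master seed; each stochastic stage derives its own stream.
#' @param out_dir output directory for per-stage TSVs and the manifest.
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(counts, tf_checklist, s_genes = NULL,
                            g2m_genes = NULL, exclusion_sets = NULL,
                            qc = qc_params(), mnn = mnn_params(),
                            clustering = cluster_params(),
                            n_pcs = 50L, min_pct = 0.25, top_n = 20L,
                            pseudocount = 1, min_detected = 1L,
                            seed = 1L, out_dir = tempfile("tfscout_run_")) {
  as_genes <- function(x) if (is.character(x) && length(x) == 1L &&
                              file.exists(x)) read_gene_list(x) else x
  structure(list(counts = counts,
                 tf_checklist = as_genes(tf_checklist),
                 s_genes = as_genes(s_genes), g2m_genes = as_genes(g2m_genes),
                 exclusion_sets = exclusion_sets,
                 qc = qc, mnn = mnn, clustering = clustering,
                 n_pcs = as.integer(n_pcs), min_pct = min_pct,
                 top_n = as.integer(top_n), pseudocount = pseudocount,
                 min_detected = as.integer(min_detected),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "PipelineConfig")
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full marker/TF discovery pipeline
#'
#' Executes, in order: empty-droplet detection, ambient-gene flagging,
#' optional marker-based cell exclusion, log-normalization,
#' variance-decomposition HVG selection, PCA, MNN batch correction (when
#' more than one batch is present), SNN-Louvain clustering, optional
#' cell-cycle scoring, and per-cluster F1 marker ranking, Wilcoxon
#' differential expression and TF-candidate selection.  Per-stage TSV tables
#' and a JSON run manifest (parameters, seed, versions) are written to
#' `config$out_dir`; a stage failure aborts with the stage name.
#'
#' @param config a [pipeline_config()] object.
#' @return invisibly, a report list: `n_barcodes`, `n_empties`,
#'   `n_ambient_genes`, `n_cells_retained`, `cluster_sizes`,
#'   `clusters` (the `ClusterAssignment`), `hvg_table`, `cell_cycle`,
#'   `markers` / `de` / `tf_candidates` (per-cluster lists), `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "load"
  report <- list(out_dir = cfg$out_dir)
  t0 <- Sys.time()
  timings <- list()
  tick <- function(name) {
    timings[[name]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 3)
    t0 <<- Sys.time()
  }
  run_stage <- function(name, expr) {
    stage <<- name
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    tick(name)
    res
  }

  counts <- run_stage("load", {
    if (inherits(cfg$counts, "CountMatrix")) cfg$counts else read_10x(cfg$counts)
  })
  report$n_barcodes <- ncol(counts$counts)

  empties <- run_stage("empty_droplets", detect_empty_droplets(counts, cfg$qc))
  ambient <- run_stage("ambient_genes", flag_ambient_genes(counts, empties, cfg$qc))
  report$n_empties <- length(empties)
  report$n_ambient_genes <- length(ambient)

  cells <- run_stage("drop_empties", {
    keep <- setdiff(colnames(counts$counts), empties)
    if (!length(keep)) abort_input("every barcode is an empty droplet")
    subset_count_matrix(counts, barcodes = keep)
  })
  if (!is.null(cfg$exclusion_sets))
    cells <- run_stage("marker_gating",
                       exclude_cells_by_markers(cells, cfg$exclusion_sets,
                                                cfg$min_detected))
  report$n_cells_retained <- ncol(cells$counts)

  norm <- run_stage("normalize", log_normalize(cells, cfg$qc))
  hvg <- run_stage("hvg", decompose_variance(norm, ambient, cfg$qc))
  emb <- run_stage("pca", run_pca(norm, hvg$gene[hvg$selected], cfg$n_pcs))
  if (length(unique(cells$batch)) > 1L)
    emb <- run_stage("mnn", mnn_correct(emb, cfg$mnn))

  cl_params <- cfg$clustering
  cl_params$seed <- sub_seed(cfg$seed, "louvain")
  graph <- run_stage("snn", build_snn_graph(emb, cl_params))
  clusters <- run_stage("louvain", louvain_cluster(graph, cl_params))
  report$cluster_sizes <- as.list(table(clusters$labels))
  report$clusters <- clusters

  cc <- NULL
  if (!is.null(cfg$s_genes) && !is.null(cfg$g2m_genes))
    cc <- run_stage("cell_cycle",
                    score_cell_cycle(norm, cfg$s_genes, cfg$g2m_genes,
                                     seed = sub_seed(cfg$seed, "cc")))
  report$cell_cycle <- cc

  labels <- sort(unique(clusters$labels))
  markers <- de <- tfs <- stats::setNames(vector("list", length(labels)),
                                          as.character(labels))
  for (k in labels) {
    key <- as.character(k)
    markers[[key]] <- run_stage(paste0("f1_markers_", k),
                                f1_marker_scores(cells, clusters, k))
    de[[key]] <- run_stage(paste0("wilcoxon_de_", k),
                           wilcoxon_de(norm, clusters, k,
                                       min_pct = cfg$min_pct,
                                       pseudocount = cfg$pseudocount))
    tfs[[key]] <- run_stage(paste0("tf_select_", k),
                            suppressWarnings(
                              select_candidate_tfs(de[[key]], cfg$tf_checklist,
                                                   top_n = cfg$top_n,
                                                   cluster = k)))
  }
  report$markers <- markers
  report$de <- de
  report$tf_candidates <- tfs
  report$hvg_table <- hvg

  stage <- "write"
  .write_tsv(hvg, file.path(cfg$out_dir, "hvg_table.tsv"))
  .write_tsv(data.frame(barcode = names(clusters$labels),
                        cluster = unname(clusters$labels)),
             file.path(cfg$out_dir, "clusters.tsv"))
  if (!is.null(cc)) .write_tsv(cc, file.path(cfg$out_dir, "cell_cycle.tsv"))
  for (k in labels) {
    key <- as.character(k)
    .write_tsv(utils::head(markers[[key]], 50),
               file.path(cfg$out_dir, sprintf("markers_cluster_%s.tsv", key)))
    .write_tsv(de[[key]],
               file.path(cfg$out_dir, sprintf("de_cluster_%s.tsv", key)))
  }
  .write_tsv(do.call(rbind, tfs), file.path(cfg$out_dir, "tf_candidates.tsv"))
  qc_report <- data.frame(metric = c("barcodes", "empty_droplets",
                                     "ambient_genes", "cells_retained",
                                     "clusters", "modularity"),
                          value = c(report$n_barcodes, report$n_empties,
                                    report$n_ambient_genes,
                                    report$n_cells_retained,
                                    length(labels),
                                    round(clusters$modularity, 6)))
  .write_tsv(qc_report, file.path(cfg$out_dir, "qc_report.tsv"))
  manifest <- list(
    seed = cfg$seed,
    parameters = list(qc = unclass(cfg$qc), mnn = unclass(cfg$mnn),
                      clustering = unclass(cl_params), n_pcs = cfg$n_pcs,
                      min_pct = cfg$min_pct, top_n = cfg$top_n,
                      pseudocount = cfg$pseudocount),
    versions = list(R = as.character(getRversion()),
                    tfscout = as.character(utils::packageVersion("tfscout"))),
    timings_sec = timings,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}
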