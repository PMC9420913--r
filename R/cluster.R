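#' Clustering parameters
#'
#' @param k_neighbors neighborhood size for the shared-nearest-neighbor
#'   graph (default 20).
#' @param prune_jaccard edges with Jaccard weight less than or equal to this
#'   value are removed (default 1/15).
#' @param resolution Louvain resolution; larger values give more, smaller
#'   clusters.  Typical single-cell analyses use values around 1.0-1.6.
#' @param seed integer seed fixing the Louvain sweep.
#' @return a validated `ClusterParams` list.
#' @export
cluster_params <- function(k_neighbors = 20L, prune_jaccard = 1 / 15,
                           resolution = 1.6, seed = 1L) {
  if (resolution <= 0) abort_input("resolution must be positive")
  if (prune_jaccard < 0 || prune_jaccard >= 1)
    abort_input("prune_jaccard must lie in [0, 1)")
  if (k_neighbors < 1L) abort_input("k_neighbors must be >= 1")
  structure(list(k_neighbors = as.integer(k_neighbors),
                 prune_jaccard = prune_jaccard,
                 resolution = resolution,
                 seed = as.integer(seed)),
            class = "ClusterParams")
}

#' Build a shared-nearest-neighbor graph
#'
#' Each cell's neighborhood is itself plus its `k_neighbors` nearest cells in
#' the embedding (Euclidean distance, ties broken by index).  Edge weight
#' between two cells is the Jaccard overlap of their neighborhoods; edges
#' with weight less than or equal to `prune_jaccard` are removed.
#'
#' @param emb an `Embedding` (see [run_pca()], [mnn_correct()]).
#' @param params a [cluster_params()] object.
#' @return a weighted undirected [igraph::graph] whose vertex names are the
#'   cell barcodes.
#' @export
build_snn_graph <- function(emb, params = cluster_params()) {
  stopifnot(inherits(emb, "Embedding"), inherits(params, "ClusterParams"))
  x <- emb$coordinates
  n <- nrow(x)
  if (params$k_neighbors >= n)
    abort_input("k_neighbors must be smaller than the number of cells")
  k <- params$k_neighbors
  d2 <- outer(rowSums(x^2), rowSums(x^2), "+") - 2 * tcrossprod(x)
  diag(d2) <- Inf
  nn <- apply(d2, 1L, function(r) order(r)[seq_len(k)])
  nn <- if (k == 1L) matrix(nn, ncol = 1L) else t(nn)
  # sparse membership matrix: cell x cell, neighborhood includes self
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), k + 1L),
                              j = c(as.vector(nn), seq_len(n)),
                              x = 1, dims = c(n, n))
  inter <- Matrix::tcrossprod(adj)
  inter <- methods::as(methods::as(inter, "generalMatrix"), "TsparseMatrix")
  keep <- inter@i < inter@j
  i <- inter@i[keep] + 1L
  j <- inter@j[keep] + 1L
  w <- inter@x[keep] / (2 * (k + 1L) - inter@x[keep])
  ok <- w > params$prune_jaccard
  g <- igraph::graph_from_data_frame(
    data.frame(from = i[ok], to = j[ok], weight = w[ok]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  igraph::V(g)$name <- rownames(x) %||% as.character(seq_len(n))
  g
}

#' Louvain community detection on a shared-nearest-neighbor graph
#'
#' Runs multi-level (Louvain) modularity optimization with the resolution
#' parameter scaling the null-model term.  The seed fixes the traversal
#' order, so identical input and seed give identical labels.
#'
#' @param graph a weighted [igraph::graph], as from [build_snn_graph()].
#' @param params a [cluster_params()] object.
#' @return a `ClusterAssignment`: list with `labels` (named integer vector,
#'   contiguous from 0), `modularity` and `params`.
#' @export
louvain_cluster <- function(graph, params = cluster_params()) {
  stopifnot(inherits(graph, "igraph"), inherits(params, "ClusterParams"))
  if (igraph::vcount(graph) == 0L) abort_input("graph has no vertices")
  if (igraph::ecount(graph) == 0L) {
    warning("graph has no edges: every cell becomes its own cluster")
    labels <- seq_len(igraph::vcount(graph)) - 1L
    names(labels) <- igraph::V(graph)$name
    return(structure(list(labels = labels, modularity = 0, params = params),
                     class = "ClusterAssignment"))
  }
  set.seed(params$seed)
  comm <- igraph::cluster_louvain(graph, resolution = params$resolution)
  mem <- igraph::membership(comm)
  # relabel contiguously from 0, largest cluster first (stable tie-break)
  sizes <- table(mem)
  new_of_old <- stats::setNames(seq_along(sizes) - 1L,
                                names(sizes)[order(-sizes, as.integer(names(sizes)))])
  labels <- unname(new_of_old[as.character(mem)])
  names(labels) <- igraph::V(graph)$name
  structure(list(labels = labels,
                 modularity = igraph::modularity(graph, mem,
                                                 weights = igraph::E(graph)$weight),
                 params = params),
            class = "ClusterAssignment")
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat(sprintf("ClusterAssignment: %d cells in %d clusters (modularity %.3f, resolution %g)\n",
              length(x$labels), length(unique(x$labels)), x$modularity,
              x$params$resolution))
  invisible(x)
}

#' Score cell-cycle phases from S and G2M gene programs
#'
#' For each phase gene set, the score of a cell is the mean log-normalized
#' expression of the set genes minus the mean of control genes drawn from
#' the same expression bins: genes are binned into `n_bins` by their mean
#' expression across cells and `n_ctrl` controls are sampled per set gene
#' (with the given seed).  A cell's phase is the arg-max of (S, G2M) when
#' that maximum is positive, else G1; an exact positive tie is called G2M.
#'
#' @param norm a [log_normalize()] result.
#' @param s_genes,g2m_genes character vectors of phase-program gene symbols;
#'   symbols absent from the matrix are dropped with a warning (all absent is
#'   an error).
#' @param n_bins number of mean-expression bins (default 25).
#' @param n_ctrl control genes sampled per program gene (default 50).
#' @param seed integer seed for control sampling.
#' @return a `CellCycleScore` data.frame: `cell`, `s_score`, `g2m_score`,
#'   `phase` (one of `"S"`, `"G2M"`, `"G1"`).
#' @export
score_cell_cycle <- function(norm, s_genes, g2m_genes, n_bins = 25L,
                             n_ctrl = 50L, seed = 1L) {
  stopifnot(inherits(norm, "NormalizedMatrix"))
  all_genes <- rownames(norm$values)
  clean <- function(set, label) {
    set <- unique(upper_symbols(set))
    miss <- setdiff(set, all_genes)
    if (length(miss) == length(set))
      abort_input("no ", label, " program gene found in the matrix")
    if (length(miss))
      warning(sprintf("%d %s program symbol(s) not in the matrix, dropped",
                      length(miss), label))
    intersect(set, all_genes)
  }
  s_genes <- clean(s_genes, "S")
  g2m_genes <- clean(g2m_genes, "G2M")

  gene_means <- Matrix::rowSums(norm$values) / ncol(norm$values)
  n_bins <- min(n_bins, length(all_genes))
  br <- unique(stats::quantile(gene_means, probs = seq(0, 1, length.out = n_bins + 1L)))
  bin <- cut(gene_means, breaks = br, include.lowest = TRUE, labels = FALSE)

  set.seed(sub_seed(seed, "cellcycle"))
  score_set <- function(set) {
    ctrl <- unlist(lapply(set, function(g) {
      pool <- all_genes[bin == bin[match(g, all_genes)]]
      sample(pool, min(n_ctrl, length(pool)), replace = FALSE)
    }), use.names = FALSE)
    set_mean <- Matrix::colSums(norm$values[set, , drop = FALSE]) / length(set)
    ctrl_mean <- Matrix::colSums(norm$values[unique(ctrl), , drop = FALSE]) /
      length(unique(ctrl))
    set_mean - ctrl_mean
  }
  s <- score_set(s_genes)
  g2m <- score_set(g2m_genes)
  # arg-max of (S, G2M) when positive, else G1; exact positive tie -> G2M
  phase <- ifelse(pmax(s, g2m) > 0, ifelse(g2m >= s, "G2M", "S"), "G1")
  data.frame(cell = colnames(norm$values), s_score = s, g2m_score = g2m,
             phase = phase, stringsAsFactors = FALSE, row.names = NULL)
}
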