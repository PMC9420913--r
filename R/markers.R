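#' Detection-based F1 marker scores for one cluster
#'
#' A gene is "detected" in a cell when at least one UMI is counted.  For a
#' cluster c and gene g, a cell contributes TP if it is in c and detects g,
#' FN if in c without detecting g, FP if outside c and detecting g, TN
#' otherwise.  Precision = TP/(TP+FP), recall = TP/(TP+FN) and
#' F1 = 2PR/(P+R), each defined as 0 when its denominator is 0.  Genes are
#' returned ranked by F1 (descending), ties broken by precision then symbol.
#'
#' @param counts a [count_matrix()] restricted to real cells.
#' @param clusters a `ClusterAssignment` (or a named label vector covering
#'   every barcode of `counts`).
#' @param cluster the cluster label to score.
#' @return a `MarkerScoreTable` data.frame: `gene`, `cluster`, `TP`, `FP`,
#'   `FN`, `TN`, `precision`, `recall`, `f1`, ordered by rank.
#' @export
f1_marker_scores <- function(counts, clusters, cluster) {
  stopifnot(inherits(counts, "CountMatrix"))
  labels <- .cluster_labels(clusters, colnames(counts$counts))
  in_c <- labels == cluster
  n_in <- sum(in_c)
  if (n_in == 0L) abort_input("cluster '", cluster, "' is empty or unknown")
  det <- counts$counts >= 1
  tp <- Matrix::rowSums(det[, in_c, drop = FALSE])
  fp <- Matrix::rowSums(det[, !in_c, drop = FALSE])
  fn <- n_in - tp
  tn <- sum(!in_c) - fp
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  tab <- data.frame(gene = rownames(counts$counts), cluster = cluster,
                    TP = tp, FP = fp, FN = fn, TN = tn,
                    precision = precision, recall = recall, f1 = f1,
                    stringsAsFactors = FALSE, row.names = NULL)
  tab <- tab[order(-tab$f1, -tab$precision, tab$gene, method = "radix"), ]
  rownames(tab) <- NULL
  class(tab) <- c("MarkerScoreTable", "data.frame")
  tab
}

.cluster_labels <- function(clusters, barcodes) {
  labels <- if (inherits(clusters, "ClusterAssignment")) clusters$labels else clusters
  if (!is.null(names(labels))) {
    idx <- match(barcodes, names(labels))
    if (anyNA(idx)) abort_input("cluster labels do not cover every barcode")
    labels <- labels[idx]
  } else if (length(labels) != length(barcodes)) {
    abort_input("cluster labels do not match the number of barcodes")
  }
  if (anyNA(labels)) abort_input("cluster labels contain NA")
  labels
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Uses exhaustive permutation enumeration when both groups have at most
#' `exact_limit` observations (exact even under ties), and a tie-corrected
#' normal approximation otherwise.
#'
#' @param x,y numeric vectors for the two groups.
#' @param exact_limit largest per-group size for exact enumeration
#'   (default 8).
#' @return a p-value in (0, 1].
#' @export
wilcoxon_rank_sum <- function(x, y, exact_limit = 8L) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n1 == 0L || n2 == 0L) abort_input("both groups must be non-empty")
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  ew <- n1 * (n + 1) / 2
  if (n1 <= exact_limit && n2 <= exact_limit) {
    # enumerate all assignments of n1 ranks out of n; exact under ties
    combs <- utils::combn(n, n1)
    ws <- colSums(matrix(r[combs], nrow = n1))
    return(mean(abs(ws - ew) >= abs(w - ew) - 1e-12))
  }
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (w - ew) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Wilcoxon differential expression of one cluster against the rest
#'
#' For each gene detected (value > 0) in at least `min_pct` of the cells of
#' the cluster or of the rest, computes a two-sided Wilcoxon rank-sum
#' p-value (tie-corrected), the natural-log fold change of average
#' de-logged expression
#' `ln[(mean(expm1(x_in)) + pseudocount) / (mean(expm1(x_out)) + pseudocount)]`,
#' the detection fractions, and a Bonferroni-adjusted p-value over the
#' tested genes.  A gene constant across all cells gets p = 1 and
#' log fold change 0.
#'
#' @param norm a [log_normalize()] result.
#' @param clusters a `ClusterAssignment` (or named label vector).
#' @param cluster the cluster to test against all remaining cells.
#' @param min_pct minimum detection fraction in either group (default 0.25).
#' @param pseudocount added to both de-logged means before the ratio
#'   (default 1).
#' @return a `DeTable` data.frame: `gene`, `p_value`, `avg_logfc`, `pct_in`,
#'   `pct_out`, `adjusted_p`, ordered by `p_value` then gene.
#' @export
wilcoxon_de <- function(norm, clusters, cluster, min_pct = 0.25,
                        pseudocount = 1) {
  stopifnot(inherits(norm, "NormalizedMatrix"))
  labels <- .cluster_labels(clusters, colnames(norm$values))
  in_c <- labels == cluster
  if (!any(in_c) || all(in_c))
    abort_input("both the cluster and the remaining cells must be non-empty")
  m <- norm$values
  pct_in <- Matrix::rowSums(m[, in_c, drop = FALSE] > 0) / sum(in_c)
  pct_out <- Matrix::rowSums(m[, !in_c, drop = FALSE] > 0) / sum(!in_c)
  test <- pmax(pct_in, pct_out) >= min_pct
  genes <- rownames(m)[test]
  if (!length(genes)) {
    warning("no gene passes the detection-fraction filter")
    out <- data.frame(gene = character(0), p_value = numeric(0),
                      avg_logfc = numeric(0), pct_in = numeric(0),
                      pct_out = numeric(0), adjusted_p = numeric(0))
    class(out) <- c("DeTable", "data.frame")
    return(out)
  }
  sub <- as.matrix(m[genes, , drop = FALSE])
  mean_in <- rowMeans(expm1(sub[, in_c, drop = FALSE]))
  mean_out <- rowMeans(expm1(sub[, !in_c, drop = FALSE]))
  logfc <- log((mean_in + pseudocount) / (mean_out + pseudocount))
  p <- vapply(seq_along(genes), function(i) {
    v <- sub[i, ]
    if (max(v) == min(v)) return(1)
    wilcoxon_rank_sum(v[in_c], v[!in_c])
  }, numeric(1))
  logfc[apply(sub, 1L, function(v) max(v) == min(v))] <- 0
  out <- data.frame(gene = genes, p_value = p, avg_logfc = logfc,
                    pct_in = pct_in[test], pct_out = pct_out[test],
                    adjusted_p = stats::p.adjust(p, method = "bonferroni"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$p_value, out$gene, method = "radix"), ]
  rownames(out) <- NULL
  class(out) <- c("DeTable", "data.frame")
  out
}

#' Select transcription-factor candidates from a differential table
#'
#' Keeps only genes whose symbols perfectly match (exact string equality
#' after uppercasing) an entry of the TF checklist, orders them by average
#' log fold change descending (ties by symbol) and truncates to the top
#' `top_n`.  Positive, raw (not absolute) log fold change is ranked: the
#' candidates of interest are enriched in the cluster.
#'
#' @param de a `DeTable` from [wilcoxon_de()].
#' @param tf_checklist character vector of TF symbols (e.g. from
#'   [read_gene_list()] on a curated DNA-binding RNA-polymerase-II TF
#'   export).
#' @param top_n maximum candidates returned (default 20).
#' @param cluster optional cluster label to record in the output.
#' @return a `TfCandidateList` data.frame: the matching `DeTable` rows with a
#'   `rank` column, at most `top_n` rows.
#' @export
select_candidate_tfs <- function(de, tf_checklist, top_n = 20L, cluster = NA) {
  stopifnot(is.data.frame(de))
  if (!length(tf_checklist)) abort_input("tf_checklist must be non-empty")
  checklist <- unique(upper_symbols(tf_checklist))
  hits <- de[upper_symbols(de$gene) %in% checklist, , drop = FALSE]
  if (nrow(hits) == 0L) {
    warning("no differential gene matches the TF checklist")
  } else if (nrow(hits) < top_n) {
    warning(sprintf("only %d eligible TF(s) for top_n = %d", nrow(hits), top_n))
  }
  hits <- hits[order(-hits$avg_logfc, hits$gene, method = "radix"), , drop = FALSE]
  hits <- utils::head(hits, top_n)
  hits$rank <- seq_len(nrow(hits))
  hits$cluster <- rep(cluster, nrow(hits))
  rownames(hits) <- NULL
  class(hits) <- c("TfCandidateList", "data.frame")
  hits
}
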