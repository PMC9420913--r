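# Shared fixture builders. Everything is generated in code; no binary data.

# tiny CountMatrix from a dense integer matrix (genes x barcodes)
toy_counts <- function(m, genes = NULL, barcodes = NULL, batch = "batch1",
                       stage = NULL) {
  genes <- genes %||% sprintf("G%03d", seq_len(nrow(m)))
  barcodes <- barcodes %||% sprintf("BC%03d", seq_len(ncol(m)))
  count_matrix(Matrix::Matrix(m, sparse = TRUE), gene_symbols = genes,
               barcode_ids = barcodes, batch = batch, stage = stage)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# a small random CountMatrix with a fixed seed
random_counts <- function(n_genes = 30, n_cells = 20, seed = 42,
                          lambda = 2, batch = "batch1") {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_cells, lambda), nrow = n_genes)
  toy_counts(m, batch = batch)
}

# a NormalizedMatrix straight from a dense matrix of counts
toy_norm <- function(m, ...) log_normalize(toy_counts(m, ...), qc_params())

# an Embedding from raw coordinates (bypasses PCA)
toy_embedding <- function(coords, batch = rep("b1", nrow(coords)),
                          corrected = FALSE) {
  rownames(coords) <- rownames(coords) %||% sprintf("C%03d", seq_len(nrow(coords)))
  structure(list(coordinates = coords, sdev = NULL, var_explained = NULL,
                 batch = batch, corrected = corrected),
            class = "Embedding")
}

# brute-force confusion-matrix oracle for the F1 marker score
oracle_f1 <- function(counts_dense, in_cluster, gene_row) {
  det <- counts_dense[gene_row, ] >= 1
  tp <- sum(det & in_cluster); fp <- sum(det & !in_cluster)
  fn <- sum(!det & in_cluster); tn <- sum(!det & !in_cluster)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(TP = tp, FP = fp, FN = fn, TN = tn, precision = p, recall = r, f1 = f1)
}

# exhaustive two-sided rank-sum p-value oracle (all C(n, n1) assignments)
oracle_wilcoxon_exact <- function(x, y) {
  r <- rank(c(x, y))
  n1 <- length(x); n <- length(r)
  w <- sum(r[seq_len(n1)])
  ew <- n1 * (n + 1) / 2
  ws <- combn(n, n1, function(ix) sum(r[ix]))
  mean(abs(ws - ew) >= abs(w - ew) - 1e-12)
}
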