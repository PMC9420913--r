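#' Construct a CountMatrix
#'
#' The package's basic container: a sparse gene-by-barcode UMI count matrix
#' with unique gene symbols, unique barcode identifiers and per-barcode batch
#' (and optionally developmental stage) labels.  Counts must be non-negative
#' integers; gene symbols are uppercased on construction so that all
#' downstream symbol matching is case-insensitive.
#'
#' @param counts a matrix or [Matrix::sparseMatrix()] of non-negative integer
#'   counts, genes in rows, barcodes in columns.  Row and column names are
#'   used as gene symbols / barcode ids when `gene_symbols` / `barcode_ids`
#'   are not given.
#' @param gene_symbols character vector of gene symbols (unique after
#'   uppercasing).
#' @param barcode_ids character vector of unique barcode identifiers.
#' @param batch per-barcode batch labels (recycled if length 1).
#' @param stage optional per-barcode stage labels.
#' @return an object of class `CountMatrix`: a list with elements `counts`
#'   (a `dgCMatrix`), `batch` and `stage`.
#' @export
count_matrix <- function(counts, gene_symbols = rownames(counts),
                         barcode_ids = colnames(counts),
                         batch = "batch1", stage = NULL) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(gene_symbols) || is.null(barcode_ids))
    abort_input("gene symbols and barcode ids are required (as dimnames or arguments)")
  gene_symbols <- upper_symbols(gene_symbols)
  barcode_ids <- as.character(barcode_ids)
  if (length(gene_symbols) != nrow(counts) || length(barcode_ids) != ncol(counts))
    abort_input("label vectors do not match matrix dimensions")
  if (anyDuplicated(gene_symbols))
    abort_input("gene symbols must be unique after uppercasing")
  if (anyDuplicated(barcode_ids))
    abort_input("barcode ids must be unique")
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x))))
    abort_input("counts must be non-negative integers")
  if (length(batch) == 1L) batch <- rep(batch, ncol(counts))
  if (length(batch) != ncol(counts))
    abort_input("batch labels do not match the number of barcodes")
  if (!is.null(stage) && length(stage) != ncol(counts))
    abort_input("stage labels do not match the number of barcodes")
  dimnames(counts) <- list(gene_symbols, barcode_ids)
  structure(list(counts = counts,
                 batch = as.character(batch),
                 stage = if (is.null(stage)) NULL else as.character(stage)),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d barcodes, %d batch(es), %s UMIs total\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$batch)),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Subset a CountMatrix by barcodes and/or genes
#'
#' @param x a `CountMatrix`.
#' @param barcodes barcode ids or column indices to keep (`NULL` keeps all).
#' @param genes gene symbols or row indices to keep (`NULL` keeps all).
#' @return a new `CountMatrix`; the input is untouched.
#' @export
subset_count_matrix <- function(x, barcodes = NULL, genes = NULL) {
  stopifnot(inherits(x, "CountMatrix"))
  bi <- if (is.null(barcodes)) seq_len(ncol(x$counts)) else {
    if (is.character(barcodes)) match(barcodes, colnames(x$counts)) else barcodes
  }
  gi <- if (is.null(genes)) seq_len(nrow(x$counts)) else {
    if (is.character(genes)) match(upper_symbols(genes), rownames(x$counts)) else genes
  }
  if (anyNA(bi)) abort_input("unknown barcode id in subset")
  if (anyNA(gi)) abort_input("unknown gene symbol in subset")
  count_matrix(x$counts[gi, bi, drop = FALSE],
               batch = x$batch[bi],
               stage = if (is.null(x$stage)) NULL else x$stage[bi])
}

#' Write a CountMatrix as a 10x-style MTX triplet
#'
#' Writes `matrix.mtx` (Matrix Market coordinate, integer), `barcodes.tsv`
#' and `features.tsv` into `dir`, plus `labels.tsv` with per-barcode batch
#' (and stage) labels.
#'
#' @param x a `CountMatrix`.
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_10x <- function(x, dir) {
  stopifnot(inherits(x, "CountMatrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  writeLines(colnames(x$counts), file.path(dir, "barcodes.tsv"))
  writeLines(rownames(x$counts), file.path(dir, "features.tsv"))
  lab <- data.frame(barcode = colnames(x$counts), batch = x$batch,
                    stage = if (is.null(x$stage)) NA_character_ else x$stage)
  utils::write.table(lab, file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a 10x-style MTX triplet into a CountMatrix
#'
#' Expects `matrix.mtx`, `barcodes.tsv` and `features.tsv` in `dir`;
#' `labels.tsv` (columns `barcode`, `batch`, optional `stage`) is read when
#' present, otherwise all barcodes are assigned a single batch.
#'
#' @param dir directory containing the triplet.
#' @return a `CountMatrix`.
#' @export
read_10x <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- readLines(file.path(dir, "features.tsv"))
  # tolerate the 10x two/three column features dialect: first column is the id
  genes <- vapply(strsplit(genes, "\t", fixed = TRUE), `[[`, "", 1L)
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  lab_file <- file.path(dir, "labels.tsv")
  batch <- "batch1"; stage <- NULL
  if (file.exists(lab_file)) {
    lab <- utils::read.delim(lab_file, stringsAsFactors = FALSE)
    idx <- match(barcodes, lab$barcode)
    if (anyNA(idx)) abort_input("labels.tsv does not cover all barcodes")
    batch <- lab$batch[idx]
    if ("stage" %in% names(lab) && !all(is.na(lab$stage))) stage <- lab$stage[idx]
  }
  count_matrix(m, gene_symbols = genes, barcode_ids = barcodes,
               batch = batch, stage = stage)
}

#' Read a one-symbol-per-line gene list
#'
#' Blank lines and `#` comments are ignored; symbols are uppercased.
#'
#' @param path file path.
#' @return character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- trimws(sub("#.*$", "", x))
  upper_symbols(x[nzchar(x)])
}
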