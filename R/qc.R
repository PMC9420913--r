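#' Quality-control and normalization parameters
#'
#' Thresholds are applied with strict inequalities: a barcode is an empty
#' droplet when its total UMI count is strictly below `empty_umi_threshold`,
#' and a gene is ambient when its share of counts in empty droplets is
#' strictly above `ambient_fraction_threshold`.
#'
#' @param empty_umi_threshold total-UMI cutoff below which a barcode is an
#'   empty droplet (default 50).
#' @param ambient_fraction_threshold fraction of a gene's total counts found
#'   in empty droplets above which it is flagged ambient (default 0.30).
#' @param normalization_scale_factor per-cell library size after scaling
#'   (default 10,000 UMIs).
#' @param n_hvgs number of highly variable genes to select.
#' @return a validated `QcParams` list.
#' @export
qc_params <- function(empty_umi_threshold = 50L,
                      ambient_fraction_threshold = 0.30,
                      normalization_scale_factor = 1e4,
                      n_hvgs = 1000L) {
  if (empty_umi_threshold < 1L) abort_input("empty_umi_threshold must be >= 1")
  if (ambient_fraction_threshold <= 0 || ambient_fraction_threshold >= 1)
    abort_input("ambient_fraction_threshold must lie in (0, 1)")
  if (normalization_scale_factor <= 0)
    abort_input("normalization_scale_factor must be positive")
  if (n_hvgs < 1L) abort_input("n_hvgs must be >= 1")
  structure(list(empty_umi_threshold = as.integer(empty_umi_threshold),
                 ambient_fraction_threshold = ambient_fraction_threshold,
                 normalization_scale_factor = normalization_scale_factor,
                 n_hvgs = as.integer(n_hvgs)),
            class = "QcParams")
}

#' Detect empty droplets by total UMI count
#'
#' @param counts a [count_matrix()].
#' @param params a [qc_params()] object.
#' @return character vector of barcode ids whose total UMI count is strictly
#'   below `empty_umi_threshold`.
#' @export
detect_empty_droplets <- function(counts, params = qc_params()) {
  stopifnot(inherits(counts, "CountMatrix"), inherits(params, "QcParams"))
  totals <- Matrix::colSums(counts$counts)
  colnames(counts$counts)[totals < params$empty_umi_threshold]
}

#' Flag ambient genes from empty-droplet counts
#'
#' A gene is ambient when the counts it accumulates in empty droplets exceed
#' `ambient_fraction_threshold` of its total counts over all barcodes
#' (strictly above).  Genes with zero total count are never flagged, and the
#' result is invariant to gene and barcode order.
#'
#' @param counts a [count_matrix()] (cells and empty droplets together).
#' @param empties character vector of empty-droplet barcode ids, as from
#'   [detect_empty_droplets()].
#' @param params a [qc_params()] object.
#' @return character vector of ambient gene symbols.
#' @export
flag_ambient_genes <- function(counts, empties, params = qc_params()) {
  stopifnot(inherits(counts, "CountMatrix"), inherits(params, "QcParams"))
  if (!all(empties %in% colnames(counts$counts)))
    abort_input("empties must be a subset of the matrix barcodes")
  total <- Matrix::rowSums(counts$counts)
  in_emp <- if (length(empties))
    Matrix::rowSums(counts$counts[, colnames(counts$counts) %in% empties,
                                  drop = FALSE])
  else rep(0, nrow(counts$counts))
  flagged <- total > 0 & in_emp > params$ambient_fraction_threshold * total
  rownames(counts$counts)[flagged]
}

#' Exclude cells by marker-gene gating
#'
#' Removes barcodes in which at least `min_detected` genes of any single
#' marker set are detected (count >= 1): the gating used to discard, e.g.,
#' red blood cells (hemoglobin subunits) and vascular cells (PDGFRB/PECAM1).
#' Marker symbols absent from the matrix are ignored with a warning.
#'
#' @param counts a [count_matrix()].
#' @param marker_sets named list of character vectors of gene symbols.
#' @param min_detected minimum number of detected genes of one set for a
#'   barcode to be excluded (default 1).
#' @return a new, smaller `CountMatrix`; the input is untouched.
#' @export
exclude_cells_by_markers <- function(counts, marker_sets, min_detected = 1L) {
  stopifnot(inherits(counts, "CountMatrix"), is.list(marker_sets))
  drop <- rep(FALSE, ncol(counts$counts))
  for (nm in names(marker_sets)) {
    set <- upper_symbols(marker_sets[[nm]])
    present <- set %in% rownames(counts$counts)
    if (!all(present))
      warning(sprintf("marker set '%s': %d symbol(s) not in the matrix, ignored",
                      nm, sum(!present)))
    set <- set[present]
    if (!length(set)) next
    detected <- Matrix::colSums(counts$counts[set, , drop = FALSE] >= 1)
    drop <- drop | detected >= min_detected
  }
  if (all(drop)) abort_input("marker gating removed every barcode")
  subset_count_matrix(counts, barcodes = which(!drop))
}

#' Log-normalize a count matrix
#'
#' Each cell is scaled to `normalization_scale_factor` total counts and
#' log-transformed: `value = ln(1 + sf * count / total)`.  Zeros map to
#' exactly zero, so sparsity is preserved; before the log1p step every cell's
#' scaled values sum to the scale factor (equivalently,
#' `sum(expm1(values))` per cell equals the scale factor).
#'
#' @param counts a [count_matrix()] with no all-zero cells.
#' @param params a [qc_params()] object.
#' @return a `NormalizedMatrix`: a list with `values` (sparse genes x cells),
#'   `batch`, `stage` and `params` (provenance).
#' @export
log_normalize <- function(counts, params = qc_params()) {
  stopifnot(inherits(counts, "CountMatrix"), inherits(params, "QcParams"))
  totals <- Matrix::colSums(counts$counts)
  if (any(totals == 0))
    abort_input("cell(s) with zero total counts: ",
                paste(utils::head(colnames(counts$counts)[totals == 0], 5),
                      collapse = ", "))
  scaled <- counts$counts %*% Matrix::Diagonal(
    x = params$normalization_scale_factor / totals)
  values <- methods::as(scaled, "CsparseMatrix")
  values@x <- log1p(values@x)
  dimnames(values) <- dimnames(counts$counts)
  structure(list(values = values, batch = counts$batch, stage = counts$stage,
                 params = params),
            class = "NormalizedMatrix")
}

#' @export
print.NormalizedMatrix <- function(x, ...) {
  cat(sprintf("NormalizedMatrix: %d genes x %d cells (log1p, scale factor %g)\n",
              nrow(x$values), ncol(x$values),
              x$params$normalization_scale_factor))
  invisible(x)
}

# sparse-aware per-gene mean and variance of a dgCMatrix
.row_stats <- function(m) {
  n <- ncol(m)
  mu <- Matrix::rowSums(m) / n
  ex2 <- Matrix::rowSums(m^2) / n
  v <- (ex2 - mu^2) * n / (n - 1)
  list(mean = mu, var = pmax(v, 0))
}

#' Decompose per-gene variance into technical trend and biological residual
#'
#' Fits a smooth mean-variance trend across genes on the log-normalized
#' values (local regression when at least 30 genes support the fit, a linear
#' fit for tiny fixtures).  The trend value at a gene's mean is its technical
#' variance; `biological = total - technical` exactly.  The top `n_hvgs`
#' genes by biological variance are marked selected, after removing
#' ambient-flagged genes; genes with non-positive biological variance are
#' never selected.
#'
#' @param norm a [log_normalize()] result.
#' @param ambient character vector of ambient gene symbols to bar from
#'   selection (they remain in the table, flagged).
#' @param params a [qc_params()] object (`n_hvgs` is used).
#' @return an `HvgTable` data.frame with columns `gene`, `mean`, `total`,
#'   `technical`, `biological`, `ambient`, `selected`.
#' @export
decompose_variance <- function(norm, ambient = character(0),
                               params = qc_params()) {
  stopifnot(inherits(norm, "NormalizedMatrix"))
  if (ncol(norm$values) < 2L) abort_input("need at least 2 cells")
  st <- .row_stats(norm$values)
  genes <- rownames(norm$values)
  if (length(genes) >= 30L) {
    fit <- stats::loess(st$var ~ st$mean, degree = 2, span = 0.5,
                        family = "symmetric")
    tech <- stats::predict(fit, st$mean)
  } else {
    fit <- stats::lm(st$var ~ st$mean)
    tech <- stats::predict(fit, data.frame(mean = st$mean))
  }
  tech <- pmax(pmin(tech, max(st$var)), 0)
  bio <- st$var - tech
  tab <- data.frame(gene = genes, mean = st$mean, total = st$var,
                    technical = tech, biological = bio,
                    ambient = genes %in% upper_symbols(ambient),
                    stringsAsFactors = FALSE, row.names = NULL)
  eligible <- which(!tab$ambient & tab$biological > 0)
  n_take <- min(params$n_hvgs, length(eligible))
  if (n_take < params$n_hvgs)
    warning(sprintf("only %d eligible gene(s) for %d requested HVGs; selecting all",
                    length(eligible), params$n_hvgs))
  ord <- eligible[order(tab$biological[eligible], tab$gene[eligible],
                        decreasing = c(TRUE, FALSE), method = "radix")]
  tab$selected <- FALSE
  tab$selected[utils::head(ord, n_take)] <- TRUE
  class(tab) <- c("HvgTable", "data.frame")
  tab
}
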