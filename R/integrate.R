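#' Mutual-nearest-neighbor correction parameters
#'
#' @param k_mnn neighbors per side for the mutual-pair search (default 20);
#'   lowered with a warning for batches smaller than `k_mnn`.
#' @param smoothing_bandwidth Gaussian kernel bandwidth for smoothing
#'   correction vectors; `NULL` (default) uses the median pair-vector length
#'   of the current merge.
#' @param merge_order either `"size-descending"` (default: merge batches from
#'   largest to smallest, the largest acting as the fixed reference) or a
#'   character vector of batch labels.
#' @param max_iter maximum correction sweeps per merge (default 10).  Mutual
#'   pairs found between displaced point clouds estimate the offset direction
#'   accurately but shrink its magnitude (nearest neighbors concentrate on
#'   facing edges), so the shift is re-estimated on the partially corrected
#'   coordinates until the remaining pair vectors are negligible.
#' @return a validated `MnnParams` list.
#' @export
mnn_params <- function(k_mnn = 20L, smoothing_bandwidth = NULL,
                       merge_order = "size-descending", max_iter = 10L) {
  if (k_mnn < 1L) abort_input("k_mnn must be >= 1")
  if (!is.null(smoothing_bandwidth) && smoothing_bandwidth <= 0)
    abort_input("smoothing_bandwidth must be positive")
  if (max_iter < 1L) abort_input("max_iter must be >= 1")
  structure(list(k_mnn = as.integer(k_mnn),
                 smoothing_bandwidth = smoothing_bandwidth,
                 merge_order = merge_order,
                 max_iter = as.integer(max_iter)),
            class = "MnnParams")
}

#' Principal component analysis on highly variable genes
#'
#' Centers each HVG across cells and returns the leading principal
#' components of the cells, ordered by decreasing explained variance.  At
#' most `min(n_components, n_cells, n_hvgs)` components are returned; asking
#' for more warns.
#'
#' @param norm a [log_normalize()] result.
#' @param hvgs character vector of gene symbols to use (e.g. the selected
#'   genes of [decompose_variance()]).
#' @param n_components number of components requested (default 50).
#' @return an `Embedding`: list with `coordinates` (cells x components),
#'   `sdev`, `var_explained`, `batch`, `corrected = FALSE`.
#' @export
run_pca <- function(norm, hvgs, n_components = 50L) {
  stopifnot(inherits(norm, "NormalizedMatrix"))
  hvgs <- upper_symbols(hvgs)
  if (!length(hvgs)) abort_input("hvgs must be non-empty")
  missing <- setdiff(hvgs, rownames(norm$values))
  if (length(missing))
    abort_input(length(missing), " HVG symbol(s) not in the matrix")
  if (ncol(norm$values) < 2L) abort_input("need at least 2 cells for PCA")
  x <- t(as.matrix(norm$values[hvgs, , drop = FALSE]))
  k_max <- min(nrow(x), ncol(x))
  if (n_components > k_max) {
    warning(sprintf("requested %d components but rank bound is %d; returning %d",
                    n_components, k_max, k_max))
    n_components <- k_max
  }
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
  coords <- p$x[, seq_len(min(n_components, ncol(p$x))), drop = FALSE]
  rownames(coords) <- colnames(norm$values)
  structure(list(coordinates = coords,
                 sdev = p$sdev,
                 var_explained = p$sdev^2 / sum(p$sdev^2),
                 batch = norm$batch,
                 corrected = FALSE),
            class = "Embedding")
}

#' @export
print.Embedding <- function(x, ...) {
  cat(sprintf("Embedding: %d cells x %d components (%scorrected)\n",
              nrow(x$coordinates), ncol(x$coordinates),
              if (x$corrected) "batch-" else "un"))
  invisible(x)
}

#' L2-normalize embedding rows (cosine normalization)
#'
#' Projects each cell onto the unit sphere, the standard preprocessing before
#' the mutual-nearest-neighbor search; exposed so that pre/post comparisons
#' can be made in the same space.
#'
#' @param coords numeric matrix, cells in rows.
#' @return the row-normalized matrix (all-zero rows are left untouched).
#' @export
cosine_normalize <- function(coords) {
  n <- sqrt(rowSums(coords^2))
  n[n == 0] <- 1
  coords / n
}

# k nearest neighbors of each row of `a` among the rows of `b` (indices into
# b), brute force with deterministic index tie-breaking
.knn_index <- function(a, b, k) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  idx <- apply(d2, 1L, function(r) order(r)[seq_len(k)])
  if (k == 1L) matrix(idx, ncol = 1L) else t(idx)
}

#' Mutual k-nearest-neighbor pairs between two coordinate sets
#'
#' A pair (i, j) is mutual when j is among the k nearest rows of `b` to
#' `a[i, ]` and i is among the k nearest rows of `a` to `b[j, ]`.  Distance
#' ties are broken by row index, deterministically.
#'
#' @param a,b numeric coordinate matrices with the same number of columns.
#' @param k neighbors per side (capped at the size of the other set).
#' @return a two-column integer matrix of row indices (`a`, `b`).
#' @export
mutual_nn_pairs <- function(a, b, k) .mutual_pairs(as.matrix(a), as.matrix(b), k)

# mutual kNN pairs between two coordinate sets; returns a 2-column index
# matrix (row in a, row in b)
.mutual_pairs <- function(a, b, k) {
  ka <- min(k, nrow(b))
  kb <- min(k, nrow(a))
  nn_ab <- .knn_index(a, b, ka)
  nn_ba <- .knn_index(b, a, kb)
  hits <- which(nn_ab > 0, arr.ind = TRUE)  # enumerate (i, rank) pairs
  i <- hits[, 1L]
  j <- nn_ab[hits]
  keep <- vapply(seq_along(i), function(t) i[t] %in% nn_ba[j[t], ], logical(1))
  cbind(a = i[keep], b = j[keep])
}

#' Mutual-nearest-neighbor batch correction of an embedding
#'
#' Cosine-normalizes the coordinates, then merges batches sequentially
#' (largest first by default).  For each merge, mutual k-nearest-neighbor
#' pairs between the accumulated reference and the incoming batch define
#' correction vectors (reference minus incoming); each incoming cell is
#' shifted by a Gaussian-kernel-weighted average of the pair vectors, with
#' weights decaying in the distance to the paired incoming cells.  Cells of
#' the first (reference) batch are never moved.  With a single batch the
#' input is returned unchanged.
#'
#' @param emb an `Embedding` from [run_pca()].
#' @param params an [mnn_params()] object.
#' @return an `Embedding` with corrected, cosine-space coordinates and
#'   `corrected = TRUE` (when at least two batches were present).
#' @export
mnn_correct <- function(emb, params = mnn_params()) {
  stopifnot(inherits(emb, "Embedding"), inherits(params, "MnnParams"))
  batches <- unique(emb$batch)
  if (length(batches) < 2L) {
    message("single batch: nothing to correct")
    return(emb)
  }
  ord <- if (identical(params$merge_order, "size-descending")) {
    names(sort(table(emb$batch), decreasing = TRUE))
  } else {
    if (!setequal(params$merge_order, batches))
      abort_input("merge_order must name every batch exactly once")
    params$merge_order
  }
  x <- cosine_normalize(emb$coordinates)
  ref_idx <- which(emb$batch == ord[1L])
  for (b in ord[-1L]) {
    new_idx <- which(emb$batch == b)
    k <- params$k_mnn
    if (length(new_idx) < k || length(ref_idx) < k) {
      k <- max(1L, min(length(new_idx), length(ref_idx)))
      warning(sprintf("batch '%s': fewer cells than k_mnn; lowering k to %d", b, k))
    }
    scale0 <- NULL
    for (it in seq_len(params$max_iter)) {
      pairs <- .mutual_pairs(x[ref_idx, , drop = FALSE],
                             x[new_idx, , drop = FALSE], k)
      if (nrow(pairs) == 0L) {
        if (it == 1L)
          warning(sprintf("batch '%s': no mutual neighbor pairs found; left uncorrected", b))
        break
      }
      vec <- x[ref_idx[pairs[, "a"]], , drop = FALSE] -
        x[new_idx[pairs[, "b"]], , drop = FALSE]
      len <- stats::median(sqrt(rowSums(vec^2)))
      if (is.null(scale0)) scale0 <- max(len, .Machine$double.eps)
      if (len < 0.01 * scale0) break  # pairs aligned: shift converged
      sigma <- params$smoothing_bandwidth %||% max(len, 1e-8)
      anchors <- x[new_idx[pairs[, "b"]], , drop = FALSE]
      d2 <- outer(rowSums(x[new_idx, , drop = FALSE]^2), rowSums(anchors^2), "+") -
        2 * tcrossprod(x[new_idx, , drop = FALSE], anchors)
      w <- exp(-pmax(d2, 0) / (2 * sigma^2))
      w <- w / pmax(rowSums(w), .Machine$double.xmin)
      x[new_idx, ] <- x[new_idx, , drop = FALSE] + w %*% vec
    }
    ref_idx <- c(ref_idx, new_idx)
  }
  out <- emb
  out$coordinates <- x
  out$corrected <- TRUE
  out
}

#' Two-dimensional embedding for plotting (plumbing)
#'
#' Returns the first two embedding components, optionally drawing a scatter
#' colored by a label vector.  This is visualization plumbing only: nothing
#' downstream depends on it and no layout guarantees are made.
#'
#' @param emb an `Embedding`.
#' @param labels optional per-cell labels to color by.
#' @param plot draw the scatter (default `TRUE` when `labels` given).
#' @return invisibly, a cells x 2 coordinate matrix.
#' @export
embed_2d <- function(emb, labels = NULL, plot = !is.null(labels)) {
  stopifnot(inherits(emb, "Embedding"))
  xy <- emb$coordinates[, seq_len(min(2L, ncol(emb$coordinates))), drop = FALSE]
  if (isTRUE(plot)) {
    col <- if (is.null(labels)) 1L else as.integer(factor(labels))
    graphics::plot(xy, col = col, pch = 16, cex = 0.6,
                   xlab = "dim 1", ylab = "dim 2",
                   main = if (emb$corrected) "corrected embedding" else "embedding")
  }
  invisible(xy)
}
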