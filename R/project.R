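#' Projection parameters
#'
#' @param n_features number of reference features to select (default 2000).
#' @param similarity_threshold minimum similarity to the winning centroid for
#'   an assignment (default 0.7; set 0 to disable threshold-based rejection).
#' @param consensus_min_agree how many of the three similarity measures
#'   (cosine, Pearson, Spearman) must vote for the same centroid
#'   (default 2 of 3).
#' @return a validated `ProjectionParams` list.
#' @export
projection_params <- function(n_features = 2000L, similarity_threshold = 0.7,
                              consensus_min_agree = 2L) {
  if (consensus_min_agree < 1L || consensus_min_agree > 3L)
    abort_input("consensus_min_agree must lie in 1..3")
  if (similarity_threshold < 0 || similarity_threshold > 1)
    abort_input("similarity_threshold must lie in [0, 1]")
  if (n_features < 1L) abort_input("n_features must be >= 1")
  structure(list(n_features = as.integer(n_features),
                 similarity_threshold = similarity_threshold,
                 consensus_min_agree = as.integer(consensus_min_agree)),
            class = "ProjectionParams")
}

#' Select reference features by dropout-rate residuals
#'
#' Regresses each gene's log dropout rate on its log mean expression and
#' ranks genes by (descending) residual: genes that drop out more often than
#' their expression level predicts carry cell-type information.  Genes
#' expressed in no cell or in every cell are not rankable and are excluded.
#'
#' @param ref a [log_normalize()] result for the reference.
#' @param n_features number of features to return.
#' @return character vector of selected gene symbols.
#' @export
select_projection_features <- function(ref, n_features = 2000L) {
  stopifnot(inherits(ref, "NormalizedMatrix"))
  m <- ref$values
  dropout <- 1 - Matrix::rowSums(m > 0) / ncol(m)
  mu <- Matrix::rowSums(m) / ncol(m)
  ok <- dropout > 0 & dropout < 1 & mu > 0
  if (!any(ok)) abort_input("no rankable gene for feature selection")
  fit <- stats::lm(log(dropout[ok]) ~ log(mu[ok]))
  res <- stats::residuals(fit)
  genes <- rownames(m)[ok]
  genes[order(-res, genes, method = "radix")][seq_len(min(n_features, length(genes)))]
}

#' Per-cluster reference centroids (gene-wise medians)
#'
#' @param ref a [log_normalize()] result for the reference.
#' @param labels a `ClusterAssignment` or named/positional label vector over
#'   the reference cells; every cluster must be non-empty.
#' @param features optional gene symbols to restrict to (default: all genes).
#' @return a numeric matrix, features x clusters, of per-gene medians.
#' @export
compute_cluster_centroids <- function(ref, labels, features = NULL) {
  stopifnot(inherits(ref, "NormalizedMatrix"))
  labels <- .cluster_labels(labels, colnames(ref$values))
  features <- if (is.null(features)) rownames(ref$values) else upper_symbols(features)
  missing <- setdiff(features, rownames(ref$values))
  if (length(missing)) abort_input(length(missing), " feature(s) not in the reference")
  m <- as.matrix(ref$values[features, , drop = FALSE])
  cl <- sort(unique(labels))
  cent <- vapply(cl, function(k) {
    cols <- labels == k
    if (!any(cols)) abort_input("empty cluster: ", k)
    apply(m[, cols, drop = FALSE], 1L, stats::median)
  }, numeric(nrow(m)))
  cent <- matrix(cent, nrow = nrow(m),
                 dimnames = list(features, as.character(cl)))
  cent
}

#' Project query cells onto reference centroids by similarity consensus
#'
#' For every query cell, cosine, Pearson and Spearman similarities to each
#' centroid are computed on the shared features (the intersection of query
#' symbols, centroid features and, when given, an ortholog map applied to the
#' query symbols).  Each measure votes for its arg-max centroid; the cell is
#' assigned when at least `consensus_min_agree` measures agree and the
#' highest similarity to the winning centroid reaches
#' `similarity_threshold`, otherwise it is `"unassigned"`.  Three-way
#' disagreement is always unassigned.
#'
#' @param query a [log_normalize()] result for the query cells.
#' @param centroids a features x clusters matrix from
#'   [compute_cluster_centroids()].
#' @param params a [projection_params()] object.
#' @param ortholog_map optional two-column data.frame mapping query symbols
#'   (column 1) to reference symbols (column 2); default identity.
#' @return a `ProjectionResult` data.frame: `cell`, `assigned` (cluster label
#'   or `"unassigned"`), `cosine`, `pearson`, `spearman` (similarities to the
#'   winning centroid, `NA` when unassigned with no consensus).
#' @export
project_to_reference <- function(query, centroids, params = projection_params(),
                                 ortholog_map = NULL) {
  stopifnot(inherits(query, "NormalizedMatrix"), is.matrix(centroids))
  q_symbols <- rownames(query$values)
  if (!is.null(ortholog_map)) {
    map <- stats::setNames(upper_symbols(ortholog_map[[2L]]),
                           upper_symbols(ortholog_map[[1L]]))
    translated <- unname(map[q_symbols])
  } else {
    translated <- q_symbols
  }
  shared <- !is.na(translated) & translated %in% rownames(centroids)
  if (sum(shared) < 10L)
    abort_input("fewer than 10 shared features between query and reference")
  qm <- as.matrix(query$values[shared, , drop = FALSE])
  cm <- centroids[translated[shared], , drop = FALSE]
  k <- ncol(cm)

  cos_sim <- function(a, b) {
    num <- crossprod(a, b)
    den <- outer(sqrt(colSums(a^2)), sqrt(colSums(b^2)))
    out <- num / den
    out[den == 0] <- NA_real_
    out
  }
  sims <- list(
    cosine = cos_sim(qm, cm),
    pearson = suppressWarnings(stats::cor(qm, cm, method = "pearson")),
    spearman = suppressWarnings(stats::cor(qm, cm, method = "spearman")))

  votes <- vapply(sims, function(s)
    apply(s, 1L, function(r) if (all(is.na(r))) NA_integer_ else which.max(r)),
    integer(ncol(qm)))
  votes <- matrix(votes, ncol = 3L)
  n <- ncol(qm)
  assigned <- character(n); win <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    v <- votes[i, ]
    v <- v[!is.na(v)]
    if (!length(v)) { assigned[i] <- "unassigned"; next }
    tab <- sort(table(v), decreasing = TRUE)
    # no consensus: too few agreeing measures, or a tie for the top vote
    if (tab[1L] < params$consensus_min_agree ||
        (length(tab) > 1L && tab[2L] == tab[1L])) {
      assigned[i] <- "unassigned"
      next
    }
    cand <- as.integer(names(tab)[1L])
    top_sim <- suppressWarnings(
      max(vapply(sims, function(s) s[i, cand], numeric(1)), na.rm = TRUE))
    if (is.finite(top_sim) && top_sim >= params$similarity_threshold) {
      assigned[i] <- colnames(cm)[cand]
      win[i] <- cand
    } else {
      assigned[i] <- "unassigned"
    }
  }
  pick <- function(s) ifelse(is.na(win), NA_real_,
                             s[cbind(seq_len(n), win)])
  out <- data.frame(cell = colnames(query$values), assigned = assigned,
                    cosine = pick(sims$cosine), pearson = pick(sims$pearson),
                    spearman = pick(sims$spearman),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("ProjectionResult", "data.frame")
  out
}
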