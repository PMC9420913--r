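make_ref <- function(seed = 20, n_genes = 60, per = 15, k = 3, shift = 6) {
  set.seed(seed)
  blocks <- split(seq_len(n_genes), rep(seq_len(k), length.out = n_genes))
  m <- matrix(rpois(n_genes * per * k, 1), nrow = n_genes)
  for (j in seq_len(k)) {
    cols <- (j - 1) * per + seq_len(per)
    m[blocks[[j]], cols] <- m[blocks[[j]], cols] + shift
  }
  cm <- toy_counts(m)
  list(norm = log_normalize(cm, qc_params()),
       labels = stats::setNames(rep(seq_len(k) - 1L, each = per),
                                colnames(cm$counts)))
}

test_that("centroids are per-gene medians (with degenerate clusters)", {
  m <- cbind(c(1, 5, 0), c(3, 7, 2), c(9, 9, 4))
  cm <- toy_counts(m)
  norm <- log_normalize(cm, qc_params())
  v <- as.matrix(norm$values)
  cent <- compute_cluster_centroids(norm, stats::setNames(c(0, 0, 0), colnames(m) <- colnames(cm$counts)))
  expect_equal(unname(cent[, 1]), unname(apply(v, 1, median)))

  # a one-cell cluster's centroid is that cell; identical cells reproduce
  # the common profile
  cent2 <- compute_cluster_centroids(norm, stats::setNames(c(0, 1, 1), colnames(cm$counts)))
  expect_equal(unname(cent2[, "0"]), unname(v[, 1]))
  expect_error(compute_cluster_centroids(norm, stats::setNames(c(0, 0, NA), colnames(cm$counts))),
               "labels")
})

test_that("self-projection assigns nearly every reference cell to its cluster", {
  ref <- make_ref()
  feats <- select_projection_features(ref$norm, 40)
  cent <- compute_cluster_centroids(ref$norm, ref$labels, feats)
  res <- project_to_reference(
    subset_norm <- structure(list(values = ref$norm$values[feats, ],
                                  batch = ref$norm$batch, stage = NULL,
                                  params = ref$norm$params),
                             class = "NormalizedMatrix"),
    cent, projection_params(similarity_threshold = 0.5))
  agree <- res$assigned == as.character(ref$labels[res$cell])
  expect_gte(mean(agree), 0.95)
})

test_that("a query cell equal to a centroid is assigned with cosine 1", {
  ref <- make_ref()
  cent <- compute_cluster_centroids(ref$norm, ref$labels)
  q <- structure(list(values = Matrix::Matrix(cent[, 1, drop = FALSE], sparse = TRUE),
                      batch = "b1", stage = NULL, params = ref$norm$params),
                 class = "NormalizedMatrix")
  colnames(q$values) <- "QUERY1"
  res <- project_to_reference(q, cent, projection_params(similarity_threshold = 0))
  expect_identical(res$assigned, "0")
  expect_equal(res$cosine, 1)
})

test_that("threshold 0 never rejects for similarity; consensus can still fail", {
  ref <- make_ref()
  cent <- compute_cluster_centroids(ref$norm, ref$labels)
  res <- project_to_reference(ref$norm, cent,
                              projection_params(similarity_threshold = 0))
  # every unassigned cell (if any) failed consensus, not the threshold
  expect_true(all(res$assigned != "unassigned" | is.na(res$cosine)))
})

test_that("2-of-3 consensus assigns when one measure dissents", {
  # features crafted so cosine+pearson favor centroid A, spearman favors B:
  # A matches q's two dominant features but reverses the tail ranking,
  # B matches q's full ranking with a different shape
  cent <- cbind(A = c(9.2, 9.6, 1.42, 1.41, 1.40, 1.39, 1.38, 1.37, 1.36, 1.35),
                B = c(9, 10, 1, 2, 3, 4, 5, 6, 7, 8))
  rownames(cent) <- sprintf("G%03d", 1:10)
  q <- c(9, 9.5, seq(1.0, 1.7, 0.1))
  qm <- structure(list(values = Matrix::Matrix(matrix(q, ncol = 1,
                                                      dimnames = list(rownames(cent), "Q1")),
                                               sparse = TRUE),
                       batch = "b1", stage = NULL, params = qc_params()),
                  class = "NormalizedMatrix")
  votes <- c(cosine = which.max(c(sum(q * cent[, 1]) / sqrt(sum(q^2) * sum(cent[, 1]^2)),
                                  sum(q * cent[, 2]) / sqrt(sum(q^2) * sum(cent[, 2]^2)))),
             pearson = which.max(c(cor(q, cent[, 1]), cor(q, cent[, 2]))),
             spearman = which.max(c(cor(q, cent[, 1], method = "spearman"),
                                    cor(q, cent[, 2], method = "spearman"))))
  expect_identical(unname(votes), c(1L, 1L, 2L))  # fixture sanity
  res <- project_to_reference(qm, cent, projection_params(similarity_threshold = 0,
                                                          consensus_min_agree = 2))
  expect_identical(res$assigned, "A")
})

test_that("similarities inherit the invariances of their measures", {
  ref <- make_ref()
  cent <- compute_cluster_centroids(ref$norm, ref$labels)
  base <- ref$norm
  res0 <- project_to_reference(base, cent, projection_params(similarity_threshold = 0))
  tweak <- function(f) {
    v <- as.matrix(base$values)
    structure(list(values = Matrix::Matrix(f(v), sparse = TRUE),
                   batch = base$batch, stage = NULL, params = base$params),
              class = "NormalizedMatrix")
  }
  # positive per-cell scaling: cosine unchanged
  res_scale <- project_to_reference(tweak(function(v) sweep(v, 2, seq(0.5, 2, length.out = ncol(v)), "*")),
                                    cent, projection_params(similarity_threshold = 0))
  expect_equal(res_scale$cosine, res0$cosine, tolerance = 1e-10)
  # per-cell affine transform: pearson unchanged
  res_aff <- project_to_reference(tweak(function(v) sweep(v * 2, 2, seq_len(ncol(v)) * 0.1, "+")),
                                  cent, projection_params(similarity_threshold = 0))
  expect_equal(res_aff$pearson, res0$pearson, tolerance = 1e-10)
  # monotone per-cell transform: spearman unchanged
  res_mono <- project_to_reference(tweak(function(v) v^3 + v),
                                   cent, projection_params(similarity_threshold = 0))
  expect_equal(res_mono$spearman, res0$spearman, tolerance = 1e-10)
})

test_that("ortholog maps translate symbols and tiny overlaps error", {
  ref <- make_ref()
  cent <- compute_cluster_centroids(ref$norm, ref$labels)
  q <- ref$norm
  rownames(q$values) <- paste0("PIG_", rownames(q$values))
  map <- data.frame(query = paste0("PIG_", rownames(cent)),
                    ref = rownames(cent))
  res <- project_to_reference(q, cent, projection_params(similarity_threshold = 0),
                              ortholog_map = map)
  expect_gte(mean(res$assigned == as.character(ref$labels[res$cell])), 0.9)
  expect_error(project_to_reference(q, cent, projection_params()),
               "shared features")
  expect_error(project_to_reference(q, cent[1:5, ], projection_params(),
                                    ortholog_map = map[1:5, ]),
               "shared features")
})
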