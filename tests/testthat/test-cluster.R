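test_that("SNN edge weights equal brute-force Jaccard on an 8-point toy", {
  set.seed(12)
  coords <- matrix(rnorm(16), ncol = 2)
  emb <- toy_embedding(coords)
  k <- 3
  g <- build_snn_graph(emb, cluster_params(k_neighbors = k, prune_jaccard = 0))
  # brute force neighborhoods (self plus k nearest, index tie-break)
  d <- as.matrix(dist(coords)); diag(d) <- Inf
  nbhd <- lapply(1:8, function(i) c(i, order(d[i, ])[1:k]))
  el <- igraph::as_data_frame(g)
  for (r in seq_len(nrow(el))) {
    i <- match(el$from[r], igraph::V(g)$name)
    j <- match(el$to[r], igraph::V(g)$name)
    expect_equal(el$weight[r],
                 length(intersect(nbhd[[i]], nbhd[[j]])) /
                   length(union(nbhd[[i]], nbhd[[j]])))
  }
  # no qualifying pair is missing: zero-overlap pairs aside, all are edges
  n_pos <- sum(vapply(1:7, function(i) sum(vapply((i + 1):8, function(j)
    length(intersect(nbhd[[i]], nbhd[[j]])) > 0, logical(1))), numeric(1)))
  expect_identical(nrow(el), as.integer(n_pos))
})

test_that("identical kNN sets give weight 1 and the prune boundary removes edges", {
  # two coincident points among well-separated others share a neighborhood
  coords <- rbind(c(0, 0), c(0, 0), c(10, 0), c(0, 10), c(10, 10), c(5, 5))
  emb <- toy_embedding(coords)
  g <- build_snn_graph(emb, cluster_params(k_neighbors = 2, prune_jaccard = 0))
  w <- igraph::E(g)[igraph::V(g)$name[1] %--% igraph::V(g)$name[2]]$weight
  expect_equal(w, 1)

  # an edge with weight exactly at the threshold is removed (<= semantics)
  g0 <- build_snn_graph(emb, cluster_params(k_neighbors = 2, prune_jaccard = 0))
  wmin <- min(igraph::E(g0)$weight)
  g1 <- build_snn_graph(emb, cluster_params(k_neighbors = 2, prune_jaccard = wmin))
  expect_lt(igraph::ecount(g1), igraph::ecount(g0))
  expect_true(all(igraph::E(g1)$weight > wmin))
})

test_that("louvain_cluster recovers disconnected cliques exactly", {
  g <- igraph::disjoint_union(igraph::make_full_graph(5), igraph::make_full_graph(5))
  igraph::V(g)$name <- sprintf("C%02d", 1:10)
  igraph::E(g)$weight <- 1
  cl <- louvain_cluster(g, cluster_params(seed = 1))
  expect_identical(sort(unique(cl$labels)), c(0L, 1L))
  expect_identical(length(unique(cl$labels[1:5])), 1L)
  expect_identical(length(unique(cl$labels[6:10])), 1L)
  expect_gt(cl$modularity, 0.45)
})

test_that("louvain_cluster recovers a planted partition with high ARI", {
  set.seed(5)
  truth <- rep(1:3, each = 30)
  p <- matrix(0.05, 90, 90)
  p[outer(truth, truth, "==")] <- 0.9
  adj <- matrix(rbinom(90 * 90, 1, p), 90, 90)
  adj[lower.tri(adj, diag = TRUE)] <- 0
  g <- igraph::graph_from_adjacency_matrix(adj + t(adj), mode = "undirected")
  igraph::V(g)$name <- sprintf("N%02d", 1:90)
  igraph::E(g)$weight <- 1
  cl <- louvain_cluster(g, cluster_params(resolution = 1, seed = 42))
  expect_gte(adjusted_rand_index(cl$labels, truth), 0.95)
})

test_that("higher resolution never yields fewer clusters on the same graph", {
  set.seed(6)
  emb <- toy_embedding(rbind(matrix(rnorm(80, 0, 1), ncol = 2),
                             matrix(rnorm(80, 6, 1), ncol = 2)))
  g <- build_snn_graph(emb, cluster_params(k_neighbors = 10))
  n_at <- function(res) length(unique(
    louvain_cluster(g, cluster_params(resolution = res, seed = 9))$labels))
  expect_gte(n_at(1.6), n_at(1.0))
})

test_that("an edgeless graph makes every cell its own cluster, with a warning", {
  g <- igraph::make_empty_graph(4, directed = FALSE)
  igraph::V(g)$name <- sprintf("C%02d", 1:4)
  expect_warning(cl <- louvain_cluster(g, cluster_params()), "no edges")
  expect_identical(unname(cl$labels), 0:3)
})

test_that("score_cell_cycle recovers planted phase programs", {
  sim <- simulate_counts(sim_config(n_genes = 600, n_cells_per_cluster = 150,
                                    n_clusters = 2, n_empty_droplets = 0,
                                    cellcycle_program_strength = 5, seed = 13))
  cm <- sim$counts
  norm <- log_normalize(cm, qc_params())
  cc <- score_cell_cycle(norm, sim$truth$s_genes, sim$truth$g2m_genes, seed = 1)
  s_called <- cc$cell[cc$phase == "S"]
  g2m_called <- cc$cell[cc$phase == "G2M"]
  expect_gte(mean(sim$truth$s_program_cells %in% s_called), 0.9)
  expect_gte(mean(sim$truth$g2m_program_cells %in% g2m_called), 0.9)
  expect_true(all(cc$phase %in% c("S", "G2M", "G1")))
})

test_that("score_cell_cycle handles zero cells, missing genes and added genes", {
  set.seed(3)
  m <- matrix(rpois(40 * 12, 2), nrow = 40)
  m[, 1] <- 0  # an all-zero cell
  m[1:5, 2:6] <- m[1:5, 2:6] + 20
  cm <- toy_counts(m)
  cm$counts[, 1] <- 0
  # log_normalize refuses zero cells, so score a hand-normalized matrix
  vals <- as.matrix(cm$counts)
  vals[, -1] <- log1p(1e4 * sweep(vals[, -1], 2, colSums(vals[, -1]), "/"))
  norm <- structure(list(values = Matrix::Matrix(vals, sparse = TRUE),
                         batch = rep("b1", 12), stage = NULL,
                         params = qc_params()),
                    class = "NormalizedMatrix")
  s_set <- rownames(vals)[1:5]
  g2m_set <- rownames(vals)[6:10]
  cc <- score_cell_cycle(norm, s_set, g2m_set, n_bins = 5, n_ctrl = 5, seed = 2)
  expect_identical(cc$phase[1], "G1")
  expect_equal(cc$s_score[1], 0)

  expect_warning(cc2 <- score_cell_cycle(norm, c(s_set, "ABSENT"), g2m_set,
                                         n_bins = 5, n_ctrl = 5, seed = 2),
                 "dropped")
  # scores are invariant under adding genes absent from the matrix
  expect_equal(cc2$s_score, cc$s_score)
  expect_error(score_cell_cycle(norm, c("NOPE1", "NOPE2"), g2m_set), "no S")
})
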