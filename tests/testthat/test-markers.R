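test_that("f1_marker_scores matches hand-counted confusion matrices", {
  # 4 cells, cluster = {c1, c2}; gene detected in {c1, c3}
  m <- rbind(GA = c(1, 0, 2, 0),
             GB = c(1, 1, 0, 0),   # perfect marker
             GC = c(0, 0, 0, 0))   # never detected
  cm <- toy_counts(m, genes = c("GA", "GB", "GC"))
  labels <- stats::setNames(c(1, 1, 2, 2), colnames(cm$counts))
  tab <- f1_marker_scores(cm, labels, 1)
  ga <- tab[tab$gene == "GA", ]
  expect_equal(ga[, c("TP", "FP", "FN", "TN")],
               data.frame(TP = 1, FP = 1, FN = 1, TN = 1),
               ignore_attr = TRUE)
  expect_equal(ga$precision, 0.5)
  expect_equal(ga$recall, 0.5)
  expect_equal(ga$f1, 0.5)
  # exclusive, complete detection gives a perfect score and first rank
  expect_equal(tab$gene[1], "GB")
  expect_equal(tab[1, c("precision", "recall", "f1")],
               data.frame(precision = 1, recall = 1, f1 = 1),
               ignore_attr = TRUE)
  # zero-denominator convention
  expect_equal(tab$f1[tab$gene == "GC"], 0)
  expect_error(f1_marker_scores(cm, labels, 99), "empty or unknown")
})

test_that("f1_marker_scores equals the exhaustive oracle on random fixtures", {
  for (seed in 1:5) {
    set.seed(seed)
    n_cells <- sample(4:12, 1)
    dense <- matrix(rbinom(20 * n_cells, 3, 0.3), nrow = 20)
    cm <- toy_counts(dense)
    labels <- stats::setNames(sample(0:2, n_cells, replace = TRUE),
                              colnames(cm$counts))
    for (k in unique(labels)) {
      tab <- f1_marker_scores(cm, labels, k)
      in_c <- labels[colnames(cm$counts)] == k
      for (g in seq_len(20)) {
        o <- oracle_f1(dense, in_c, g)
        row <- tab[tab$gene == rownames(cm$counts)[g], ]
        expect_equal(as.list(row[, names(o)]), o, ignore_attr = TRUE)
      }
    }
  }
})

test_that("wilcoxon_rank_sum matches exact enumeration and the normal limit", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 2, 3), c(1, 2, 2, 3)), 1)
  # exact enumeration oracle, with and without ties
  for (seed in 1:6) {
    set.seed(seed)
    x <- sample(1:6, sample(3:7, 1), replace = TRUE)
    y <- sample(1:6, sample(3:7, 1), replace = TRUE)
    expect_equal(wilcoxon_rank_sum(x, y), oracle_wilcoxon_exact(x, y))
  }
  # tie-free large samples: agree with the independent normal formula
  set.seed(77)
  x <- rnorm(60); y <- rnorm(55, 0.3)
  r <- rank(c(x, y))
  w <- sum(r[1:60])
  z <- (w - 60 * 116 / 2) / sqrt(60 * 55 * 116 / 12)
  expect_equal(wilcoxon_rank_sum(x, y), 2 * pnorm(-abs(z)), tolerance = 1e-6)
})

test_that("wilcoxon_de filters by detection fraction and flags constants", {
  set.seed(14)
  n_in <- 10; n_out <- 30
  m <- matrix(rpois(4 * (n_in + n_out), 3) + 1, nrow = 4)
  # gene 2: detected in 10% of both groups only
  m[2, ] <- 0
  m[2, c(1, 12, 13, 14)] <- 5
  # gene 4: strongly up in the cluster
  m[4, 1:n_in] <- m[4, 1:n_in] + 50
  cm <- toy_counts(m)
  labels <- stats::setNames(rep(c(1, 0), c(n_in, n_out)), colnames(cm$counts))
  norm <- log_normalize(cm, qc_params())
  de <- wilcoxon_de(norm, labels, 1, min_pct = 0.25)
  expect_false("G002" %in% de$gene)
  g4 <- de[de$gene == "G004", ]
  expect_lt(g4$p_value, 1e-4)
  expect_gt(g4$avg_logfc, 0)
  # the log fold change matches the de-logged mean formula
  x <- as.matrix(norm$values)["G004", ]
  manual <- log((mean(expm1(x[1:n_in])) + 1) / (mean(expm1(x[-(1:n_in)])) + 1))
  expect_equal(g4$avg_logfc, manual)
  # Bonferroni adjustment over the tested genes
  expect_equal(de$adjusted_p, pmin(1, de$p_value * nrow(de)))
  expect_true(all(pmax(de$pct_in, de$pct_out) >= 0.25))
})

test_that("a gene constant across all cells gets p = 1 and logFC 0", {
  set.seed(15)
  vals <- rbind(CONST = rep(1.2, 12),
                VAR = log1p(c(rpois(6, 2), rpois(6, 20))))
  colnames(vals) <- sprintf("BC%03d", 1:12)
  norm <- structure(list(values = Matrix::Matrix(vals, sparse = TRUE),
                         batch = rep("b1", 12), stage = NULL,
                         params = qc_params()),
                    class = "NormalizedMatrix")
  labels <- stats::setNames(rep(c(1, 0), each = 6), colnames(vals))
  de <- wilcoxon_de(norm, labels, 1, min_pct = 0.25)
  expect_equal(de$p_value[de$gene == "CONST"], 1)
  expect_equal(de$avg_logfc[de$gene == "CONST"], 0)
})

test_that("select_candidate_tfs keeps perfect matches only, ordered by logFC", {
  de <- data.frame(gene = c("FOXP1", "FOXP1L", sprintf("TF%02d", 1:30)),
                   p_value = 0.001, avg_logfc = c(2.5, 3.0, seq(3, 0.1, length.out = 30)),
                   pct_in = 0.8, pct_out = 0.2, adjusted_p = 0.01,
                   stringsAsFactors = FALSE)
  checklist <- c("FOXP1", sprintf("TF%02d", 1:30))
  out <- select_candidate_tfs(de, checklist, top_n = 20)
  expect_false("FOXP1L" %in% out$gene)
  expect_identical(nrow(out), 20L)
  expect_true(all(diff(out$avg_logfc) <= 0))
  expect_true(all(out$gene %in% checklist))

  expect_warning(short <- select_candidate_tfs(de[de$gene == "FOXP1", ],
                                               checklist, top_n = 20),
                 "only 1 eligible")
  expect_identical(nrow(short), 1L)
  expect_warning(none <- select_candidate_tfs(de, "ZZZZ9", top_n = 20),
                 "no differential gene")
  expect_identical(nrow(none), 0L)
  expect_error(select_candidate_tfs(de, character(0)), "non-empty")
})

test_that("matching is case-insensitive but exact", {
  de <- data.frame(gene = c("Foxp1", "SOX5"), p_value = 0.01,
                   avg_logfc = c(1, 2), pct_in = 0.5, pct_out = 0.1,
                   adjusted_p = 0.02, stringsAsFactors = FALSE)
  expect_warning(out <- select_candidate_tfs(de, c("foxp1", "sox5"), top_n = 5),
                 "only 2")
  expect_setequal(out$gene, c("Foxp1", "SOX5"))
})
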