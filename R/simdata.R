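#' Configuration for the single-cell count simulator
#'
#' Defaults describe a desk-scale world with the statistical structure the
#' downstream pipeline assumes: a few hundred cells per planted cluster,
#' negative-binomial UMI counts, two batches with multiplicative gene-wise
#' effects, cluster-enriched marker genes (half of them labelled as
#' transcription factors), a pool of ambient genes shared with low-UMI empty
#' droplets, and S/G2M cell-cycle programs planted in a subset of cells.
#'
#' @param n_genes number of genes.
#' @param n_cells_per_cluster cells per cluster; recycled to `n_clusters`.
#' @param n_clusters number of planted clusters.
#' @param n_batches number of batches; cells are assigned to batches in a
#'   balanced, cluster-stratified way so batch is not confounded with cluster.
#' @param batch_effect_sd SD of the per-(gene, batch) log-normal
#'   multiplicative factor (log scale).
#' @param marker_genes_per_cluster planted marker genes per cluster
#'   (disjoint across clusters).
#' @param marker_fold_change mean fold elevation of a marker gene in its own
#'   cluster; must be > 1.
#' @param tf_fraction_of_markers fraction of each cluster's markers that are
#'   labelled transcription factors (every planted TF is a planted marker).
#' @param nb_dispersion negative-binomial dispersion phi, with
#'   Var = mu + phi * mu^2 (so `size = 1/phi` in [stats::rnbinom()]).
#' @param mean_library_size expected UMIs per cell.
#' @param n_empty_droplets number of empty-droplet barcodes appended to the
#'   matrix; their totals are strictly below 50 UMIs.
#' @param ambient_gene_fraction fraction of genes forming the ambient pool
#'   from which empty droplets draw; these genes are expressed at very low
#'   levels in real cells so the ambient-fraction rule is discoverable.
#' @param cellcycle_program_strength multiplicative boost of the S (or G2M)
#'   program genes in cells planted in that phase; must be >= 1.
#' @param seed integer master seed; every sub-generator derives its own
#'   stream via [sub_seed()].
#' @return a validated `SimConfig` list.
#' @export
sim_config <- function(n_genes = 2000L,
                       n_cells_per_cluster = 500L,
                       n_clusters = 4L,
                       n_batches = 2L,
                       batch_effect_sd = 0.15,
                       marker_genes_per_cluster = 20L,
                       marker_fold_change = 4,
                       tf_fraction_of_markers = 0.5,
                       nb_dispersion = 0.5,
                       mean_library_size = 5000,
                       n_empty_droplets = 200L,
                       ambient_gene_fraction = 0.05,
                       cellcycle_program_strength = 5,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_cells_per_cluster = as.integer(rep_len(n_cells_per_cluster, n_clusters)),
              n_clusters = as.integer(n_clusters),
              n_batches = as.integer(n_batches),
              batch_effect_sd = batch_effect_sd,
              marker_genes_per_cluster = as.integer(marker_genes_per_cluster),
              marker_fold_change = marker_fold_change,
              tf_fraction_of_markers = tf_fraction_of_markers,
              nb_dispersion = nb_dispersion,
              mean_library_size = mean_library_size,
              n_empty_droplets = as.integer(n_empty_droplets),
              ambient_gene_fraction = ambient_gene_fraction,
              cellcycle_program_strength = cellcycle_program_strength,
              seed = as.integer(seed))
  with(cfg, {
    if (n_genes < 1L || n_clusters < 1L || n_batches < 1L ||
        any(n_cells_per_cluster < 1L) || marker_genes_per_cluster < 1L)
      abort_input("all counts must be >= 1 (n_empty_droplets may be 0)")
    if (n_empty_droplets < 0L) abort_input("n_empty_droplets must be >= 0")
    if (marker_fold_change <= 1) abort_input("marker_fold_change must be > 1")
    if (tf_fraction_of_markers < 0 || tf_fraction_of_markers > 1 ||
        ambient_gene_fraction < 0 || ambient_gene_fraction > 1)
      abort_input("fractions must lie in [0, 1]")
    if (nb_dispersion <= 0 || mean_library_size <= 0 || batch_effect_sd < 0)
      abort_input("nb_dispersion and mean_library_size must be positive")
    if (cellcycle_program_strength < 1)
      abort_input("cellcycle_program_strength must be >= 1")
    if (marker_genes_per_cluster * n_clusters > n_genes)
      abort_input("contradictory config: marker_genes_per_cluster * n_clusters > n_genes")
  })
  structure(cfg, class = "SimConfig")
}

# number of cell-cycle program genes planted per phase and the fraction of
# cells planted in each of S and G2M; fixed world constants of the simulator
.CC_GENES_PER_PHASE <- 40L
.CC_CELL_FRACTION <- 0.10

#' Simulate a multi-batch UMI count matrix with known ground truth
#'
#' Draws negative-binomial counts for `sum(n_cells_per_cluster)` cells plus
#' `n_empty_droplets` empty droplets.  Marker genes are elevated by
#' `marker_fold_change` (in expectation) in their own cluster; batch effects
#' are per-(gene, batch) log-normal multiplicative factors; empty droplets
#' draw a multinomial profile over the ambient gene pool with totals strictly
#' below 50 UMIs; S and G2M cell-cycle programs are boosted in planted cell
#' subsets.  Identical config and seed give byte-identical output.
#'
#' @param config a [sim_config()] object.
#' @return a list with elements `counts` (a [count_matrix()] over cells and
#'   empty droplets) and `truth` (a `GroundTruth` list: `true_cluster_of_cell`,
#'   `true_markers_of_cluster`, `true_tfs_of_cluster`, `ambient_genes`,
#'   `batch_of_cell`, `s_program_cells`, `g2m_program_cells`, plus the
#'   planted `s_genes`/`g2m_genes` and a `tf_checklist` containing every
#'   planted TF and decoy TF symbols that are not cluster markers).
#' @export
simulate_counts <- function(config = sim_config()) {
  stopifnot(inherits(config, "SimConfig"))
  cfg <- config
  n_cells <- sum(cfg$n_cells_per_cluster)
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  cells <- sprintf("CELL%05d", seq_len(n_cells))

  n_amb <- round(cfg$ambient_gene_fraction * cfg$n_genes)
  n_cc <- if (cfg$n_genes >= cfg$marker_genes_per_cluster * cfg$n_clusters +
                n_amb + 2L * .CC_GENES_PER_PHASE) .CC_GENES_PER_PHASE else 0L

  # --- gene roles ---------------------------------------------------------
  set.seed(sub_seed(cfg$seed, "roles"))
  perm <- sample.int(cfg$n_genes)
  take <- function(n) {
    idx <- perm[seq_len(n)]
    perm <<- perm[-seq_len(n)]
    idx
  }
  marker_idx <- lapply(seq_len(cfg$n_clusters),
                       function(k) sort(take(cfg$marker_genes_per_cluster)))
  ambient_idx <- sort(take(n_amb))
  s_idx <- sort(take(n_cc))
  g2m_idx <- sort(take(n_cc))
  n_tf <- round(cfg$tf_fraction_of_markers * cfg$marker_genes_per_cluster)
  tf_idx <- lapply(marker_idx, function(ix) ix[seq_len(n_tf)])
  # decoy TFs: broadly expressed genes on the checklist that are not markers
  decoy_pool <- perm
  decoy_idx <- sort(decoy_pool[seq_len(min(length(decoy_pool),
                                           round(0.1 * cfg$n_genes)))])

  # --- base expression profile -------------------------------------------
  set.seed(sub_seed(cfg$seed, "profile"))
  base <- stats::rlnorm(cfg$n_genes, meanlog = 0, sdlog = 1)
  if (n_amb) base[ambient_idx] <- base[ambient_idx] * 0.02
  prof <- base / sum(base)

  # --- cell structure -----------------------------------------------------
  cluster_of_cell <- rep(seq_len(cfg$n_clusters) - 1L, cfg$n_cells_per_cluster)
  # cluster-stratified round-robin keeps batches balanced within clusters
  batch_of_cell <- unlist(lapply(cfg$n_cells_per_cluster, function(n)
    rep_len(seq_len(cfg$n_batches), n)), use.names = FALSE)

  set.seed(sub_seed(cfg$seed, "cells"))
  libsize <- cfg$mean_library_size * stats::rlnorm(n_cells, -0.3^2 / 2, 0.3)
  n_phase <- round(.CC_CELL_FRACTION * n_cells)
  phase_pick <- sample.int(n_cells, min(2L * n_phase, n_cells))
  s_cells <- if (n_cc) phase_pick[seq_len(n_phase)] else integer(0)
  g2m_cells <- if (n_cc) phase_pick[n_phase + seq_len(n_phase)] else integer(0)

  # --- expected means and NB draws ---------------------------------------
  set.seed(sub_seed(cfg$seed, "batch"))
  batch_fac <- matrix(exp(stats::rnorm(cfg$n_genes * cfg$n_batches,
                                       0, cfg$batch_effect_sd)),
                      nrow = cfg$n_genes)
  mu <- outer(prof, libsize)
  for (k in seq_len(cfg$n_clusters)) {
    in_k <- cluster_of_cell == (k - 1L)
    mu[marker_idx[[k]], in_k] <- mu[marker_idx[[k]], in_k] * cfg$marker_fold_change
  }
  if (n_cc) {
    mu[s_idx, s_cells] <- mu[s_idx, s_cells] * cfg$cellcycle_program_strength
    mu[g2m_idx, g2m_cells] <- mu[g2m_idx, g2m_cells] * cfg$cellcycle_program_strength
  }
  mu <- mu * batch_fac[, batch_of_cell]

  set.seed(sub_seed(cfg$seed, "counts"))
  x <- stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion)
  counts <- Matrix::Matrix(matrix(x, nrow = cfg$n_genes), sparse = TRUE)

  # --- empty droplets -----------------------------------------------------
  if (cfg$n_empty_droplets > 0L) {
    set.seed(sub_seed(cfg$seed, "empties"))
    amb_w <- if (n_amb) base[ambient_idx] else prof
    totals <- sample(5:45, cfg$n_empty_droplets, replace = TRUE)
    emp <- matrix(0, nrow = cfg$n_genes, ncol = cfg$n_empty_droplets)
    rows <- if (n_amb) ambient_idx else seq_len(cfg$n_genes)
    for (j in seq_len(cfg$n_empty_droplets))
      emp[rows, j] <- stats::rmultinom(1L, size = totals[j], prob = amb_w)
    counts <- cbind(counts, Matrix::Matrix(emp, sparse = TRUE))
    empties <- sprintf("EMPTY%04d", seq_len(cfg$n_empty_droplets))
    barcodes <- c(cells, empties)
    batch_all <- c(batch_of_cell, rep_len(seq_len(cfg$n_batches),
                                          cfg$n_empty_droplets))
  } else {
    barcodes <- cells
    batch_all <- batch_of_cell
  }

  cm <- count_matrix(counts, gene_symbols = genes, barcode_ids = barcodes,
                     batch = sprintf("batch%d", batch_all))
  truth <- structure(list(
    true_cluster_of_cell = stats::setNames(cluster_of_cell, cells),
    true_markers_of_cluster = lapply(marker_idx, function(ix) genes[ix]),
    true_tfs_of_cluster = lapply(tf_idx, function(ix) genes[ix]),
    ambient_genes = genes[ambient_idx],
    batch_of_cell = stats::setNames(sprintf("batch%d", batch_all), barcodes),
    s_program_cells = cells[s_cells],
    g2m_program_cells = cells[g2m_cells],
    s_genes = genes[s_idx],
    g2m_genes = genes[g2m_idx],
    tf_checklist = sort(unique(c(unlist(lapply(tf_idx, function(ix) genes[ix])),
                                 genes[decoy_idx])))),
    class = "GroundTruth")
  list(counts = cm, truth = truth)
}

#' Configuration for the qPCR simulator
#'
#' Describes a two-arm ddCt design (a `reference` and a `treatment` sample
#' with known per-gene fold changes, normalized to a housekeeping gene) and a
#' lentiviral titration series in which the relative integrated copy number
#' is linear in the virus volume added, consistent with a known true titer.
#'
#' @param true_fold_changes named positive numeric: expression fold change of
#'   each target gene in `treatment` relative to `reference`.
#' @param housekeeping_ct housekeeping-gene Ct (cycles).
#' @param amplification_efficiency per-cycle amplification factor E in
#'   (1, 2]; 2 is perfect doubling.
#' @param ct_noise_sd SD of Gaussian Ct noise (cycles); 0 gives exact tables.
#' @param replicates technical replicates per (sample, gene).
#' @param titration_volumes distinct positive virus volumes (ul).
#' @param true_titer true titer of the produced virus (U/ul).
#' @param n_cells_transduced number of cells in each titration well.
#' @param moi multiplicity of infection of the reference virus.
#' @param seed integer seed for the noise stream.
#' @return a validated `QpcrSimConfig` list.
#' @export
qpcr_sim_config <- function(true_fold_changes = c(RELN = 4, BCL11B = 2, SATB2 = 2, LEF1 = 8),
                            housekeeping_ct = 18,
                            amplification_efficiency = 2,
                            ct_noise_sd = 0,
                            replicates = 3L,
                            titration_volumes = c(1, 2, 5, 10, 15),
                            true_titer = 2e4,
                            n_cells_transduced = 1e5,
                            moi = 10,
                            seed = 1L) {
  cfg <- list(true_fold_changes = true_fold_changes,
              housekeeping_ct = housekeeping_ct,
              amplification_efficiency = amplification_efficiency,
              ct_noise_sd = ct_noise_sd,
              replicates = as.integer(replicates),
              titration_volumes = as.numeric(titration_volumes),
              true_titer = true_titer,
              n_cells_transduced = n_cells_transduced,
              moi = moi,
              seed = as.integer(seed))
  with(cfg, {
    if (amplification_efficiency <= 1 || amplification_efficiency > 2)
      abort_input("amplification_efficiency must lie in (1, 2]")
    if (any(true_fold_changes <= 0) || is.null(names(true_fold_changes)))
      abort_input("true_fold_changes must be a named positive vector")
    if (ct_noise_sd < 0) abort_input("ct_noise_sd must be >= 0")
    if (replicates < 1L) abort_input("replicates must be >= 1")
    if (any(titration_volumes <= 0) || anyDuplicated(titration_volumes))
      abort_input("titration volumes must be strictly positive and distinct")
    if (true_titer <= 0 || moi <= 0 || n_cells_transduced < 1)
      abort_input("true_titer, moi and n_cells_transduced must be positive")
  })
  structure(cfg, class = "QpcrSimConfig")
}

# fixed Ct offset (cycles) of every target gene above the housekeeping gene
# in the reference sample; any constant works since ddCt removes it
.QPCR_TARGET_OFFSET <- 3

#' Simulate qPCR Ct tables for a ddCt design and a viral titration
#'
#' Ct values follow `Ct = Ct_ref - log_E(relative quantity) + noise`.  In the
#' ddCt table the `treatment` sample's target quantities are elevated by the
#' configured fold changes; the housekeeping gene is constant across samples.
#' In the titration table the LV2/actin relative copy number is proportional
#' to the virus volume with proportionality fixed by the true titer through
#' `VPD = cells * MOI / titer`, so the downstream titer fit recovers
#' `true_titer` exactly at zero noise.
#'
#' @param config a [qpcr_sim_config()] object.
#' @return a list: `ct_table` (columns `sample`, `gene`, `replicate`, `ct`),
#'   `titration_table` (adds a `volume` column; genes `LV2` and `ACTB`), and
#'   `ref_relative_copy` (the reference virus's relative copy number, 1).
#' @export
simulate_qpcr <- function(config = qpcr_sim_config()) {
  stopifnot(inherits(config, "QpcrSimConfig"))
  cfg <- config
  E <- cfg$amplification_efficiency
  logE <- function(q) log(q) / log(E)
  genes <- names(cfg$true_fold_changes)

  set.seed(sub_seed(cfg$seed, "ddct"))
  grid <- expand.grid(replicate = seq_len(cfg$replicates),
                      gene = c(genes, "ACTIN"),
                      sample = c("reference", "treatment"),
                      stringsAsFactors = FALSE)[, c("sample", "gene", "replicate")]
  ct0 <- ifelse(grid$gene == "ACTIN", cfg$housekeeping_ct,
                cfg$housekeeping_ct + .QPCR_TARGET_OFFSET)
  fold <- ifelse(grid$sample == "treatment" & grid$gene != "ACTIN",
                 cfg$true_fold_changes[grid$gene], 1)
  grid$ct <- ct0 - logE(fold) + stats::rnorm(nrow(grid), 0, cfg$ct_noise_sd)
  ct_table <- grid

  set.seed(sub_seed(cfg$seed, "titration"))
  vpd_true <- cfg$n_cells_transduced * cfg$moi / cfg$true_titer
  tit <- expand.grid(replicate = seq_len(cfg$replicates),
                     gene = c("LV2", "ACTB"),
                     volume = cfg$titration_volumes,
                     stringsAsFactors = FALSE)
  tit$sample <- sprintf("vol_%g", tit$volume)
  copy <- tit$volume / vpd_true  # relative copy number, linear in volume
  tit$ct <- ifelse(tit$gene == "LV2",
                   cfg$housekeeping_ct - logE(copy),
                   cfg$housekeeping_ct) +
    stats::rnorm(nrow(tit), 0, cfg$ct_noise_sd)
  titration <- tit[, c("sample", "volume", "gene", "replicate", "ct")]

  list(ct_table = ct_table, titration_table = titration, ref_relative_copy = 1)
}
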