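#' Convert a Ct value to a linear Xo quantity
#'
#' The Xo transform maps a quantification cycle to a quantity linear in the
#' initial template amount: `xo = E^(-ct)` with per-cycle amplification
#' factor E.  One cycle at E = 2 corresponds to a doubling.
#'
#' @param ct numeric Ct value(s), finite.
#' @param efficiency amplification factor E in (1, 2].
#' @return positive numeric, strictly decreasing in `ct`.
#' @export
xo_from_ct <- function(ct, efficiency = 2) {
  if (efficiency <= 1 || efficiency > 2)
    abort_input("efficiency must lie in (1, 2]")
  if (any(!is.finite(ct))) abort_input("ct values must be finite")
  efficiency^(-ct)
}

#' Fit a viral titration standard curve
#'
#' Per titration volume, the relative copy number of the integrated viral
#' sequence is the mean Xo of the LV2 replicates divided by the mean Xo of
#' the beta-actin replicates.  The standard curve regresses volume on
#' relative copy number (ordinary least squares), matching the orientation
#' of `VPD = a * relative copy number + b`.
#'
#' @param table a Ct data.frame with columns `sample`, `gene`, `replicate`,
#'   `ct` and either a `volume` column or a `volumes` argument.
#' @param lv2_gene symbol of the virus-specific amplicon (default `"LV2"`).
#' @param actin_gene symbol of the genome-copy amplicon (default `"ACTB"`).
#' @param volumes named numeric mapping sample label to volume (ul); not
#'   needed when `table$volume` exists.
#' @param efficiency amplification factor for the Xo transform.
#' @return a `TitrationFit`: list with `slope`, `intercept`, `r_squared` and
#'   `points` (data.frame of `volume`, `relative_copy`).
#' @export
fit_titration_curve <- function(table, lv2_gene = "LV2", actin_gene = "ACTB",
                                volumes = NULL, efficiency = 2) {
  stopifnot(is.data.frame(table))
  if (is.null(volumes)) {
    if (!"volume" %in% names(table))
      abort_input("supply `volumes` or a `volume` column")
    volumes <- tapply(table$volume, table$sample, function(v) v[1L])
  }
  gene <- upper_symbols(table$gene)
  samples <- names(volumes)
  rel <- vapply(samples, function(s) {
    rows <- table$sample == s
    lv2 <- table$ct[rows & gene == upper_symbols(lv2_gene)]
    act <- table$ct[rows & gene == upper_symbols(actin_gene)]
    if (!length(lv2) || !length(act))
      abort_input("sample '", s, "' is missing LV2 or actin replicates")
    a <- mean(xo_from_ct(act, efficiency))
    if (a == 0) abort_input("zero actin Xo in sample '", s, "'")
    mean(xo_from_ct(lv2, efficiency)) / a
  }, numeric(1))
  pts <- data.frame(volume = as.numeric(volumes), relative_copy = unname(rel))
  if (nrow(pts) < 2L) abort_input("at least 2 titration volumes are required")
  fit <- stats::lm(volume ~ relative_copy, data = pts)
  # perfect fits are an intended case (zero-noise synthetics): keep lm's
  # "essentially perfect fit" warning out of the way
  r2 <- if (nrow(pts) == 2L) 1 else suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2,
                 points = pts),
            class = "TitrationFit")
}

#' @export
print.TitrationFit <- function(x, ...) {
  cat(sprintf("TitrationFit: volume = %.4g * copy + %.4g (R^2 = %.3f, %d points)\n",
              x$slope, x$intercept, x$r_squared, nrow(x$points)))
  invisible(x)
}

#' Compute a viral titer from a standard curve
#'
#' `VPD = a * relative copy number of the reference virus + b` is the volume
#' of the produced virus matching the reference virus's integration;
#' `titer = cells * MOI / VPD` in U/ul, so `titer * VPD = cells * MOI`
#' exactly.
#'
#' @param fit a [fit_titration_curve()] result.
#' @param ref_relative_copy relative copy number measured for the reference
#'   virus.
#' @param n_cells number of cells per titration well.
#' @param moi multiplicity of infection of the reference virus.
#' @return a `TiterResult`: list with `vpd` (ul), `titer` (U/ul), `n_cells`,
#'   `moi`.
#' @export
compute_titer <- function(fit, ref_relative_copy, n_cells, moi) {
  stopifnot(inherits(fit, "TitrationFit"))
  vpd <- fit$slope * ref_relative_copy + fit$intercept
  if (!is.finite(vpd) || vpd <= 0)
    abort_input("standard curve gives non-positive VPD (extrapolation failure)")
  structure(list(vpd = vpd, titer = n_cells * moi / vpd,
                 n_cells = n_cells, moi = moi),
            class = "TiterResult")
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, `dCt = mean Ct(gene) - mean Ct(housekeeping)`;
#' `ddCt = dCt(sample) - dCt(reference sample)`; `fold = 2^(-ddCt)`.  The SD
#' is computed over replicate-level fold changes (each replicate's Ct against
#' the sample's mean housekeeping Ct and the reference dCt).
#'
#' @param table a Ct data.frame with columns `sample`, `gene`, `replicate`,
#'   `ct`.
#' @param housekeeping housekeeping gene symbol (default `"ACTIN"`); must be
#'   present in every sample.
#' @param reference_sample the sample every ddCt is normalized to; its own
#'   fold change is exactly 1.
#' @return a `FoldChangeTable` data.frame: `gene`, `sample`, `delta_ct`,
#'   `delta_delta_ct`, `fold_change`, `sd`.
#' @export
fold_change_ddct <- function(table, housekeeping = "ACTIN", reference_sample) {
  stopifnot(is.data.frame(table))
  gene <- upper_symbols(table$gene)
  housekeeping <- upper_symbols(housekeeping)
  samples <- unique(table$sample)
  if (!reference_sample %in% samples)
    abort_input("reference sample '", reference_sample, "' not in the table")
  hk_mean <- vapply(samples, function(s) {
    ct <- table$ct[table$sample == s & gene == housekeeping]
    if (!length(ct)) abort_input("housekeeping gene missing in sample '", s, "'")
    mean(ct)
  }, numeric(1))
  targets <- setdiff(unique(gene), housekeeping)
  rows <- list()
  for (g in targets) {
    have <- vapply(samples, function(s)
      any(table$sample == s & gene == g), logical(1))
    ref_ct <- table$ct[table$sample == reference_sample & gene == g]
    if (!length(ref_ct)) next  # gene not measured in the reference sample
    dct_ref <- mean(ref_ct) - hk_mean[[reference_sample]]
    for (s in samples[have]) {
      ct <- table$ct[table$sample == s & gene == g]
      dct <- mean(ct) - hk_mean[[s]]
      ddct <- dct - dct_ref
      rep_fold <- 2^(-((ct - hk_mean[[s]]) - dct_ref))
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, sample = s, delta_ct = dct, delta_delta_ct = ddct,
        fold_change = 2^(-ddct),
        sd = if (length(ct) > 1L) stats::sd(rep_fold) else 0,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("FoldChangeTable", "data.frame")
  out
}

#' Welch's two-sample t-test (unequal variances, two-sided)
#'
#' @param group_a,group_b numeric vectors with at least 2 values each.
#' @return a list with `t`, `df` (Welch-Satterthwaite) and `p` (two-sided).
#'   When both groups have zero variance and equal means, `t = 0`, `p = 1`.
#' @export
welch_ttest <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    abort_input("each group needs at least 2 values")
  n1 <- length(group_a); n2 <- length(group_b)
  v1 <- stats::var(group_a); v2 <- stats::var(group_b)
  se2 <- v1 / n1 + v2 / n2
  dm <- mean(group_a) - mean(group_b)
  if (se2 == 0) {
    if (dm == 0) return(list(t = 0, df = n1 + n2 - 2, p = 1))
    return(list(t = sign(dm) * Inf, df = n1 + n2 - 2, p = 0))
  }
  t <- dm / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Significance stars for p-values
#'
#' Thresholds 0.05, 0.01 and 0.001 map to `*`, `**`, `***`; larger p-values
#' map to `"ns"`.
#'
#' @param p numeric p-value(s).
#' @return character vector of the same length.
#' @export
significance_stars <- function(p) {
  ifelse(p <= 0.001, "***", ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", "ns")))
}
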