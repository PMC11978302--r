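#' Differential contrast with fold-change and BH gates
#'
#' The core differential rule of the Total-proteome analysis: per protein,
#' the log2 fold change between a contrast time point (default T2, the
#' fibrosis peak) and controls, a pooled-variance t-test, BH adjustment
#' across all tested proteins, and a significance flag requiring both the
#' adjusted p <= `q` and a minimum linear fold change (default 1.5-fold in
#' either direction).
#'
#' @param mat an imputed [intensity_matrix()] (log2 scale).
#' @param design study design for the columns.
#' @param model model whose samples are contrasted.
#' @param timepoint contrast time point (default `"T2"`).
#' @param reference reference time point (default `"Ctrl"`).
#' @param fold_change_min minimum linear fold change (default 1.5).
#' @param q BH FDR level (default 0.05).
#' @return data.frame per protein: `protein_id, log2fc, statistic, p, q,
#'   significant, direction`.
#' @export
de_contrast <- function(mat, design, model, timepoint = "T2",
                        reference = "Ctrl", fold_change_min = 1.5,
                        q = 0.05) {
  stopifnot(fold_change_min >= 1, q > 0, q < 1)
  d <- design_lookup(design, colnames(mat$values))
  ia <- which(d$model == model & d$timepoint == timepoint)
  ib <- which(d$model == model & d$timepoint == reference)
  if (length(ia) < 2L || length(ib) < 2L)
    stopf("contrast group missing or too small (%s %s vs %s)", model,
          timepoint, reference)
  tt <- row_t_test(mat$values, ia, ib)
  bh <- benjamini_hochberg(tt$p_value, q)
  lfc <- tt$estimate
  sig <- bh$rejected & abs(lfc) >= log2(fold_change_min)
  data.frame(protein_id = rownames(mat$values), log2fc = lfc,
             statistic = tt$statistic, p = tt$p_value, q = bh$adjusted,
             significant = sig,
             direction = ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "none")),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Time-course one-way ANOVA per protein
#'
#' Tests every protein for any change across time points within one model,
#' with BH adjustment at level `q`.
#'
#' @param mat imputed [intensity_matrix()].
#' @param design study design.
#' @param model model analysed.
#' @param q BH FDR level.
#' @return data.frame: `protein_id, statistic, p, q, significant`.
#' @export
anova_time_course <- function(mat, design, model, q = 0.05) {
  d <- design_lookup(design, colnames(mat$values))
  cols <- which(d$model == model)
  if (length(cols) == 0L) stopf("no samples for model %s", model)
  group <- droplevels(order_timepoints(d$timepoint[cols]))
  if (nlevels(group) < 2L) stopf("need >= 2 time-point groups")
  res <- row_anova(mat$values[, cols, drop = FALSE], group)
  bh <- benjamini_hochberg(res$p_value, q)
  data.frame(protein_id = rownames(mat$values), statistic = res$statistic,
             p = res$p_value, q = bh$adjusted, significant = bh$rejected,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Detect treatment-induced proteins from the pre-imputation mask
#'
#' A protein is "induced" when it was never detected in control samples but
#' was detected at both fibrosis time points (T1 and T2) of a model, in at
#' least `ceil(min_detect_frac * n)` replicates at each.
#'
#' @param mask logical detection matrix (proteins x samples), pre-imputation.
#' @param design study design for the mask columns.
#' @param model model analysed.
#' @param min_detect_frac minimum detected fraction of replicates at T1 and
#'   at T2 (default 0.5).
#' @return character vector of induced protein ids.
#' @export
detect_induced <- function(mask, design, model, min_detect_frac = 0.5) {
  mask <- as.matrix(mask)
  d <- design_lookup(design, colnames(mask))
  sel <- function(tp) which(d$model == model & d$timepoint == tp)
  ctrl <- sel("Ctrl"); t1 <- sel("T1"); t2 <- sel("T2")
  if (length(ctrl) == 0L || length(t1) == 0L || length(t2) == 0L)
    stopf("model %s needs Ctrl, T1 and T2 samples", model)
  n_ctrl <- rowSums(mask[, ctrl, drop = FALSE])
  n_t1 <- rowSums(mask[, t1, drop = FALSE])
  n_t2 <- rowSums(mask[, t2, drop = FALSE])
  need1 <- ceiling(min_detect_frac * length(t1))
  need2 <- ceiling(min_detect_frac * length(t2))
  rownames(mask)[n_ctrl == 0 & n_t1 >= need1 & n_t2 >= need2]
}
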