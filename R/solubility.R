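#' E/S solubility ratios
#'
#' For every protein and every E-fraction replicate, the log2 ratio of the
#' E intensity to the median S-fraction intensity of that protein.  Scope
#' `"global"` (default) takes the median over all S samples of the model;
#' `"per_timepoint"` matches S samples of the same time point.
#'
#' @param e_mat,s_mat imputed [intensity_matrix()] objects (log2) sharing
#'   the protein index.
#' @param design study design covering both matrices' columns.
#' @param model model analysed.
#' @param scope `"global"` or `"per_timepoint"`.
#' @return matrix of log2 ratios, proteins x E samples of the model.
#' @export
es_ratio <- function(e_mat, s_mat, design, model,
                     scope = c("global", "per_timepoint")) {
  scope <- match.arg(scope)
  if (!identical(rownames(e_mat$values), rownames(s_mat$values)))
    stopf("E and S matrices must share the same protein index")
  de <- design_lookup(design, colnames(e_mat$values))
  ds <- design_lookup(design, colnames(s_mat$values))
  ecols <- which(de$model == model)
  if (length(ecols) == 0L) stopf("no E samples for model %s", model)
  e <- e_mat$values[, ecols, drop = FALSE]
  if (scope == "global") {
    scols <- which(ds$model == model)
    s_med <- apply(s_mat$values[, scols, drop = FALSE], 1L, median)
    ratios <- e - s_med
  } else {
    ratios <- e
    for (tp in unique(de$timepoint[ecols])) {
      scols <- which(ds$model == model & ds$timepoint == tp)
      if (length(scols) == 0L) stopf("no S samples at %s", tp)
      s_med <- apply(s_mat$values[, scols, drop = FALSE], 1L, median)
      sub <- which(de$timepoint[ecols] == tp)
      ratios[, sub] <- e[, sub, drop = FALSE] - s_med
    }
  }
  ratios
}

#' Select insolubilized (E-fraction-enriched) proteins
#'
#' Two gates, both required: (1) a mean log2 E/S ratio of at least
#' `log2(fold_min)` (default threefold, inclusive) in at least one time
#' point group; (2) a significant change of the E-fraction intensity over
#' time (one-way ANOVA, BH FDR <= `q`).
#'
#' @param ratios matrix from [es_ratio()] (proteins x E samples).
#' @param e_mat imputed E-fraction [intensity_matrix()].
#' @param design study design.
#' @param model model analysed.
#' @param fold_min minimum linear E/S enrichment (default 3).
#' @param q BH FDR level for the time-course ANOVA (default 0.05).
#' @return list with `selected` (protein ids), and a per-protein `table`
#'   (`max_mean_log2_ratio`, `anova_q`, the two gate flags).
#' @export
select_insolubilized <- function(ratios, e_mat, design, model,
                                 fold_min = 3, q = 0.05) {
  stopifnot(fold_min >= 1)
  d <- design_lookup(design, colnames(ratios))
  tp <- d$timepoint
  if (length(unique(tp)) < 2L) stopf("need >= 2 time points")
  gm <- rowsum(t(ratios), tp)
  gm <- gm / as.vector(table(tp)[rownames(gm)])
  max_mean <- apply(t(gm), 1L, max)
  gate_fold <- max_mean >= log2(fold_min)
  an <- anova_time_course(e_mat, design, model, q = q)
  stopifnot(identical(an$protein_id, rownames(ratios)))
  sel <- gate_fold & an$significant
  list(selected = rownames(ratios)[sel],
       table = data.frame(protein_id = rownames(ratios),
                          max_mean_log2_ratio = max_mean,
                          anova_q = an$q, fold_gate = gate_fold,
                          anova_gate = an$significant,
                          selected = sel, row.names = NULL,
                          stringsAsFactors = FALSE))
}

#' Induced proteins in the E fraction
#'
#' Applies the induced-protein rule (absent from all controls, detected at
#' T1 and T2) to the pre-imputation detection mask of E-fraction samples.
#'
#' @inheritParams detect_induced
#' @return character vector of protein ids.
#' @export
induced_in_efraction <- function(mask, design, model, min_detect_frac = 0.5) {
  detect_induced(mask, design, model, min_detect_frac)
}
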