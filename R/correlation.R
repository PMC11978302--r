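#' Control-baselined protein abundance deltas
#'
#' Subtracts from every sample the protein's mean log2 intensity over the
#' model's control samples, yielding the temporal abundance-change profile
#' used in the proteome-histology correlation.
#'
#' @param mat imputed [intensity_matrix()] (log2).
#' @param design study design.
#' @param model model analysed.
#' @param fraction restrict to one fraction (`"Total"` or `"E"`); `NULL`
#'   keeps every sample of the model present in the matrix.
#' @return list with `deltas` (proteins x samples of the model) and the
#'   matching `design` rows.
#' @export
baseline_deltas <- function(mat, design, model, fraction = NULL) {
  d <- design_lookup(design, colnames(mat$values))
  cols <- if (is.null(fraction)) which(d$model == model) else
    which(d$model == model & d$fraction == fraction)
  if (length(cols) == 0L) stopf("no samples for model %s", model)
  dc <- d[cols, ]
  ctrl <- which(dc$timepoint == "Ctrl")
  if (length(ctrl) == 0L) stopf("control group missing")
  v <- mat$values[, cols, drop = FALSE]
  ctrl_mean <- rowMeans(v[, ctrl, drop = FALSE])
  list(deltas = v - ctrl_mean, design = dc)
}

#' Control-baselined fibrosis-area deltas
#'
#' Subtracts the mean sirius-red-positive area of the model's control
#' livers (the staining background) from every mouse's area.
#'
#' @param areas data.frame with `mouse_id, model, timepoint, sr_area_pct`.
#' @param model model analysed.
#' @return data.frame `mouse_id, timepoint, delta_area`.
#' @export
fibrosis_deltas <- function(areas, model) {
  sub <- areas[areas$model == model, ]
  if (nrow(sub) == 0L) stopf("no areas for model %s", model)
  if (any(sub$sr_area_pct < 0)) stopf("areas must be >= 0")
  ctrl <- sub$sr_area_pct[sub$timepoint == "Ctrl"]
  if (length(ctrl) == 0L) stopf("control areas missing")
  data.frame(mouse_id = sub$mouse_id, timepoint = sub$timepoint,
             delta_area = sub$sr_area_pct - mean(ctrl),
             stringsAsFactors = FALSE)
}

#' Correlate protein abundance deltas with fibrosis-area deltas
#'
#' The headline procedure: for every protein, the per-mouse abundance delta
#' is paired with that mouse's fibrosis-area delta, and Pearson r, the
#' regression slope and the slope's p-value are computed; slope p-values are
#' BH-adjusted across all proteins of the compartment at level `q`.
#' Control mice are included by default: they are measured animals with
#' measured areas, and they anchor the regression at baseline;
#' `include_controls = FALSE` restricts to the treated time points.
#'
#' @param prot output of [baseline_deltas()].
#' @param area_deltas output of [fibrosis_deltas()].
#' @param q BH FDR level (default 0.05).
#' @param include_controls keep control mice in the regression.
#' @return data.frame per protein: `protein_id, slope, r, p, q,
#'   significant, direction`, plus attribute `"n_points"`.
#' @export
correlate_proteome_fibrosis <- function(prot, area_deltas, q = 0.05,
                                        include_controls = TRUE) {
  d <- prot$design
  keep <- if (include_controls) seq_len(nrow(d)) else
    which(d$timepoint != "Ctrl")
  idx <- match(d$mouse_id[keep], area_deltas$mouse_id)
  if (anyNA(idx))
    stopf("fibrosis areas missing for mice: %s",
          paste(head(unique(d$mouse_id[keep][is.na(idx)]), 5L),
                collapse = ", "))
  x <- area_deltas$delta_area[idx]
  if (length(x) < 3L) stopf("need >= 3 paired points")
  if (var(x) <= 0) stopf("fibrosis-area deltas have zero variance")
  y <- prot$deltas[, keep, drop = FALSE]
  ps <- row_pearson_slope(y, x)
  bh <- benjamini_hochberg(ps$p_value, q)
  out <- data.frame(protein_id = rownames(prot$deltas), slope = ps$slope,
                    r = ps$r, p = ps$p_value, q = bh$adjusted,
                    significant = bh$rejected,
                    direction = ifelse(ps$slope > 0, "positive", "negative"),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_points") <- length(x)
  out
}

#' Classify fibrosis correlates across compartments
#'
#' Partitions significant correlates by sign across the Total and
#' E-fraction compartments.  "Positive in both" is the clusterin-like
#' behaviour: abundance tracking scar formation and resolution in the whole
#' lysate and in the insoluble ECM-enriched fraction.
#'
#' @param total,efrac correlation tables from
#'   [correlate_proteome_fibrosis()] for the Total and E compartments.
#' @return list of protein id sets: `positive_both`, `negative_both`,
#'   `total_specific`, `efraction_specific`.
#' @export
classify_correlates <- function(total, efrac) {
  sig <- function(tab, dir) tab$protein_id[tab$significant &
                                             tab$direction == dir]
  pos_t <- sig(total, "positive"); pos_e <- sig(efrac, "positive")
  neg_t <- sig(total, "negative"); neg_e <- sig(efrac, "negative")
  any_t <- total$protein_id[total$significant]
  any_e <- efrac$protein_id[efrac$significant]
  list(positive_both = intersect(pos_t, pos_e),
       negative_both = intersect(neg_t, neg_e),
       total_specific = setdiff(any_t, any_e),
       efraction_specific = setdiff(any_e, any_t))
}
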