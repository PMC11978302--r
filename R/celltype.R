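#' Cell-type signature scores per mouse
#'
#' Scores each published marker set (hepatocytes, HSCs, BECs, leukocyte
#' populations, ...) per mouse as the mean z-scored intensity over the
#' signature proteins resolvable in the matrix.  Mouse-level aggregation
#' comes first so that downstream group statistics use n = animals.
#' Signatures with no resolvable protein are skipped with a message;
#' unresolved members are dropped and counted.
#'
#' @param z z-scored matrix (proteins x samples).
#' @param design study design for the columns.
#' @param signatures named list: signature -> protein id vector.
#' @return data.frame: `signature, model, timepoint, mouse_id, score,
#'   n_resolved`.
#' @export
signature_scores <- function(z, design, signatures) {
  d <- design_lookup(design, colnames(z))
  out <- list()
  for (sig in names(signatures)) {
    members <- intersect(signatures[[sig]], rownames(z))
    if (length(members) == 0L) {
      message(sprintf("signature '%s' has no resolvable proteins; skipped", sig))
      next
    }
    sub <- z[members, , drop = FALSE]
    score <- colMeans(sub)
    out[[sig]] <- data.frame(signature = sig, model = d$model,
                             timepoint = d$timepoint, mouse_id = d$mouse_id,
                             score = score, n_resolved = length(members),
                             row.names = NULL, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(signature = character(0), model = character(0),
                      timepoint = character(0), mouse_id = character(0),
                      score = numeric(0), n_resolved = integer(0)))
  do.call(rbind, out)
}

#' ANOVA + Bonferroni post-test on signature scores
#'
#' Per (signature, model): one-way ANOVA of the mouse-level scores across
#' time points, then Bonferroni-adjusted pairwise comparisons of every time
#' point against control.
#'
#' @param scores output of [signature_scores()].
#' @return list with `anova` (per signature x model) and `posthoc` (per
#'   signature x model x timepoint vs Ctrl) data.frames.
#' @export
signature_tests <- function(scores) {
  an <- list(); ph <- list()
  for (sig in unique(scores$signature)) {
    for (mod in unique(scores$model[scores$signature == sig])) {
      sub <- scores[scores$signature == sig & scores$model == mod, ]
      tps <- levels(droplevels(order_timepoints(sub$timepoint)))
      groups <- lapply(tps, function(tp) sub$score[sub$timepoint == tp])
      names(groups) <- tps
      if (length(groups) < 2L || any(lengths(groups) < 2L)) next
      a <- one_way_anova(groups)
      an[[length(an) + 1L]] <- data.frame(signature = sig, model = mod,
                                          statistic = a$statistic,
                                          p = a$p_value,
                                          stringsAsFactors = FALSE)
      ref <- which(tps == "Ctrl")
      if (length(ref) == 1L) {
        b <- bonferroni_posttest(groups, reference = ref)
        ph[[length(ph) + 1L]] <- data.frame(signature = sig, model = mod,
                                            timepoint = tps[b$group],
                                            estimate = b$estimate,
                                            p_raw = b$p_raw,
                                            p_adjusted = b$p_adjusted,
                                            stringsAsFactors = FALSE)
      }
    }
  }
  list(anova = if (length(an)) do.call(rbind, an) else NULL,
       posthoc = if (length(ph)) do.call(rbind, ph) else NULL)
}
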