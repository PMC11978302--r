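#!/usr/bin/env Rscript
# Stage 7 — cell-type dynamics and proteome-histology correlation.
#
# Cell-type signature scores (mean z over resolved marker proteins, one
# score per mouse) with ANOVA + Bonferroni post-tests, then the headline
# correlation: per-protein control-baselined abundance deltas against
# per-mouse fibrosis-area deltas (Pearson, slope p, BH < 0.05) for the
# Total and E compartments, classified by sign across compartments.

suppressPackageStartupMessages(library(fibromics))
out <- "results/data"
design <- utils::read.delim(file.path(out, "design.tsv"))
areas <- utils::read.delim(file.path(out, "fibrosis_areas.tsv"))
imp_t <- read_intensity_tsv(file.path(out, "protein_Total_imputed.tsv"))
imp_e <- read_intensity_tsv(file.path(out, "protein_E_imputed.tsv"))
signatures <- read_gmt(file.path(out, "signatures.gmt"))

z <- zscore_rows(imp_t)
scores <- signature_scores(z, design, signatures)
tests <- signature_tests(scores)
utils::write.table(scores, "results/signature_scores.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(tests$posthoc, "results/signature_posthoc.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
sig_hits <- tests$posthoc[tests$posthoc$p_adjusted < 0.05, ]
cat(sprintf("signature shifts vs control (p<0.05): %d of %d tests\n",
            nrow(sig_hits), nrow(tests$posthoc)))

for (m in c("CCl4like", "DDClike")) {
  fd <- fibrosis_deltas(areas, m)
  ct <- correlate_proteome_fibrosis(baseline_deltas(imp_t, design, m), fd)
  ce <- correlate_proteome_fibrosis(baseline_deltas(imp_e, design, m), fd)
  cls <- classify_correlates(ct, ce)
  utils::write.table(ct, sprintf("results/correlation_total_%s.tsv", m),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ce, sprintf("results/correlation_efraction_%s.tsv", m),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(cls$positive_both,
             sprintf("results/positive_both_%s.txt", m))
  cat(sprintf(
    "%s: %d Total / %d E significant correlates; %d positive in both\n",
    m, sum(ct$significant), sum(ce$significant),
    length(cls$positive_both)))
}
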