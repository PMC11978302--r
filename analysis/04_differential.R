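#!/usr/bin/env Rscript
# Stage 4 — differential expression on the Total proteome.
#
# Per model: the 1.5-fold / t-test / BH FDR < 0.05 rule at the fibrosis
# peak (T2 vs control), the time-course one-way ANOVA, and induced-protein
# detection (absent from every control, detected at T1 and T2) from the
# pre-imputation mask.

suppressPackageStartupMessages(library(fibromics))
out <- "results/data"
res_dir <- "results"
design <- utils::read.delim(file.path(out, "design.tsv"))
imp <- read_intensity_tsv(file.path(out, "protein_Total_imputed.tsv"))
filt <- read_intensity_tsv(file.path(out, "protein_Total_filtered.tsv"))

for (m in c("CCl4like", "DDClike")) {
  de <- de_contrast(imp, design, m)
  an <- anova_time_course(imp, design, m)
  ind <- detect_induced(filt$observed, design, m)
  utils::write.table(de, file.path(res_dir, sprintf("de_%s.tsv", m)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(an, file.path(res_dir, sprintf("anova_%s.tsv", m)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(ind, file.path(res_dir, sprintf("induced_%s.txt", m)))
  cat(sprintf(
    "%s: %d/%d DE at T2 (%d up, %d down); %d ANOVA-significant; %d induced\n",
    m, sum(de$significant), nrow(de),
    sum(de$significant & de$direction == "up"),
    sum(de$significant & de$direction == "down"),
    sum(an$significant), length(ind)))
}
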