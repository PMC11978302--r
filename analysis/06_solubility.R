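#!/usr/bin/env Rscript
# Stage 6 — solubility profiling of the ECM-enriched E fraction.
#
# Per model: log2 E/S ratios against the global per-protein S median, the
# threefold enrichment rule in at least one time point, the time-course
# ANOVA gate (BH FDR < 0.05), clustering of the selected ratio profiles,
# and E-fraction induced proteins.

suppressPackageStartupMessages(library(fibromics))
out <- "results/data"
design <- utils::read.delim(file.path(out, "design.tsv"))
e <- read_intensity_tsv(file.path(out, "protein_E_imputed.tsv"))
s <- read_intensity_tsv(file.path(out, "protein_S_imputed.tsv"))
e_filt <- read_intensity_tsv(file.path(out, "protein_E_filtered.tsv"))
shared <- intersect(rownames(e$values), rownames(s$values))
e <- e[match(shared, rownames(e$values)), ]
s <- s[match(shared, rownames(s$values)), ]

for (m in c("CCl4like", "DDClike")) {
  ratios <- es_ratio(e, s, design, m)
  sel <- select_insolubilized(ratios, e, design, m)
  utils::write.table(sel$table, sprintf("results/solubility_%s.tsv", m),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ind <- induced_in_efraction(e_filt$observed, design, m)
  writeLines(ind, sprintf("results/induced_efraction_%s.txt", m))
  cat(sprintf("%s: %d insolubilized proteins; %d E-fraction induced\n",
              m, length(sel$selected), length(ind)))
  if (length(sel$selected) >= 2L) {
    sub <- ratios[sel$selected, , drop = FALSE]
    labels <- cut_clusters(hierarchical_cluster(sub),
                           min(3L, nrow(sub)))
    utils::write.table(data.frame(protein_id = names(labels),
                                  cluster = labels),
                       sprintf("results/solubility_clusters_%s.tsv", m),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
}
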