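#!/usr/bin/env Rscript
# Stage 2 — peptide-level quantification.
#
# For each mouse, its paired S and E fraction runs form one normalization
# unit: proportional coefficients are estimated from the median log-ratios
# of peptides shared between the paired runs and protein intensity is the
# sum of coefficient-scaled unique+razor peptide intensities.  Total runs
# are single experiments (coefficient 1).

suppressPackageStartupMessages(library(fibromics))
out <- "results/data"
peptides <- read_peptide_tsv(file.path(out, "peptides.tsv"))
design <- utils::read.delim(file.path(out, "design.tsv"))

coeffs <- setNames(rep(1, ncol(peptides$intensities)),
                   colnames(peptides$intensities))
se <- design[design$fraction %in% c("S", "E"), ]
for (mouse in unique(se$mouse_id)) {
  pair <- se$sample_id[se$mouse_id == mouse]
  if (length(pair) >= 2L)
    coeffs[pair] <- estimate_proportional_coefficients(peptides, pair)
}
assembled <- assemble_protein_intensity(peptides, coeffs)

utils::write.table(data.frame(sample_id = names(coeffs),
                              coefficient = coeffs),
                   file.path(out, "coefficients.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
for (fr in c("Total", "S", "E")) {
  cols <- design$sample_id[design$fraction == fr]
  write_intensity_tsv(assembled[, match(cols, colnames(assembled$values))],
                      file.path(out, sprintf("protein_%s_assembled.tsv", fr)))
}
cat(sprintf("assembled %d proteins x %d samples; coefficient range %.2f-%.2f\n",
            nrow(assembled$values), ncol(assembled$values),
            min(coeffs), max(coeffs)))
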