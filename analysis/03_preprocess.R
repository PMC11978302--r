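#!/usr/bin/env Rscript
# Stage 3 — filtering, normalization, imputation.
#
# Per fraction: keep proteins with >= 5 observed values in at least one
# (model, time point) group, median-center the sample columns, and impute
# missing cells from a down-shifted Gaussian (mean - 1.8 SD, width 0.3 SD
# of each column's observed values) — the standard treatment of
# left-censored label-free data.

suppressPackageStartupMessages(library(fibromics))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
out <- "results/data"
design <- utils::read.delim(file.path(out, "design.tsv"))

for (fr in c("Total", "S", "E")) {
  raw <- read_intensity_tsv(file.path(out,
                                      sprintf("protein_%s_assembled.tsv", fr)))
  filt <- filter_by_valid_values(raw, design, min_valid = 5L)
  imp <- impute_downshift(normalize_columns(filt),
                          seed = stage_seed(seed, paste0("impute_", fr)))
  write_intensity_tsv(filt, file.path(out,
                                      sprintf("protein_%s_filtered.tsv", fr)))
  write_intensity_tsv(imp, file.path(out,
                                     sprintf("protein_%s_imputed.tsv", fr)))
  cat(sprintf("%s: %d/%d proteins retained, %.1f%% cells imputed\n", fr,
              nrow(filt$values), nrow(raw$values),
              100 * mean(!filt$observed)))
}
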