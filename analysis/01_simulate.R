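#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic fibrosis study.
#
# Emulates the full design: hepatotoxic (CCl4-like, healing) and cholestatic
# (DDC-like, persistent) models, five terminal time points (Ctrl, T1-T2
# progression, T3-T4 resolution), six mice per group, three fractions
# (Total lysate, soluble S, detergent-insoluble ECM-enriched E), peptide
# tables with per-sample loading factors, MNAR missingness, per-mouse
# sirius-red fibrosis areas, matrisome annotations and cell-type marker
# sets.  Planted protein classes (fibrosis-tracking, declining,
# solubility-shifting, null) are recorded as ground truth.

suppressPackageStartupMessages(library(fibromics))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- simulation_config(n_proteins = 600L,
                         seed = stage_seed(seed, "simulate"))
study <- simulate_study(cfg)

write_tsv <- function(df, name) utils::write.table(
  df, file.path(out, name), sep = "\t", quote = FALSE, row.names = FALSE)
write_tsv(study$design, "design.tsv")
write_tsv(study$areas, "fibrosis_areas.tsv")
write_peptide_tsv(study$peptides, file.path(out, "peptides.tsv"))
for (fr in names(study$matrices))
  write_intensity_tsv(study$matrices[[fr]],
                      file.path(out, sprintf("protein_%s_raw.tsv", fr)))
write_gmt(study$signatures, file.path(out, "signatures.gmt"))
write_gmt(study$annotations, file.path(out, "annotations.gmt"))
jsonlite::write_json(
  list(class = as.list(study$ground_truth$class),
       seed = cfg$seed, n_proteins = cfg$n_proteins),
  file.path(out, "ground_truth.json"), auto_unbox = TRUE)

cat(sprintf("study: %d proteins, %d samples, %.1f%% cells observed\n",
            cfg$n_proteins, nrow(study$design),
            100 * mean(study$matrices$Total$observed)))
cat(sprintf("planted classes: %s\n",
            paste(names(table(study$ground_truth$class)),
                  table(study$ground_truth$class), collapse = ", ",
                  sep = "=")))
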