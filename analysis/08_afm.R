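#!/usr/bin/env Rscript
# Stage 8 — AFM stiffness analysis of the hepatotoxic model.
#
# Simulates force-curve maps (10 x 36 pixels, 7 areas per region and
# treatment over 3 mice) at the reference moduli, fits each curve
# (two-segment contact detection + Hertz sphere, nu = 0.45, R = 2.85 um),
# summarizes per-region stiffness, compares treatments against control
# (Kruskal-Wallis + Dunn on pooled pixels) and correlates per-mouse
# stiffness deltas with protein abundance deltas.

suppressPackageStartupMessages(library(fibromics))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
out <- "results/data"
design <- utils::read.delim(file.path(out, "design.tsv"))
imp_t <- read_intensity_tsv(file.path(out, "protein_Total_imputed.tsv"))

fcs <- simulate_afm_experiment(n_maps = 7L, noise_cv = 0.05,
                               seed = stage_seed(seed, "afm"))
fits <- fit_stiffness_map(fcs)
stats <- build_region_stats(fits)
tests <- compare_regions(fits)

utils::write.table(stats$summary, "results/afm_region_summary.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(tests, "results/afm_region_tests.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

bd <- baseline_deltas(imp_t, design, "CCl4like")
prot_by_mouse <- bd$deltas
colnames(prot_by_mouse) <- bd$design$mouse_id
corr <- correlate_stiffness_proteome(stats$per_map, prot_by_mouse)
utils::write.table(corr, "results/afm_proteome_correlation.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

for (tr in c("Ctrl", "T1", "T2", "T4")) {
  med <- stats$summary[stats$summary$treatment == tr, ]
  cat(sprintf("%s: %s\n", tr,
              paste(sprintf("%s %.1f kPa", med$region, med$median_E / 1000),
                    collapse = ", ")))
}
cat(sprintf("stiffness-proteome: %d significant (region, protein) pairs\n",
            sum(corr$significant)))
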