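#!/usr/bin/env Rscript
# Stage 5 — unsupervised structure of the Total proteome.
#
# PCA of the imputed matrix, hierarchical clustering (Euclidean, complete
# linkage) of mean z-scored profiles per (model, time point), and cluster
# annotation enrichment by Fisher's exact test at BH FDR < 4%.

suppressPackageStartupMessages(library(fibromics))
out <- "results/data"
design <- utils::read.delim(file.path(out, "design.tsv"))
imp <- read_intensity_tsv(file.path(out, "protein_Total_imputed.tsv"))
catalog <- read_gmt(file.path(out, "annotations.gmt"))

pca <- pca_scores(imp)
cat(sprintf("PC1/PC2 explain %.1f%% / %.1f%% of sample variance\n",
            100 * pca$explained_variance[1], 100 * pca$explained_variance[2]))

z <- zscore_rows(imp)
profiles <- group_mean_profiles(z, design)
dend <- hierarchical_cluster(profiles)
labels <- cut_clusters(dend, 5L)
enr <- cluster_annotation_enrichment(labels, catalog, q = 0.04)

utils::write.table(data.frame(sample_id = rownames(pca$scores),
                              pca$scores[, 1:2]),
                   "results/pca_scores.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
utils::write.table(data.frame(protein_id = names(labels), cluster = labels),
                   "results/clusters.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
utils::write.table(enr, "results/cluster_enrichment.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
hit <- enr[enr$enriched & enr$term == "matrisome", ]
cat(sprintf("clusters: %s; matrisome-enriched: %s\n",
            paste(table(labels), collapse = "/"),
            if (nrow(hit)) paste(hit$cluster, collapse = ", ") else "none"))
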