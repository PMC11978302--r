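#' Principal component analysis of samples
#'
#' Column-centered SVD of the sample x protein matrix: samples are the
#' observations, proteins the variables.  Explained-variance fractions sum
#' to 1 over all components.  Sign convention: within each component the
#' largest-magnitude loading is made positive, so score orientations are
#' reproducible.
#'
#' @param mat imputed [intensity_matrix()] or plain matrix
#'   (proteins x samples).
#' @return list with `scores` (samples x components), `loadings`
#'   (proteins x components) and `explained_variance` fractions.
#' @export
pca_scores <- function(mat) {
  v <- if (inherits(mat, "intensity_matrix")) mat$values else as.matrix(mat)
  if (ncol(v) < 2L) stopf("PCA needs >= 2 samples")
  if (anyNA(v)) stopf("PCA requires an imputed matrix")
  x <- t(v)                       # samples as rows
  x <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(x)
  k <- sum(sv$d > max(sv$d) * 1e-12)
  d <- sv$d[seq_len(k)]
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(d, k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(i) {
    j <- which.max(abs(loadings[, i]))
    sign(loadings[j, i])
  }, numeric(1))
  scores <- sweep(scores, 2L, flip, `*`)
  loadings <- sweep(loadings, 2L, flip, `*`)
  ev <- sv$d^2 / sum(sv$d^2)
  rownames(scores) <- colnames(v)
  rownames(loadings) <- rownames(v)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  list(scores = scores, loadings = loadings,
       explained_variance = ev[seq_len(k)], all_variance = ev)
}

#' Agglomerative hierarchical clustering (Euclidean, complete linkage)
#'
#' Clusters row profiles (typically mean z-scored intensities per group)
#' with Euclidean distance and complete linkage, the configuration used for
#' the proteome heatmaps.  Merges are deterministic; distance ties are
#' broken by the lowest row index (the behaviour of [stats::hclust()]).
#'
#' @param profiles numeric matrix without missing values; rows are
#'   clustered.
#' @return an object of class `hclust`.
#' @export
hierarchical_cluster <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2L) stopf("need >= 2 rows to cluster")
  if (anyNA(profiles)) stopf("profiles must not contain missing values")
  hclust(dist(profiles, method = "euclidean"), method = "complete")
}

#' Cut a dendrogram into k clusters with stable labels
#'
#' Labels are renumbered by order of first appearance along the dendrogram
#' leaf order, so cluster 1 is always the leftmost in a heatmap.
#'
#' @param dend an `hclust` object.
#' @param k number of clusters, `1 <= k <= n`.
#' @return integer vector of cluster labels named by row.
#' @export
cut_clusters <- function(dend, k) {
  n <- length(dend$order)
  if (k < 1L || k > n) stopf("k must be in [1, %d]", n)
  raw <- cutree(dend, k = k)
  first_seen <- unique(raw[dend$order])
  relabel <- match(raw, first_seen)
  names(relabel) <- names(raw)
  relabel
}

#' Annotation enrichment of clusters by Fisher's exact test
#'
#' For every (cluster, annotation term) pair, builds the 2x2 table of
#' in/out-of-cluster versus term membership over the clustered proteins,
#' computes the two-sided Fisher p, and adjusts across all pairs by BH at
#' level `q` (the heatmap analyses use q = 0.04).  Terms annotating none of
#' the clustered proteins are skipped.
#'
#' @param labels named integer cluster labels (names = protein ids).
#' @param catalog named list: term -> character vector of member protein
#'   ids.
#' @param q BH FDR level (default 0.04).
#' @return data.frame: `cluster, term, n_in_term, n_in, n_term, n_total,
#'   odds_ratio, p, q, enriched`.
#' @export
cluster_annotation_enrichment <- function(labels, catalog, q = 0.04) {
  ids <- names(labels)
  if (is.null(ids)) stopf("labels must be named by protein id")
  rows <- list()
  for (term in names(catalog)) {
    member <- ids %in% catalog[[term]]
    if (!any(member)) next
    for (cl in sort(unique(labels))) {
      inc <- labels == cl
      tab <- matrix(c(sum(inc & member), sum(inc & !member),
                      sum(!inc & member), sum(!inc & !member)), 2L, 2L)
      ft <- fisher_exact(tab)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, term = term, n_in_term = tab[1, 1],
        n_in = sum(inc), n_term = sum(member), n_total = length(ids),
        odds_ratio = ft$odds_ratio, p = ft$p_value,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(cluster = integer(0), term = character(0),
                      n_in_term = integer(0), n_in = integer(0),
                      n_term = integer(0), n_total = integer(0),
                      odds_ratio = numeric(0), p = numeric(0),
                      q = numeric(0), enriched = logical(0)))
  out <- do.call(rbind, rows)
  bh <- benjamini_hochberg(out$p, q)
  out$q <- bh$adjusted
  out$enriched <- bh$rejected & out$odds_ratio > 1
  out
}

#' Mean profile per (model, time point) group
#'
#' Collapses a z-scored matrix to the group means used as clustering input
#' for the heatmap analyses.
#'
#' @param z z-scored matrix (proteins x samples).
#' @param design study design for the columns.
#' @return matrix proteins x groups, columns named `<model>.<timepoint>` in
#'   canonical time order.
#' @export
group_mean_profiles <- function(z, design) {
  d <- design_lookup(design, colnames(z))
  key <- paste(d$model, d$timepoint, sep = ".")
  ord <- order(d$model, order_timepoints(d$timepoint))
  key_levels <- unique(key[ord])
  gm <- rowsum(t(z), key)                      # groups x proteins
  gm <- gm / as.vector(table(key)[rownames(gm)])
  t(gm)[, key_levels, drop = FALSE]
}
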