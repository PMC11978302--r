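#' Peptide table constructor
#'
#' Long-to-wide peptide quantification input: one row per peptide, with its
#' (pre-assigned) protein, evidence class, and one linear-scale intensity
#' column per sample.  Missing observations are `NA`, never zero.
#'
#' @param peptide_id,protein_id character vectors.
#' @param evidence_class `"unique"`, `"razor"` or `"other"` per peptide.
#' @param intensities numeric matrix (peptides x samples), linear scale,
#'   `NA` for missing; column names are sample ids.
#' @return a `peptide_table` (data.frame with an `intensities` matrix
#'   attribute kept alongside for fast math).
#' @export
peptide_table <- function(peptide_id, protein_id, evidence_class,
                          intensities) {
  intensities <- as.matrix(intensities)
  stopifnot(length(peptide_id) == nrow(intensities),
            length(protein_id) == nrow(intensities),
            all(evidence_class %in% c("unique", "razor", "other")))
  if (any(intensities < 0, na.rm = TRUE))
    stopf("peptide intensities must be >= 0 or NA")
  if (is.null(colnames(intensities)))
    stopf("peptide intensities need sample ids as column names")
  rownames(intensities) <- peptide_id
  structure(list(peptide_id = as.character(peptide_id),
                 protein_id = as.character(protein_id),
                 evidence_class = as.character(evidence_class),
                 intensities = intensities),
            class = "peptide_table")
}

#' @export
print.peptide_table <- function(x, ...) {
  cat(sprintf("<peptide_table> %d peptides, %d proteins, %d samples\n",
              length(x$peptide_id), length(unique(x$protein_id)),
              ncol(x$intensities)))
  invisible(x)
}

#' Estimate per-sample proportional coefficients from shared peptides
#'
#' The fraction-aware normalization at the heart of label-free
#' quantification across paired runs: for every pair of samples, the median
#' log-ratio of peptides observed in both defines a pairwise scaling target;
#' the per-sample coefficients are the least-squares solution of all
#' pairwise targets in log space, gauged so that the geometric mean of the
#' coefficients within each connected group of samples is 1.  Samples that
#' share no peptide with any other sample get coefficient 1 with a warning.
#'
#' Peptides of the requested evidence classes (unique + razor by default)
#' enter the pairwise medians.
#'
#' @param peptides a [peptide_table()].
#' @param samples sample ids to normalize together (one "experiment", e.g.
#'   a paired S/E fraction set); default all columns.
#' @param classes evidence classes used.
#' @return named numeric vector of positive coefficients, one per sample,
#'   with attribute `gauge = "geometric_mean_1"`.
#' @export
estimate_proportional_coefficients <- function(peptides,
                                               samples = colnames(peptides$intensities),
                                               classes = c("unique", "razor")) {
  x <- peptides$intensities[peptides$evidence_class %in% classes, samples,
                            drop = FALSE]
  n <- length(samples)
  if (n < 2L) stopf("need >= 2 samples to estimate coefficients")
  lx <- log2(x)
  lx[!is.finite(lx)] <- NA  # zero intensities carry no ratio information
  pairs <- utils::combn(n, 2L)
  rows <- list(); target <- numeric(0)
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    shared <- !is.na(lx[, i]) & !is.na(lx[, j])
    if (!any(shared)) next
    m_ij <- median(lx[shared, i] - lx[shared, j])  # median log2 I_i/I_j
    row <- numeric(n); row[i] <- 1; row[j] <- -1
    rows[[length(rows) + 1L]] <- row
    # c_i * I_i should equal c_j * I_j  =>  log c_i - log c_j = -m_ij
    target <- c(target, -m_ij)
  }
  if (length(rows) == 0L) stopf("disconnected design: no shared peptides")
  A <- do.call(rbind, rows)
  # connected components of the pairwise-equation graph
  comp <- seq_len(n)
  for (r in seq_len(nrow(A))) {
    ij <- which(A[r, ] != 0)
    old <- comp[ij[2]]; comp[comp == old] <- comp[ij[1]]
  }
  logc <- numeric(n)
  isolated <- !(seq_len(n) %in% unlist(apply(A, 1L, function(r) which(r != 0),
                                             simplify = FALSE)))
  if (any(isolated))
    warnf("samples with no shared peptides get coefficient 1: %s",
          paste(samples[isolated], collapse = ", "))
  for (cc in unique(comp)) {
    members <- which(comp == cc)
    if (length(members) == 1L) next  # isolated: log c = 0
    use <- which(apply(A[, members, drop = FALSE] != 0, 1L, any))
    Ac <- A[use, members, drop = FALSE]
    # least squares with the gauge sum(log c) = 0 inside the component
    Ag <- rbind(Ac, rep(1, length(members)))
    bg <- c(target[use], 0)
    fit <- qr.solve(crossprod(Ag), crossprod(Ag, bg))
    logc[members] <- fit
  }
  coef <- 2^as.vector(logc)
  names(coef) <- samples
  attr(coef, "gauge") <- "geometric_mean_1"
  coef
}

#' Assemble protein intensities from normalized peptides
#'
#' Protein intensity per sample is the sum of coefficient-scaled intensities
#' of its unique + razor peptides.  A protein with no observed peptide in a
#' sample is missing in that sample (never zero).
#'
#' @param peptides a [peptide_table()].
#' @param coeffs named coefficient vector covering all requested samples
#'   (see [estimate_proportional_coefficients()]); default all 1.
#' @param classes evidence classes summed; must be a subset of
#'   `unique`, `razor`, `other`.
#' @param log2_output return log2 intensities (the pipeline's working
#'   scale) rather than linear sums.
#' @return an [intensity_matrix()] (provenance `"raw"`).
#' @export
assemble_protein_intensity <- function(peptides, coeffs = NULL,
                                       classes = c("unique", "razor"),
                                       log2_output = TRUE) {
  bad <- setdiff(classes, c("unique", "razor", "other"))
  if (length(bad)) stopf("unknown evidence class: %s", paste(bad, collapse = ", "))
  samples <- colnames(peptides$intensities)
  if (is.null(coeffs)) coeffs <- setNames(rep(1, length(samples)), samples)
  if (!all(samples %in% names(coeffs)))
    stopf("coefficients do not cover all samples")
  keep <- peptides$evidence_class %in% classes
  x <- peptides$intensities[keep, , drop = FALSE]
  x <- sweep(x, 2L, coeffs[samples], `*`)
  prot <- peptides$protein_id[keep]
  x0 <- x; x0[is.na(x0)] <- 0
  sums <- rowsum(x0, prot)
  nobs <- rowsum((!is.na(x)) * 1, prot)
  sums[nobs == 0] <- NA
  vals <- if (log2_output) log2(sums) else sums
  intensity_matrix(vals, observed = nobs > 0, provenance = "raw")
}
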