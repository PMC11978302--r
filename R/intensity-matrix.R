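#' Protein intensity matrix with an explicit missingness mask
#'
#' The pipeline's central container: a proteins x samples matrix of log2
#' intensities plus a logical mask recording which cells were actually
#' observed.  Missing cells hold `NA` in `values` until imputation; after
#' imputation every cell holds a number but the mask still distinguishes
#' observed from imputed, which downstream detection-based rules (induced
#' proteins) rely on.
#'
#' @param values numeric matrix (proteins x samples) of log2 intensities;
#'   missing cells `NA`.
#' @param observed logical matrix of the same shape, `TRUE` where a value was
#'   measured.  Defaults to `!is.na(values)`.
#' @param provenance one of `"raw"`, `"normalized"`, `"imputed"`.
#' @param seed imputation seed, recorded once the matrix is imputed.
#' @return an `intensity_matrix` object.
#' @export
intensity_matrix <- function(values, observed = !is.na(values),
                             provenance = c("raw", "normalized", "imputed"),
                             seed = NULL) {
  provenance <- match.arg(provenance)
  values <- as.matrix(values)
  observed <- as.matrix(observed)
  if (!identical(dim(values), dim(observed)))
    stopf("values and observed mask differ in shape")
  if (is.null(rownames(values)) && nrow(values) > 0L)
    rownames(values) <- paste0("P", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    stopf("intensity matrix needs sample ids as column names")
  dimnames(observed) <- dimnames(values)
  if (provenance != "imputed" && any(!observed & !is.na(values)))
    stopf("unobserved cells must be NA before imputation")
  if (provenance == "imputed" && anyNA(values))
    stopf("imputed matrix may not contain NA")
  structure(list(values = values, observed = observed,
                 provenance = provenance, seed = seed),
            class = "intensity_matrix")
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

#' @export
dimnames.intensity_matrix <- function(x) dimnames(x$values)

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("<intensity_matrix> %d proteins x %d samples [%s]%s\n",
              nrow(x$values), ncol(x$values), x$provenance,
              if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  cat(sprintf("  observed: %.1f%% of cells\n", 100 * mean(x$observed)))
  invisible(x)
}

#' Subset an intensity matrix
#'
#' @param x an `intensity_matrix`.
#' @param i,j row (protein) and column (sample) indices.
#' @param ... ignored.
#' @export
`[.intensity_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  intensity_matrix(x$values[i, j, drop = FALSE],
                   x$observed[i, j, drop = FALSE],
                   provenance = x$provenance, seed = x$seed)
}

#' Build a study design table
#'
#' Maps every sample (intensity column) to its model, time point, fraction
#' and mouse.  Sample ids follow `<model>.<timepoint>.<fraction>.m<mouse>`.
#'
#' @param models character vector of model names, e.g.
#'   `c("CCl4like", "DDClike")`.
#' @param timepoints character vector, default `Ctrl, T1..T4`.
#' @param fractions character vector among `Total`, `S`, `E`.
#' @param n_mice mice per (model, time point) group.
#' @return data.frame with columns `sample_id, model, timepoint, fraction,
#'   mouse_id`.
#' @export
study_design <- function(models = c("CCl4like", "DDClike"),
                         timepoints = timepoint_levels(),
                         fractions = c("Total", "S", "E"),
                         n_mice = 6L) {
  g <- expand.grid(mouse = seq_len(n_mice), fraction = fractions,
                   timepoint = timepoints, model = models,
                   stringsAsFactors = FALSE)
  # one physical mouse yields all three fractions at its terminal time point
  g$mouse_id <- sprintf("%s.%s.m%d", g$model, g$timepoint, g$mouse)
  g$sample_id <- sprintf("%s.%s.%s.m%d", g$model, g$timepoint, g$fraction,
                         g$mouse)
  data.frame(sample_id = g$sample_id, model = g$model,
             timepoint = g$timepoint, fraction = g$fraction,
             mouse_id = g$mouse_id, stringsAsFactors = FALSE)
}

# design rows for a set of sample ids, in that order; errors on unmapped ids
design_lookup <- function(design, sample_ids) {
  idx <- match(sample_ids, design$sample_id)
  if (anyNA(idx))
    stopf("samples missing from design: %s",
          paste(head(sample_ids[is.na(idx)], 5L), collapse = ", "))
  design[idx, , drop = FALSE]
}
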