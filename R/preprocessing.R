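#' Filter proteins by valid values per group
#'
#' Keeps proteins with at least `min_valid` observed values in at least one
#' (time point) group.  Scope `"any_group_per_model"` forms groups per
#' (model, time point); `"any_group_joint"` pools both models per time
#' point, mirroring a joint filter across models.
#'
#' @param mat an [intensity_matrix()].
#' @param design study design covering every column of `mat`.
#' @param min_valid minimum observed values in a qualifying group
#'   (default 5).
#' @param scope `"any_group_per_model"` (default) or `"any_group_joint"`.
#' @return the filtered `intensity_matrix`; row order preserved.  The
#'   dropped protein ids are kept in attribute `"dropped"`.
#' @export
filter_by_valid_values <- function(mat, design, min_valid = 5L,
                                   scope = c("any_group_per_model",
                                             "any_group_joint")) {
  scope <- match.arg(scope)
  stopifnot(min_valid >= 1L)
  d <- design_lookup(design, colnames(mat$values))
  group <- if (scope == "any_group_per_model")
    paste(d$model, d$timepoint) else d$timepoint
  counts <- t(rowsum(t(mat$observed * 1), group))
  keep <- apply(counts >= min_valid, 1L, any)
  out <- mat[keep, ]
  attr(out, "dropped") <- rownames(mat$values)[!keep]
  out
}

#' Median-center sample columns
#'
#' Subtracts each column's observed median and re-adds the grand median of
#' all observed values, equalizing column medians while keeping the overall
#' intensity scale.  The missingness mask is unchanged.
#'
#' @param mat an [intensity_matrix()] on the log2 scale.
#' @param method `"median_center"` or `"none"`.
#' @return a normalized `intensity_matrix`.
#' @export
normalize_columns <- function(mat, method = c("median_center", "none")) {
  method <- match.arg(method)
  if (method == "none") return(mat)
  v <- mat$values
  if (any(colSums(mat$observed) == 0L)) stopf("all-missing column")
  med <- apply(v, 2L, median, na.rm = TRUE)
  grand <- median(v[mat$observed])
  v <- sweep(v, 2L, med) + grand
  intensity_matrix(v, mat$observed, provenance = "normalized")
}

#' Impute missing values from a down-shifted Gaussian
#'
#' Left-censored (missing-not-at-random) imputation: each missing cell is
#' replaced by a draw from `Normal(m - shift * s, (width * s)^2)` where `m`
#' and `s` are the mean and SD of the observed values of the chosen scope
#' (per column by default, or of the whole matrix).  Defaults `shift = 1.8`,
#' `width = 0.3` are the field's standard down-shift parameters.  Observed
#' cells are never touched; given a seed, the result is reproducible (draws
#' are consumed in row-major order over missing cells).
#'
#' @param mat an [intensity_matrix()] on the log2 scale.
#' @param shift down-shift in observed-SD units (default 1.8).
#' @param width width of the imputation distribution in observed-SD units
#'   (default 0.3).
#' @param per `"column"` (default) or `"matrix"` scope for `m` and `s`.
#' @param seed integer seed.
#' @return an imputed `intensity_matrix` carrying the seed.
#' @export
impute_downshift <- function(mat, shift = 1.8, width = 0.3,
                             per = c("column", "matrix"), seed = 1L) {
  per <- match.arg(per)
  stopifnot(shift > 0, width > 0)
  v <- mat$values
  miss <- !mat$observed
  if (!any(miss))
    return(intensity_matrix(v, mat$observed, provenance = "imputed",
                            seed = as.integer(seed)))
  if (per == "column") {
    nobs <- colSums(mat$observed)
    if (any(nobs < 2L)) stopf("column with < 2 observed values")
    m <- apply(v, 2L, mean, na.rm = TRUE)
    s <- apply(v, 2L, sd, na.rm = TRUE)
    mu <- matrix(m, nrow(v), ncol(v), byrow = TRUE)
    sig <- matrix(s, nrow(v), ncol(v), byrow = TRUE)
  } else {
    obs <- v[mat$observed]
    if (length(obs) < 2L) stopf("matrix has < 2 observed values")
    mu <- matrix(mean(obs), nrow(v), ncol(v))
    sig <- matrix(sd(obs), nrow(v), ncol(v))
  }
  # row-major order over missing cells for reproducibility
  miss_t <- t(miss)
  idx_rowmajor <- which(miss_t)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  draws <- rnorm(length(idx_rowmajor))
  vt <- t(v); mut <- t(mu); sigt <- t(sig)
  vt[idx_rowmajor] <- mut[idx_rowmajor] - shift * sigt[idx_rowmajor] +
    width * sigt[idx_rowmajor] * draws
  intensity_matrix(t(vt), mat$observed, provenance = "imputed",
                   seed = as.integer(seed))
}

# save/restore the global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Z-score matrix rows
#'
#' Centers and scales every protein profile to mean 0, SD 1, using the
#' population (divide-by-n) SD.  Constant rows cannot be scaled; they are
#' excluded and reported in the `"excluded"` attribute.
#'
#' @param mat an imputed [intensity_matrix()] (no missing values) or a plain
#'   numeric matrix.
#' @return a numeric matrix of z-scores (possibly fewer rows), with
#'   attribute `"excluded"` naming the constant rows.
#' @export
zscore_rows <- function(mat) {
  v <- if (inherits(mat, "intensity_matrix")) mat$values else as.matrix(mat)
  if (anyNA(v)) stopf("z-scoring requires a fully observed (imputed) matrix")
  m <- rowMeans(v)
  s <- sqrt(rowMeans((v - m)^2))  # population SD
  const <- s == 0
  z <- (v[!const, , drop = FALSE] - m[!const]) / s[!const]
  attr(z, "excluded") <- rownames(v)[const]
  z
}
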