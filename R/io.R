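#' Write / read an intensity matrix as TSV with a provenance sidecar
#'
#' The TSV holds `protein_id` plus one column per sample; missing cells are
#' empty.  A sidecar JSON (`<path>.json`) records provenance, the seed and
#' the observed-cell mask is recoverable because imputed matrices also store
#' the mask as a companion TSV of 0/1 flags.
#'
#' @param mat an [intensity_matrix()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_intensity_tsv <- function(mat, path) {
  df <- data.frame(protein_id = rownames(mat$values), mat$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  mask <- data.frame(protein_id = rownames(mat$values), mat$observed * 1L,
                     check.names = FALSE)
  write.table(mask, paste0(path, ".mask.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(list(provenance = mat$provenance,
                            seed = mat$seed),
                       paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_intensity_tsv
#' @export
read_intensity_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df$protein_id
  mask_path <- paste0(path, ".mask.tsv")
  meta_path <- paste0(path, ".json")
  observed <- if (file.exists(mask_path)) {
    md <- read.delim(mask_path, check.names = FALSE)
    m <- as.matrix(md[, -1, drop = FALSE]) > 0
    rownames(m) <- md$protein_id
    m
  } else !is.na(v)
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path) else list(provenance = "raw", seed = NULL)
  intensity_matrix(v, observed, provenance = meta$provenance %||% "raw",
                   seed = meta$seed)
}

#' Write / read a peptide table TSV
#'
#' Columns: `peptide_id`, `protein_id`, `evidence_class`, then one linear
#' intensity column per sample (empty = missing).
#'
#' @param peptides a [peptide_table()].
#' @param path TSV path.
#' @export
write_peptide_tsv <- function(peptides, path) {
  df <- data.frame(peptide_id = peptides$peptide_id,
                   protein_id = peptides$protein_id,
                   evidence_class = peptides$evidence_class,
                   peptides$intensities, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peptide_tsv
#' @export
read_peptide_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  peptide_table(df$peptide_id, df$protein_id, df$evidence_class,
                as.matrix(df[, -(1:3), drop = FALSE]))
}

#' Read / write gene-set (GMT) files
#'
#' One set per line: name, description, then member ids, tab-separated —
#' the standard gene-set exchange format.
#'
#' @param sets named list of character vectors.
#' @param path GMT path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  sets
}

#' Write a force-curve set to per-curve TSVs plus a JSON manifest
#'
#' Each curve becomes a two-column TSV (`height_m`, `force_N`); the
#' manifest records per-curve metadata (grid position, region, treatment,
#' mouse, map) and the probe constants.
#'
#' @param fcs force-curve set (see [simulate_force_curves()]).
#' @param dir output directory (created).
#' @export
write_force_curves <- function(fcs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(nrow(fcs$meta))
  for (i in seq_along(fcs$curves)) {
    files[i] <- file.path(dir, paste0(fcs$meta$curve_id[i], ".tsv"))
    write.table(data.frame(height_m = fcs$curves[[i]]$z,
                           force_N = fcs$curves[[i]]$force),
                files[i], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(R = fcs$R, nu = fcs$nu, k = fcs$k,
                   curves = cbind(fcs$meta, file = basename(files)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' @rdname write_force_curves
#' @export
read_force_curves <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  meta <- manifest$curves
  curves <- lapply(meta$file, function(f) {
    df <- read.delim(file.path(dir, f))
    list(z = df$height_m, force = df$force_N)
  })
  meta$file <- NULL
  list(curves = curves, meta = meta, R = manifest$R, nu = manifest$nu,
       k = manifest$k)
}

# simple TSV helpers for design / fibrosis / generic tables
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
read_tsv <- function(path) read.delim(path, check.names = FALSE,
                                      stringsAsFactors = FALSE)
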