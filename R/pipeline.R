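#' Default run configuration
#'
#' All stage parameters of the pipeline in one serializable list, with the
#' study's standard settings: valid-value filter >= 5, imputation down-shift
#' 1.8 / width 0.3, differential rule 1.5-fold at BH FDR 0.05, solubility
#' rule threefold at FDR 0.05, cluster enrichment FDR 0.04, correlation FDR
#' 0.05, AFM grid 10 x 36 with probe radius 2.85 um, Poisson ratio 0.45 and
#' spring constant 0.09 N/m.
#'
#' @param n_proteins simulated proteome size for the built-in study.
#' @param seed master seed fanned out to all stages.
#' @return a `run_config` list.
#' @export
run_config <- function(n_proteins = 600L, seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    sim = list(n_proteins = as.integer(n_proteins)),
    filter = list(min_valid = 5L, scope = "any_group_per_model"),
    impute = list(shift = 1.8, width = 0.3, per = "column"),
    de = list(fold_change_min = 1.5, q = 0.05, contrast = "T2",
              reference = "Ctrl"),
    cluster = list(k = 5L, enrichment_q = 0.04),
    solubility = list(fold_min = 3, q = 0.05, scope = "global"),
    correlation = list(q = 0.05, include_controls = TRUE),
    afm = list(grid = c(10L, 36L), n_maps = 7L, n_mice = 3L,
               noise_cv = 0.05, R = 2.85e-6, nu = 0.45, k = 0.09,
               q = 0.05)),
    class = "run_config")
}

#' Validate a run configuration
#'
#' Rejects out-of-range parameters and warns (as diagnostics, not errors)
#' when a value deviates from the pipeline's standard defaults.
#'
#' @param config a [run_config()] (possibly edited).
#' @return list with `ok`, `errors`, `warnings`.
#' @export
validate_config <- function(config) {
  errors <- character(0); warnings <- character(0)
  chk <- function(cond, msg) if (!cond) errors <<- c(errors, msg)
  dev <- function(cond, msg) if (cond) warnings <<- c(warnings, msg)
  chk(config$filter$min_valid >= 1, "filter$min_valid must be >= 1")
  chk(config$impute$shift > 0, "impute$shift must be > 0")
  chk(config$impute$width > 0, "impute$width must be > 0")
  chk(config$de$q > 0 && config$de$q < 1, "de$q must lie in (0, 1)")
  chk(config$de$fold_change_min >= 1, "de$fold_change_min must be >= 1")
  chk(config$solubility$fold_min >= 1, "solubility$fold_min must be >= 1")
  chk(config$solubility$q > 0 && config$solubility$q < 1,
      "solubility$q must lie in (0, 1)")
  chk(config$cluster$enrichment_q > 0 && config$cluster$enrichment_q < 1,
      "cluster$enrichment_q must lie in (0, 1)")
  chk(config$correlation$q > 0 && config$correlation$q < 1,
      "correlation$q must lie in (0, 1)")
  chk(config$afm$nu >= 0 && config$afm$nu < 0.5,
      "afm$nu must lie in [0, 0.5)")
  chk(config$afm$R > 0, "afm$R must be > 0")
  dev(config$filter$min_valid != 5L, "filter$min_valid deviates from 5")
  dev(config$impute$shift != 1.8, "impute$shift deviates from 1.8")
  dev(config$impute$width != 0.3, "impute$width deviates from 0.3")
  dev(config$de$fold_change_min != 1.5,
      "de$fold_change_min deviates from 1.5")
  dev(config$de$q != 0.05, "de$q deviates from 0.05")
  dev(config$solubility$fold_min != 3, "solubility$fold_min deviates from 3")
  dev(config$cluster$enrichment_q != 0.04,
      "cluster$enrichment_q deviates from 0.04")
  dev(config$afm$nu != 0.45, "afm$nu deviates from 0.45")
  list(ok = length(errors) == 0L, errors = errors, warnings = warnings)
}

# coefficients per "experiment": each mouse's paired S/E samples are one
# normalization unit; Total samples are single-run experiments (coefficient 1)
pair_coefficients <- function(peptides, design) {
  samples <- colnames(peptides$intensities)
  d <- design_lookup(design, samples)
  coeffs <- setNames(rep(1, length(samples)), samples)
  se <- d[d$fraction %in% c("S", "E"), ]
  for (mouse in unique(se$mouse_id)) {
    pair <- se$sample_id[se$mouse_id == mouse]
    if (length(pair) < 2L) next
    coeffs[pair] <- estimate_proportional_coefficients(peptides, pair)
  }
  coeffs
}

#' Run the complete analysis pipeline on a synthetic study
#'
#' Executes every stage in dependency order: simulation, peptide-level
#' quantification (proportional coefficients for paired S/E fractions,
#' protein assembly), filtering/normalization/imputation per fraction and
#' model, differential expression and induced-protein detection on the
#' Total proteome, clustering with annotation enrichment, solubility
#' profiling of the E fraction, cell-type signature dynamics,
#' proteome-fibrosis correlation for Total and E compartments, and the AFM
#' stiffness analysis with the stiffness-proteome correlation.  All outputs
#' are written as TSV under `out_dir` and hashed into the run report.
#'
#' @param config a [run_config()].
#' @param out_dir output directory; created.  `NULL` skips file output.
#' @return invisible list of in-memory stage results plus `report`.
#' @export
run_study_pipeline <- function(config = run_config(), out_dir = NULL) {
  val <- validate_config(config)
  if (!val$ok) stopf("invalid configuration: %s",
                     paste(val$errors, collapse = "; "))
  seed <- config$seed
  outputs <- list()
  t0 <- Sys.time()

  # --- simulate ---------------------------------------------------------
  sim_cfg <- do.call(simulation_config,
                     c(config$sim, list(seed = stage_seed(seed, "simulate"))))
  study <- simulate_study(sim_cfg, peptides = TRUE)

  # --- quantification ---------------------------------------------------
  coeffs <- pair_coefficients(study$peptides, study$design)
  assembled <- assemble_protein_intensity(study$peptides, coeffs)
  fractions <- c("Total", "S", "E")
  mats_raw <- lapply(fractions, function(fr) {
    cols <- study$design$sample_id[study$design$fraction == fr]
    assembled[, match(cols, colnames(assembled$values))]
  })
  names(mats_raw) <- fractions

  # --- preprocessing (per fraction) ------------------------------------
  prep <- lapply(fractions, function(fr) {
    filt <- filter_by_valid_values(mats_raw[[fr]], study$design,
                                   min_valid = config$filter$min_valid,
                                   scope = config$filter$scope)
    norm <- normalize_columns(filt)
    imp <- impute_downshift(norm, shift = config$impute$shift,
                            width = config$impute$width,
                            per = config$impute$per,
                            seed = stage_seed(seed, paste0("impute_", fr)))
    list(raw = filt, imputed = imp)
  })
  names(prep) <- fractions

  models <- sim_cfg$models
  # --- differential expression (Total) ---------------------------------
  de <- lapply(models, function(m)
    de_contrast(prep$Total$imputed, study$design, m,
                timepoint = config$de$contrast,
                reference = config$de$reference,
                fold_change_min = config$de$fold_change_min,
                q = config$de$q))
  names(de) <- models
  anova_tc <- lapply(models, function(m)
    anova_time_course(prep$Total$imputed, study$design, m, q = config$de$q))
  names(anova_tc) <- models
  induced <- lapply(models, function(m)
    detect_induced(prep$Total$raw$observed, study$design, m))
  names(induced) <- models

  # --- clustering + enrichment (Total) ---------------------------------
  z <- zscore_rows(prep$Total$imputed)
  profiles <- group_mean_profiles(z, study$design)
  dend <- hierarchical_cluster(profiles)
  labels <- cut_clusters(dend, config$cluster$k)
  enrichment <- cluster_annotation_enrichment(labels, study$annotations,
                                              q = config$cluster$enrichment_q)
  pca <- pca_scores(prep$Total$imputed)

  # --- solubility profiling (E vs S) -----------------------------------
  shared <- intersect(rownames(prep$E$imputed$values),
                      rownames(prep$S$imputed$values))
  e_shared <- prep$E$imputed[match(shared, rownames(prep$E$imputed$values)), ]
  s_shared <- prep$S$imputed[match(shared, rownames(prep$S$imputed$values)), ]
  solubility <- lapply(models, function(m) {
    ratios <- es_ratio(e_shared, s_shared, study$design, m,
                       scope = config$solubility$scope)
    select_insolubilized(ratios, e_shared, study$design, m,
                         fold_min = config$solubility$fold_min,
                         q = config$solubility$q)
  })
  names(solubility) <- models
  induced_e <- lapply(models, function(m)
    induced_in_efraction(prep$E$raw$observed, study$design, m))
  names(induced_e) <- models

  # --- cell-type signatures --------------------------------------------
  sig_scores <- signature_scores(z, study$design, study$signatures)
  sig_stats <- signature_tests(sig_scores)

  # --- proteome-fibrosis correlation -----------------------------------
  correlation <- lapply(models, function(m) {
    area_d <- fibrosis_deltas(study$areas, m)
    tot <- correlate_proteome_fibrosis(
      baseline_deltas(prep$Total$imputed, study$design, m), area_d,
      q = config$correlation$q,
      include_controls = config$correlation$include_controls)
    efr <- correlate_proteome_fibrosis(
      baseline_deltas(prep$E$imputed, study$design, m), area_d,
      q = config$correlation$q,
      include_controls = config$correlation$include_controls)
    list(total = tot, efraction = efr,
         classes = classify_correlates(tot, efr))
  })
  names(correlation) <- models

  # --- AFM --------------------------------------------------------------
  afm_cfg <- config$afm
  fcs <- simulate_afm_experiment(n_maps = afm_cfg$n_maps,
                                 n_mice = afm_cfg$n_mice,
                                 grid = afm_cfg$grid,
                                 noise_cv = afm_cfg$noise_cv,
                                 seed = stage_seed(seed, "afm"),
                                 R = afm_cfg$R, nu = afm_cfg$nu,
                                 k = afm_cfg$k)
  fits <- fit_stiffness_map(fcs)
  region_stats <- build_region_stats(fits)
  region_tests <- compare_regions(fits)
  # per-mouse protein deltas of the hepatotoxic model for the AFM mice
  bd <- baseline_deltas(prep$Total$imputed, study$design, "CCl4like")
  prot_by_mouse <- bd$deltas
  colnames(prot_by_mouse) <- bd$design$mouse_id
  stiff_corr <- correlate_stiffness_proteome(region_stats$per_map,
                                             prot_by_mouse, q = afm_cfg$q)

  results <- list(study = study, coefficients = coeffs, matrices = prep,
                  de = de, anova = anova_tc, induced = induced,
                  clustering = list(dendrogram = dend, labels = labels,
                                    enrichment = enrichment, pca = pca),
                  solubility = solubility, induced_efraction = induced_e,
                  signatures = list(scores = sig_scores, tests = sig_stats),
                  correlation = correlation,
                  afm = list(fits = fits, stats = region_stats,
                             tests = region_tests,
                             proteome_correlation = stiff_corr))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(df, name) write_tsv(df, file.path(out_dir, name))
    wt(study$design, "design.tsv")
    wt(study$areas, "fibrosis_areas.tsv")
    write_gmt(study$signatures, file.path(out_dir, "signatures.gmt"))
    wt(data.frame(sample_id = names(coeffs), coefficient = coeffs),
       "coefficients.tsv")
    for (fr in fractions)
      write_intensity_tsv(prep[[fr]]$imputed,
                          file.path(out_dir,
                                    sprintf("protein_%s_imputed.tsv", fr)))
    for (m in models) {
      wt(de[[m]], sprintf("de_%s.tsv", m))
      wt(anova_tc[[m]], sprintf("anova_%s.tsv", m))
      wt(solubility[[m]]$table, sprintf("solubility_%s.tsv", m))
      wt(correlation[[m]]$total, sprintf("correlation_total_%s.tsv", m))
      wt(correlation[[m]]$efraction,
         sprintf("correlation_efraction_%s.tsv", m))
    }
    wt(data.frame(protein_id = names(labels), cluster = labels),
       "clusters.tsv")
    wt(enrichment, "cluster_enrichment.tsv")
    wt(data.frame(sample_id = rownames(pca$scores), pca$scores,
                  check.names = FALSE), "pca_scores.tsv")
    wt(sig_scores, "signature_scores.tsv")
    wt(region_stats$summary, "afm_region_summary.tsv")
    wt(region_tests, "afm_region_tests.tsv")
    wt(stiff_corr, "afm_proteome_correlation.tsv")
    files <- list.files(out_dir, full.names = TRUE, recursive = TRUE)
    files <- files[!grepl("run_report\\.json$", files)]
    report <- list(seed = seed,
                   n_proteins = sim_cfg$n_proteins,
                   warnings = val$warnings,
                   wall_time_s = as.numeric(difftime(Sys.time(), t0,
                                                     units = "secs")),
                   outputs = data.frame(
                     file = basename(files),
                     md5 = unname(tools::md5sum(files)),
                     stringsAsFactors = FALSE))
    jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    results$report <- report
  }
  invisible(results)
}
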