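#' Configuration for a synthetic fibrosis study
#'
#' Defines the study the generator emulates: two liver-injury models
#' (hepatotoxic, with strong spontaneous healing; cholestatic, with little),
#' five terminal time points (control, two progression, two resolution), six
#' mice per group and three fractions (Total lysate, soluble S, insoluble
#' ECM-enriched E).  Proteins carry planted classes: `tracking_pos` rises
#' with fibrosis and reverts with healing, `declining` mirrors it with
#' negative sign, `solubility_shift` gains abundance only in the E fraction,
#' and the remainder are `null`.
#'
#' @param n_proteins number of simulated proteins.
#' @param n_mice_per_group mice per (model, time point) group (default 6).
#' @param models model names; healing is model-specific.
#' @param frac_fibrosis_tracking,frac_declining,frac_solubility_shift
#'   proportions of the planted classes; must sum to <= 1.
#' @param effect_log2 planted log2 effect at the fibrosis peak (T2).
#' @param noise_sd_log2 residual SD of log2 intensities (> 0).
#' @param mnar_midpoint log2 intensity at 50% detection probability.
#' @param mnar_slope steepness of the logistic detection model (> 0).
#' @param healing_factor named fractional reversal of the planted effect at
#'   T4 per model (near 1 = full healing, near 0 = persistent fibrosis).
#' @param peptides_per_protein integer range (min, max) of peptides per
#'   protein.
#' @param peptide_noise_sd_log2 peptide-level measurement noise (log2 SD).
#' @param peptide_offset_sd_log2 SD of fixed per-peptide ionization-efficiency
#'   offsets (log2); these make peptide intensities differ in level while
#'   tracking the protein profile.
#' @param sample_scale_sd_log2 SD of true per-sample log2 scaling factors
#'   (the run-to-run loading differences the proportional coefficients must
#'   undo).
#' @param baseline_mean_log2,baseline_sd_log2 log-normal protein abundance
#'   baseline (log2 mean 23, SD 2 mimics the LFQ dynamic range).
#' @param fibrosis_max_area named peak sirius-red-positive area (%) per
#'   model; `fibrosis_background` control staining background (%);
#'   `fibrosis_noise_sd` per-mouse area noise (%).
#' @param seed integer master seed.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_proteins = 1000L, n_mice_per_group = 6L,
                              models = c("CCl4like", "DDClike"),
                              frac_fibrosis_tracking = 0.10,
                              frac_declining = 0.05,
                              frac_solubility_shift = 0.05,
                              effect_log2 = 2, noise_sd_log2 = 0.5,
                              mnar_midpoint = 18, mnar_slope = 1,
                              healing_factor = c(CCl4like = 0.9,
                                                 DDClike = 0.1),
                              peptides_per_protein = c(3L, 8L),
                              peptide_noise_sd_log2 = 0.1,
                              peptide_offset_sd_log2 = 1,
                              sample_scale_sd_log2 = 0.5,
                              baseline_mean_log2 = 23,
                              baseline_sd_log2 = 2,
                              fibrosis_max_area = c(CCl4like = 12,
                                                    DDClike = 10),
                              fibrosis_background = 1,
                              fibrosis_noise_sd = 1,
                              seed = 1L) {
  fracs <- c(frac_fibrosis_tracking, frac_declining, frac_solubility_shift)
  if (any(fracs < 0) || sum(fracs) > 1)
    stopf("class proportions must be >= 0 and sum to <= 1")
  if (noise_sd_log2 <= 0) stopf("noise_sd_log2 must be > 0")
  if (mnar_slope <= 0) stopf("mnar_slope must be > 0")
  if (!all(models %in% names(healing_factor)))
    stopf("healing_factor must be named for every model")
  if (any(healing_factor < 0 | healing_factor > 1))
    stopf("healing_factor must lie in [0, 1]")
  stopifnot(length(peptides_per_protein) == 2L,
            peptides_per_protein[1] >= 1L,
            peptides_per_protein[2] >= peptides_per_protein[1])
  structure(list(n_proteins = as.integer(n_proteins),
                 n_mice_per_group = as.integer(n_mice_per_group),
                 models = models,
                 timepoints = timepoint_levels(),
                 frac_fibrosis_tracking = frac_fibrosis_tracking,
                 frac_declining = frac_declining,
                 frac_solubility_shift = frac_solubility_shift,
                 effect_log2 = effect_log2, noise_sd_log2 = noise_sd_log2,
                 mnar_midpoint = mnar_midpoint, mnar_slope = mnar_slope,
                 healing_factor = healing_factor,
                 peptides_per_protein = as.integer(peptides_per_protein),
                 peptide_noise_sd_log2 = peptide_noise_sd_log2,
                 peptide_offset_sd_log2 = peptide_offset_sd_log2,
                 sample_scale_sd_log2 = sample_scale_sd_log2,
                 baseline_mean_log2 = baseline_mean_log2,
                 baseline_sd_log2 = baseline_sd_log2,
                 fibrosis_max_area = fibrosis_max_area,
                 fibrosis_background = fibrosis_background,
                 fibrosis_noise_sd = fibrosis_noise_sd,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# planted temporal profile: 0 at control, ramps to 1 at T2, reverts by
# healing_factor (half at T3, fully at T4)
effect_profile <- function(timepoint, healing) {
  healing <- rep_len(healing, length(timepoint))
  p <- unname(c(Ctrl = 0, T1 = 0.5, T2 = 1, T3 = NA, T4 = NA)[timepoint])
  p[timepoint == "T3"] <- 1 - healing[timepoint == "T3"] / 2
  p[timepoint == "T4"] <- 1 - healing[timepoint == "T4"]
  p
}

#' Apply intensity-dependent (MNAR) missingness
#'
#' Masks each observed cell with probability
#' `1 / (1 + exp(slope * (x - midpoint)))` — a left-censoring detection
#' model: low-intensity values vanish, high-intensity values survive.
#' Unmasked values are untouched; the full pre-masking matrix is kept in
#' the `"true_values"` attribute.
#'
#' @param mat an [intensity_matrix()] (log2 values).
#' @param midpoint log2 intensity of 50% detection; `-Inf` masks nothing.
#' @param slope logistic steepness (> 0); `Inf` gives a hard threshold.
#' @param seed integer seed.
#' @return the masked `intensity_matrix`.
#' @export
apply_missingness <- function(mat, midpoint, slope, seed = 1L) {
  if (slope <= 0) stopf("slope must be > 0")
  v <- mat$values
  x <- v - midpoint
  p_mask <- if (is.infinite(slope)) {
    ifelse(x < 0, 1, ifelse(x > 0, 0, 0.5))
  } else stats::plogis(-slope * x)
  p_mask[is.na(v)] <- 0
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  u <- matrix(runif(length(v)), nrow(v), ncol(v))
  masked <- mat$observed & (u < p_mask)
  obs <- mat$observed & !masked
  out_v <- v
  out_v[!obs] <- NA
  out <- intensity_matrix(out_v, obs, provenance = mat$provenance)
  attr(out, "true_values") <- v
  out
}

#' Generate a complete synthetic fibrosis study
#'
#' Draws protein baselines log-normally, plants class effects per fraction
#' and model, derives peptide-level tables with true per-sample scaling
#' factors, applies MNAR missingness at the protein level, and produces the
#' sample design, per-mouse fibrosis areas, annotation catalog (planted
#' tracking proteins annotated as matrisome) and cell-type signature sets.
#' Ground truth for every planted quantity is returned alongside.
#' Deterministic given the config seed.
#'
#' @param config a [simulation_config()].
#' @param peptides also generate the peptide-level table (needed for the
#'   quantification stage; skip for speed when only protein matrices are
#'   used).
#' @return a `synthetic_study` list: `design`, `matrices` (per-fraction
#'   [intensity_matrix()] with missingness applied), `peptides` (or NULL),
#'   `areas`, `annotations`, `signatures`, `ground_truth`, `config`.
#' @export
simulate_study <- function(config = simulation_config(), peptides = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  np <- config$n_proteins
  protein_ids <- sprintf("P%04d", seq_len(np))
  n_track <- round(config$frac_fibrosis_tracking * np)
  n_decl <- round(config$frac_declining * np)
  n_shift <- round(config$frac_solubility_shift * np)
  class <- rep("null", np)
  class[seq_len(n_track)] <- "tracking_pos"
  class[seq_len(n_decl) + n_track] <- "declining"
  class[seq_len(n_shift) + n_track + n_decl] <- "solubility_shift"
  names(class) <- protein_ids

  baseline <- rnorm(np, config$baseline_mean_log2, config$baseline_sd_log2)
  names(baseline) <- protein_ids

  design <- study_design(models = config$models,
                         n_mice = config$n_mice_per_group)
  fractions <- c("Total", "S", "E")

  # per-protein, per-fraction effect sign/size multiplier
  effect_for <- function(cls, fraction) {
    switch(cls,
           tracking_pos = config$effect_log2,
           declining = -config$effect_log2,
           solubility_shift = if (fraction == "E") config$effect_log2 else 0,
           null = 0)
  }

  matrices_true <- list()
  planted <- list()
  for (fr in fractions) {
    cols <- design$sample_id[design$fraction == fr]
    d <- design_lookup(design, cols)
    healing <- config$healing_factor[d$model]
    prof <- effect_profile(d$timepoint, healing)  # per sample
    eff <- vapply(class, effect_for, numeric(1), fraction = fr)
    mu <- outer(eff, prof) + baseline
    v <- mu + matrix(rnorm(length(mu), 0, config$noise_sd_log2),
                     nrow(mu), ncol(mu))
    dimnames(v) <- list(protein_ids, cols)
    matrices_true[[fr]] <- v
    planted[[fr]] <- outer(eff, prof)
    dimnames(planted[[fr]]) <- dimnames(v)
  }

  # true per-sample log2 scaling factors (loading / instrument response)
  sample_scale <- setNames(rnorm(nrow(design), 0, config$sample_scale_sd_log2),
                           design$sample_id)

  # MNAR missingness at the protein level (peptides inherit the mask below)
  matrices <- list()
  for (fr in fractions) {
    m <- intensity_matrix(matrices_true[[fr]], provenance = "raw")
    matrices[[fr]] <- apply_missingness(m, config$mnar_midpoint,
                                        config$mnar_slope,
                                        seed = stage_seed(config$seed,
                                                          paste0("mnar_", fr)))
  }

  pep_tab <- NULL
  if (peptides) {
    n_pep <- sample(seq(config$peptides_per_protein[1],
                        config$peptides_per_protein[2]),
                    np, replace = TRUE)
    pep_protein <- rep(protein_ids, n_pep)
    pep_id <- paste0("pep_", seq_along(pep_protein))
    pep_offset <- rnorm(length(pep_id), 0, config$peptide_offset_sd_log2)
    # peptides partition the protein signal: fixed fractional weights
    # (ionization efficiencies) per protein, summing to 1, so the sum of a
    # protein's peptides reconstructs its intensity
    w <- 2^pep_offset
    w <- w / stats::ave(w, pep_protein, FUN = sum)
    log2_w <- log2(w)
    evidence <- sample(c("unique", "razor"), length(pep_id), replace = TRUE,
                       prob = c(0.8, 0.2))
    all_samples <- design$sample_id
    frac_of <- design$fraction[match(all_samples, design$sample_id)]
    pep_mat <- matrix(NA_real_, length(pep_id), length(all_samples),
                      dimnames = list(pep_id, all_samples))
    for (fr in fractions) {
      cols <- which(frac_of == fr)
      base_lp <- matrices_true[[fr]][pep_protein, , drop = FALSE]
      noise <- matrix(rnorm(length(pep_id) * length(cols), 0,
                            config$peptide_noise_sd_log2),
                      length(pep_id), length(cols))
      lp <- base_lp + log2_w + noise +
        matrix(sample_scale[all_samples[cols]], length(pep_id),
               length(cols), byrow = TRUE)
      # a protein undetected in a sample has no quantified peptides there
      lp[!matrices[[fr]]$observed[pep_protein, , drop = FALSE]] <- NA
      pep_mat[, cols] <- 2^lp
    }
    pep_tab <- peptide_table(pep_id, pep_protein, evidence, pep_mat)
  }

  # per-mouse fibrosis areas following the planted burden profile
  mice <- unique(design[, c("mouse_id", "model", "timepoint")])
  healing <- config$healing_factor[mice$model]
  burden <- effect_profile(mice$timepoint, healing) *
    config$fibrosis_max_area[mice$model]
  areas <- data.frame(mouse_id = mice$mouse_id, model = mice$model,
                      timepoint = mice$timepoint,
                      sr_area_pct = pmax(0, config$fibrosis_background +
                                           burden +
                                           rnorm(nrow(mice), 0,
                                                 config$fibrosis_noise_sd)),
                      stringsAsFactors = FALSE)

  # annotation catalog: planted tracking proteins are "matrisome"; nulls
  # provide the background; extra keyword terms exercise multi-term paths
  idx <- split(protein_ids, class)
  null_ids <- idx$null %||% character(0)
  catalog <- list(
    matrisome = c(idx$tracking_pos %||% character(0),
                  sample(null_ids, min(length(null_ids),
                                       max(1L, round(0.02 * np))))),
    intracellular = setdiff(protein_ids, idx$tracking_pos %||% character(0)))
  sig_from <- function(pool, n) sample(pool, min(n, length(pool)))
  kupffer <- sig_from(null_ids, 15L)
  bec <- sig_from(setdiff(null_ids, kupffer), 15L)  # disjoint null signatures
  signatures <- Filter(length, list(
    hepatocytes = sig_from(idx$declining %||% character(0), 18L),
    hsc_activated = sig_from(idx$tracking_pos %||% character(0), 15L),
    kupffer_null = kupffer,
    bec_null = bec))

  ground_truth <- list(class = class, baseline_log2 = baseline,
                       planted_effects = planted,
                       sample_scale_log2 = sample_scale,
                       true_matrices = matrices_true,
                       fibrosis_burden = setNames(burden, mice$mouse_id))

  structure(list(design = design, matrices = matrices, peptides = pep_tab,
                 areas = areas, annotations = catalog,
                 signatures = signatures, ground_truth = ground_truth,
                 config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "<synthetic_study> %d proteins, %d models x %d time points x %d mice, seed %d\n",
    x$config$n_proteins, length(x$config$models),
    length(x$config$timepoints), x$config$n_mice_per_group, x$config$seed))
  invisible(x)
}

#' Reference region moduli for the AFM simulator
#'
#' Median Young's moduli (Pa) per tissue region and treatment used as
#' generator defaults: control around 1.2-1.6 kPa in all regions,
#' progressive stiffening to a 4.4 kPa collagen scar at peak fibrosis with
#' an initial softening of interface hepatocytes, and partial recovery
#' after healing.
#'
#' @return matrix treatments x regions (Pa).
#' @export
default_region_moduli <- function() {
  m <- matrix(c(1600, 1300, 1200,
                2700, 1900, 800,
                4400, 2800, 2000,
                3000, 2500, 1400),
              nrow = 4L, byrow = TRUE,
              dimnames = list(c("Ctrl", "T1", "T2", "T4"),
                              c("collagen", "injured_hepatocyte",
                                "interface_hepatocyte")))
  m
}

#' Simulate a grid of Hertzian force curves
#'
#' Every pixel of the grid receives an approach curve computed from the
#' Hertz spherical model at its region's true modulus, with multiplicative
#' force noise of the given CV and a random linear pre-contact baseline
#' (offset + small tilt), so contact-point detection is non-trivial.  When
#' several regions are given, the grid is split into contiguous column
#' bands, one per region.
#'
#' @param region_truth named numeric: region -> true Young's modulus (Pa),
#'   all > 0.
#' @param grid `c(rows, cols)` (default 10 x 36).
#' @param noise_cv multiplicative force-noise coefficient of variation.
#' @param seed integer seed.
#' @param R,nu,k probe radius (m), Poisson ratio, spring constant (N/m).
#' @param treatment,mouse_id,map_id metadata labels stored per curve.
#' @param n_pre,n_post samples before/after contact; `delta_max` deepest
#'   indentation (m).
#' @return a force-curve set: list with `curves` (each `z`, `force`),
#'   `meta` (pixel metadata incl. `E_true`), `R`, `nu`, `k`.
#' @export
simulate_force_curves <- function(region_truth, grid = c(10L, 36L),
                                  noise_cv = 0.05, seed = 1L,
                                  R = 2.85e-6, nu = 0.45, k = 0.09,
                                  treatment = "Ctrl", mouse_id = "m1",
                                  map_id = "map1",
                                  n_pre = 25L, n_post = 60L,
                                  delta_max = 0.8e-6) {
  if (any(region_truth <= 0)) stopf("moduli must be > 0")
  if (noise_cv < 0) stopf("noise_cv must be >= 0")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  regions <- names(region_truth)
  if (is.null(regions)) stopf("region_truth must be named")
  nr <- grid[1]; nc <- grid[2]
  band <- if (length(regions) == 1L) factor(rep(regions, nc)) else
    cut(seq_len(nc), breaks = length(regions), labels = regions)
  px <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  px$region <- as.character(band[px$col])
  px$E_true <- region_truth[px$region]
  curves <- vector("list", nrow(px))
  for (i in seq_len(nrow(px))) {
    E <- px$E_true[i]
    delta <- seq(0, delta_max, length.out = n_post + 1L)[-1L]
    f_hertz <- hertz_force(delta, E, R = R, nu = nu)
    zc <- runif(1, -0.1e-6, 0.1e-6)
    z_pre <- seq(zc - 0.5e-6, zc, length.out = n_pre)
    z_post <- zc + delta + f_hertz / k
    b0 <- runif(1, -2e-11, 2e-11)           # baseline offset, +-20 pN
    b1 <- runif(1, -1e-5, 1e-5)             # baseline tilt, N/m
    z <- c(z_pre, z_post)
    f_clean <- c(rep(0, n_pre), f_hertz * (1 + noise_cv * rnorm(n_post)))
    force <- f_clean + b0 + b1 * z
    curves[[i]] <- list(z = z, force = force, contact_index = n_pre)
  }
  meta <- data.frame(curve_id = sprintf("%s_px%03d", map_id,
                                        seq_len(nrow(px))),
                     map_id = map_id, mouse_id = mouse_id,
                     treatment = treatment, region = px$region,
                     row = px$row, col = px$col, E_true = px$E_true,
                     stringsAsFactors = FALSE)
  list(curves = curves, meta = meta, R = R, nu = nu, k = k)
}

#' Simulate a full AFM stiffness experiment
#'
#' One single-region map per (region, treatment, replicate): `n_maps` areas
#' per condition distributed over `n_mice` mice (as in a design measuring
#' several areas from a few animals per time point), with true moduli from
#' [default_region_moduli()] or a user table.
#'
#' @param moduli matrix treatments x regions (Pa).
#' @param n_maps maps (measured areas) per (region, treatment).
#' @param n_mice mice the maps are spread over per treatment.
#' @param model model name used to form mouse ids matching the proteomic
#'   study design.
#' @param grid,noise_cv,seed,R,nu,k passed to [simulate_force_curves()].
#' @return a combined force-curve set (same shape as
#'   [simulate_force_curves()]).
#' @export
simulate_afm_experiment <- function(moduli = default_region_moduli(),
                                    n_maps = 7L, n_mice = 3L,
                                    model = "CCl4like",
                                    grid = c(10L, 36L), noise_cv = 0.05,
                                    seed = 1L, R = 2.85e-6, nu = 0.45,
                                    k = 0.09) {
  curves <- list(); meta <- list()
  for (tr in rownames(moduli)) {
    for (reg in colnames(moduli)) {
      for (m in seq_len(n_maps)) {
        mouse <- sprintf("%s.%s.m%d", model, tr, ((m - 1L) %% n_mice) + 1L)
        map_id <- sprintf("%s_%s_a%d", tr, reg, m)
        fc <- simulate_force_curves(
          setNames(moduli[tr, reg], reg), grid = grid, noise_cv = noise_cv,
          seed = stage_seed(seed, map_id), R = R, nu = nu, k = k,
          treatment = tr, mouse_id = mouse, map_id = map_id)
        curves <- c(curves, fc$curves)
        meta[[length(meta) + 1L]] <- fc$meta
      }
    }
  }
  list(curves = curves, meta = do.call(rbind, meta), R = R, nu = nu, k = k)
}
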