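test_that("baseline deltas center controls and ignore constant shifts", {
  design <- tiny_design(n = 4L)
  set.seed(1)
  v <- matrix(rnorm(3 * nrow(design), 20, 1), 3, nrow(design),
              dimnames = list(paste0("P", 1:3), design$sample_id))
  mat <- intensity_matrix(v, provenance = "imputed", seed = 1L)
  bd <- baseline_deltas(mat, design, "CCl4like")
  ctrl <- bd$design$timepoint == "Ctrl"
  expect_equal(unname(rowMeans(bd$deltas[, ctrl])), rep(0, 3),
               tolerance = 1e-12)
  v2 <- v; v2[2, ] <- v2[2, ] + 7
  bd2 <- baseline_deltas(intensity_matrix(v2, provenance = "imputed",
                                          seed = 1L), design, "CCl4like")
  expect_equal(bd2$deltas[2, ], bd$deltas[2, ], tolerance = 1e-12)
})

test_that("fibrosis deltas subtract the control background", {
  areas <- data.frame(mouse_id = paste0("m", 1:6),
                      model = "CCl4like",
                      timepoint = c("Ctrl", "Ctrl", "T1", "T2", "T3", "T4"),
                      sr_area_pct = c(1, 3, 6, 13, 8, 3))
  fd <- fibrosis_deltas(areas, "CCl4like")
  expect_equal(fd$delta_area, areas$sr_area_pct - 2)
  expect_equal(mean(fd$delta_area[fd$timepoint == "Ctrl"]), 0)
  same <- areas; same$sr_area_pct <- 5
  expect_true(all(fibrosis_deltas(same, "CCl4like")$delta_area == 0))
  expect_error(fibrosis_deltas(areas[areas$timepoint != "Ctrl", ],
                               "CCl4like"), "control areas")
})

test_that("a protein tracking the areas exactly gives slope 1, r 1", {
  cfg <- simulation_config(n_proteins = 30L, seed = 2L)
  study <- simulate_study(cfg, peptides = FALSE)
  fd <- fibrosis_deltas(study$areas, "CCl4like")
  design <- study$design[study$design$fraction == "Total" &
                           study$design$model == "CCl4like", ]
  v <- matrix(20, 2, nrow(design),
              dimnames = list(c("mirror", "noise"), design$sample_id))
  v["mirror", ] <- 20 + fd$delta_area[match(design$mouse_id, fd$mouse_id)]
  set.seed(3)
  v["noise", ] <- rnorm(nrow(design), 20, 1)
  mat <- intensity_matrix(v, provenance = "imputed", seed = 1L)
  bd <- baseline_deltas(mat, study$design, "CCl4like")
  rec <- correlate_proteome_fibrosis(bd, fd)
  mir <- rec[rec$protein_id == "mirror", ]
  expect_equal(mir$slope, 1, tolerance = 0.05)
  expect_gt(mir$r, 0.999)
  expect_true(mir$significant)
})

test_that("sign-flipping the areas flips slopes and r but not p", {
  cfg <- simulation_config(n_proteins = 40L, seed = 4L)
  study <- simulate_study(cfg, peptides = FALSE)
  imp <- prep_fraction(study, "Total", seed = 4L)
  bd <- baseline_deltas(imp, study$design, "CCl4like")
  fd <- fibrosis_deltas(study$areas, "CCl4like")
  r1 <- correlate_proteome_fibrosis(bd, fd)
  fd2 <- fd; fd2$delta_area <- -fd2$delta_area
  r2 <- correlate_proteome_fibrosis(bd, fd2)
  expect_equal(r2$slope, -r1$slope, tolerance = 1e-10)
  expect_equal(r2$r, -r1$r, tolerance = 1e-10)
  expect_equal(r2$p, r1$p, tolerance = 1e-10)
})

test_that("area units cancel in r and p; slope rescales", {
  cfg <- simulation_config(n_proteins = 40L, seed = 5L)
  study <- simulate_study(cfg, peptides = FALSE)
  imp <- prep_fraction(study, "Total", seed = 5L)
  bd <- baseline_deltas(imp, study$design, "CCl4like")
  fd <- fibrosis_deltas(study$areas, "CCl4like")
  r1 <- correlate_proteome_fibrosis(bd, fd)
  fd_frac <- fd; fd_frac$delta_area <- fd_frac$delta_area / 100
  r2 <- correlate_proteome_fibrosis(bd, fd_frac)
  expect_equal(r2$r, r1$r, tolerance = 1e-10)
  expect_equal(r2$p, r1$p, tolerance = 1e-10)
  expect_equal(r2$slope, r1$slope * 100, tolerance = 1e-8)
})

test_that("classification partitions correlates by sign and compartment", {
  mk <- function(ids, sig, dir) data.frame(protein_id = ids,
                                           slope = ifelse(dir == "positive", 1, -1),
                                           r = 0.9, p = 0.001, q = 0.01,
                                           significant = sig, direction = dir)
  tot <- rbind(mk("A", TRUE, "positive"), mk("B", TRUE, "negative"),
               mk("C", TRUE, "positive"), mk("D", FALSE, "positive"))
  efr <- rbind(mk("A", TRUE, "positive"), mk("B", TRUE, "negative"),
               mk("C", FALSE, "positive"), mk("D", FALSE, "positive"))
  cls <- classify_correlates(tot, efr)
  expect_identical(cls$positive_both, "A")
  expect_identical(cls$negative_both, "B")
  expect_identical(cls$total_specific, "C")
  expect_length(cls$efraction_specific, 0)
  empty <- classify_correlates(tot[0, ], efr[0, ])
  expect_true(all(lengths(empty) == 0))
})

test_that("clusterin-like planted proteins land in positive_both", {
  hits <- c()
  for (s in 1:5) {
    cfg <- simulation_config(n_proteins = 300L, seed = 9000L + s)
    study <- simulate_study(cfg, peptides = FALSE)
    tot <- prep_fraction(study, "Total", seed = s)
    efr <- prep_fraction(study, "E", seed = s + 100L)
    fd <- fibrosis_deltas(study$areas, "CCl4like")
    ct <- correlate_proteome_fibrosis(
      baseline_deltas(tot, study$design, "CCl4like"), fd)
    ce <- correlate_proteome_fibrosis(
      baseline_deltas(efr, study$design, "CCl4like"), fd)
    cls <- classify_correlates(ct, ce)
    trk <- names(study$ground_truth$class)[
      study$ground_truth$class == "tracking_pos"]
    hits <- c(hits, mean(trk %in% cls$positive_both))
  }
  expect_gte(mean(hits), 0.9)
})

test_that("null studies keep BH rejections within the bound", {
  n_any <- 0; n_seeds <- 40
  for (s in seq_len(n_seeds)) {
    cfg <- simulation_config(n_proteins = 100L, frac_fibrosis_tracking = 0,
                             frac_declining = 0, frac_solubility_shift = 0,
                             seed = 9500L + s)
    study <- simulate_study(cfg, peptides = FALSE)
    imp <- prep_fraction(study, "Total", seed = s)
    bd <- baseline_deltas(imp, study$design, "CCl4like")
    fd <- fibrosis_deltas(study$areas, "CCl4like")
    rec <- correlate_proteome_fibrosis(bd, fd)
    if (any(rec$significant)) n_any <- n_any + 1
  }
  expect_lte(n_any / n_seeds, 0.08 + 0.05)
})
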