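make_es_pair <- function(e_vals, s_vals, design) {
  list(e = intensity_matrix(e_vals, provenance = "imputed", seed = 1L),
       s = intensity_matrix(s_vals, provenance = "imputed", seed = 1L))
}

test_that("E/S ratios are zero for identical fractions and exact for shifts", {
  design <- study_design(models = "CCl4like", fractions = c("S", "E"),
                         n_mice = 3L)
  ecols <- design$sample_id[design$fraction == "E"]
  scols <- design$sample_id[design$fraction == "S"]
  v <- matrix(20, 2, length(ecols), dimnames = list(c("A", "B"), ecols))
  sv <- matrix(20, 2, length(scols), dimnames = list(c("A", "B"), scols))
  pair <- make_es_pair(v, sv, design)
  r <- es_ratio(pair$e, pair$s, design, "CCl4like")
  expect_true(all(r == 0))
  # threefold at one time point: log2 ratio = log2 3 there
  v2 <- v
  t2e <- ecols[design$timepoint[match(ecols, design$sample_id)] == "T2"]
  v2["A", t2e] <- 20 + log2(3)
  r2 <- es_ratio(intensity_matrix(v2, provenance = "imputed", seed = 1),
                 pair$s, design, "CCl4like")
  expect_equal(unname(r2["A", t2e]), rep(log2(3), length(t2e)),
               tolerance = 1e-12)
  expect_true(all(r2["B", ] == 0))
})

test_that("per-timepoint S medians change the reference per group", {
  design <- study_design(models = "CCl4like", fractions = c("S", "E"),
                         n_mice = 3L)
  ecols <- design$sample_id[design$fraction == "E"]
  scols <- design$sample_id[design$fraction == "S"]
  sv <- matrix(20, 1, length(scols), dimnames = list("A", scols))
  # S rises at T2: per-timepoint scope subtracts 25 there, global stays low
  t2s <- scols[design$timepoint[match(scols, design$sample_id)] == "T2"]
  sv["A", t2s] <- 25
  ev <- matrix(22, 1, length(ecols), dimnames = list("A", ecols))
  e <- intensity_matrix(ev, provenance = "imputed", seed = 1)
  s <- intensity_matrix(sv, provenance = "imputed", seed = 1)
  t2e <- ecols[design$timepoint[match(ecols, design$sample_id)] == "T2"]
  r_glob <- es_ratio(e, s, design, "CCl4like", scope = "global")
  r_tp <- es_ratio(e, s, design, "CCl4like", scope = "per_timepoint")
  expect_equal(unname(r_glob["A", t2e]), rep(2, 3))      # 22 - 20
  expect_equal(unname(r_tp["A", t2e]), rep(-3, 3))       # 22 - 25
})

test_that("selection needs both the threefold and the ANOVA gate", {
  design <- study_design(models = "CCl4like", fractions = c("S", "E"),
                         n_mice = 6L)
  ecols <- design$sample_id[design$fraction == "E"]
  scols <- design$sample_id[design$fraction == "S"]
  tp <- design$timepoint[match(ecols, design$sample_id)]
  set.seed(8)
  mk <- function(x) matrix(rep(x, each = 1), nrow = 1)
  # "both": 3.2-fold at T2 with time variation; "weak": 2.9-fold best;
  # "flat": threefold always, no time change
  ev <- rbind(both = 20 + ifelse(tp == "T2", log2(3.2), 0) + rnorm(30, 0, 0.05),
              weak = 20 + ifelse(tp == "T2", log2(2.9), 0) + rnorm(30, 0, 0.05),
              flat = 20 + log2(3) + rnorm(30, 0, 0.05))
  colnames(ev) <- ecols
  sv <- matrix(20, 3, length(scols),
               dimnames = list(c("both", "weak", "flat"), scols))
  e <- intensity_matrix(ev, provenance = "imputed", seed = 1)
  s <- intensity_matrix(sv, provenance = "imputed", seed = 1)
  r <- es_ratio(e, s, design, "CCl4like")
  sel <- select_insolubilized(r, e, design, "CCl4like")
  expect_identical(sel$selected, "both")
  tab <- sel$table
  expect_false(tab$fold_gate[tab$protein_id == "weak"])
  expect_true(tab$fold_gate[tab$protein_id == "flat"])
  expect_false(tab$anova_gate[tab$protein_id == "flat"])
})

test_that("selection is monotone in the fold threshold", {
  cfg <- simulation_config(n_proteins = 150L, seed = 18L)
  study <- simulate_study(cfg, peptides = FALSE)
  e <- prep_fraction(study, "E", seed = 18L)
  s <- prep_fraction(study, "S", seed = 18L)
  shared <- intersect(rownames(e$values), rownames(s$values))
  e <- e[match(shared, rownames(e$values)), ]
  s <- s[match(shared, rownames(s$values)), ]
  r <- es_ratio(e, s, study$design, "CCl4like")
  sel2 <- select_insolubilized(r, e, study$design, "CCl4like", fold_min = 2)
  sel3 <- select_insolubilized(r, e, study$design, "CCl4like", fold_min = 3)
  sel4 <- select_insolubilized(r, e, study$design, "CCl4like", fold_min = 4)
  expect_true(all(sel3$selected %in% sel2$selected))
  expect_true(all(sel4$selected %in% sel3$selected))
})

test_that("planted solubility shifts are recovered with bounded FDR", {
  sens <- c(); fdr <- c()
  for (s in 1:5) {
    cfg <- simulation_config(n_proteins = 300L, seed = 8000L + s)
    study <- simulate_study(cfg, peptides = FALSE)
    e <- prep_fraction(study, "E", seed = s)
    sm <- prep_fraction(study, "S", seed = s + 1L)
    shared <- intersect(rownames(e$values), rownames(sm$values))
    e <- e[match(shared, rownames(e$values)), ]
    sm <- sm[match(shared, rownames(sm$values)), ]
    r <- es_ratio(e, sm, study$design, "CCl4like")
    sel <- select_insolubilized(r, e, study$design, "CCl4like")
    gt <- study$ground_truth$class
    planted <- names(gt)[gt == "solubility_shift"]
    sens <- c(sens, mean(planted %in% sel$selected))
    fdr <- c(fdr, if (length(sel$selected))
      mean(!(sel$selected %in% planted)) else 0)
  }
  expect_gte(mean(sens), 0.8)
  expect_lte(mean(fdr), 0.1)
})

test_that("E-fraction induced detection mirrors the Total rule", {
  design <- study_design(models = "CCl4like", fractions = "E", n_mice = 6L)
  m <- matrix(FALSE, 1, nrow(design), dimnames = list("p", design$sample_id))
  sel <- function(tp) design$sample_id[design$timepoint == tp]
  m["p", c(sel("T1"), sel("T2"))] <- TRUE
  expect_identical(induced_in_efraction(m, design, "CCl4like"), "p")
  m["p", sel("Ctrl")[1]] <- TRUE
  expect_length(induced_in_efraction(m, design, "CCl4like"), 0)
  empty <- matrix(FALSE, 0, nrow(design),
                  dimnames = list(NULL, design$sample_id))
  expect_length(induced_in_efraction(empty, design, "CCl4like"), 0)
})
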