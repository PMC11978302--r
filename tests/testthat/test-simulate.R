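test_that("identical config and seed give identical studies", {
  cfg <- simulation_config(n_proteins = 60L, seed = 42L)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$matrices$Total$values, s2$matrices$Total$values)
  expect_identical(s1$peptides$intensities, s2$peptides$intensities)
  expect_identical(s1$areas, s2$areas)
  s3 <- simulate_study(simulation_config(n_proteins = 60L, seed = 43L))
  expect_false(identical(s1$matrices$Total$values, s3$matrices$Total$values))
})

test_that("null configuration plants no effects", {
  cfg <- simulation_config(n_proteins = 50L, frac_fibrosis_tracking = 0,
                           frac_declining = 0, frac_solubility_shift = 0,
                           seed = 2L)
  study <- simulate_study(cfg, peptides = FALSE)
  expect_true(all(study$ground_truth$class == "null"))
  expect_true(all(study$ground_truth$planted_effects$Total == 0))
})

test_that("planted T2 effects are detectable by a two-sample t-test", {
  hits <- 0; n_trials <- 40
  for (s in seq_len(n_trials)) {
    cfg <- simulation_config(n_proteins = 20L, effect_log2 = 2,
                             noise_sd_log2 = 0.1, mnar_midpoint = -Inf,
                             mnar_slope = 1, seed = 1000L + s)
    study <- simulate_study(cfg, peptides = FALSE)
    gt <- study$ground_truth$class
    p <- names(gt)[gt == "tracking_pos"][1]
    d <- study$design
    t2 <- d$sample_id[d$fraction == "Total" & d$model == "CCl4like" &
                        d$timepoint == "T2"]
    ct <- d$sample_id[d$fraction == "Total" & d$model == "CCl4like" &
                        d$timepoint == "Ctrl"]
    v <- study$matrices$Total$values
    pv <- oracle_t(v[p, t2], v[p, ct])$p_value
    if (pv < 0.001) hits <- hits + 1
  }
  expect_gte(hits / n_trials, 0.95)
})

test_that("group mean differences match planted effects within tolerance", {
  cfg <- simulation_config(n_proteins = 100L, seed = 7L,
                           mnar_midpoint = -Inf)
  study <- simulate_study(cfg, peptides = FALSE)
  gt <- study$ground_truth
  d <- study$design
  trk <- names(gt$class)[gt$class == "tracking_pos"]
  v <- study$matrices$Total$values
  t2 <- d$sample_id[d$fraction == "Total" & d$model == "CCl4like" &
                      d$timepoint == "T2"]
  ct <- d$sample_id[d$fraction == "Total" & d$model == "CCl4like" &
                      d$timepoint == "Ctrl"]
  tol <- 4 * cfg$noise_sd_log2 / sqrt(6)
  diffs <- rowMeans(v[trk, t2]) - rowMeans(v[trk, ct])
  expect_true(all(abs(diffs - cfg$effect_log2) < 2 * tol))
  expect_lt(abs(mean(diffs) - cfg$effect_log2), tol)
})

test_that("solubility-shift proteins gain effect only in the E fraction", {
  cfg <- simulation_config(n_proteins = 100L, seed = 8L)
  study <- simulate_study(cfg, peptides = FALSE)
  gt <- study$ground_truth
  sh <- names(gt$class)[gt$class == "solubility_shift"]
  expect_true(all(gt$planted_effects$Total[sh, ] == 0))
  expect_true(all(gt$planted_effects$S[sh, ] == 0))
  expect_gt(max(gt$planted_effects$E[sh, ]), 0)
})

test_that("healing reverts CCl4like effects at T4 but not DDClike", {
  cfg <- simulation_config(n_proteins = 60L, seed = 9L)
  study <- simulate_study(cfg, peptides = FALSE)
  gt <- study$ground_truth
  d <- study$design
  trk <- names(gt$class)[gt$class == "tracking_pos"][1]
  t4c <- d$sample_id[d$fraction == "Total" & d$model == "CCl4like" &
                       d$timepoint == "T4"]
  t4d <- d$sample_id[d$fraction == "Total" & d$model == "DDClike" &
                       d$timepoint == "T4"]
  expect_equal(unique(gt$planted_effects$Total[trk, t4c]),
               cfg$effect_log2 * (1 - cfg$healing_factor["CCl4like"]),
               ignore_attr = TRUE)
  expect_equal(unique(gt$planted_effects$Total[trk, t4d]),
               cfg$effect_log2 * (1 - cfg$healing_factor["DDClike"]),
               ignore_attr = TRUE)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(frac_fibrosis_tracking = 0.8,
                                 frac_declining = 0.3), "proportions")
  expect_error(simulation_config(noise_sd_log2 = 0), "noise_sd_log2")
  expect_error(simulation_config(healing_factor = c(CCl4like = 1.5,
                                                    DDClike = 0)),
               "healing_factor")
})

test_that("missingness model follows the logistic and its limits", {
  set.seed(3)
  v <- matrix(rnorm(1e5, 20, 2), ncol = 100,
              dimnames = list(NULL, paste0("s", 1:100)))
  mat <- intensity_matrix(v)
  # logistic at the median with slope 1: masked fraction ~ analytic mean
  mid <- median(v)
  masked <- apply_missingness(mat, mid, 1, seed = 4L)
  expected <- mean(plogis(-(v - mid)))
  expect_lt(abs(mean(!masked$observed) - expected), 0.03)
  # hard threshold: everything below midpoint masked, above kept
  hard <- apply_missingness(mat, mid, Inf, seed = 5L)
  expect_true(all(is.na(hard$values[v < mid])))
  expect_true(all(!is.na(hard$values[v > mid])))
  # midpoint -Inf masks nothing
  none <- apply_missingness(mat, -Inf, 1, seed = 6L)
  expect_true(all(none$observed))
  # unmasked values preserved
  expect_equal(masked$values[masked$observed], v[masked$observed])
})

test_that("detection rate is non-decreasing in intensity decile", {
  cfg <- simulation_config(n_proteins = 300L, seed = 11L)
  study <- simulate_study(cfg, peptides = FALSE)
  truth <- study$ground_truth$true_matrices$Total
  obs <- study$matrices$Total$observed
  dec <- cut(truth, quantile(truth, 0:10 / 10), include.lowest = TRUE,
             labels = FALSE)
  rates <- tapply(as.vector(obs), as.vector(dec), mean)
  expect_true(all(diff(rates) >= -0.01))
  expect_lt(rates[1], rates[10])
})

test_that("fibrosis areas track the planted burden with background", {
  cfg <- simulation_config(n_proteins = 30L, seed = 12L)
  study <- simulate_study(cfg, peptides = FALSE)
  a <- study$areas
  m <- tapply(a$sr_area_pct[a$model == "CCl4like"],
              a$timepoint[a$model == "CCl4like"], mean)
  expect_gt(m["T2"], m["Ctrl"] + 8)     # near peak burden 12%
  expect_gt(m["T2"], m["T4"])           # healing reduces area
  expect_true(all(a$sr_area_pct >= 0))
  d <- tapply(a$sr_area_pct[a$model == "DDClike"],
              a$timepoint[a$model == "DDClike"], mean)
  expect_gt(d["T4"], d["Ctrl"] + 5)     # cholestatic model barely heals
})

test_that("simulated force curves invert to their true moduli", {
  fc <- simulate_force_curves(c(collagen = 1000), grid = c(1L, 1L),
                              noise_cv = 0, seed = 1L)
  cu <- fc$curves[[1]]
  res <- process_force_curve(cu$z, cu$force)
  expect_lt(abs(res$E - 1000) / 1000, 0.005)
  # linearity: doubling E doubles force at every indentation
  f1 <- hertz_force(seq(0, 1e-6, length.out = 20), 1000)
  f2 <- hertz_force(seq(0, 1e-6, length.out = 20), 2000)
  expect_equal(f2, 2 * f1, tolerance = 1e-12)
  expect_error(simulate_force_curves(c(x = -5)), "moduli")
})

test_that("a mixed-region grid recovers region medians from the reference values", {
  moduli <- c(collagen = 4400, injured_hepatocyte = 2800,
              interface_hepatocyte = 2000)
  fc <- simulate_force_curves(moduli, grid = c(10L, 36L), noise_cv = 0.05,
                              seed = 21L)
  fits <- fit_stiffness_map(fc)
  med <- tapply(fits$E, fits$region, median, na.rm = TRUE)
  for (r in names(moduli))
    expect_lt(abs(med[r] - moduli[r]) / moduli[r], 0.10)
})
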