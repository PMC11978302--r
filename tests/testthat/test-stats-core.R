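test_that("BH step-up matches exhaustive enumeration and base p.adjust", {
  set.seed(11)
  for (i in 1:50) {
    m <- sample(1:200, 1)
    p <- runif(m)
    q <- runif(1, 0.01, 0.2)
    got <- benjamini_hochberg(p, q)
    ora <- oracle_bh(p, q)
    expect_identical(got$rejected, ora$rejected)
    expect_equal(got$adjusted, ora$adjusted, tolerance = 1e-12)
  }
  # boundary cases
  expect_true(all(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04, 0.05),
                                     0.05)$rejected))
  one <- benjamini_hochberg(0.04, 0.05)
  expect_true(one$rejected)
  expect_equal(one$adjusted, 0.04)
  expect_false(any(benjamini_hochberg(rep(1, 10), 0.05)$rejected))
  empty <- benjamini_hochberg(numeric(0), 0.05)
  expect_length(empty$rejected, 0)
})

test_that("lowering q never adds BH rejections", {
  set.seed(12)
  for (i in 1:20) {
    p <- runif(sample(5:100, 1))
    hi <- benjamini_hochberg(p, 0.1)$rejected
    lo <- benjamini_hochberg(p, 0.02)$rejected
    expect_true(all(which(lo) %in% which(hi)))
  }
})

test_that("pooled t-test matches the textbook formula and handles degeneracy", {
  set.seed(21)
  for (i in 1:100) {
    a <- rnorm(6); b <- rnorm(6, sd = runif(1, 0.5, 2))
    got <- student_t_test(a, b)
    ora <- oracle_t(a, b)
    expect_equal(got$statistic, ora$statistic, tolerance = 1e-10)
    expect_equal(got$p_value, ora$p_value, tolerance = 1e-10)
    # cross-check against the base implementation on the same data
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  }
  same <- student_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_warning(deg <- student_t_test(c(0, 0, 0), c(1, 1, 1)),
                 "zero pooled variance")
  expect_equal(deg$p_value, 0)
})

test_that("row-wise t-test agrees with the scalar version", {
  set.seed(22)
  x <- matrix(rnorm(50 * 12), 50, 12)
  res <- fibromics:::row_t_test(x, 1:6, 7:12)
  for (i in c(1, 17, 50)) {
    s <- student_t_test(x[i, 1:6], x[i, 7:12])
    expect_equal(res$p_value[i], s$p_value, tolerance = 1e-12)
    expect_equal(res$estimate[i], s$estimate, tolerance = 1e-12)
  }
})

test_that("one-way ANOVA matches textbook formula; two groups give F = t^2", {
  set.seed(31)
  for (i in 1:100) {
    groups <- lapply(1:5, function(j) rnorm(sample(3:8, 1)))
    got <- one_way_anova(groups)
    ora <- oracle_anova(groups)
    expect_equal(got$statistic, ora$statistic, tolerance = 1e-10)
    expect_equal(got$p_value, ora$p_value, tolerance = 1e-10)
  }
  a <- rnorm(6); b <- rnorm(6)
  f2 <- one_way_anova(list(a, b))
  tt <- student_t_test(a, b)
  expect_equal(f2$statistic, tt$statistic^2, tolerance = 1e-10)
  expect_equal(f2$p_value, tt$p_value, tolerance = 1e-10)
  ident <- one_way_anova(list(c(1, 2), c(1, 2), c(1, 2)))
  expect_equal(ident$p_value, oracle_anova(list(c(1, 2), c(1, 2),
                                                c(1, 2)))$p_value)
})

test_that("row-wise ANOVA agrees with the scalar version", {
  set.seed(32)
  x <- matrix(rnorm(30 * 15), 30, 15)
  g <- rep(c("a", "b", "c"), each = 5)
  res <- fibromics:::row_anova(x, g)
  for (i in c(1, 15, 30)) {
    s <- one_way_anova(split(x[i, ], g))
    expect_equal(res$p_value[i], s$p_value, tolerance = 1e-12)
  }
})

test_that("Bonferroni post-test multiplies pairwise p by the comparison count", {
  groups <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  res <- bonferroni_posttest(groups)
  expect_true(all(res$p_adjusted == 1))
  set.seed(41)
  groups <- lapply(1:5, function(i) rnorm(6, mean = i / 4))
  res <- bonferroni_posttest(groups, reference = 1)
  expect_equal(res$p_adjusted, pmin(1, res$p_raw * 4))
  two <- bonferroni_posttest(list(rnorm(5), rnorm(5)))
  expect_equal(two$p_adjusted, two$p_raw)
  expect_error(bonferroni_posttest(groups, reference = 9), "out of range")
})

test_that("Kruskal-Wallis H matches the rank formula and base kruskal.test", {
  set.seed(51)
  for (i in 1:50) {
    groups <- lapply(1:3, function(j) sample(1:20, 7, replace = TRUE))
    got <- kruskal_wallis_dunn(groups)
    expect_equal(got$statistic, oracle_kw(groups), tolerance = 1e-10)
    ref <- kruskal.test(unlist(groups),
                        rep(seq_along(groups), lengths(groups)))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  }
  const <- kruskal_wallis_dunn(list(c(1, 1, 1), c(1, 1, 1)))
  expect_equal(const$p_value, 1)
  expect_error(kruskal_wallis_dunn(list(1:3, numeric(0))), "empty")
})

test_that("Dunn post-tests respond to separation and permute consistently", {
  g <- list(c(1, 2, 3, 4, 5), c(101, 102, 103, 104, 105),
            c(51, 52, 53, 54, 55))
  res <- kruskal_wallis_dunn(g)
  pair12 <- res$posthoc[res$posthoc$i == 1 & res$posthoc$j == 2, ]
  expect_lt(pair12$p_raw, 0.01)
  # permuting groups permutes z magnitudes as a multiset
  res2 <- kruskal_wallis_dunn(g[c(2, 3, 1)])
  expect_equal(sort(abs(res$posthoc$z)), sort(abs(res2$posthoc$z)),
               tolerance = 1e-12)
})

test_that("Fisher exact p equals hypergeometric enumeration", {
  tabs <- list(matrix(c(0, 10, 10, 0), 2), matrix(c(5, 5, 5, 5), 2),
               matrix(c(8, 2, 3, 9), 2), matrix(c(1, 0, 5, 14), 2))
  for (tab in tabs) {
    got <- fisher_exact(tab)
    expect_equal(got$p_value, min(1, oracle_fisher(tab)), tolerance = 1e-9)
  }
  set.seed(61)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 6), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab)$p_value, min(1, oracle_fisher(tab)),
                 tolerance = 1e-9)
    # transposing leaves p unchanged
    expect_equal(fisher_exact(tab)$p_value, fisher_exact(t(tab))$p_value,
                 tolerance = 1e-12)
  }
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  expect_equal(fisher_exact(matrix(c(0, 0, 3, 7), 2))$p_value, 1)
})

test_that("pearson_slope matches lm/cor.test and honours conventions", {
  expect_equal(pearson_slope(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(pearson_slope(c(1, 2, 3), c(2, 4, 6))$slope, 2)
  set.seed(71)
  for (i in 1:50) {
    x <- rnorm(20); y <- 0.5 * x + rnorm(20)
    got <- pearson_slope(x, y)
    fit <- summary(lm(y ~ x))
    expect_equal(got$slope, unname(fit$coefficients["x", 1]),
                 tolerance = 1e-10)
    expect_equal(got$p_value, unname(fit$coefficients["x", 4]),
                 tolerance = 1e-10)
    expect_equal(got$r, unname(cor(x, y)), tolerance = 1e-10)
  }
  expect_error(pearson_slope(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_warning(flat <- pearson_slope(c(1, 2, 3), c(5, 5, 5)), "zero")
  expect_equal(flat$p_value, 1)
})

test_that("row_pearson_slope agrees with scalar pearson_slope", {
  set.seed(72)
  x <- rnorm(15)
  y <- matrix(rnorm(10 * 15), 10, 15)
  res <- fibromics:::row_pearson_slope(y, x)
  for (i in c(1, 5, 10)) {
    s <- pearson_slope(x, y[i, ])
    expect_equal(res$slope[i], s$slope, tolerance = 1e-12)
    expect_equal(res$p_value[i], s$p_value, tolerance = 1e-12)
  }
})

test_that("type-I error of t-test and ANOVA is nominal under the global null", {
  set.seed(81)
  n_rep <- 4000
  x <- matrix(rnorm(n_rep * 12), n_rep, 12)
  pt_ <- fibromics:::row_t_test(x, 1:6, 7:12)$p_value
  expect_lt(abs(mean(pt_ < 0.05) - 0.05), 0.015)
  pa <- fibromics:::row_anova(x, rep(1:3, each = 4))$p_value
  expect_lt(abs(mean(pa < 0.05) - 0.05), 0.015)
})
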