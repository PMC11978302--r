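#' Benjamini-Hochberg step-up FDR control
#'
#' Standard step-up procedure: order the m p-values, reject the largest k
#' with `p_(k) <= k q / m` and everything smaller; adjusted p-values are the
#' monotone step-up values (`p.adjust` method `"BH"`).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param q FDR level in (0, 1).
#' @return list with `p`, `adjusted`, and logical `rejected`.
#' @export
benjamini_hochberg <- function(p, q = 0.05) {
  stopifnot(q > 0, q < 1)
  if (length(p) == 0L)
    return(list(p = numeric(0), adjusted = numeric(0), rejected = logical(0)))
  if (anyNA(p) || any(p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  adjusted <- p.adjust(p, method = "BH")
  list(p = p, adjusted = adjusted, rejected = adjusted <= q)
}

#' Two-sample Student's t-test (pooled variance)
#'
#' Two-tailed unpaired t-test with the pooled-variance (equal variances)
#' statistic, `df = n_a + n_b - 2`.  Degenerate inputs do not crash the
#' pipeline: zero pooled variance returns p = 1 when the means agree and
#' p = 0 (with a warning) when they differ.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param two_sided if `FALSE`, the one-sided p for `mean(a) > mean(b)`.
#' @return list with `statistic`, `df`, `p_value`, `estimate` (mean
#'   difference a - b).
#' @export
student_t_test <- function(a, b, two_sided = TRUE) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stopf("each group needs n >= 2")
  d <- mean(a) - mean(b)
  df <- na + nb - 2L
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / df
  if (sp2 <= 0) {
    if (isTRUE(all.equal(d, 0)) || d == 0)
      return(list(statistic = 0, df = df, p_value = 1, estimate = d))
    warnf("zero pooled variance with unequal means; returning p = 0")
    return(list(statistic = sign(d) * Inf, df = df, p_value = 0, estimate = d))
  }
  tt <- d / sqrt(sp2 * (1 / na + 1 / nb))
  p <- if (two_sided) 2 * pt(-abs(tt), df) else pt(tt, df, lower.tail = FALSE)
  list(statistic = tt, df = df, p_value = p, estimate = d)
}

# Vectorized pooled-variance t-test over matrix rows.
# x: matrix; ia, ib: column index vectors for the two groups.
row_t_test <- function(x, ia, ib) {
  na <- length(ia); nb <- length(ib)
  stopifnot(na >= 2L, nb >= 2L)
  xa <- x[, ia, drop = FALSE]; xb <- x[, ib, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  df <- na + nb - 2L
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
  d <- ma - mb
  tt <- d / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * pt(-abs(tt), df)
  zero <- sp2 <= 0
  if (any(zero)) {
    p[zero] <- ifelse(d[zero] == 0, 1, 0)
    tt[zero] <- ifelse(d[zero] == 0, 0, sign(d[zero]) * Inf)
  }
  data.frame(estimate = d, statistic = tt, df = df, p_value = p,
             row.names = rownames(x))
}

#' One-way ANOVA
#'
#' F-test of equal group means across two or more groups; with two groups
#' the F statistic equals the squared pooled t statistic.  Zero within-group
#' variance is handled as in [student_t_test()].
#'
#' @param groups list of numeric vectors, each of length >= 2.
#' @return list with `statistic` (F), `df` (between, within), `p_value`.
#' @export
one_way_anova <- function(groups) {
  k <- length(groups)
  if (k < 2L) stopf("need >= 2 groups")
  n <- lengths(groups)
  if (any(n < 2L)) stopf("each group needs n >= 2")
  N <- sum(n)
  gm <- mean(unlist(groups))
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(n * (means - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1L; df2 <- N - k
  if (ssw <= 0) {
    if (ssb <= 0)
      return(list(statistic = 0, df = c(df1, df2), p_value = 1))
    warnf("zero within-group variance with unequal means; returning p = 0")
    return(list(statistic = Inf, df = c(df1, df2), p_value = 0))
  }
  f <- (ssb / df1) / (ssw / df2)
  list(statistic = f, df = c(df1, df2), p_value = pf(f, df1, df2,
                                                    lower.tail = FALSE))
}

# Vectorized one-way ANOVA over matrix rows.  group: factor over columns.
row_anova <- function(x, group) {
  group <- as.factor(group)
  k <- nlevels(group); N <- ncol(x)
  stopifnot(k >= 2L, all(table(group) >= 2L))
  gm <- rowMeans(x)
  ssb <- 0; ssw <- 0
  for (lev in levels(group)) {
    cols <- which(group == lev)
    xg <- x[, cols, drop = FALSE]
    mg <- rowMeans(xg)
    ssb <- ssb + length(cols) * (mg - gm)^2
    ssw <- ssw + rowSums((xg - mg)^2)
  }
  df1 <- k - 1L; df2 <- N - k
  f <- (ssb / df1) / (ssw / df2)
  p <- pf(f, df1, df2, lower.tail = FALSE)
  zero <- ssw <= 0
  if (any(zero)) {
    p[zero] <- ifelse(ssb[zero] <= 0, 1, 0)
    f[zero] <- ifelse(ssb[zero] <= 0, 0, Inf)
  }
  data.frame(statistic = f, p_value = p, row.names = rownames(x))
}

#' Bonferroni post-test against a reference group
#'
#' Pairwise comparisons of every group against the reference, using the
#' pooled within-group variance from all groups (the classical post-ANOVA
#' multiple-comparison t), with p-values multiplied by the number of
#' comparisons and capped at 1.
#'
#' @param groups list of numeric vectors.
#' @param reference index of the reference group (default 1).
#' @return data.frame with one row per non-reference group: `group`,
#'   `estimate`, `statistic`, `p_raw`, `p_adjusted`.
#' @export
bonferroni_posttest <- function(groups, reference = 1L) {
  k <- length(groups)
  if (reference < 1L || reference > k) stopf("reference index out of range")
  n <- lengths(groups)
  if (any(n < 2L)) stopf("each group needs n >= 2")
  df <- sum(n) - k
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  msw <- ssw / df
  others <- setdiff(seq_len(k), reference)
  ncmp <- length(others)
  res <- lapply(others, function(i) {
    d <- mean(groups[[i]]) - mean(groups[[reference]])
    se <- sqrt(msw * (1 / n[i] + 1 / n[reference]))
    if (se <= 0) {
      tt <- if (d == 0) 0 else sign(d) * Inf
      p <- if (d == 0) 1 else 0
    } else {
      tt <- d / se
      p <- 2 * pt(-abs(tt), df)
    }
    data.frame(group = i, estimate = d, statistic = tt, p_raw = p,
               p_adjusted = min(1, p * ncmp))
  })
  do.call(rbind, res)
}

#' Kruskal-Wallis test with Dunn's post-test
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square p-value, followed by
#' Dunn's pairwise z-tests on mean ranks.  The post-test adjustment defaults
#' to Bonferroni (the convention of common graphing software); BH is
#' available.
#'
#' @param groups list of numeric vectors, all non-empty.
#' @param adjust `"bonferroni"` or `"BH"` for the Dunn p-values.
#' @return list with `statistic` (H), `df`, `p_value`, and `posthoc`, a
#'   data.frame of all pairwise comparisons (`i`, `j`, `z`, `p_raw`,
#'   `p_adjusted`).
#' @export
kruskal_wallis_dunn <- function(groups, adjust = c("bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  k <- length(groups)
  if (k < 2L) stopf("need >= 2 groups")
  n <- lengths(groups)
  if (any(n == 0L)) stopf("empty group")
  x <- unlist(groups)
  N <- length(x)
  r <- rank(x)
  g <- rep(seq_len(k), n)
  rbar <- tapply(r, g, mean)
  h <- 12 / (N * (N + 1)) * sum(n * (rbar - (N + 1) / 2)^2)
  ties <- table(x)
  tie_corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (tie_corr <= 0) {
    # every value identical: no evidence of any difference
    h <- 0; p <- 1
  } else {
    h <- h / tie_corr
    p <- pchisq(h, df = k - 1L, lower.tail = FALSE)
  }
  pairs <- utils::combn(k, 2L)
  sigma0 <- N * (N + 1) / 12 * tie_corr
  zval <- apply(pairs, 2L, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt(sigma0 * (1 / n[i] + 1 / n[j]))
    if (se > 0) unname((rbar[i] - rbar[j]) / se) else 0
  })
  post <- data.frame(i = pairs[1, ], j = pairs[2, ], z = zval)
  post$p_raw <- 2 * stats::pnorm(-abs(post$z))
  post$p_adjusted <- if (adjust == "bonferroni")
    pmin(1, post$p_raw * ncol(pairs)) else p.adjust(post$p_raw, "BH")
  list(statistic = h, df = k - 1L, p_value = p, posthoc = post)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p by the standard convention of summing hypergeometric
#' probabilities no larger than the observed table's.  A table with an
#' all-zero margin carries no information and returns p = 1.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return list with `p_value` and `odds_ratio` (sample odds ratio,
#'   `Inf`/0 conventions for zero cells).
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0))
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  # a zero margin fixes the table: only one table is possible, p = 1
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(p_value = 1, odds_ratio = or))
  p <- fisher.test(tab)$p.value
  list(p_value = min(1, p), odds_ratio = or)
}

#' Pearson correlation and least-squares slope with slope p-value
#'
#' Simple linear regression of `y` on `x`: returns Pearson r, the slope and
#' intercept, and the two-sided p-value of the slope from
#' `t = slope / SE(slope)` on `n - 2` df (identical to the p-value of r).
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return list with `r`, `slope`, `intercept`, `statistic`, `df`,
#'   `p_value`.
#' @export
pearson_slope <- function(x, y) {
  n <- length(x)
  if (n < 3L || length(y) != n) stopf("need n >= 3 paired points")
  vx <- var(x)
  if (vx <= 0) stopf("x has zero variance")
  vy <- var(y)
  cxy <- cov(x, y)
  slope <- cxy / vx
  intercept <- mean(y) - slope * mean(x)
  if (vy <= 0) {
    warnf("y has zero variance; returning r = 0, p = 1")
    return(list(r = 0, slope = 0, intercept = mean(y), statistic = 0,
                df = n - 2L, p_value = 1))
  }
  r <- cxy / sqrt(vx * vy)
  r <- max(-1, min(1, r))
  df <- n - 2L
  if (abs(r) >= 1) {
    tt <- sign(r) * Inf; p <- 0
  } else {
    tt <- r * sqrt(df / (1 - r^2))
    p <- 2 * pt(-abs(tt), df)
  }
  list(r = r, slope = slope, intercept = intercept, statistic = tt,
       df = df, p_value = p)
}

# Vectorized pearson_slope over matrix rows of y against a common x.
row_pearson_slope <- function(y, x) {
  n <- length(x)
  stopifnot(ncol(y) == n, n >= 3L)
  vx <- var(x)
  if (vx <= 0) stopf("x has zero variance")
  xc <- x - mean(x)
  ym <- rowMeans(y)
  yc <- y - ym
  cxy <- as.vector(yc %*% xc) / (n - 1)
  vy <- rowSums(yc^2) / (n - 1)
  slope <- cxy / vx
  r <- cxy / sqrt(vx * vy)
  r[vy <= 0] <- 0
  r <- pmax(-1, pmin(1, r))
  df <- n - 2L
  tt <- ifelse(abs(r) >= 1, sign(r) * Inf, r * sqrt(df / (1 - r^2)))
  p <- ifelse(abs(r) >= 1, 0, 2 * pt(-abs(tt), df))
  p[vy <= 0] <- 1
  slope[vy <= 0] <- 0
  data.frame(slope = slope, r = r, statistic = tt, df = df, p_value = p,
             row.names = rownames(y))
}
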