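# Independent textbook-formula oracles, coded separately from the package
# implementations so the two routes can disagree.

oracle_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i * q / m) k <- i
  rejected <- logical(m)
  if (k > 0) rejected[o[seq_len(k)]] <- TRUE
  # adjusted p by step-up monotonization
  adj <- ps * m / seq_len(m)
  if (m > 1) for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  adjusted <- numeric(m)
  adjusted[o] <- pmin(1, adj)
  list(rejected = rejected, adjusted = adjusted)
}

oracle_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(statistic = tt, p_value = 2 * pt(-abs(tt), na + nb - 2))
}

oracle_anova <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  ssb <- sum(tapply(x, g, function(v) length(v) * (mean(v) - mean(x))^2))
  ssw <- sum(tapply(x, g, function(v) sum((v - mean(v))^2)))
  df1 <- length(groups) - 1
  df2 <- length(x) - length(groups)
  f <- (ssb / df1) / (ssw / df2)
  list(statistic = f, p_value = pf(f, df1, df2, lower.tail = FALSE))
}

# two-sided Fisher p by full hypergeometric enumeration over tables with
# the observed margins
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(support, function(a)
    exp(lchoose(c1, a) + lchoose(n - c1, r1 - a) - lchoose(n, r1)),
    numeric(1))
  p_obs <- probs[support == tab[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

oracle_kw <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x)
  n <- lengths(groups); N <- length(x)
  h <- 12 / (N * (N + 1)) * sum(tapply(r, g, sum)^2 / n) - 3 * (N + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# brute-force complete-linkage agglomeration for small n
oracle_complete_linkage_heights <- function(x) {
  d <- as.matrix(dist(x))
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, i, j)
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# small deterministic intensity matrix fixture
make_matrix <- function(values, sample_ids = NULL, protein_ids = NULL) {
  v <- as.matrix(values)
  if (!is.null(sample_ids)) colnames(v) <- sample_ids
  if (is.null(colnames(v))) colnames(v) <- paste0("s", seq_len(ncol(v)))
  if (!is.null(protein_ids)) rownames(v) <- protein_ids
  intensity_matrix(v)
}

# minimal one-model design for matrix fixtures: n mice per time point,
# Total fraction
tiny_design <- function(n = 6L, model = "CCl4like", fraction = "Total") {
  study_design(models = model, fractions = fraction, n_mice = n)
}

# preprocess one fraction of a synthetic study with the standard settings
prep_fraction <- function(study, fraction, seed, min_valid = 5L) {
  filt <- filter_by_valid_values(study$matrices[[fraction]], study$design,
                                 min_valid = min_valid)
  impute_downshift(normalize_columns(filt),
                   seed = stage_seed(seed, paste0("impute_", fraction)))
}
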