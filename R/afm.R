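#' Hertz force for a spherical indenter
#'
#' `F = 4/3 * E / (1 - nu^2) * sqrt(R) * delta^(3/2)`: the contact-mechanics
#' force-indentation relation for a rigid sphere of radius `R` on an elastic
#' half-space with Young's modulus `E` and Poisson ratio `nu`.
#'
#' @param delta indentation depth (m), >= 0.
#' @param E Young's modulus (Pa).
#' @param R probe radius (m); default half of a 5.7 um bead.
#' @param nu Poisson ratio; 0.45 for soft, nearly incompressible tissue.
#' @return force in newtons.
#' @export
hertz_force <- function(delta, E, R = 2.85e-6, nu = 0.45) {
  stopifnot(E > 0, R > 0, nu >= 0, nu < 0.5)
  (4 / 3) * (E / (1 - nu^2)) * sqrt(R) * pmax(delta, 0)^1.5
}

#' Locate the contact point of a force curve
#'
#' Exhaustive two-segment least squares: every interior sample is tried as
#' the contact point; the pre-contact segment is fit with a linear baseline
#' (offset + tilt), the post-contact segment with the Hertz `delta^(3/2)`
#' rise (after converting piezo height to indentation,
#' `delta = (z - z_c) - F/k`), and the candidate minimizing the total
#' squared residual wins.  Robust to constant force offsets and baseline
#' tilt; deterministic.
#'
#' @param z piezo height (m), increasing along the approach.
#' @param force measured force (N).
#' @param k cantilever spring constant (N/m).
#' @param min_pre,min_post minimum samples in each segment.
#' @return list with `contact_index`, `baseline` (intercept, slope), `A`
#'   (Hertz prefactor of the winning fit) and `rss`.
#' @export
find_contact_point <- function(z, force, k = 0.09, min_pre = 5L,
                               min_post = 10L) {
  n <- length(z)
  if (n < min_pre + min_post + 1L || n < 20L)
    stopf("curve too short for contact detection")
  all_cand <- seq.int(min_pre, n - min_post)
  # coarse-to-fine search: stride pass, then exhaustive refinement around
  # the best coarse candidate (the objective is near-unimodal in practice)
  stride <- max(1L, length(all_cand) %/% 24L)
  eval_cands <- function(candidates) {
  best <- list(rss = Inf, contact_index = NA_integer_)
  for (i in candidates) {
    zi <- z[seq_len(i)]; fi <- force[seq_len(i)]
    # closed-form linear fit of the baseline
    zm <- mean(zi); fm <- mean(fi)
    vz <- sum((zi - zm)^2)
    b1 <- if (vz > 0) sum((zi - zm) * (fi - fm)) / vz else 0
    b0 <- fm - b1 * zm
    rss_pre <- sum((fi - b0 - b1 * zi)^2)
    post <- seq.int(i + 1L, n)
    fcorr <- force[post] - (b0 + b1 * z[post])
    delta <- (z[post] - z[i]) - fcorr / k
    ok <- delta > 0
    if (sum(ok) < 3L) next
    d32 <- delta[ok]^1.5
    A <- sum(fcorr[ok] * d32) / sum(d32^2)
    pred <- numeric(length(post))
    pred[ok] <- A * d32
    rss_post <- sum((fcorr - pred)^2)
    rss <- rss_pre + rss_post
    if (rss < best$rss)
      best <- list(rss = rss, contact_index = i,
                   baseline = c(intercept = b0, slope = b1), A = A)
  }
  best
  }
  coarse <- eval_cands(unique(c(all_cand[seq(1L, length(all_cand),
                                             by = stride)],
                                all_cand[length(all_cand)])))
  best <- if (is.na(coarse$contact_index)) coarse else
    eval_cands(all_cand[abs(all_cand - coarse$contact_index) <= stride])
  if (!is.finite(best$rss) || is.na(best$contact_index) ||
      !is.finite(best$A) || best$A <= 0)
    stopf("no contact detected")
  best
}

#' Fit Young's modulus by the Hertz spherical model
#'
#' Least-squares fit of `F = 4/3 * E/(1-nu^2) * sqrt(R) * delta^(3/2)` on a
#' contact-aligned curve (linear in the prefactor, hence closed form).  The
#' fit range is capped at `delta <= delta_cap * R` to stay in the
#' small-indentation regime.
#'
#' @param delta indentation (m), contact at 0.
#' @param force baseline-corrected force (N).
#' @param R probe radius (m).
#' @param nu Poisson ratio.
#' @param delta_cap indentation cap as a fraction of `R` (default 0.3;
#'   `Inf` disables).
#' @return Young's modulus in Pa.
#' @export
fit_hertz_sphere <- function(delta, force, R = 2.85e-6, nu = 0.45,
                             delta_cap = 0.3) {
  stopifnot(R > 0, nu >= 0, nu < 0.5)
  use <- delta > 0 & delta <= delta_cap * R
  if (sum(use) < 3L) stopf("too few post-contact samples inside the fit range")
  d32 <- delta[use]^1.5
  A <- sum(force[use] * d32) / sum(d32^2)
  E <- A * 0.75 * (1 - nu^2) / sqrt(R)
  if (!is.finite(E) || E <= 0) stopf("Hertz fit failed (non-positive modulus)")
  E
}

#' Process a raw force curve to a Young's modulus
#'
#' Contact detection, baseline subtraction, height-to-indentation
#' conversion and Hertz fit in one step.  Failed fits return `NA` with the
#' failure reason instead of aborting a whole map.
#'
#' @param z,force raw approach curve (m, N).
#' @param R probe radius (m); `nu` Poisson ratio; `k` spring constant
#'   (N/m).
#' @param delta_cap fit-range cap, see [fit_hertz_sphere()].
#' @return list with `E` (Pa or `NA`), `contact_index`, `error`.
#' @export
process_force_curve <- function(z, force, R = 2.85e-6, nu = 0.45, k = 0.09,
                                delta_cap = 0.3) {
  res <- tryCatch({
    cp <- find_contact_point(z, force, k = k)
    i <- cp$contact_index
    post <- seq.int(i + 1L, length(z))
    fcorr <- force[post] - (cp$baseline[1] + cp$baseline[2] * z[post])
    delta <- (z[post] - z[i]) - fcorr / k
    keep <- delta > 0
    E <- fit_hertz_sphere(delta[keep], fcorr[keep], R = R, nu = nu,
                          delta_cap = delta_cap)
    list(E = E, contact_index = i, error = NA_character_)
  }, error = function(e) list(E = NA_real_, contact_index = NA_integer_,
                              error = conditionMessage(e)))
  res
}

#' Fit every curve of a force-curve set
#'
#' @param fcs a force-curve set from [simulate_force_curves()] or
#'   [read_force_curves()]: list with `curves`, `meta`, `R`, `nu`, `k`.
#' @param delta_cap fit-range cap.
#' @return the set's `meta` data.frame with columns `E` (Pa) and
#'   `fit_error` appended.
#' @export
fit_stiffness_map <- function(fcs, delta_cap = 0.3) {
  fits <- lapply(fcs$curves, function(cu)
    process_force_curve(cu$z, cu$force, R = fcs$R, nu = fcs$nu, k = fcs$k,
                        delta_cap = delta_cap))
  meta <- fcs$meta
  meta$E <- vapply(fits, function(f) f$E, numeric(1))
  meta$fit_error <- vapply(fits, function(f) f$error, character(1))
  meta
}

#' Region-level stiffness statistics
#'
#' Pools fitted pixel moduli per (region, treatment): median, frequency
#' histogram, and the per-map medians kept for the stiffness-proteome
#' correlation.  Failed fits are excluded.
#'
#' @param fits data.frame from [fit_stiffness_map()] (possibly several maps
#'   row-bound), with columns `region, treatment, map_id, mouse_id, E`.
#' @param breaks histogram breaks in Pa (default 250 Pa bins up to the data
#'   maximum).
#' @return list with `summary` (per region x treatment median, n), `hist`
#'   (long-format bin counts) and `per_map` (median per map).
#' @export
build_region_stats <- function(fits, breaks = NULL) {
  ok <- fits[is.finite(fits$E), , drop = FALSE]
  if (nrow(ok) == 0L) stopf("no successful fits")
  if (is.null(breaks))
    breaks <- seq(0, max(ok$E) + 250, by = 250)
  key <- interaction(ok$region, ok$treatment, drop = TRUE)
  summary <- do.call(rbind, lapply(levels(key), function(kk) {
    sub <- ok[key == kk, ]
    data.frame(region = sub$region[1], treatment = sub$treatment[1],
               median_E = median(sub$E), n_curves = nrow(sub),
               stringsAsFactors = FALSE)
  }))
  hist_tab <- do.call(rbind, lapply(levels(key), function(kk) {
    sub <- ok[key == kk, ]
    h <- hist(pmin(sub$E, max(breaks)), breaks = breaks, plot = FALSE)
    data.frame(region = sub$region[1], treatment = sub$treatment[1],
               bin_lo = head(h$breaks, -1), bin_hi = tail(h$breaks, -1),
               count = h$counts, stringsAsFactors = FALSE)
  }))
  per_map <- aggregate(E ~ map_id + mouse_id + region + treatment, data = ok,
                       FUN = median)
  names(per_map)[names(per_map) == "E"] <- "median_E"
  list(summary = summary, hist = hist_tab, per_map = per_map)
}

#' Compare stiffness across treatments per region
#'
#' Kruskal-Wallis over pooled pixel moduli across treatments within each
#' region, followed by Dunn's post-tests against control.
#'
#' @param fits data.frame from [fit_stiffness_map()].
#' @param reference control treatment label (default `"Ctrl"`).
#' @param adjust Dunn adjustment, see [kruskal_wallis_dunn()].
#' @return data.frame per (region, treatment vs reference): `region,
#'   treatment, kw_p, z, p_adjusted`.
#' @export
compare_regions <- function(fits, reference = "Ctrl",
                            adjust = c("bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  ok <- fits[is.finite(fits$E), , drop = FALSE]
  out <- list()
  for (reg in unique(ok$region)) {
    sub <- ok[ok$region == reg, ]
    treatments <- unique(sub$treatment)
    treatments <- c(reference, setdiff(treatments, reference))
    groups <- lapply(treatments, function(tr) sub$E[sub$treatment == tr])
    if (length(groups) < 2L || any(lengths(groups) == 0L)) next
    kw <- kruskal_wallis_dunn(groups, adjust = adjust)
    vs_ref <- kw$posthoc[kw$posthoc$i == 1L | kw$posthoc$j == 1L, ]
    other <- ifelse(vs_ref$i == 1L, vs_ref$j, vs_ref$i)
    out[[length(out) + 1L]] <- data.frame(
      region = reg, treatment = treatments[other], kw_p = kw$p_value,
      z = vs_ref$z, p_adjusted = vs_ref$p_adjusted,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Correlate regional stiffness with protein abundance
#'
#' For each region: per-mouse stiffness (average of that mouse's per-map
#' median moduli) minus the mean control stiffness, paired by mouse with the
#' per-mouse protein abundance deltas; Pearson slope + BH over all proteins.
#'
#' @param per_map per-map medians from [build_region_stats()].
#' @param prot_by_mouse matrix proteins x mice of control-baselined log2
#'   deltas (columns named by `mouse_id`).
#' @param q BH FDR level.
#' @param reference control treatment label.
#' @return data.frame: `region, protein_id, slope, r, p, q, significant`.
#' @export
correlate_stiffness_proteome <- function(per_map, prot_by_mouse, q = 0.05,
                                         reference = "Ctrl") {
  out <- list()
  for (reg in unique(per_map$region)) {
    sub <- per_map[per_map$region == reg, ]
    by_mouse <- aggregate(median_E ~ mouse_id + treatment, data = sub,
                          FUN = mean)
    ctrl <- by_mouse$median_E[by_mouse$treatment == reference]
    if (length(ctrl) == 0L) stopf("no control maps for region %s", reg)
    by_mouse$delta_E <- by_mouse$median_E - mean(ctrl)
    mice <- intersect(by_mouse$mouse_id, colnames(prot_by_mouse))
    if (length(mice) < 3L) {
      message(sprintf("region %s: fewer than 3 paired mice; skipped", reg))
      next
    }
    x <- by_mouse$delta_E[match(mice, by_mouse$mouse_id)]
    y <- prot_by_mouse[, mice, drop = FALSE]
    ps <- row_pearson_slope(y, x)
    bh <- benjamini_hochberg(ps$p_value, q)
    out[[length(out) + 1L]] <- data.frame(
      region = reg, protein_id = rownames(prot_by_mouse),
      slope = ps$slope, r = ps$r, p = ps$p_value, q = bh$adjusted,
      significant = bh$rejected, row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
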