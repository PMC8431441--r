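#' Cohen's d effect size
#'
#' Standardized mean difference: d = (mean_a - mean_b) / s_pooled, with the
#' pooled standard deviation s_pooled = sqrt(((n_a-1) s_a^2 + (n_b-1) s_b^2)
#' / (n_a + n_b - 2)). Size classes follow the conventional |d| cutoffs
#' 0.2 (small), 0.5 (medium), 0.8 (large).
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return List with `d`, `size_class` and `degenerate` (TRUE when both
#'   variances are zero but the means differ, in which case `d` is signed
#'   infinity).
#' @export
cohens_d <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  stopifnot(na >= 2L, nb >= 2L)
  va <- stats::var(group_a); vb <- stats::var(group_b)
  diff <- mean(group_a) - mean(group_b)
  s_pooled <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
  degenerate <- FALSE
  if (s_pooled == 0) {
    if (diff == 0) {
      d <- 0
    } else {
      d <- sign(diff) * Inf
      degenerate <- TRUE
    }
  } else {
    d <- diff / s_pooled
  }
  list(d = d, size_class = d_size_class(d), degenerate = degenerate)
}

#' Classify an effect size by the conventional |d| cutoffs
#' @param d Cohen's d (signed).
#' @return One of "negligible", "small", "medium", "large".
#' @export
d_size_class <- function(d) {
  a <- abs(d)
  if (a >= 0.8) "large" else if (a >= 0.5) "medium" else if (a >= 0.2) "small" else "negligible"
}

#' Two-sided Wilcoxon rank-sum test
#'
#' `exact` mode enumerates the full permutation distribution of the
#' rank-sum statistic (all choose(N, n_a) group assignments) and is used
#' automatically when N <= 12 and the data are tie-free; otherwise the
#' normal approximation with tie and continuity corrections is applied.
#' Pallant's r = |z| / sqrt(N) is attached (z from the normal
#' approximation).
#'
#' @param group_a,group_b Nonempty numeric vectors.
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @param alternative `"two.sided"`, `"greater"` (a tends larger) or
#'   `"less"`.
#' @return List of class `msiith_test`: `test_name`, `statistic` (U of
#'   group a), `p_value`, `z`, `effect_size` (Pallant's r), `effect_kind`,
#'   `n_a`, `n_b`, `mode`.
#' @export
wilcoxon_rank_sum <- function(group_a, group_b,
                              mode = c("auto", "exact", "normal"),
                              alternative = c("two.sided", "greater", "less")) {
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  na <- length(group_a); nb <- length(group_b)
  if (na == 0L || nb == 0L) stop("both groups must be nonempty")
  values <- c(group_a, group_b)
  n <- na + nb
  ties <- anyDuplicated(values) > 0L
  if (mode == "auto") {
    mode <- if (n <= 12L && !ties) "exact" else "normal"
  }
  if (mode == "exact" && ties) {
    stop("exact mode requires tie-free data")
  }
  r <- rank(values)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  # tie-corrected normal approximation (always computed, for z and r)
  tie_tab <- table(values)
  tie_term <- sum(tie_tab^3 - tie_tab)
  sigma2 <- na * nb / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  sigma <- sqrt(max(sigma2, 0))
  if (sigma > 0) {
    cc <- 0.5 * sign(u_obs - mu)
    z <- (u_obs - mu - cc) / sigma
    if (u_obs == mu) z <- 0
  } else {
    z <- 0
  }
  if (mode == "exact") {
    assignments <- utils::combn(n, na)
    u_all <- colSums(matrix(r[assignments], nrow = na)) - na * (na + 1) / 2
    p <- switch(alternative,
      two.sided = mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9),
      greater = mean(u_all >= u_obs - 1e-9),
      less = mean(u_all <= u_obs + 1e-9))
  } else {
    if (sigma == 0) {
      p <- 1
    } else {
      p <- switch(alternative,
        two.sided = 2 * stats::pnorm(-abs(z)),
        greater = stats::pnorm(-(u_obs - mu - 0.5) / sigma),
        less = stats::pnorm((u_obs - mu + 0.5) / sigma))
      p <- min(p, 1)
    }
  }
  structure(list(test_name = "wilcoxon_rank_sum", statistic = u_obs,
                 p_value = p, z = z, effect_size = pallant_r(z, n),
                 effect_kind = "pallant_r", n_a = na, n_b = nb,
                 mode = mode, alternative = alternative),
            class = "msiith_test")
}

#' Pallant's r effect size for rank tests
#' @param z Normal-equivalent test statistic.
#' @param n Total observations in the comparison.
#' @return |z| / sqrt(n).
#' @export
pallant_r <- function(z, n) abs(z) / sqrt(n)

#' Kruskal-Wallis test with eta-squared effect size
#'
#' H is computed on pooled ranks with the usual tie correction and referred
#' to the chi-square distribution with k - 1 degrees of freedom. The
#' attached effect size is eta-squared = (H - k + 1) / (N - k).
#'
#' @param groups List of >= 2 numeric vectors.
#' @return List of class `msiith_test`: `statistic` (H), `p_value`, `df`,
#'   `effect_size` (eta squared), `group_sizes`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  sizes <- lengths(groups)
  if (any(sizes < 1L)) stop("every group must be nonempty")
  values <- unlist(groups)
  n <- length(values)
  if (n < 3L) stop("need at least 3 observations in total")
  k <- length(groups)
  g <- rep(seq_len(k), sizes)
  r <- rank(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, sum)^2 / sizes) - 3 * (n + 1)
  tie_tab <- table(values)
  correction <- 1 - sum(tie_tab^3 - tie_tab) / (n^3 - n)
  if (correction > 0) h <- h / correction
  p <- stats::pchisq(h, df = k - 1, lower.tail = FALSE)
  structure(list(test_name = "kruskal_wallis", statistic = h, p_value = p,
                 df = k - 1L, effect_size = eta_squared(h, k, n),
                 effect_kind = "eta_squared", group_sizes = sizes),
            class = "msiith_test")
}

#' Eta-squared effect size for a Kruskal-Wallis H
#' @param h The H statistic.
#' @param k Number of groups in the comparison.
#' @param n Total observations.
#' @return (H - k + 1) / (N - k); can be slightly negative under the null.
#' @export
eta_squared <- function(h, k, n) (h - k + 1) / (n - k)

#' Conover-Iman post hoc pairwise comparisons
#'
#' Pairwise t statistics on the pooled ranks after a Kruskal-Wallis test:
#' t_ij = (Rbar_i - Rbar_j) / sqrt(S^2 (N-1-H)/(N-k) (1/n_i + 1/n_j)),
#' where S^2 is the pooled rank variance (tie-aware); two-sided p from the
#' t distribution with N - k degrees of freedom. Pallant's r per pair uses
#' the z equivalent of the pair's p and the pair's total n. P-values are
#' not adjusted for multiplicity by default; `holm = TRUE` applies Holm's
#' correction.
#'
#' @param groups List of >= 3 numeric vectors.
#' @param holm Apply Holm adjustment to the pairwise p-values.
#' @return Data frame with one row per unordered pair: `group_i`,
#'   `group_j`, `t`, `p_value`, `pallant_r`, `n_i`, `n_j`, `low_power`
#'   (any singleton group).
#' @export
conover_posthoc <- function(groups, holm = FALSE) {
  stopifnot(is.list(groups), length(groups) >= 3L)
  sizes <- lengths(groups)
  if (any(sizes < 1L)) stop("every group must be nonempty")
  k <- length(groups)
  values <- unlist(groups)
  n <- length(values)
  g <- rep(seq_len(k), sizes)
  r <- rank(values)
  kw <- kruskal_wallis(groups)
  h <- kw$statistic
  rbar <- tapply(r, g, mean)
  s2 <- (sum(r^2) - n * (n + 1)^2 / 4) / (n - 1)
  scale2 <- s2 * (n - 1 - h) / (n - k)
  scale2 <- max(scale2, 0)
  pairs <- utils::combn(k, 2L)
  out <- data.frame(
    group_i = pairs[1L, ], group_j = pairs[2L, ],
    t = NA_real_, p_value = NA_real_, pallant_r = NA_real_,
    n_i = sizes[pairs[1L, ]], n_j = sizes[pairs[2L, ]],
    low_power = sizes[pairs[1L, ]] == 1L | sizes[pairs[2L, ]] == 1L
  )
  for (idx in seq_len(ncol(pairs))) {
    i <- pairs[1L, idx]; j <- pairs[2L, idx]
    se <- sqrt(scale2 * (1 / sizes[i] + 1 / sizes[j]))
    t_stat <- if (se > 0) (rbar[i] - rbar[j]) / se else 0
    p <- 2 * stats::pt(-abs(t_stat), df = n - k)
    out$t[idx] <- t_stat
    out$p_value[idx] <- min(p, 1)
  }
  if (holm) out$p_value <- stats::p.adjust(out$p_value, method = "holm")
  z_equiv <- stats::qnorm(pmin(out$p_value, 1 - 1e-16) / 2, lower.tail = FALSE)
  out$pallant_r <- pmin(1, abs(z_equiv) / sqrt(out$n_i + out$n_j))
  out
}

#' Screen spectral components by a dual effect-size rule
#'
#' For every component, two Cohen's d values are computed on pixel-level
#' abundances: d1 contrasts the target level-1 cluster against all other
#' pixels, d2 contrasts all ND pixels against all PD pixels. A component is
#' selected iff |d1| >= `d_cluster_min` (at least medium by default) and
#' |d2| >= `d_outcome_min` (at least small by default).
#'
#' @param features A `feature_matrix`.
#' @param level1_labels Per-pixel cluster labels (character vector or
#'   `level_labels`).
#' @param target_cluster Label of the cluster of interest.
#' @param outcome Per-pixel outcome, values "ND"/"PD".
#' @param d_cluster_min,d_outcome_min Absolute-d thresholds.
#' @return List of class `screening_result`: `selected` (component ids),
#'   `table` (per-component d1, d2, selected flag), thresholds.
#' @export
screen_components <- function(features, level1_labels, target_cluster,
                              outcome, d_cluster_min = 0.5,
                              d_outcome_min = 0.2) {
  labels <- if (inherits(level1_labels, "level_labels")) level1_labels$labels else level1_labels
  vals <- features$values
  stopifnot(length(labels) == nrow(vals), length(outcome) == nrow(vals))
  in_cluster <- labels == target_cluster
  if (sum(in_cluster) < 2L) stop("target cluster has fewer than 2 pixels")
  if (sum(!in_cluster) < 2L) stop("fewer than 2 pixels outside the target cluster")
  is_nd <- outcome == "ND"
  d1 <- numeric(ncol(vals)); d2 <- numeric(ncol(vals))
  for (j in seq_len(ncol(vals))) {
    d1[j] <- cohens_d(vals[in_cluster, j], vals[!in_cluster, j])$d
    d2[j] <- cohens_d(vals[is_nd, j], vals[!is_nd, j])$d
  }
  ids <- features$components$component_id
  tab <- data.frame(component_id = ids,
                    center = features$components$center,
                    d_cluster = d1, d_outcome = d2,
                    selected = abs(d1) >= d_cluster_min & abs(d2) >= d_outcome_min)
  structure(list(selected = ids[tab$selected], table = tab,
                 d_cluster_min = d_cluster_min, d_outcome_min = d_outcome_min,
                 target_cluster = target_cluster),
            class = "screening_result")
}

#' Per-ROI contribution of one cluster, compared between outcome groups
#'
#' The contribution of a cluster to an ROI is the fraction of the ROI's
#' unflagged pixels carrying that label (0 when absent). Fractions are
#' compared between ND and PD ROIs with the Wilcoxon rank-sum test.
#'
#' @param labels Per-pixel cluster labels.
#' @param roi_ids Per-pixel ROI ids, parallel to `labels`.
#' @param cluster Cluster label of interest.
#' @param roi_outcome Named character vector mapping roi_id to "ND"/"PD".
#' @return List with `fractions` (data frame roi_id, outcome, fraction) and
#'   `test` (Wilcoxon result, NULL if a group is absent).
#' @export
cluster_contribution <- function(labels, roi_ids, cluster, roi_outcome) {
  labels <- if (inherits(labels, "level_labels")) labels$labels else labels
  stopifnot(length(labels) == length(roi_ids))
  ids <- unique(roi_ids)
  frac <- vapply(ids, function(id) {
    sel <- roi_ids == id
    mean(labels[sel] == cluster)
  }, numeric(1L))
  df <- data.frame(roi_id = ids, outcome = unname(roi_outcome[ids]),
                   fraction = unname(frac), stringsAsFactors = FALSE)
  test <- NULL
  nd <- df$fraction[df$outcome == "ND"]
  pd <- df$fraction[df$outcome == "PD"]
  if (length(nd) > 0L && length(pd) > 0L) {
    test <- wilcoxon_rank_sum(nd, pd, mode = "normal")
  }
  list(fractions = df, test = test)
}

#' Correlate tumor-infiltrating lymphocytes with heterogeneity
#'
#' Pearson correlation between the TILs percentage and the per-ROI Simpson
#' diversity at one segmentation level, with the least-squares line and its
#' 95% confidence band parameters, plus a Wilcoxon comparison and Cohen's d
#' of TILs between the ND and PD groups.
#'
#' @param profiles Data frame from [roi_profiles()].
#' @param metadata Validated clinical table (needs `tils_percent`).
#' @param roi_patient Named character vector mapping roi_id to patient_id.
#' @param level Segmentation level for the diversity index.
#' @return List with `r`, `p_value`, `n`, `slope`, `intercept`,
#'   `ci_level`, `sigma`, `group_test`, `group_d`.
#' @export
correlate_tils <- function(profiles, metadata, roi_patient, level = 1L) {
  d_col <- paste0("simpson_level", level)
  pid <- unname(roi_patient[profiles$roi_id])
  m <- metadata[match(pid, metadata$patient_id), ]
  tils <- m$tils_percent
  ok <- !is.na(tils)
  if (sum(ok) < 3L) stop("need at least 3 patients with TILs data")
  d <- profiles[[d_col]][ok]
  t <- tils[ok]
  if (stats::sd(t) == 0 || stats::sd(d) == 0) {
    return(list(r = NA_real_, p_value = NA_real_, n = sum(ok),
                degenerate = TRUE))
  }
  ct <- stats::cor.test(t, d, method = "pearson")
  fit <- stats::lm(t ~ d)
  out <- list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok),
              slope = unname(stats::coef(fit)[2L]),
              intercept = unname(stats::coef(fit)[1L]),
              ci_level = 0.95,
              sigma = suppressWarnings(summary(fit)$sigma),
              degenerate = FALSE)
  nd <- t[m$outcome[ok] == "ND"]
  pd <- t[m$outcome[ok] == "PD"]
  if (length(nd) >= 2L && length(pd) >= 2L) {
    out$group_test <- wilcoxon_rank_sum(nd, pd, mode = "normal")
    out$group_d <- cohens_d(nd, pd)
  }
  out
}

#' Association between two categorical variables (2 x m table)
#'
#' Utility for contrasts such as estrogen-receptor status versus outcome
#' group: Fisher's exact test on the contingency table.
#'
#' @param x,y Categorical vectors of equal length.
#' @return The `htest` result of [stats::fisher.test()].
#' @export
categorical_association <- function(x, y) {
  stats::fisher.test(table(x, y))
}
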