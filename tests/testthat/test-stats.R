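test_that("Cohen's d matches closed forms and invariances", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3))$d, 0)
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3))$size_class, "negligible")
  r <- cohens_d(c(0, 1), c(1, 2))
  expect_equal(r$d, -sqrt(2), tolerance = 1e-12)
  expect_equal(round(r$d, 4), -1.4142)
  expect_equal(r$size_class, "large")
  # |d| = 1 when means differ by exactly one pooled SD
  a <- c(0, 1, 2); b <- a + stats::sd(a)
  expect_equal(abs(cohens_d(a, b)$d), 1)
  # antisymmetry and affine invariance
  set.seed(1)
  x <- rnorm(10); y <- rnorm(12, 1)
  expect_equal(cohens_d(x, y)$d, -cohens_d(y, x)$d)
  expect_equal(cohens_d(3 * x + 7, 3 * y + 7)$d, cohens_d(x, y)$d)
  # degenerate zero-variance groups
  dg <- cohens_d(c(1, 1), c(2, 2))
  expect_true(dg$degenerate)
  expect_identical(dg$d, -Inf)
  expect_false(cohens_d(c(1, 1), c(1, 1))$degenerate)
})

test_that("exact Wilcoxon equals permutation enumeration", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$mode, "exact")
  expect_equal(w$p_value, 0.1)
  # identical samples (ties): normal path, p = 1
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "nonempty")

  # oracle: independent enumeration over all assignments, several fixtures
  set.seed(4)
  for (i in 1:15) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    vals <- sample(seq_len(50), na + nb)  # tie-free
    a <- vals[seq_len(na)]; b <- vals[-seq_len(na)]
    got <- wilcoxon_rank_sum(a, b, mode = "exact")$p_value
    # independent oracle: rank-sum statistic over all label assignments
    rk <- rank(vals)
    obs <- sum(rk[seq_len(na)])
    all_sums <- combn(na + nb, na, function(ix) sum(rk[ix]))
    center <- na * (na + nb + 1) / 2
    oracle <- mean(abs(all_sums - center) >= abs(obs - center) - 1e-9)
    expect_equal(got, oracle)
    # and R's own exact test agrees
    expect_equal(got, stats::wilcox.test(a, b, exact = TRUE)$p.value)
  }
})

test_that("Pallant's r follows |z|/sqrt(N)", {
  expect_equal(pallant_r(2, 16), 0.5)
  w <- wilcoxon_rank_sum(rnorm(20), rnorm(20, 2), mode = "normal")
  expect_equal(w$effect_size, abs(w$z) / sqrt(40))
})

test_that("Kruskal-Wallis matches the closed form and stats::kruskal.test", {
  kw <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(kw$statistic, 32 / 7, tolerance = 1e-9)
  expect_equal(round(kw$statistic, 4), 4.5714)
  expect_equal(eta_squared(7.5, 2, 20), 6.5 / 18)
  expect_equal(round(eta_squared(7.5, 2, 20), 4), 0.3611)
  # identical values: H = 0, p = 1
  kw0 <- kruskal_wallis(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(kw0$statistic, 0)
  expect_equal(kw0$p_value, 1)
  # oracle on random data with ties
  set.seed(6)
  for (i in 1:10) {
    g <- lapply(1:4, function(j) sample(1:8, sample(3:9, 1), replace = TRUE))
    got <- kruskal_wallis(g)
    ref <- stats::kruskal.test(unlist(g), rep(seq_along(g), lengths(g)))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }
  # invariance under strictly monotone transforms
  g <- list(rnorm(8), rnorm(6, 1), rnorm(7, 2))
  expect_equal(kruskal_wallis(g)$statistic,
               kruskal_wallis(lapply(g, function(v) exp(v)))$statistic)
})

test_that("Conover post hoc separates shifted groups and matches first principles", {
  set.seed(2)
  base <- rnorm(10)
  groups <- list(base, base + rnorm(10, 0, 1e-3), rnorm(10, 0.2), rnorm(10, 10))
  res <- conover_posthoc(groups)
  near_identical <- res[res$group_i == 1 & res$group_j == 2, ]
  expect_gt(near_identical$p_value, 0.9)
  shifted <- res[res$group_i == 4 | res$group_j == 4, ]
  expect_true(all(shifted$p_value < 0.01))

  # first-principles oracle on a seeded 4 x 10 fixture
  set.seed(77)
  g <- lapply(1:4, function(i) rnorm(10, i * 0.3))
  got <- conover_posthoc(g)
  vals <- unlist(g); lab <- rep(1:4, each = 10)
  rk <- rank(vals); n <- 40; k <- 4
  hh <- stats::kruskal.test(vals, lab)$statistic
  s2 <- (sum(rk^2) - n * (n + 1)^2 / 4) / (n - 1)
  for (row in seq_len(nrow(got))) {
    i <- got$group_i[row]; j <- got$group_j[row]
    tij <- (mean(rk[lab == i]) - mean(rk[lab == j])) /
      sqrt(s2 * ((n - 1 - hh) / (n - k)) * (1 / 10 + 1 / 10))
    expect_equal(got$t[row], unname(tij), tolerance = 1e-6)
    expect_equal(got$p_value[row],
                 unname(2 * stats::pt(-abs(tij), n - k)), tolerance = 1e-6)
  }
  # Holm adjustment never lowers a p-value
  gh <- conover_posthoc(g, holm = TRUE)
  expect_true(all(gh$p_value >= got$p_value - 1e-12))
})

test_that("component screening applies the dual effect-size rule", {
  set.seed(3)
  n <- 400
  cl <- rep(c("1", "2"), each = n / 2)
  out <- rep(c("ND", "PD"), times = n / 2)
  # f1: cluster- and outcome-modulated; f2: cluster only; f3: noise
  f1 <- rnorm(n) + (cl == "2") * 1.0 + (out == "ND") * 0.4
  f2 <- rnorm(n) + (cl == "2") * 1.0
  f3 <- rnorm(n)
  fm <- structure(list(
    values = cbind(f1, f2, f3),
    pixels = data.frame(roi_id = "r", x = 1:n, y = 1),
    components = data.frame(component_id = 1:3, center = c(800, 900, 1000))),
    class = "feature_matrix")
  scr <- screen_components(fm, cl, "2", out)
  expect_true(1L %in% scr$selected)
  expect_false(2L %in% scr$selected)
  expect_false(3L %in% scr$selected)
  # monotone in both thresholds: raising never adds a component
  scr_hi <- screen_components(fm, cl, "2", out, d_cluster_min = 0.9,
                              d_outcome_min = 0.3)
  expect_true(all(scr_hi$selected %in% scr$selected))
  expect_error(screen_components(fm, cl, "nope", out), "fewer than 2")
})

test_that("screening recovers planted dual-modulated features at scale", {
  set.seed(9)
  n <- 1000
  cl <- sample(c("1", "2"), n, replace = TRUE, prob = c(0.6, 0.4))
  out <- sample(c("ND", "PD"), n, replace = TRUE)
  n_mod <- 20L; n_null <- 80L
  mk <- function(modulated) {
    if (modulated) rnorm(n) + (cl == "2") * 1.2 + (out == "ND") * 0.6
    else rnorm(n)
  }
  vals <- cbind(sapply(seq_len(n_mod), function(i) mk(TRUE)),
                sapply(seq_len(n_null), function(i) mk(FALSE)))
  fm <- structure(list(
    values = vals, pixels = data.frame(roi_id = "r", x = 1:n, y = 1),
    components = data.frame(component_id = seq_len(n_mod + n_null),
                            center = 600 + seq_len(n_mod + n_null))),
    class = "feature_matrix")
  scr <- screen_components(fm, cl, "2", out)
  expect_gte(sum(scr$selected <= n_mod), 0.8 * n_mod)
  expect_lte(sum(scr$selected > n_mod), 0.1 * n_null)
})

test_that("cluster contribution fractions partition each ROI", {
  labels <- c(rep("1", 3), rep("2", 7), rep("2", 10))
  roi_ids <- rep(c("a", "b"), c(10, 10))
  roi_outcome <- c(a = "ND", b = "PD")
  cc <- cluster_contribution(labels, roi_ids, "2", roi_outcome)
  expect_equal(cc$fractions$fraction[cc$fractions$roi_id == "a"], 0.7)
  expect_equal(cc$fractions$fraction[cc$fractions$roi_id == "b"], 1.0)
  cc1 <- cluster_contribution(labels, roi_ids, "1", roi_outcome)
  expect_equal(cc1$fractions$fraction[cc1$fractions$roi_id == "a"], 0.3)
  # fractions over all clusters sum to 1 per ROI
  tot <- rowSums(vapply(c("1", "2"), function(cl) {
    cluster_contribution(labels, roi_ids, cl, roi_outcome)$fractions$fraction
  }, numeric(2L)))
  expect_equal(tot, c(1, 1))
  # absent cluster -> fraction 0
  cc0 <- cluster_contribution(labels, roi_ids, "9", roi_outcome)
  expect_equal(cc0$fractions$fraction, c(0, 0))
})

test_that("TILs correlation recovers linear dependence", {
  prof <- data.frame(roi_id = sprintf("r%02d", 1:10),
                     n_pixels = 100, k_level1 = 2,
                     simpson_level1 = seq(0.1, 0.9, length.out = 10))
  md <- tiny_metadata(sprintf("p%02d", 1:10))
  md$tils_percent <- 50 * prof$simpson_level1  # exactly linear
  rp <- setNames(sprintf("p%02d", 1:10), prof$roi_id)
  res <- correlate_tils(prof, md, rp, 1L)
  expect_equal(res$r, 1)
  expect_equal(res$slope, 50, tolerance = 1e-9)
  # guard: too few patients with TILs
  md2 <- md; md2$tils_percent[3:10] <- NA
  expect_error(correlate_tils(prof, md2, rp, 1L), "at least 3")

  # stochastic recovery: TILs = 50 D + noise(sd 5), n = 33
  set.seed(10)
  hits <- 0L
  for (i in 1:100) {
    d <- runif(33, 0, 0.9)
    prof_i <- data.frame(roi_id = sprintf("r%02d", 1:33), n_pixels = 100,
                         k_level1 = 2, simpson_level1 = d)
    md_i <- tiny_metadata(sprintf("p%02d", 1:33))
    md_i$tils_percent <- pmin(100, pmax(0, 50 * d + rnorm(33, 0, 5)))
    rp_i <- setNames(sprintf("p%02d", 1:33), prof_i$roi_id)
    if (correlate_tils(prof_i, md_i, rp_i, 1L)$r > 0.6) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("categorical association utility runs a 2x2 Fisher test", {
  md <- read_clinical_table(clinical_fixture_path())
  res <- categorical_association(md$er, md$outcome)
  expect_s3_class(res, "htest")
  expect_true(res$p.value >= 0 && res$p.value <= 1)
})
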