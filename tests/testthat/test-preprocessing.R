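test_that("mass-axis unification interpolates linearly and guards its span", {
  axis <- mass_axis(c(600, 602, 604))
  roi <- tiny_roi(axis = axis,
                  intensities = rbind(c(0, 2, 4), c(1, 1, 1)), p = 2L)
  # identity when already on target
  expect_identical(unify_mass_axis(roi, axis)$intensities, roi$intensities)
  # closed-form midpoint: channels 600 and 602 with 0 and 2 -> 1.0 at 601
  out <- unify_mass_axis(roi, mass_axis(c(600, 601, 604)))
  expect_equal(out$intensities[1L, 2L], 1.0)
  expect_equal(out$intensities[2L, ], c(1, 1, 1))
  expect_error(unify_mass_axis(roi, mass_axis(c(600, 3600))), "beyond")
})

test_that("baseline subtraction removes smooth floors and keeps peaks", {
  cfg <- pipeline_config()
  # constant spectrum is all baseline
  expect_lt(max(abs(subtract_baseline(rep(5, 400), cfg))), 1e-6)
  expect_identical(subtract_baseline(rep(0, 100), cfg), rep(0, 100))
  # Gaussian peak (sigma = 3 channels, amp 100) on offset 10
  spec <- 10 + gauss_peak(seq_len(500), 250, 3, 100)
  out <- subtract_baseline(spec, cfg)
  expect_gte(max(out), 85)
  expect_lte(max(out), 100)
  # the estimated floor never exceeds the signal
  expect_true(all(estimate_baseline(spec, 50L) <= spec + 1e-12))
})

test_that("outlier flagging follows the log-TIC distribution rules", {
  axis <- tiny_axis(20L)
  mk_roi <- function(tics) {
    p <- length(tics)
    side <- ceiling(sqrt(p))
    coords <- cbind((seq_len(p) - 1L) %% side, (seq_len(p) - 1L) %/% side)
    roi_dataset("r1", "p1", coords,
                matrix(tics / 20, p, 20, byrow = FALSE), axis)
  }
  cfg_mad <- pipeline_config(preprocessing = list(outlier_rule = "mad"))
  cfg_gmm <- pipeline_config(preprocessing = list(outlier_rule = "gmm"))
  equal <- mk_roi(rep(1000, 50))
  expect_false(any(detect_outlier_spectra(equal, cfg_mad)))
  expect_false(any(detect_outlier_spectra(equal, cfg_gmm)))
  # 999 pixels at TIC ~1000, one at 10 -> that one flagged (mad); false
  # positives stay at the tail rate of the 3-MAD rule
  set.seed(21)
  tics <- c(rnorm(999, 1000, 10), 10)
  roi <- mk_roi(tics)
  flags <- detect_outlier_spectra(roi, cfg_mad)
  expect_true(flags[1000L])
  expect_lt(mean(flags[-1000L]), 0.01)
  expect_error(detect_outlier_spectra(mk_roi(rep(1, 5)), cfg_mad), "10 pixels")
})

test_that("planted outliers are recovered at the configured rate", {
  cc <- small_cohort_config(n_patients_nd = 1L, n_patients_pd = 1L,
                            roi_pixels = c(400L, 400L),
                            outlier_fraction = 0.05, shift_channels = 0L)
  gen <- generate_cohort(cc)
  cfg <- pipeline_config(preprocessing = list(outlier_rule = "gmm"))
  for (id in names(gen$cohort$rois)) {
    flags <- detect_outlier_spectra(gen$cohort$rois[[id]], cfg)
    truth <- gen$truth$rois[[id]]$outlier
    # planted outliers have gain x 0.01: all caught, few false positives
    expect_true(all(flags[truth]))
    n <- length(truth)
    expect_lt(sum(flags & !truth), 0.02 * n + 3)
  }
})

test_that("alignment recovers planted rigid shifts", {
  set.seed(1)
  cfg <- pipeline_config()
  axis <- mass_axis(seq(600, 700, length.out = 300))
  base <- gauss_peak(axis, 630, 2, 50) + gauss_peak(axis, 670, 3, 80)
  p <- 40L
  coords <- cbind((seq_len(p) - 1L) %% 7L, (seq_len(p) - 1L) %/% 7L)
  intens <- matrix(rep(base, each = p), p)
  roi <- roi_dataset("r1", "p1", coords, intens, axis)
  al <- align_peaks(roi, cfg)
  expect_true(all(al$shifts == 0L))  # already aligned

  planted <- sample(-3:3, p, replace = TRUE)
  planted[1L] <- 0L  # keep the consensus anchored
  shifted <- t(vapply(seq_len(p), function(i) {
    s <- planted[i]
    out <- numeric(length(base))
    if (s >= 0) out[(s + 1):length(base)] <- base[1:(length(base) - s)]
    else out[1:(length(base) + s)] <- base[(1 - s):length(base)]
    out
  }, numeric(length(base))))
  roi2 <- roi_dataset("r1", "p1", coords, shifted, axis)
  al2 <- align_peaks(roi2, cfg)
  # planted +s must be undone by applied shift -s; >= 95% exact
  expect_gte(mean(al2$shifts == -planted), 0.95)
  # single spectrum worked example: planted +2 -> recovered -2
  expect_equal(al2$shifts[planted == 2L][1L], -2L)
})

test_that("TIC normalization hits the target and is idempotent", {
  axis <- tiny_axis(10L)
  coords <- cbind(0:2, rep(0L, 3))
  intens <- rbind(rep(5, 10), rep(10, 10), rep(20, 10))  # TICs 50/100/200
  roi <- roi_dataset("r1", "p1", coords, intens, axis)
  cfg <- pipeline_config()
  out <- normalize_tic(roi, cfg)
  expect_equal(rowSums(out$intensities), rep(100, 3))
  # idempotent
  out2 <- normalize_tic(out, cfg)
  expect_equal(out2$intensities, out$intensities)
  # relative proportions unchanged
  expect_equal(out$intensities[3L, ] / sum(out$intensities[3L, ]),
               intens[3L, ] / sum(intens[3L, ]))
  bad <- roi_dataset("r1", "p1", coords,
                     rbind(rep(5, 10), rep(0, 10), rep(20, 10)), axis)
  expect_error(normalize_tic(bad, cfg), "zero TIC")
})

test_that("mean spectrum equals the brute-force average", {
  cc <- small_cohort_config(n_patients_nd = 1L, n_patients_pd = 1L,
                            roi_pixels = c(50L, 50L), outlier_fraction = 0)
  gen <- generate_cohort(cc)
  ms <- mean_spectrum(gen$cohort)
  all_rows <- do.call(rbind, lapply(gen$cohort$rois, function(r) r$intensities))
  expect_equal(ms, colSums(all_rows) / nrow(all_rows), tolerance = 1e-12)
  single <- gen$cohort
  single$rois <- single$rois[1L]
  one <- single$rois[[1L]]$intensities[1L, , drop = FALSE]
  single$rois[[1L]]$intensities <- one
  single$rois[[1L]]$coordinates <- single$rois[[1L]]$coordinates[1L, , drop = FALSE]
  expect_equal(mean_spectrum(single), as.numeric(one))
})

test_that("full chain balances QC accounting and kills planted gain", {
  cc <- small_cohort_config(n_patients_nd = 2L, n_patients_pd = 2L,
                            roi_pixels = c(100L, 120L), tic_cv = 0.3,
                            outlier_fraction = 0.02)
  gen <- generate_cohort(cc)
  pp <- preprocess_cohort(gen$cohort, pipeline_config(seed = 5L))
  expect_equal(pp$qc$n_retained, pp$qc$n_input - pp$qc$n_flagged)
  expect_true(all(pp$qc$max_abs_shift <= 5L))
  # post-normalization TIC CV across unflagged pixels <= 1%
  for (id in names(pp$cohort$rois)) {
    tics <- rowSums(pp$cohort$rois[[id]]$intensities)[!pp$flags[[id]]]
    expect_lt(stats::sd(tics) / mean(tics), 0.01)
  }
})
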