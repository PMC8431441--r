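#' Interpolate an ROI onto a target mass axis
#'
#' Mass-channel unification: every pixel spectrum is linearly interpolated
#' onto `target`. Interpolation is strictly within the source span; no
#' extrapolation is attempted.
#'
#' @param roi A [roi_dataset()].
#' @param target A [mass_axis()] contained in the span of `roi$axis`.
#' @return The ROI resampled onto `target` (unchanged if axes are identical).
#' @export
unify_mass_axis <- function(roi, target) {
  target <- if (inherits(target, "mass_axis")) target else mass_axis(target)
  src <- as.numeric(roi$axis)
  if (length(src) == length(target) && all(src == as.numeric(target))) {
    return(roi)
  }
  if (min(target) < src[1L] || max(target) > src[length(src)]) {
    stop("target axis extends beyond the source axis; refusing to extrapolate")
  }
  j <- findInterval(as.numeric(target), src, rightmost.closed = TRUE)
  j <- pmin(pmax(j, 1L), length(src) - 1L)
  w <- (as.numeric(target) - src[j]) / (src[j + 1L] - src[j])
  newI <- roi$intensities[, j, drop = FALSE] * rep(1 - w, each = nrow(roi$intensities)) +
    roi$intensities[, j + 1L, drop = FALSE] * rep(w, each = nrow(roi$intensities))
  newI[newI < 0] <- 0
  roi$intensities <- newI
  roi$axis <- target
  roi
}

#' Subtract a smooth baseline from one spectrum
#'
#' SNIP-style iterative clipping: for window sizes m = 1..`baseline_window`
#' the spectrum is replaced pointwise by min(y\[i\], (y\[i-m\] + y\[i+m\])/2),
#' which converges to a smooth floor lying at or below the signal at
#' peak-free channels. The output is max(0, input - baseline).
#'
#' @param spectrum Nonnegative numeric vector.
#' @param config A [pipeline_config()] (uses `preprocessing$baseline_window`).
#' @return Baseline-subtracted spectrum; an all-zero input is returned
#'   unchanged.
#' @export
subtract_baseline <- function(spectrum, config = pipeline_config()) {
  if (all(spectrum == 0)) return(spectrum)
  base <- estimate_baseline(spectrum, config$preprocessing$baseline_window)
  out <- spectrum - base
  out[out < 0] <- 0
  out
}

#' Estimate the smooth baseline of one spectrum
#' @param spectrum Nonnegative numeric vector.
#' @param window Maximum clipping half-window in channels.
#' @return The estimated baseline (<= spectrum pointwise).
#' @export
estimate_baseline <- function(spectrum, window = 50L) {
  n <- length(spectrum)
  y <- spectrum
  window <- min(window, n - 1L)
  for (m in seq_len(window)) {
    left <- c(rep(y[1L], m), y[seq_len(n - m)])
    right <- c(y[(m + 1L):n], rep(y[n], m))
    avg <- (left + right) / 2
    y <- pmin(y, avg)
  }
  y
}

# Univariate Gaussian mixture by EM with quantile-based deterministic
# initialization; model order chosen by BIC over k = 1..k_max. Shared by
# outlier detection and DivIK feature filtering.
fit_gmm1d <- function(x, k_max = 3L, max_iter = 200L, tol = 1e-8) {
  x <- as.numeric(x)
  n <- length(x)
  if (stats::sd(x) == 0 || n < 3L) {
    return(list(k = 1L, mean = mean(x), sd = max(stats::sd(x), 0),
                weight = 1, assignment = rep(1L, n), bic = NA_real_))
  }
  best <- NULL
  for (k in seq_len(min(k_max, n - 1L))) {
    qs <- stats::quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
    mu <- qs
    sd0 <- rep(stats::sd(x) / k, k)
    sd0[sd0 <= 0] <- 1e-6
    w <- rep(1 / k, k)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      dens <- vapply(seq_len(k), function(j) {
        w[j] * stats::dnorm(x, mu[j], sd0[j])
      }, numeric(n))
      dens <- matrix(dens, n, k)
      tot <- rowSums(dens)
      tot[tot == 0] <- .Machine$double.xmin
      ll <- sum(log(tot))
      r <- dens / tot
      nk <- colSums(r)
      if (any(nk < 1e-8)) break
      w <- nk / n
      mu <- colSums(r * x) / nk
      sd0 <- sqrt(colSums(r * (x - rep(mu, each = n))^2) / nk)
      sd0[sd0 < 1e-6] <- 1e-6
      if (abs(ll - ll_old) < tol * (1 + abs(ll))) break
      ll_old <- ll
    }
    bic <- -2 * ll + (3 * k - 1) * log(n)
    if (is.null(best) || bic < best$bic) {
      dens <- vapply(seq_len(k), function(j) {
        w[j] * stats::dnorm(x, mu[j], sd0[j])
      }, numeric(n))
      dens <- matrix(dens, n, k)
      best <- list(k = k, mean = mu, sd = sd0, weight = w,
                   assignment = max.col(dens, ties.method = "first"),
                   bic = bic)
    }
  }
  best
}

#' Flag outlying spectra of an ROI
#'
#' Outliers (off-tissue pixels, failed ablations) are detected from the
#' distribution of log total ion current. The `mad` rule flags
#' |log TIC - median| > `mad_k` x 1.4826 x MAD. The `gmm` rule fits a 1--3
#' component univariate Gaussian mixture to log TIC (BIC model choice) and
#' flags pixels assigned to any component whose mean lies below the dominant
#' (largest-weight) component's mean by more than that dominant component's
#' standard deviation.
#'
#' @param roi A [roi_dataset()] with at least 10 pixels.
#' @param config A [pipeline_config()] (uses `preprocessing$outlier_rule`,
#'   `preprocessing$mad_k`).
#' @return Logical vector, `TRUE` = flagged; flagged pixels are excluded
#'   from all downstream stages but kept in the QC accounting.
#' @export
detect_outlier_spectra <- function(roi, config = pipeline_config()) {
  p <- nrow(roi$intensities)
  if (p < 10L) {
    stop("fewer than 10 pixels: fit the outlier rule on the full cohort with the mad rule")
  }
  tic <- rowSums(roi$intensities)
  ltic <- log(pmax(tic, .Machine$double.xmin))
  rule <- config$preprocessing$outlier_rule
  if (stats::sd(ltic) == 0) return(rep(FALSE, p))
  if (rule == "mad") {
    med <- stats::median(ltic)
    madv <- stats::mad(ltic, constant = 1)
    if (madv == 0) {
      # degenerate spread: fall back on plain deviation from the median
      return(abs(ltic - med) > 0)
    }
    return(abs(ltic - med) > config$preprocessing$mad_k * 1.4826 * madv)
  }
  fit <- fit_gmm1d(ltic, k_max = 3L)
  if (fit$k == 1L) return(rep(FALSE, p))
  dom <- which.max(fit$weight)
  low <- which(fit$mean < fit$mean[dom] - fit$sd[dom])
  fit$assignment %in% low
}

.shift_vector <- function(v, s) {
  n <- length(v)
  if (s == 0L) return(v)
  out <- numeric(n)
  if (s > 0L) out[(s + 1L):n] <- v[1L:(n - s)]
  else out[1L:(n + s)] <- v[(1L - s):n]
  out
}

#' Align pixel spectra to the ROI mean by rigid channel shift
#'
#' MALDI-ToF miscalibration across a slide is predominantly a small rigid
#' m/z shift, so alignment is a per-spectrum integer channel offset (at most
#' `alignment_max_shift`) chosen to maximize the cross-correlation with the
#' reference (the mean spectrum of unflagged pixels). Edges are zero-padded;
#' ties prefer the smaller |shift|.
#'
#' @param roi A [roi_dataset()].
#' @param config A [pipeline_config()].
#' @param flags Optional logical outlier flags (flagged pixels do not enter
#'   the reference but are still shifted).
#' @return List with `roi` (aligned) and `shifts` (integer per pixel).
#' @export
align_peaks <- function(roi, config = pipeline_config(), flags = NULL) {
  max_shift <- config$preprocessing$alignment_max_shift
  p <- nrow(roi$intensities)
  if (is.null(flags)) flags <- rep(FALSE, p)
  ref_rows <- roi$intensities[!flags, , drop = FALSE]
  if (nrow(ref_rows) == 0L) ref_rows <- roi$intensities
  ref <- colMeans(ref_rows)
  shifts <- integer(p)
  if (max_shift > 0L && any(ref != 0)) {
    offsets <- seq(-max_shift, max_shift)
    # score each candidate applied shift a: sum_i spec[i - a] * ref[i]
    for (i in seq_len(p)) {
      spec <- roi$intensities[i, ]
      if (all(spec == 0)) next
      scores <- vapply(offsets, function(a) sum(.shift_vector(spec, a) * ref),
                       numeric(1L))
      best <- max(scores)
      cand <- offsets[scores >= best - 1e-9 * abs(best)]
      shifts[i] <- cand[which.min(abs(cand))]
      if (shifts[i] != 0L) {
        roi$intensities[i, ] <- .shift_vector(spec, shifts[i])
      }
    }
  }
  list(roi = roi, shifts = shifts)
}

#' Normalize spectra to a common total ion current
#'
#' Each unflagged spectrum is rescaled so its TIC equals the target: the
#' median TIC of the unflagged spectra (`"dataset_median"`, supplied
#' cohort-wide through `target`) or 1 (`"unity"`). Relative channel
#' proportions are untouched.
#'
#' @param roi A [roi_dataset()].
#' @param config A [pipeline_config()].
#' @param flags Optional logical outlier flags; flagged pixels are left as-is.
#' @param target Optional numeric target TIC overriding the config rule
#'   (used to apply one cohort-wide median to every ROI).
#' @return The normalized ROI.
#' @export
normalize_tic <- function(roi, config = pipeline_config(), flags = NULL,
                          target = NULL) {
  p <- nrow(roi$intensities)
  if (is.null(flags)) flags <- rep(FALSE, p)
  tic <- rowSums(roi$intensities)
  zero <- which(!flags & tic == 0)
  if (length(zero) > 0L) {
    stop(sprintf("pixel %d of ROI '%s' has zero TIC but is not flagged",
                 zero[1L], roi$roi_id))
  }
  if (is.null(target)) {
    target <- switch(config$preprocessing$tic_target,
                     unity = 1,
                     dataset_median = stats::median(tic[!flags]))
  }
  idx <- which(!flags)
  roi$intensities[idx, ] <- roi$intensities[idx, , drop = FALSE] * (target / tic[idx])
  roi
}

#' Cohort mean spectrum over unflagged pixels
#'
#' @param cohort A [cohort_dataset()] (typically preprocessed).
#' @param flags Optional named list of per-ROI logical flag vectors.
#' @return Channel-wise arithmetic mean intensity vector.
#' @export
mean_spectrum <- function(cohort, flags = NULL) {
  total <- numeric(length(cohort$axis))
  n <- 0L
  for (roi in cohort$rois) {
    f <- if (is.null(flags)) rep(FALSE, nrow(roi$intensities)) else flags[[roi$roi_id]]
    keep <- roi$intensities[!f, , drop = FALSE]
    if (nrow(keep) > 0L) {
      total <- total + colSums(keep)
      n <- n + nrow(keep)
    }
  }
  if (n == 0L) stop("no unflagged pixels in cohort")
  total / n
}

#' Run the full preprocessing chain on a cohort
#'
#' Fixed stage order: mass-axis unification, baseline subtraction, outlier
#' flagging, peak alignment, TIC normalization. Outliers are flagged before
#' alignment so they cannot distort the alignment reference; one
#' cohort-median TIC target is applied to every ROI.
#'
#' @param cohort A [cohort_dataset()].
#' @param config A [pipeline_config()].
#' @param target_axis Optional [mass_axis()]; default keeps the cohort axis.
#' @return Object of class `processed_cohort`: list with `cohort`
#'   (preprocessed), `flags` (named list of logical vectors), `shifts`
#'   (named list of integer vectors) and `qc` (per-ROI accounting data
#'   frame).
#' @export
preprocess_cohort <- function(cohort, config = pipeline_config(),
                              target_axis = NULL) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  rois <- cohort$rois
  if (!is.null(target_axis)) {
    rois <- lapply(rois, unify_mass_axis, target = target_axis)
  }
  rois <- lapply(rois, function(roi) {
    roi$intensities <- t(apply(roi$intensities, 1L, subtract_baseline,
                               config = config))
    roi
  })
  flags <- lapply(rois, detect_outlier_spectra, config = config)
  shifts <- vector("list", length(rois))
  names(shifts) <- names(rois)
  for (id in names(rois)) {
    al <- align_peaks(rois[[id]], config, flags[[id]])
    rois[[id]] <- al$roi
    shifts[[id]] <- al$shifts
  }
  tics <- unlist(lapply(names(rois), function(id) {
    rowSums(rois[[id]]$intensities)[!flags[[id]]]
  }))
  target <- switch(config$preprocessing$tic_target,
                   unity = 1, dataset_median = stats::median(tics))
  pre_tic_median <- vapply(names(rois), function(id) {
    stats::median(rowSums(rois[[id]]$intensities)[!flags[[id]]])
  }, numeric(1L))
  rois <- lapply(names(rois), function(id) {
    normalize_tic(rois[[id]], config, flags[[id]], target = target)
  })
  names(rois) <- vapply(rois, function(r) r$roi_id, character(1L))
  qc <- data.frame(
    roi_id = names(rois),
    n_input = vapply(rois, function(r) nrow(r$intensities), integer(1L)),
    n_flagged = vapply(flags, sum, integer(1L)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  qc$n_retained <- qc$n_input - qc$n_flagged
  qc$tic_pre_median <- unname(pre_tic_median)
  qc$tic_post_target <- target
  qc$max_abs_shift <- vapply(shifts, function(s) as.integer(max(abs(s))), integer(1L))
  out <- cohort
  out$rois <- rois
  structure(list(cohort = out, flags = flags, shifts = shifts, qc = qc),
            class = "processed_cohort")
}

#' @export
print.processed_cohort <- function(x, ...) {
  cat(sprintf("<processed_cohort> %d ROIs, %d/%d pixels retained\n",
              nrow(x$qc), sum(x$qc$n_retained), sum(x$qc$n_input)))
  invisible(x)
}
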