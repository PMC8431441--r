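#' Split a mean spectrum into independent fragments at signal valleys
#'
#' Divide-and-conquer device for tractable mixture fitting: the axis is cut
#' wherever the mean intensity drops below `min_valley_rel` x max(mean), and
#' each maximal run of above-threshold channels becomes one fragment that is
#' fitted independently.
#'
#' @param mean_spec Nonnegative mean-spectrum intensity vector.
#' @param min_valley_rel Valley threshold relative to the spectrum maximum.
#' @return List of integer channel-index vectors (possibly empty).
#' @export
segment_spectrum <- function(mean_spec, min_valley_rel = 0.01) {
  if (all(mean_spec <= 0)) return(list())
  thr <- min_valley_rel * max(mean_spec)
  above <- mean_spec >= thr & mean_spec > 0
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  lapply(which(r$values), function(i) starts[i]:ends[i])
}

# Smoothed local maxima of a fragment profile, ordered by height.
.local_maxima <- function(w) {
  n <- length(w)
  if (n < 3L) return(which.max(w))
  sm <- (c(w[1L], w[-n]) + w + c(w[-1L], w[n])) / 3
  i <- 2L:(n - 1L)
  idx <- i[sm[i] > sm[i - 1L] & sm[i] >= sm[i + 1L]]
  if (length(idx) == 0L) idx <- which.max(w)
  idx[order(w[idx], decreasing = TRUE)]
}

# Weighted univariate EM: treats channel intensities as unnormalized mass
# over m/z. Initial means come from the fragment's local maxima (filled
# from weighted quantiles when k exceeds the maxima count); seeded jittered
# restarts guard against poor starts.
.weighted_gmm_em <- function(x, w, k, max_iter = 200L, tol = 1e-8,
                             restarts = 2L, seed = 1L, sigma_floor = 1e-6,
                             init_means = NULL) {
  W <- sum(w)
  cw <- cumsum(w) / W
  best <- NULL
  for (r0 in seq_len(max(1L, restarts)) - 1L) {
    if (is.null(init_means)) {
      probs <- (seq_len(k) - 0.5) / k
      mu <- vapply(probs, function(p) x[which.min(abs(cw - p))], numeric(1L))
    } else {
      mu <- init_means
      if (length(mu) < k) {
        probs <- (seq_len(k - length(mu)) - 0.5) / (k - length(mu))
        mu <- c(mu, vapply(probs, function(p) x[which.min(abs(cw - p))],
                           numeric(1L)))
      }
      mu <- sort(mu[seq_len(k)])
    }
    if (r0 > 0L) {
      set.seed(derive_seed(seed, paste0("em-restart-", r0)))
      span <- diff(range(x))
      mu <- mu + stats::rnorm(k, sd = 0.05 * span / k)
    }
    sig <- rep(max(sqrt(sum(w * (x - sum(w * x) / W)^2) / W) / k, sigma_floor), k)
    pi_k <- rep(1 / k, k)
    ll_old <- -Inf
    ll <- -Inf
    for (it in seq_len(max_iter)) {
      dens <- vapply(seq_len(k), function(j) {
        pi_k[j] * stats::dnorm(x, mu[j], sig[j])
      }, numeric(length(x)))
      dens <- matrix(dens, length(x), k)
      tot <- rowSums(dens)
      tot[tot == 0] <- .Machine$double.xmin
      ll <- sum(w * log(tot))
      resp <- dens / tot
      nk <- colSums(w * resp)
      if (any(nk < 1e-12 * W)) { ll <- -Inf; break }
      pi_k <- nk / W
      mu <- colSums(w * resp * x) / nk
      sig <- sqrt(colSums(w * resp * (x - rep(mu, each = length(x)))^2) / nk)
      sig[sig < sigma_floor] <- sigma_floor
      if (abs(ll - ll_old) < tol * (1 + abs(ll))) break
      ll_old <- ll
    }
    if (is.finite(ll) && (is.null(best) || ll > best$ll)) {
      best <- list(mu = mu, sigma = sig, pi = pi_k, ll = ll)
    }
  }
  best
}

#' Decompose the mean spectrum into Gaussian spectral components
#'
#' The cohort mean spectrum is treated as an unnormalized 1-D density over
#' m/z and fitted fragment-by-fragment (see [segment_spectrum()]) with
#' weighted-EM Gaussian mixtures. The per-fragment component count is chosen
#' by a BIC scan up to `max_components_per_fragment`; components below an
#' amplitude floor are discarded and near-coincident neighbours (center gap
#' under `merge_sigma` x the smaller width) are merged by moment matching.
#' Each component defines one feature of the downstream analysis.
#'
#' @param mean_spec Preprocessed mean-spectrum intensity vector.
#' @param axis The [mass_axis()] the spectrum lives on.
#' @param config A [pipeline_config()] (block `components`).
#' @param seed Seed for the (deterministic, restart-jitter) EM.
#' @return Data frame of class `spectral_components` with columns
#'   `component_id`, `center`, `sigma`, `amplitude`, `channel_lo`,
#'   `channel_hi` (half-open range covering center +- 3 sigma), sorted by
#'   center.
#' @export
fit_gmm_components <- function(mean_spec, axis, config = pipeline_config(),
                               seed = config$seed) {
  p <- config$components
  axis <- as.numeric(axis)
  spacing <- stats::median(diff(axis))
  frags <- segment_spectrum(mean_spec, p$min_valley_rel)
  comps <- list()
  for (fi in seq_along(frags)) {
    idx <- frags[[fi]]
    x <- axis[idx]
    w <- mean_spec[idx]
    if (length(idx) < 3L || sum(w) <= 0) next
    W <- sum(w)
    k_cap <- min(p$max_components_per_fragment,
                 max(1L, floor(length(idx) / 3)))
    # start from the fragment's local maxima, then grow the mixture by
    # residual-driven insertion: overlapping peaks hide behind one apex, so
    # new components are proposed where the model underestimates the signal
    # most, and kept while BIC improves
    maxima <- .local_maxima(w)
    k_guess <- min(length(maxima), k_cap)
    frag_seed <- derive_seed(seed, paste0("frag-", fi))
    em_k <- function(k, init) {
      fit <- .weighted_gmm_em(x, w, k, max_iter = p$em_max_iter,
                              tol = p$em_tol, restarts = p$em_restarts,
                              seed = frag_seed, sigma_floor = spacing / 2,
                              init_means = init)
      if (!is.null(fit)) fit$bic <- -2 * fit$ll + (3 * k - 1) * log(W)
      fit
    }
    best <- em_k(k_guess, sort(x[maxima[seq_len(k_guess)]]))
    if (!is.null(best)) {
      best$k <- k_guess
      while (best$k < k_cap) {
        pred <- W * rowSums(vapply(seq_len(best$k), function(j) {
          best$pi[j] * stats::dnorm(x, best$mu[j], best$sigma[j])
        }, numeric(length(x))))
        resid <- w - pred
        if (max(resid) <= 0) break
        cand <- em_k(best$k + 1L, sort(c(best$mu, x[which.max(resid)])))
        if (is.null(cand) || cand$bic >= best$bic) break
        cand$k <- best$k + 1L
        best <- cand
      }
    }
    if (is.null(best)) {
      # moment-fit fallback for a fragment EM could not handle
      mu <- sum(w * x) / W
      sg <- max(sqrt(sum(w * (x - mu)^2) / W), spacing / 2)
      warning(sprintf("fragment %d: EM failed, single-Gaussian moment fit", fi))
      best <- list(mu = mu, sigma = sg, pi = 1, k = 1L)
    }
    comps[[length(comps) + 1L]] <- data.frame(
      center = best$mu, sigma = best$sigma, amplitude = best$pi * W)
  }
  if (length(comps) == 0L) {
    out <- data.frame(component_id = integer(0), center = numeric(0),
                      sigma = numeric(0), amplitude = numeric(0),
                      channel_lo = integer(0), channel_hi = integer(0))
    class(out) <- c("spectral_components", "data.frame")
    return(out)
  }
  df <- do.call(rbind, comps)
  df <- df[order(df$center), , drop = FALSE]
  # merge near-coincident neighbours by moment matching
  if (nrow(df) > 1L && p$merge_sigma > 0) {
    keep <- list()
    cur <- df[1L, ]
    for (i in 2L:nrow(df)) {
      nxt <- df[i, ]
      if (abs(nxt$center - cur$center) < p$merge_sigma * min(cur$sigma, nxt$sigma)) {
        a <- cur$amplitude + nxt$amplitude
        m <- (cur$amplitude * cur$center + nxt$amplitude * nxt$center) / a
        v <- (cur$amplitude * (cur$sigma^2 + (cur$center - m)^2) +
                nxt$amplitude * (nxt$sigma^2 + (nxt$center - m)^2)) / a
        cur <- data.frame(center = m, sigma = sqrt(v), amplitude = a)
      } else {
        keep[[length(keep) + 1L]] <- cur
        cur <- nxt
      }
    }
    keep[[length(keep) + 1L]] <- cur
    df <- do.call(rbind, keep)
  }
  df <- df[df$amplitude >= p$amplitude_floor_rel * max(df$amplitude), ,
           drop = FALSE]
  df$channel_lo <- pmax(findInterval(df$center - 3 * df$sigma, axis) + 1L, 1L)
  df$channel_hi <- pmin(findInterval(df$center + 3 * df$sigma, axis) + 1L,
                        length(axis) + 1L)
  bad <- df$channel_hi <= df$channel_lo
  df <- df[!bad, , drop = FALSE]
  df$component_id <- seq_len(nrow(df))
  rownames(df) <- NULL
  df <- df[, c("component_id", "center", "sigma", "amplitude",
               "channel_lo", "channel_hi")]
  class(df) <- c("spectral_components", "data.frame")
  df
}

# Channel weight matrix (J x C): per-channel responsibilities of each
# component, zero outside its channel range; columns sum to <= 1.
.component_weights <- function(components, axis) {
  axis <- as.numeric(axis)
  J <- nrow(components)
  C <- length(axis)
  Wm <- matrix(0, J, C)
  for (j in seq_len(J)) {
    rng <- components$channel_lo[j]:(components$channel_hi[j] - 1L)
    Wm[j, rng] <- components$amplitude[j] *
      stats::dnorm(axis[rng], components$center[j], components$sigma[j])
  }
  denom <- colSums(Wm)
  pos <- denom > 0
  Wm[, pos] <- Wm[, pos, drop = FALSE] / rep(denom[pos], each = J)
  Wm
}

#' Convert pixel spectra into component abundances
#'
#' Abundance(pixel, component) = sum over the component's channel range of
#' intensity x the component's normalized Gaussian weight at that channel.
#' Weights of overlapping components are renormalized channel-wise so they
#' sum to at most 1; a pixel's total abundance therefore never exceeds its
#' TIC.
#'
#' @param cohort A preprocessed [cohort_dataset()] or `processed_cohort`.
#' @param components A `spectral_components` table from
#'   [fit_gmm_components()].
#' @param flags Optional named list of per-ROI outlier flags (taken from a
#'   `processed_cohort` automatically).
#' @return Object of class `feature_matrix`: list with `values` (pixels x
#'   components), `pixels` (data frame roi_id/x/y) and `components`.
#' @export
compute_feature_matrix <- function(cohort, components, flags = NULL) {
  if (inherits(cohort, "processed_cohort")) {
    flags <- cohort$flags
    cohort <- cohort$cohort
  }
  stopifnot(inherits(cohort, "cohort_dataset"))
  if (nrow(components) == 0L) stop("component list is empty")
  if (max(components$channel_hi) > length(cohort$axis) + 1L ||
      min(components$channel_lo) < 1L) {
    stop("component channel range lies outside the mass axis")
  }
  Wt <- t(.component_weights(components, cohort$axis))
  vals <- list()
  pix <- list()
  for (roi in cohort$rois) {
    f <- if (is.null(flags)) rep(FALSE, nrow(roi$intensities)) else flags[[roi$roi_id]]
    keep <- which(!f)
    if (length(keep) == 0L) next
    vals[[roi$roi_id]] <- roi$intensities[keep, , drop = FALSE] %*% Wt
    pix[[roi$roi_id]] <- data.frame(
      roi_id = roi$roi_id,
      x = roi$coordinates[keep, "x"],
      y = roi$coordinates[keep, "y"],
      stringsAsFactors = FALSE
    )
  }
  values <- do.call(rbind, vals)
  values[values < 0] <- 0
  dimnames(values) <- NULL
  structure(
    list(values = values,
         pixels = do.call(rbind, c(pix, list(make.row.names = FALSE))),
         components = components),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d pixels x %d components (%d ROIs)\n",
              nrow(x$values), ncol(x$values), length(unique(x$pixels$roi_id))))
  invisible(x)
}
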