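#' Configuration for the synthetic MSI cohort generator
#'
#' The generator emulates the data regime of peptide MALDI-MSI of cancer
#' tissue: tens of ROIs of hundreds to thousands of pixels, spectra built
#' from hundreds of Gaussian peptide peaks on an m/z 600--3500 axis,
#' contiguous planted sub-regions with distinct component-abundance
#' profiles, group-dependent numbers of sub-regions (more sub-regions in the
#' better-outcome ND group than in PD), multiplicative per-pixel TIC
#' variation, a smooth additive baseline, additive noise, a small fraction
#' of near-empty outlier spectra, and small rigid per-pixel mass shifts.
#'
#' Most spectra remain highly similar across regions: only a subset
#' (`modulated_fraction`) of peaks is region-modulated on top of a shared
#' core profile, reproducing the low-heterogeneity regime of real cancer
#' tissue (median pairwise similarity near 0.98).
#'
#' @param n_patients_nd,n_patients_pd Patients (one ROI each) per outcome group.
#' @param roi_pixels Length-2 range for pixels per ROI.
#' @param mz_min,mz_max,n_channels The shared mass axis.
#' @param n_peptide_peaks Number of true Gaussian peptide peaks.
#' @param regions_nd,regions_pd Integer vectors; the number of planted
#'   sub-regions of each ROI is drawn uniformly from the group's vector.
#' @param region_geometry `"voronoi"` (contiguous patches) or `"blobs"`.
#' @param modulated_fraction Fraction of peaks that differ between regions.
#' @param profile_effect Mean |log2| abundance shift of region-modulated peaks.
#' @param tic_cv Coefficient of variation of the per-pixel multiplicative gain.
#' @param baseline_amp Amplitude of the smooth additive baseline.
#' @param noise_sd Additive Gaussian noise scale (intensity units).
#' @param outlier_fraction Fraction of pixels whose gain is multiplied by 0.01.
#' @param shift_channels Maximum planted per-pixel rigid mass shift (channels).
#' @param sigma_rel Peak width: sigma = `sigma_rel` * center (Da), a constant
#'   relative resolution; the default resolves on the default 6000-channel
#'   axis (peak width must exceed two channel spacings).
#' @param seed Integer seed; identical config + seed gives identical cohorts.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_patients_nd = 20L, n_patients_pd = 20L,
                          roi_pixels = c(900L, 2500L),
                          mz_min = 600, mz_max = 3500, n_channels = 6000L,
                          n_peptide_peaks = 300L,
                          regions_nd = 4:7, regions_pd = 2:3,
                          region_geometry = c("voronoi", "blobs"),
                          modulated_fraction = 0.3,
                          profile_effect = 1.0,
                          tic_cv = 0.15,
                          baseline_amp = 1.0,
                          noise_sd = 0.5,
                          outlier_fraction = 0.005,
                          shift_channels = 1L,
                          sigma_rel = 2e-3,
                          seed = 1L) {
  region_geometry <- match.arg(region_geometry)
  stopifnot(n_patients_nd >= 1L, n_patients_pd >= 1L,
            length(roi_pixels) == 2L, roi_pixels[1L] >= 1L,
            roi_pixels[2L] >= roi_pixels[1L],
            n_channels >= 2L, n_peptide_peaks >= 1L,
            all(regions_nd >= 1L), all(regions_pd >= 1L),
            modulated_fraction >= 0, modulated_fraction <= 1,
            profile_effect >= 0, tic_cv >= 0, baseline_amp >= 0,
            noise_sd >= 0, outlier_fraction >= 0, outlier_fraction <= 1,
            shift_channels >= 0L, sigma_rel > 0)
  structure(as.list(environment()), class = "cohort_config")
}

.voronoi_labels <- function(coords, n_regions) {
  n <- nrow(coords)
  k <- min(n_regions, n)
  seeds <- coords[sample.int(n, k), , drop = FALSE]
  d <- outer(coords[, 1L], seeds[, 1L], "-")^2 +
    outer(coords[, 2L], seeds[, 2L], "-")^2
  max.col(-d, ties.method = "first")
}

.blob_labels <- function(coords, n_regions) {
  n <- nrow(coords)
  k <- min(n_regions, n)
  seeds <- coords[sample.int(n, k), , drop = FALSE]
  # jittered nearest-seed assignment gives ragged, blob-like patches
  d <- sqrt(outer(coords[, 1L], seeds[, 1L], "-")^2 +
              outer(coords[, 2L], seeds[, 2L], "-")^2)
  d <- d * matrix(exp(stats::rnorm(n * k, sd = 0.25)), n, k)
  max.col(-d, ties.method = "first")
}

#' Generate a synthetic MSI cohort with planted ground truth
#'
#' Spectra are built as sum over peaks of amplitude x Gaussian(center, width)
#' evaluated on the axis; amplitudes come from the pixel's region profile,
#' the sum is scaled by a per-pixel multiplicative gain, shifted rigidly by a
#' planted channel offset, then a smooth baseline and additive noise are
#' applied and the result is clipped at zero. The returned truth object is
#' aligned index-for-index with the cohort's canonical pixel order.
#'
#' @param config A [cohort_config()].
#' @return List with `cohort` (a [cohort_dataset()]) and `truth` (class
#'   `synthetic_truth`): per-ROI region label maps, per-region peak profiles,
#'   true peak centers/sigmas, per-pixel gain/shift/outlier flags, and the
#'   peak-linked peptide rows used by [generate_peptide_library()].
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  axis <- seq(config$mz_min, config$mz_max, length.out = config$n_channels)
  spacing <- axis[2L] - axis[1L]

  set.seed(derive_seed(config$seed, "peaks"))
  # keep full +-4 sigma footprints inside the axis so no peak mass is clipped
  margin <- 4 * config$sigma_rel * config$mz_max
  centers <- sort(stats::runif(config$n_peptide_peaks,
                               config$mz_min + margin, config$mz_max - margin))
  sigmas <- config$sigma_rel * centers
  if (any(sigmas < 2 * spacing)) {
    stop(sprintf(
      "axis too coarse: peak width %.3g Da < 2 channel spacings (%.3g Da); increase n_channels",
      min(sigmas), spacing))
  }
  # core (shared) log-normal abundance profile; heavier peaks weaker
  core_amp <- exp(stats::rnorm(config$n_peptide_peaks, mean = 3, sd = 0.8)) *
    (600 / centers)^0.5
  n_mod <- round(config$modulated_fraction * config$n_peptide_peaks)
  modulated <- sort(sample.int(config$n_peptide_peaks, n_mod))

  # cohort-level pool of region profiles: pooled segmentation sees global
  # molecular populations, of which each ROI contains a subset. Each pool
  # region modulates its own disjoint block of the modulated peaks by
  # +-profile_effect in log2, so every pair of regions is separated by the
  # same planted effect (iid random shifts can create near-duplicate
  # regions by chance, which would make the planted truth ill-defined).
  set.seed(derive_seed(config$seed, "region-pool"))
  pool_size <- max(config$regions_nd, config$regions_pd)
  pool_profiles <- matrix(rep(core_amp, pool_size), nrow = pool_size,
                          byrow = TRUE)
  if (n_mod > 0L && pool_size > 1L) {
    block <- rep(seq_len(pool_size), length.out = n_mod)  # round-robin blocks
    signs <- sample(c(-1, 1), n_mod, replace = TRUE)
    for (r in seq_len(pool_size)) {
      own <- modulated[block == r]
      pool_profiles[r, own] <- pool_profiles[r, own] *
        2^(signs[block == r] * config$profile_effect)
    }
  }

  # precompute each peak's dense Gaussian footprint on the axis (+-4 sigma)
  peak_lo <- findInterval(centers - 4 * sigmas, axis) + 1L
  peak_hi <- findInterval(centers + 4 * sigmas, axis)
  peak_shape <- lapply(seq_along(centers), function(j) {
    idx <- peak_lo[j]:peak_hi[j]
    list(idx = idx, val = exp(-0.5 * ((axis[idx] - centers[j]) / sigmas[j])^2))
  })
  baseline <- config$baseline_amp * exp(-(axis - config$mz_min) / 700)

  groups <- c(rep("ND", config$n_patients_nd), rep("PD", config$n_patients_pd))
  n_rois <- length(groups)
  pad <- max(2L, nchar(n_rois))
  roi_ids <- sprintf(paste0("roi%0", pad, "d"), seq_len(n_rois))
  patient_ids <- sprintf(paste0("pt%0", pad, "d"), seq_len(n_rois))

  rois <- vector("list", n_rois)
  truth_rois <- vector("list", n_rois)
  region_counts <- integer(n_rois)
  for (i in seq_len(n_rois)) {
    set.seed(derive_seed(config$seed, paste0("roi-", roi_ids[i])))
    p <- if (config$roi_pixels[1L] == config$roi_pixels[2L]) {
      config$roi_pixels[1L]
    } else {
      sample(config$roi_pixels[1L]:config$roi_pixels[2L], 1L)
    }
    side <- ceiling(sqrt(p))
    coords <- cbind(x = (seq_len(p) - 1L) %% side,
                    y = (seq_len(p) - 1L) %/% side)
    rng_pool <- if (groups[i] == "ND") config$regions_nd else config$regions_pd
    n_regions <- if (length(rng_pool) == 1L) rng_pool else sample(rng_pool, 1L)
    region_counts[i] <- n_regions
    labels <- switch(config$region_geometry,
                     voronoi = .voronoi_labels(coords, n_regions),
                     blobs = .blob_labels(coords, n_regions))

    # this ROI hosts a subset of the cohort-level region pool
    pool_idx <- sort(sample.int(pool_size, n_regions))
    profiles <- pool_profiles[pool_idx, , drop = FALSE]

    templates <- matrix(0, n_regions, config$n_channels)
    for (j in seq_along(centers)) {
      sh <- peak_shape[[j]]
      templates[, sh$idx] <- templates[, sh$idx] +
        outer(profiles[, j], sh$val)
    }

    gain <- if (config$tic_cv > 0) {
      sdlog <- sqrt(log(1 + config$tic_cv^2))
      stats::rlnorm(p, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else rep(1, p)
    outlier <- stats::runif(p) < config$outlier_fraction
    gain[outlier] <- gain[outlier] * 0.01
    shift <- if (config$shift_channels > 0L) {
      sample(seq(-config$shift_channels, config$shift_channels), p, replace = TRUE)
    } else rep(0L, p)

    intens <- templates[labels, , drop = FALSE] * gain
    if (config$shift_channels > 0L) {
      for (s in setdiff(unique(shift), 0L)) {
        rows <- which(shift == s)
        shifted <- matrix(0, length(rows), config$n_channels)
        if (s > 0) {
          shifted[, (s + 1L):config$n_channels] <-
            intens[rows, 1L:(config$n_channels - s), drop = FALSE]
        } else {
          shifted[, 1L:(config$n_channels + s)] <-
            intens[rows, (1L - s):config$n_channels, drop = FALSE]
        }
        intens[rows, ] <- shifted
      }
    }
    intens <- sweep(intens, 2L, baseline, "+")
    if (config$noise_sd > 0) {
      intens <- intens + stats::rnorm(length(intens), sd = config$noise_sd)
    }
    intens[intens < 0] <- 0

    roi <- roi_dataset(roi_ids[i], patient_ids[i], coords, intens, axis)
    ord <- order(coords[, 2L], coords[, 1L])  # canonical order used by cohort
    rois[[i]] <- roi
    truth_rois[[i]] <- list(
      roi_id = roi_ids[i], patient_id = patient_ids[i], group = groups[i],
      n_regions = n_regions, pool_regions = pool_idx,
      region_labels = pool_idx[labels[ord]],  # labels in cohort-pool ids
      profiles = profiles,
      gain = gain[ord], shift = shift[ord], outlier = outlier[ord]
    )
  }
  names(truth_rois) <- roi_ids

  # clinical metadata: outcome matches the planted group; TILs tracks the
  # planted diversity (50 * D + N(0, 5), clipped), remaining fields drawn
  # from valid categories
  set.seed(derive_seed(config$seed, "clinical"))
  true_d <- vapply(truth_rois, function(tr) {
    simpson_index(tr$region_labels, estimator = "plug_in")
  }, numeric(1L))
  nodal <- sample(c("N0", "N+"), n_rois, replace = TRUE)
  metadata <- data.frame(
    patient_id = patient_ids,
    outcome = groups,
    nodal = nodal,
    n_stage = ifelse(nodal == "N0", "N0",
                     sample(c("N1", "N2", "N3"), n_rois, replace = TRUE)),
    t_stage = sample(c("T1c", "T2"), n_rois, replace = TRUE),
    stage = sample(c("IA", "IIA", "IIB", "IIIA", "IIIC"), n_rois, replace = TRUE),
    grade = sample(c("G2", "G3"), n_rois, replace = TRUE),
    er = sample(c("pos", "neg"), n_rois, replace = TRUE),
    pr = sample(c("pos", "neg"), n_rois, replace = TRUE),
    tils_percent = pmin(100, pmax(0, 50 * true_d + stats::rnorm(n_rois, sd = 5))),
    stringsAsFactors = FALSE
  )

  truth <- structure(
    list(rois = truth_rois,
         peak_centers = centers, peak_sigmas = sigmas, core_amp = core_amp,
         modulated_peaks = modulated, pool_profiles = pool_profiles,
         baseline = baseline,
         region_counts = stats::setNames(region_counts, roi_ids),
         config = config),
    class = "synthetic_truth"
  )
  list(cohort = cohort_dataset(rois, metadata), truth = truth)
}

#' Generate a synthetic peptide library from planted truth
#'
#' One entry per true peak, with neutral monoisotopic mass consistent with
#' the peak's m/z under the \[M+H\]+ convention (neutral mass = center -
#' 1.00728 Da), plus `round(decoy_fraction * n_peaks)` decoy masses placed at
#' least 0.2% away from every true center. Synthetic protein accessions
#' group 5--10 peptides per protein.
#'
#' @param truth A `synthetic_truth` from [generate_cohort()].
#' @param decoy_fraction Proportion in \[0, 1).
#' @param seed Integer seed for decoy placement and protein grouping.
#' @return Data frame with columns `peptide_id`, `sequence`, `neutral_mass`,
#'   `protein_accession`, `is_decoy`.
#' @export
generate_peptide_library <- function(truth, decoy_fraction = 0, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (decoy_fraction < 0 || decoy_fraction >= 1) {
    stop("decoy_fraction must lie in [0, 1)")
  }
  set.seed(derive_seed(seed, "peptide-library"))
  proton <- 1.00728
  centers <- truth$peak_centers
  n <- length(centers)
  n_decoy <- round(decoy_fraction * n)
  decoys <- numeric(0)
  lo <- min(centers) * 0.99
  hi <- max(centers) * 1.01
  while (length(decoys) < n_decoy) {
    cand <- stats::runif(n_decoy - length(decoys), lo, hi)
    ok <- vapply(cand, function(m) all(abs(m - centers) / centers > 0.002),
                 logical(1L))
    decoys <- c(decoys, cand[ok])
  }
  masses <- c(centers - proton, decoys - proton)
  is_decoy <- c(rep(FALSE, n), rep(TRUE, length(decoys)))
  total <- length(masses)
  # contiguous protein groups of 5-10 peptides
  sizes <- integer(0)
  while (sum(sizes) < total) sizes <- c(sizes, sample(5:10, 1L))
  accession <- rep(sprintf("SYNP%04d", seq_along(sizes)), times = sizes)[seq_len(total)]
  data.frame(
    peptide_id = sprintf("pep%04d", seq_len(total)),
    sequence = NA_character_,
    neutral_mass = masses,
    protein_accession = accession,
    is_decoy = is_decoy,
    stringsAsFactors = FALSE
  )
}
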