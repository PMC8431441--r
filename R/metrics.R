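#' Pairwise spectral similarity within one ROI
#'
#' The similarity index between two pixels is the Pearson correlation (or
#' cosine) of their component-abundance vectors. All unordered pairs are
#' evaluated when there are at most `max_pairs` of them; larger ROIs use a
#' seeded uniform subsample of `max_pairs` pairs. The summary carries the
#' median and the empirical CDF of the evaluated similarities.
#'
#' @param roi_features Numeric matrix: the feature-matrix rows of one ROI.
#' @param max_pairs Pair evaluation cap.
#' @param seed Seed for pair subsampling.
#' @param method `"pearson"` or `"cosine"`.
#' @param roi_id Optional id carried into the summary.
#' @return List of class `similarity_summary`: `roi_id`, `n_pairs_evaluated`,
#'   `median_similarity`, `ecdf` (data frame: similarity, cumulative_prob).
#' @export
pairwise_similarity <- function(roi_features, max_pairs = 1e5, seed = 1L,
                                method = c("pearson", "cosine"),
                                roi_id = NA_character_) {
  method <- match.arg(method)
  p <- nrow(roi_features)
  if (p < 2L) stop("need at least 2 pixels for pairwise similarity")
  x <- roi_features
  if (method == "pearson") {
    sds <- apply(x, 1L, stats::sd)
    degenerate <- sds == 0
    if (any(degenerate)) {
      warning(sprintf("%d pixel(s) have zero variance across components; their pairs get similarity 0",
                      sum(degenerate)))
    }
    mu <- rowMeans(x)
    z <- (x - mu) / ifelse(sds > 0, sds, 1)
    z[degenerate, ] <- 0
    denom <- ncol(x) - 1L
    simfun <- function(i, j) sum(z[i, ] * z[j, ]) / denom
  } else {
    nrm <- sqrt(rowSums(x^2))
    degenerate <- nrm == 0
    z <- x / ifelse(nrm > 0, nrm, 1)
    z[degenerate, ] <- 0
    simfun <- function(i, j) sum(z[i, ] * z[j, ])
  }
  n_all <- p * (p - 1) / 2
  if (n_all <= max_pairs) {
    # full enumeration via the correlation matrix of standardized rows
    sims <- (tcrossprod(z) / if (method == "pearson") (ncol(x) - 1L) else 1)
    vals <- sims[upper.tri(sims)]
  } else {
    set.seed(derive_seed(seed, "pair-subsample"))
    k <- as.integer(max_pairs)
    pair_idx <- sample(n_all, k)
    # map linear upper-triangle index to (i, j), i < j, column-major
    j <- ceiling((1 + sqrt(1 + 8 * pair_idx)) / 2)
    i <- pair_idx - (j - 1) * (j - 2) / 2
    vals <- vapply(seq_len(k), function(t) simfun(i[t], j[t]), numeric(1L))
  }
  vals <- pmin(1, pmax(-1, vals))
  sv <- sort(vals)
  structure(
    list(roi_id = roi_id, n_pairs_evaluated = length(vals),
         median_similarity = stats::median(vals),
         ecdf = data.frame(similarity = sv,
                           cumulative_prob = seq_along(sv) / length(sv))),
    class = "similarity_summary"
  )
}

#' Simpson's diversity index of a cluster labeling
#'
#' The probability that two randomly selected pixels of an ROI belong to
#' different clusters. `distinct_pairs` (default) samples without
#' replacement: D = 1 - sum n_i (n_i - 1) / (N (N - 1)); `plug_in` is the
#' Gini-Simpson form D = 1 - sum (n_i / N)^2.
#'
#' @param labels Per-pixel cluster labels of one ROI.
#' @param estimator `"distinct_pairs"` or `"plug_in"`.
#' @return Diversity in \[0, 1\]; 0 iff a single cluster.
#' @export
simpson_index <- function(labels, estimator = c("distinct_pairs", "plug_in")) {
  estimator <- match.arg(estimator)
  if (length(labels) == 0L) stop("empty label vector")
  n <- length(labels)
  counts <- as.numeric(table(labels))
  if (estimator == "distinct_pairs") {
    if (n < 2L) stop("distinct_pairs estimator needs at least 2 pixels")
    1 - sum(counts * (counts - 1)) / (n * (n - 1))
  } else {
    1 - sum((counts / n)^2)
  }
}

#' Per-ROI heterogeneity profiles
#'
#' For each ROI and each segmentation level: the number of distinct clusters
#' present in the ROI, Simpson's diversity of the ROI's labels, and the
#' median pairwise similarity.
#'
#' @param tree A `segmentation_tree` from [divik()] (must carry the pixel
#'   table, i.e. be built from a `feature_matrix`).
#' @param features The `feature_matrix` the tree was built from.
#' @param config A [pipeline_config()] (block `metrics`).
#' @return Data frame with one row per ROI: `roi_id`, `n_pixels`,
#'   `k_level<l>` and `simpson_level<l>` for each level, and
#'   `median_similarity`.
#' @export
roi_profiles <- function(tree, features, config = pipeline_config()) {
  stopifnot(inherits(tree, "segmentation_tree"),
            inherits(features, "feature_matrix"))
  pix <- features$pixels
  if (is.null(pix) || nrow(pix) != tree$n_pixels) {
    stop("segmentation does not cover the feature matrix pixels")
  }
  level_labels <- lapply(seq_len(tree$max_depth),
                         function(l) labels_at_level(tree, l)$labels)
  roi_ids <- unique(pix$roi_id)
  rows <- vector("list", length(roi_ids))
  for (i in seq_along(roi_ids)) {
    idx <- which(pix$roi_id == roi_ids[i])
    sim <- pairwise_similarity(
      features$values[idx, , drop = FALSE],
      max_pairs = config$metrics$max_pairs,
      seed = derive_seed(config$seed, paste0("sim-", roi_ids[i])),
      method = config$metrics$similarity, roi_id = roi_ids[i])
    row <- list(roi_id = roi_ids[i], n_pixels = length(idx))
    for (l in seq_len(tree$max_depth)) {
      lab <- level_labels[[l]][idx]
      row[[paste0("k_level", l)]] <- length(unique(lab))
      row[[paste0("simpson_level", l)]] <-
        simpson_index(lab, config$metrics$simpson_estimator)
    }
    row$median_similarity <- sim$median_similarity
    rows[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Correlation between ROI size and cluster count
#'
#' Spearman rank correlation between the number of pixels and the number of
#' clusters present per ROI at one segmentation level.
#'
#' @param profiles Data frame from [roi_profiles()].
#' @param level Segmentation level.
#' @return List with `rho`, `p_value`, `n`; `rho` is `NA` (with
#'   `degenerate = TRUE`) when cluster counts are constant.
#' @export
roi_size_cluster_correlation <- function(profiles, level = 1L) {
  if (nrow(profiles) < 3L) stop("need at least 3 ROI profiles")
  k <- profiles[[paste0("k_level", level)]]
  p <- profiles$n_pixels
  if (length(unique(k)) == 1L) {
    return(list(rho = NA_real_, p_value = NA_real_, n = nrow(profiles),
                degenerate = TRUE))
  }
  ct <- suppressWarnings(stats::cor.test(p, k, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(profiles),
       degenerate = FALSE)
}
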