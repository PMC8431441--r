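#' DivIK segmentation parameters
#'
#' @param k_max Maximum clusters considered per split.
#' @param distance `"correlation"` (1 - Pearson r between pixel feature
#'   vectors; robust to residual per-pixel gain) or `"euclidean"`.
#' @param feature_filter `"variance_gmm"`, `"amplitude_gmm"` or `"none"`;
#'   region-driven feature selection recomputed at every node.
#' @param gap_reference_count B reference datasets for the GAP split test.
#' @param min_split_size Minimum node size to attempt a split.
#' @param max_depth Maximum recursion depth (levels).
#' @param n_init k-means restarts per k.
#' @param seed Integer seed.
#' @return List of class `divik_params`.
#' @export
divik_params <- function(k_max = 10L, distance = c("correlation", "euclidean"),
                         feature_filter = c("variance_gmm", "amplitude_gmm", "none"),
                         gap_reference_count = 10L, min_split_size = 200L,
                         max_depth = 3L, n_init = 3L, seed = 1L) {
  distance <- match.arg(distance)
  feature_filter <- match.arg(feature_filter)
  stopifnot(k_max >= 2L, gap_reference_count >= 1L, min_split_size > k_max,
            max_depth >= 1L, n_init >= 1L)
  structure(list(k_max = as.integer(k_max), distance = distance,
                 feature_filter = feature_filter,
                 gap_reference_count = as.integer(gap_reference_count),
                 min_split_size = as.integer(min_split_size),
                 max_depth = as.integer(max_depth),
                 n_init = as.integer(n_init), seed = as.integer(seed)),
            class = "divik_params")
}

# Map rows into the space in which Euclidean distance realizes the
# configured dissimilarity: correlation distance == squared Euclidean
# distance between row-standardized vectors (up to the constant 2(C-1)).
.divik_space <- function(x, distance) {
  if (distance == "euclidean" || ncol(x) < 2L) return(x)
  mu <- rowMeans(x)
  sd <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1L))
  z <- (x - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  z
}

.kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  if (k == 1L) return(centers)
  d2 <- rowSums((x - rep(centers[1L, ], each = n))^2)
  for (j in 2:k) {
    if (sum(d2) <= 0) {
      idx <- sample.int(n, 1L)
    } else {
      idx <- sample.int(n, 1L, prob = d2)
    }
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums((x - rep(centers[j, ], each = n))^2))
  }
  centers
}

.lloyd_kmeans <- function(x, centers, max_iter = 50L) {
  n <- nrow(x)
  k <- nrow(centers)
  xs <- rowSums(x^2)
  labels <- integer(n)
  for (it in seq_len(max_iter)) {
    d2 <- outer(xs, rowSums(centers^2), "+") - 2 * x %*% t(centers)
    new_labels <- max.col(-d2, ties.method = "first")
    for (j in seq_len(k)) {
      members <- which(new_labels == j)
      if (length(members) == 0L) {
        # re-seed an emptied cluster at the point farthest from its center
        far <- which.max(apply(d2, 1L, min))
        centers[j, ] <- x[far, ]
        new_labels[far] <- j
      } else {
        centers[j, ] <- colMeans(x[members, , drop = FALSE])
      }
    }
    if (identical(new_labels, labels)) break
    labels <- new_labels
  }
  wss <- 0
  for (j in seq_len(k)) {
    members <- which(labels == j)
    if (length(members) > 0L) {
      wss <- wss + sum((x[members, , drop = FALSE] -
                          rep(centers[j, ], each = length(members)))^2)
    }
  }
  list(labels = labels, centers = centers, tot_withinss = wss)
}

.seeded_kmeans <- function(x, k, n_init, seed) {
  best <- NULL
  for (r in seq_len(n_init)) {
    set.seed(derive_seed(seed, paste0("kmeans-", k, "-", r)))
    fit <- .lloyd_kmeans(x, .kmeanspp_init(x, k))
    if (is.null(best) || fit$tot_withinss < best$tot_withinss) best <- fit
  }
  best
}

# Dunn index: min inter-centroid distance / max intra-cluster diameter.
# Diameters are exact up to 2000 members, seeded-subsampled above.
.dunn_index <- function(x, fit, seed) {
  k <- nrow(fit$centers)
  dc <- as.matrix(stats::dist(fit$centers))
  min_between <- min(dc[upper.tri(dc)])
  max_diam <- 0
  for (j in seq_len(k)) {
    members <- which(fit$labels == j)
    if (length(members) < 2L) next
    if (length(members) > 2000L) {
      set.seed(derive_seed(seed, paste0("dunn-", j)))
      members <- sample(members, 2000L)
    }
    diam <- max(stats::dist(x[members, , drop = FALSE]))
    max_diam <- max(max_diam, diam)
  }
  if (max_diam == 0) return(Inf)
  min_between / max_diam
}

#' Region-driven feature selection for one node
#'
#' `variance_gmm` fits a 1--3 component univariate Gaussian mixture (BIC
#' choice) to the log2 per-feature variance within the node and keeps the
#' features assigned to the highest-mean component(s), adding components
#' top-down until at least 1% of features survive. `amplitude_gmm` does the
#' same on log2 mean abundance; `none` keeps everything.
#'
#' @param sub_matrix Numeric matrix (node pixels x features).
#' @param mode Filter mode.
#' @return Integer vector of selected feature column indices.
#' @export
filter_features <- function(sub_matrix,
                            mode = c("variance_gmm", "amplitude_gmm", "none")) {
  mode <- match.arg(mode)
  nf <- ncol(sub_matrix)
  if (mode == "none") return(seq_len(nf))
  stat <- switch(mode,
    variance_gmm = apply(sub_matrix, 2L, stats::var),
    amplitude_gmm = colMeans(sub_matrix))
  if (all(stat == stat[1L])) {
    warning("all features identical under the filter statistic; keeping all")
    return(seq_len(nf))
  }
  ls <- log2(stat + .Machine$double.eps)
  fit <- fit_gmm1d(ls, k_max = 3L)
  if (fit$k == 1L) return(seq_len(nf))
  ord <- order(fit$mean, decreasing = TRUE)
  need <- max(2L, ceiling(0.01 * nf))
  selected <- integer(0)
  for (comp in ord) {
    selected <- c(selected, which(fit$assignment == comp))
    if (length(selected) >= need) break
  }
  sort(selected)
}

#' Choose the cluster count for one node by the Dunn index
#'
#' Runs seeded k-means++ (with restarts) for k = 2..`k_max` in the space of
#' the configured distance and returns the k maximizing the Dunn index
#' (minimum inter-centroid distance over maximum intra-cluster diameter);
#' ties break toward smaller k.
#'
#' @param sub_matrix Numeric matrix (node pixels x selected features).
#' @param params A [divik_params()].
#' @param seed Seed for this node (defaults to `params$seed`).
#' @return List with `k_best`, `labels`, `fit` (k-means result in the
#'   working space) and `space` (the transformed matrix), or `NULL` when the
#'   rows carry no structure (all identical).
#' @export
choose_k <- function(sub_matrix, params = divik_params(), seed = params$seed) {
  x <- .divik_space(sub_matrix, params$distance)
  if (all(abs(x - rep(x[1L, ], each = nrow(x))) < 1e-12)) {
    return(NULL)  # no structure
  }
  k_cap <- min(params$k_max, nrow(x) - 1L)
  best <- NULL
  for (k in 2:k_cap) {
    fit <- .seeded_kmeans(x, k, params$n_init, derive_seed(seed, "choose-k"))
    dunn <- .dunn_index(x, fit, derive_seed(seed, paste0("dunn-k", k)))
    if (is.null(best) || dunn > best$dunn + 1e-12) {
      best <- list(k_best = k, labels = fit$labels, fit = fit, dunn = dunn)
    }
  }
  c(best, list(space = x))
}

#' GAP-statistic split decision
#'
#' Accepts the candidate split iff gap(k_best) - s(k_best) > gap(1) (the
#' standard one-standard-error GAP rule, preferring the smaller k), where
#' gap(k) = E*\[log W_k\] - log W_k over B seeded reference datasets and s is
#' the usual sd x sqrt(1 + 1/B) correction. Under the no-structure null the
#' data partitions like the reference (gap(k) ~ gap(1)), so the decision
#' must demand a clear excess before splitting. References are drawn uniformly
#' in the principal-component-aligned bounding box of the node's data (in
#' the working space) and rotated back: spectral features are strongly
#' correlated, and the axis-aligned box reference over-accepts splits of
#' elongated single clusters.
#'
#' @param sub_matrix Node pixels x selected features (raw abundances).
#' @param candidate Result of [choose_k()] on the same matrix.
#' @param params A [divik_params()].
#' @param seed Seed for the reference draws.
#' @return `TRUE` to split, `FALSE` to stop.
#' @export
should_split <- function(sub_matrix, candidate, params = divik_params(),
                         seed = params$seed) {
  if (is.null(candidate)) return(FALSE)
  x <- candidate$space
  n <- nrow(x)
  k <- candidate$k_best
  w_k <- candidate$fit$tot_withinss
  center <- colMeans(x)
  w_1 <- sum((x - rep(center, each = n))^2)
  xc <- x - rep(center, each = n)
  sv <- svd(xc, nu = 0)
  rot <- xc %*% sv$v
  lo <- apply(rot, 2L, min)
  hi <- apply(rot, 2L, max)
  B <- params$gap_reference_count
  ref_k <- numeric(B)
  ref_1 <- numeric(B)
  for (b in seq_len(B)) {
    set.seed(derive_seed(seed, paste0("gap-ref-", b)))
    ref <- matrix(stats::runif(n * ncol(x)), n, ncol(x))
    ref <- ref * rep(hi - lo, each = n) + rep(lo, each = n)
    # W_k is rotation invariant, so the reference is clustered in the
    # rotated frame directly
    fit <- .seeded_kmeans(ref, k, params$n_init,
                          derive_seed(seed, paste0("gap-km-", b)))
    ref_k[b] <- fit$tot_withinss
    rc <- colMeans(ref)
    ref_1[b] <- sum((ref - rep(rc, each = n))^2)
  }
  eps <- .Machine$double.xmin
  gap_k <- mean(log(ref_k + eps)) - log(w_k + eps)
  gap_1 <- mean(log(ref_1 + eps)) - log(w_1 + eps)
  s_k <- stats::sd(log(ref_k + eps)) * sqrt(1 + 1 / B)
  gap_k - s_k > gap_1
}

#' Divisive iterative k-means segmentation
#'
#' Recursively applies region-driven feature selection ([filter_features()]),
#' Dunn-index cluster-count optimization ([choose_k()]) and the GAP split
#' decision ([should_split()]) to the pooled feature matrix. Recursion stops
#' at `max_depth`, below `min_split_size`, or on a rejected split; clusters
#' that stop early persist unchanged at deeper levels.
#'
#' @param features A `feature_matrix` (from [compute_feature_matrix()]) or a
#'   plain numeric matrix.
#' @param params A [divik_params()].
#' @return Object of class `segmentation_tree`: list with `root` (nested
#'   nodes carrying `node_id`, `depth`, `members`, `selected_features`,
#'   `children`), `leaf_id` (per-pixel deepest node label), `n_pixels`,
#'   `max_depth` and the `pixels` table when available.
#' @export
divik <- function(features, params = divik_params()) {
  values <- if (inherits(features, "feature_matrix")) features$values else features
  pixels <- if (inherits(features, "feature_matrix")) features$pixels else NULL
  if (is.null(values) || nrow(values) == 0L) stop("empty feature matrix")
  n <- nrow(values)
  leaf_id <- rep("1", n)

  rec <- function(members, depth, node_id) {
    node <- list(node_id = node_id, depth = depth, members = members,
                 selected_features = NULL, children = NULL)
    if (depth >= params$max_depth) return(node)
    if (length(members) < params$min_split_size) return(node)
    sub <- values[members, , drop = FALSE]
    sel <- withCallingHandlers(
      filter_features(sub, params$feature_filter),
      warning = function(w) invokeRestart("muffleWarning"))
    node$selected_features <- sel
    sub <- sub[, sel, drop = FALSE]
    node_seed <- derive_seed(params$seed, paste0("node-", node_id))
    cand <- choose_k(sub, params, seed = node_seed)
    if (is.null(cand)) return(node)
    if (!should_split(sub, cand, params, seed = node_seed)) return(node)
    kids <- vector("list", cand$k_best)
    for (j in seq_len(cand$k_best)) {
      child_id <- if (node_id == "") as.character(j) else paste0(node_id, ".", j)
      child_members <- members[cand$labels == j]
      leaf_id[child_members] <<- child_id
      kids[[j]] <- rec(child_members, depth + 1L, child_id)
    }
    node$children <- kids
    node
  }
  root <- rec(seq_len(n), 0L, "")
  structure(list(root = root, leaf_id = leaf_id, n_pixels = n,
                 max_depth = params$max_depth, pixels = pixels,
                 params = params),
            class = "segmentation_tree")
}

#' @export
print.segmentation_tree <- function(x, ...) {
  for (l in seq_len(x$max_depth)) {
    cat(sprintf("level %d: %d clusters\n", l,
                length(unique(labels_at_level(x, l)$labels))))
  }
  invisible(x)
}

#' Flatten a segmentation tree at one level
#'
#' The per-pixel label is the deepest node id truncated to `level` path
#' segments; clusters that stopped splitting earlier keep their shallower id
#' unchanged.
#'
#' @param tree A `segmentation_tree`.
#' @param level Integer in 1..`max_depth`.
#' @return List of class `level_labels`: `level`, `labels` (character per
#'   pixel) and `k` (number of distinct labels).
#' @export
labels_at_level <- function(tree, level) {
  if (level < 1L || level > tree$max_depth) {
    stop(sprintf("level must lie in 1..%d", tree$max_depth))
  }
  labels <- truncate_label(tree$leaf_id, level)
  structure(list(level = as.integer(level), labels = labels,
                 k = length(unique(labels))),
            class = "level_labels")
}

#' Truncate hierarchical labels to a depth
#' @param labels Character vector of dot-separated path labels.
#' @param level Number of path segments to keep.
#' @return Character vector.
#' @export
truncate_label <- function(labels, level) {
  vapply(strsplit(labels, ".", fixed = TRUE), function(parts) {
    paste(parts[seq_len(min(level, length(parts)))], collapse = ".")
  }, character(1L))
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b Label vectors of equal length (any atomic type).
#' @return ARI in \[-1, 1\]; 1 means identical partitions up to renaming.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
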