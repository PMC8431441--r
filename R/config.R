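#' Default pipeline configuration
#'
#' Assembles the parameter blocks for every pipeline stage. All defaults are
#' documented here and can be overridden block-wise; the configuration
#' round-trips through plain-text JSON so a run is fully described by
#' (config file, seed, input).
#'
#' @param seed Integer master seed; every stochastic stage derives its own
#'   substream from it (see [derive_seed()]).
#' @param preprocessing,components,divik,metrics,stats,annotation Named lists
#'   overriding individual defaults of the corresponding block.
#' @return A nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            preprocessing = list(),
                            components = list(),
                            divik = list(),
                            metrics = list(),
                            stats = list(),
                            annotation = list()) {
  defaults <- list(
    seed = as.integer(seed),
    preprocessing = list(
      baseline_window = 50L,      # channels; SNIP-style clipping half-window
      outlier_rule = "gmm",       # "gmm" or "mad"
      mad_k = 3,                  # MAD multiplier for the mad rule
      alignment_max_shift = 5L,   # max rigid shift, channels
      tic_target = "dataset_median"  # or "unity"
    ),
    components = list(
      min_valley_rel = 0.01,      # valley threshold rel. to max(mean spectrum)
      max_components_per_fragment = 100L,
      amplitude_floor_rel = 1e-3, # discard components below this rel. weight
      merge_sigma = 1.0,          # merge if |dcenter| < merge_sigma * min(sd)
      em_max_iter = 200L,
      em_tol = 1e-8,
      em_restarts = 2L
    ),
    divik = list(
      k_max = 10L,
      distance = "correlation",   # or "euclidean"
      feature_filter = "variance_gmm",  # "variance_gmm", "amplitude_gmm", "none"
      gap_reference_count = 10L,
      min_split_size = 200L,
      max_depth = 3L,
      n_init = 3L
    ),
    metrics = list(
      max_pairs = 1e5,            # pair subsampling cap per ROI
      similarity = "pearson",     # or "cosine"
      simpson_estimator = "distinct_pairs"  # or "plug_in"
    ),
    stats = list(
      d_cluster_min = 0.5,        # at least medium vs target cluster
      d_outcome_min = 0.2,        # at least small ND vs PD
      wilcoxon_mode = "auto",     # exact when N <= 12 and tie-free
      holm_adjust = FALSE
    ),
    annotation = list(
      tolerance = 5e-4,           # +/-0.05% relative mass tolerance
      charge_convention = "MH_plus"  # or "neutral"
    )
  )
  overrides <- list(preprocessing = preprocessing, components = components,
                    divik = divik, metrics = metrics, stats = stats,
                    annotation = annotation)
  for (block in names(overrides)) {
    ov <- overrides[[block]]
    unknown <- setdiff(names(ov), names(defaults[[block]]))
    if (length(unknown) > 0L) {
      stop(sprintf("unknown %s parameter(s): %s", block,
                   paste(unknown, collapse = ", ")))
    }
    defaults[[block]][names(ov)] <- ov
  }
  structure(defaults, class = "pipeline_config")
}

#' Derive a reproducible substream seed
#'
#' Every stage (and, inside the generator, every ROI) uses its own seed
#' derived deterministically from the master seed and a label, so partial
#' reruns reproduce exactly. The derivation hashes the label into an offset
#' and keeps the result below 2^31.
#'
#' @param seed Integer master seed.
#' @param label Character stage/stream label.
#' @return Integer seed in \[0, 2^31).
#' @export
derive_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 1000003
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Write a pipeline configuration to a JSON text file
#' @param config A `pipeline_config`.
#' @param path Output file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a synthetic-cohort configuration to JSON
#' @param config A [cohort_config()].
#' @param path Output file path.
#' @export
write_cohort_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a synthetic-cohort configuration from JSON
#' @param path File written by [write_cohort_config()].
#' @return A [cohort_config()].
#' @export
read_cohort_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- raw[intersect(names(raw), names(formals(cohort_config)))]
  do.call(cohort_config, raw)
}

#' Read a pipeline configuration from JSON
#' @param path File written by [write_config()] (or hand-edited).
#' @return A `pipeline_config` with defaults filled for absent fields.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, c(
    list(seed = if (is.null(raw$seed)) 1L else raw$seed),
    raw[intersect(names(raw), c("preprocessing", "components", "divik",
                                "metrics", "stats", "annotation"))]
  ))
}
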