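.stage_order <- c("input", "preprocess", "components", "segment",
                  "heterogeneity", "stats", "annotate")

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the end-to-end heterogeneity pipeline
#'
#' Executes the full analysis flow in fixed order: input (simulation or
#' import), preprocessing, spectral-component extraction, DivIK
#' segmentation, heterogeneity metrics, group statistics, and peptide
#' annotation. Every stage writes its artifacts into `out_dir` and can be
#' resumed from the previous stage's files; identical config + seed yields
#' identical result tables. A manifest with the config snapshot, stage
#' timings and artifact digests is written last.
#'
#' @param config A [pipeline_config()].
#' @param input `"simulate"` or the path of an internal cohort container.
#' @param out_dir Output directory (created if absent).
#' @param cohort_cfg A [cohort_config()] used when `input == "simulate"`;
#'   defaults to `cohort_config(seed = config$seed)`.
#' @param stages Subset of stages to run (prior stages are loaded from
#'   `out_dir`); default all.
#' @param resume Reuse stage artifacts already present in `out_dir`.
#' @return The run manifest (invisibly also written as `manifest.json`).
#' @export
run_pipeline <- function(config = pipeline_config(), input = "simulate",
                         out_dir, cohort_cfg = NULL,
                         stages = .stage_order, resume = FALSE) {
  stopifnot(all(stages %in% .stage_order))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)
  timings <- list()
  artifacts <- character(0)
  state <- new.env(parent = emptyenv())

  note <- function(...) artifacts <<- unique(c(artifacts, c(...)))
  last_needed <- max(match(stages, .stage_order))
  run_stage <- function(name, fun) {
    if (match(name, .stage_order) > last_needed) return(invisible())
    t0 <- proc.time()[["elapsed"]]
    tryCatch(fun(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
  }

  need <- function(name) name %in% stages
  load_or <- function(file, loader, compute) {
    if (file.exists(pth(file))) loader(pth(file)) else compute()
  }

  ## --- input -------------------------------------------------------------
  run_stage("input", function() {
    if (need("input") && !(resume && file.exists(pth("cohort.msic")))) {
      if (identical(input, "simulate")) {
        if (is.null(cohort_cfg)) cohort_cfg <- cohort_config(seed = config$seed)
        gen <- generate_cohort(cohort_cfg)
        state$cohort <- gen$cohort
        state$truth <- gen$truth
        saveRDS(gen$truth, pth("truth.rds"))
        region_tab <- do.call(rbind, lapply(gen$truth$rois, function(tr) {
          data.frame(roi_id = tr$roi_id, group = tr$group,
                     n_regions = tr$n_regions, stringsAsFactors = FALSE)
        }))
        note(.write_csv(region_tab, pth("truth_regions.csv")))
        lib <- generate_peptide_library(gen$truth, decoy_fraction = 0.2,
                                        seed = config$seed)
        state$library <- lib
        note(.write_csv(lib, pth("peptide_library.csv")))
      } else {
        state$cohort <- read_cohort(input, format = "internal")
      }
      write_cohort(state$cohort, pth("cohort.msic"), overwrite = TRUE)
      note(pth("cohort.msic"))
    } else {
      state$cohort <- read_cohort(pth("cohort.msic"), format = "internal")
      if (file.exists(pth("truth.rds"))) state$truth <- readRDS(pth("truth.rds"))
      if (file.exists(pth("peptide_library.csv"))) {
        state$library <- utils::read.csv(pth("peptide_library.csv"),
                                         stringsAsFactors = FALSE)
      }
    }
  })

  ## --- preprocess --------------------------------------------------------
  run_stage("preprocess", function() {
    if (need("preprocess") && !(resume && file.exists(pth("processed.rds")))) {
      state$processed <- preprocess_cohort(state$cohort, config)
      saveRDS(state$processed, pth("processed.rds"))
      note(.write_csv(state$processed$qc, pth("qc.csv")))
    } else {
      state$processed <- readRDS(pth("processed.rds"))
    }
  })

  ## --- components --------------------------------------------------------
  run_stage("components", function() {
    if (need("components") && !(resume && file.exists(pth("features.rds")))) {
      ms <- mean_spectrum(state$processed$cohort, state$processed$flags)
      comps <- fit_gmm_components(ms, state$processed$cohort$axis, config,
                                  seed = config$seed)
      state$features <- compute_feature_matrix(state$processed, comps)
      note(.write_csv(as.data.frame(comps), pth("components.csv")))
      saveRDS(state$features, pth("features.rds"))
    } else {
      state$features <- readRDS(pth("features.rds"))
    }
  })

  ## --- segment -----------------------------------------------------------
  run_stage("segment", function() {
    if (need("segment") && !(resume && file.exists(pth("tree.rds")))) {
      dp <- divik_params(
        k_max = config$divik$k_max, distance = config$divik$distance,
        feature_filter = config$divik$feature_filter,
        gap_reference_count = config$divik$gap_reference_count,
        min_split_size = config$divik$min_split_size,
        max_depth = config$divik$max_depth, n_init = config$divik$n_init,
        seed = derive_seed(config$seed, "divik"))
      state$tree <- divik(state$features, dp)
      saveRDS(state$tree, pth("tree.rds"))
      lab <- state$features$pixels
      for (l in seq_len(state$tree$max_depth)) {
        lab[[paste0("level", l)]] <- labels_at_level(state$tree, l)$labels
      }
      note(.write_csv(lab, pth("labels.csv")))
      summary_counts <- lapply(seq_len(state$tree$max_depth), function(l) {
        labels_at_level(state$tree, l)$k
      })
      jsonlite::write_json(
        list(levels = seq_len(state$tree$max_depth),
             clusters = unlist(summary_counts)),
        pth("tree_summary.json"), auto_unbox = FALSE)
      note(pth("tree_summary.json"))
    } else {
      state$tree <- readRDS(pth("tree.rds"))
    }
  })

  ## --- heterogeneity -----------------------------------------------------
  run_stage("heterogeneity", function() {
    if (need("heterogeneity") && !(resume && file.exists(pth("profiles.csv")))) {
      state$profiles <- roi_profiles(state$tree, state$features, config)
      note(.write_csv(state$profiles, pth("profiles.csv")))
    } else {
      state$profiles <- utils::read.csv(pth("profiles.csv"),
                                        stringsAsFactors = FALSE)
    }
  })

  ## --- stats -------------------------------------------------------------
  run_stage("stats", function() {
    if (!need("stats")) return(invisible())
    md <- state$cohort$metadata
    roi_patient <- vapply(state$cohort$rois, function(r) r$patient_id,
                          character(1L))
    roi_outcome <- stats::setNames(
      md$outcome[match(roi_patient, md$patient_id)], names(roi_patient))
    l1 <- labels_at_level(state$tree, 1L)
    pix <- state$features$pixels
    pixel_outcome <- unname(roi_outcome[pix$roi_id])

    # group comparisons of cluster count and diversity per level
    tests <- list()
    for (l in seq_len(state$tree$max_depth)) {
      for (what in c("k_level", "simpson_level")) {
        col <- paste0(what, l)
        nd <- state$profiles[[col]][roi_outcome[state$profiles$roi_id] == "ND"]
        pd <- state$profiles[[col]][roi_outcome[state$profiles$roi_id] == "PD"]
        if (length(nd) > 0L && length(pd) > 0L) {
          w <- wilcoxon_rank_sum(nd, pd, mode = "normal")
          tests[[col]] <- data.frame(
            metric = col, statistic = w$statistic, p_value = w$p_value,
            pallant_r = w$effect_size, n_nd = length(nd), n_pd = length(pd))
        }
      }
    }
    if (length(tests) > 0L) {
      note(.write_csv(do.call(rbind, c(tests, list(make.row.names = FALSE))),
                      pth("group_tests.csv")))
    }

    # target cluster: the level-1 cluster whose per-ROI contribution
    # differs most between the outcome groups (data-driven analogue of the
    # most discriminatory cluster)
    clusters <- sort(unique(l1$labels))
    best <- NULL
    for (cl in clusters) {
      cc <- cluster_contribution(l1, pix$roi_id, cl, roi_outcome)
      nd <- cc$fractions$fraction[cc$fractions$outcome == "ND"]
      pd <- cc$fractions$fraction[cc$fractions$outcome == "PD"]
      gapv <- abs(stats::median(nd) - stats::median(pd))
      if (is.null(best) || gapv > best$gap) {
        best <- list(cluster = cl, gap = gapv, cc = cc)
      }
    }
    state$target_cluster <- best$cluster
    contrib <- best$cc$fractions
    contrib$cluster <- best$cluster
    contrib$p_value <- if (!is.null(best$cc$test)) best$cc$test$p_value else NA_real_
    note(.write_csv(contrib, pth("cluster_contribution.csv")))

    scr <- screen_components(state$features, l1, best$cluster, pixel_outcome,
                             d_cluster_min = config$stats$d_cluster_min,
                             d_outcome_min = config$stats$d_outcome_min)
    state$screening <- scr
    note(.write_csv(scr$table, pth("screening.csv")))

    tils <- tryCatch(
      correlate_tils(state$profiles, md, roi_patient, level = 1L),
      error = function(e) NULL)
    if (!is.null(tils)) {
      jsonlite::write_json(
        tils[c("r", "p_value", "n", "slope", "intercept")],
        pth("tils_correlation.json"), auto_unbox = TRUE, digits = NA)
      note(pth("tils_correlation.json"))
    }
  })

  ## --- annotate ----------------------------------------------------------
  run_stage("annotate", function() {
    if (!need("annotate")) return(invisible())
    lib <- state$library
    if (is.null(lib) && file.exists(pth("peptide_library.csv"))) {
      lib <- utils::read.csv(pth("peptide_library.csv"), stringsAsFactors = FALSE)
    }
    if (is.null(lib)) return(invisible())  # no library available: skip stage
    matches <- match_components(state$features$components, lib,
                                tolerance = config$annotation$tolerance,
                                charge_convention = config$annotation$charge_convention)
    note(.write_csv(matches, pth("matches.csv")))
    restrict <- if (!is.null(state$screening)) state$screening$selected else NULL
    prots <- summarize_proteins(matches, restrict_to = restrict)
    note(.write_csv(prots, pth("proteins.csv")))
  })

  digests <- as.list(tools::md5sum(artifacts[file.exists(artifacts)]))
  names(digests) <- basename(names(digests))
  manifest <- list(
    package_version = as.character(utils::packageVersion("msiith")),
    seed = config$seed,
    config = unclass(config),
    input = if (identical(input, "simulate")) "simulate" else normalizePath(input),
    stages_run = stages,
    timings_sec = timings,
    artifact_md5 = digests
  )
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Command-line entry point
#'
#' Dispatcher behind the `msi-ith` script (see `inst/scripts/msi-ith`):
#' `msi-ith <simulate|import|preprocess|components|segment|heterogeneity|stats|annotate|run>`
#' with shared flags `--out DIR`, `--seed INT`, `--config FILE`,
#' `--input PATH`, `--format internal|imzml`, `--overwrite`, `--verbose`.
#' Stage subcommands resume from the artifacts already present in `--out`.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
msi_ith_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    message("usage: msi-ith <simulate|import|preprocess|components|segment|",
            "heterogeneity|stats|annotate|run> [--out DIR] [--seed INT] ",
            "[--config FILE] [--input PATH] [--format FMT] [--overwrite]")
    return(invisible(1L))
  }
  cmd <- args[1L]
  opts <- list(out = "msiith-out", seed = 1L, config = NULL, input = "simulate",
               format = "internal", overwrite = FALSE, verbose = FALSE,
               cohort_config = NULL)
  i <- 2L
  while (i <= length(args)) {
    a <- args[i]
    take <- function() { i <<- i + 1L; args[i] }
    switch(a,
      "--out" = { opts$out <- take() },
      "--seed" = { opts$seed <- as.integer(take()) },
      "--config" = { opts$config <- take() },
      "--cohort-config" = { opts$cohort_config <- take() },
      "--input" = { opts$input <- take() },
      "--format" = { opts$format <- take() },
      "--overwrite" = { opts$overwrite <- TRUE },
      "--verbose" = { opts$verbose <- TRUE },
      stop(sprintf("unknown flag '%s'", a))
    )
    i <- i + 1L
  }
  cfg <- if (!is.null(opts$config)) read_config(opts$config) else pipeline_config()
  cfg$seed <- as.integer(opts$seed)
  log_msg <- function(...) if (opts$verbose) message(sprintf(...))

  if (cmd == "import") {
    cohort <- read_cohort(opts$input, format = opts$format)
    dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
    write_cohort(cohort, file.path(opts$out, "cohort.msic"),
                 overwrite = opts$overwrite)
    log_msg("imported %d ROIs into %s", length(cohort$rois), opts$out)
    return(invisible(0L))
  }
  stage_map <- list(
    simulate = "input", run = .stage_order,
    preprocess = "preprocess", components = "components",
    segment = "segment", heterogeneity = "heterogeneity",
    stats = "stats", annotate = "annotate")
  if (!cmd %in% names(stage_map)) stop(sprintf("unknown subcommand '%s'", cmd))
  ccfg <- if (!is.null(opts$cohort_config)) read_cohort_config(opts$cohort_config)
  run_pipeline(cfg, input = opts$input, out_dir = opts$out, cohort_cfg = ccfg,
               stages = stage_map[[cmd]], resume = cmd != "run")
  log_msg("%s completed into %s", cmd, opts$out)
  invisible(0L)
}
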