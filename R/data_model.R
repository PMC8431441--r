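#' Construct a mass axis
#'
#' A mass axis is the shared m/z grid (in Da) on which all pixel spectra of a
#' cohort are sampled. MALDI-ToF peptide imaging typically covers m/z
#' 600--3500.
#'
#' @param values Numeric vector of m/z values, strictly increasing, all
#'   nonnegative, length >= 2.
#' @return A numeric vector of class `mass_axis`.
#' @export
mass_axis <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop("mass axis needs at least 2 channels")
  }
  if (anyNA(values) || any(values < 0)) {
    stop("mass axis values must be nonnegative and non-missing")
  }
  if (any(diff(values) <= 0)) {
    stop("mass axis must be strictly increasing")
  }
  structure(values, class = "mass_axis")
}

#' Construct an ROI dataset
#'
#' One cancer region of interest (ROI): per-pixel raster coordinates and an
#' intensity matrix with one row per pixel and one column per mass channel.
#' Coordinates are 0-based grid indices; the physical raster pitch (nominally
#' 100 um) never enters any computation and is kept as an attribute only.
#'
#' @param roi_id,patient_id Character scalars.
#' @param coordinates Integer matrix P x 2 of (x, y) grid indices; rows unique.
#' @param intensities Numeric matrix P x C, all values >= 0.
#' @param axis A [mass_axis()] of length C.
#' @param raster_um Nominal raster pitch in micrometres (annotation only).
#' @return An object of class `roi_dataset`.
#' @export
roi_dataset <- function(roi_id, patient_id, coordinates, intensities, axis,
                        raster_um = 100) {
  stopifnot(is.character(roi_id), length(roi_id) == 1L,
            is.character(patient_id), length(patient_id) == 1L)
  axis <- if (inherits(axis, "mass_axis")) axis else mass_axis(axis)
  coordinates <- as.matrix(coordinates)
  storage.mode(coordinates) <- "integer"
  if (ncol(coordinates) != 2L) stop("coordinates must be a P x 2 matrix")
  intensities <- as.matrix(intensities)
  if (nrow(intensities) < 1L) stop("ROI must contain at least one pixel")
  if (nrow(coordinates) != nrow(intensities)) {
    stop("coordinates and intensities disagree on pixel count")
  }
  if (ncol(intensities) != length(axis)) {
    stop(sprintf("intensity matrix has %d columns but axis has %d channels",
                 ncol(intensities), length(axis)))
  }
  if (anyNA(intensities) || any(intensities < 0)) {
    stop("intensities must be nonnegative and non-missing")
  }
  if (anyDuplicated(paste(coordinates[, 1L], coordinates[, 2L]))) {
    stop("pixel coordinates must be unique within an ROI")
  }
  colnames(coordinates) <- c("x", "y")
  structure(
    list(roi_id = roi_id, patient_id = patient_id,
         coordinates = coordinates, intensities = intensities,
         axis = axis, raster_um = raster_um),
    class = "roi_dataset"
  )
}

#' @export
print.roi_dataset <- function(x, ...) {
  cat(sprintf("<roi_dataset> %s (patient %s): %d pixels x %d channels, m/z %.1f-%.1f\n",
              x$roi_id, x$patient_id, nrow(x$intensities),
              ncol(x$intensities), min(x$axis), max(x$axis)))
  invisible(x)
}

#' Order pixels deterministically
#'
#' Downstream per-pixel label vectors are only reproducible if pixel order is
#' fixed; the canonical order is by y, then x.
#' @param roi A `roi_dataset`.
#' @return The ROI with rows reordered canonically.
#' @export
order_pixels <- function(roi) {
  ord <- order(roi$coordinates[, "y"], roi$coordinates[, "x"])
  roi$coordinates <- roi$coordinates[ord, , drop = FALSE]
  roi$intensities <- roi$intensities[ord, , drop = FALSE]
  roi
}

#' Construct a cohort dataset
#'
#' A cohort bundles ROIs sharing one mass axis with the per-patient clinical
#' table. ROIs are stored sorted by `roi_id` so spectrum order is
#' deterministic.
#'
#' @param rois List of [roi_dataset()] objects sharing an identical axis.
#' @param metadata Data frame of clinical records (see
#'   [read_clinical_table()]) with one row per `patient_id`.
#' @return An object of class `cohort_dataset`.
#' @export
cohort_dataset <- function(rois, metadata) {
  if (length(rois) < 1L) stop("cohort needs at least one ROI")
  ids <- vapply(rois, function(r) r$roi_id, character(1L))
  if (anyDuplicated(ids)) stop("duplicate roi_id in cohort")
  rois <- lapply(rois[order(ids)], order_pixels)
  names(rois) <- sort(ids)
  ax <- rois[[1L]]$axis
  for (r in rois) {
    if (length(r$axis) != length(ax) || any(r$axis != ax)) {
      stop(sprintf("ROI '%s' is not on the shared mass axis", r$roi_id))
    }
  }
  pids <- vapply(rois, function(r) r$patient_id, character(1L))
  missing <- setdiff(pids, metadata$patient_id)
  if (length(missing) > 0L) {
    bad <- names(rois)[match(missing[1L], pids)]
    stop(sprintf("no clinical metadata for ROI '%s' (patient '%s')",
                 bad, missing[1L]))
  }
  structure(list(rois = rois, metadata = metadata, axis = ax),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  p <- sum(vapply(x$rois, function(r) nrow(r$intensities), integer(1L)))
  cat(sprintf("<cohort_dataset> %d ROIs, %d pixels total, %d channels, %d patients\n",
              length(x$rois), p, length(x$axis), nrow(x$metadata)))
  invisible(x)
}

#' Total pixel count of a cohort
#' @param cohort A `cohort_dataset`.
#' @return Integer.
#' @export
n_pixels <- function(cohort) {
  sum(vapply(cohort$rois, function(r) nrow(r$intensities), integer(1L)))
}

# Valid category levels for the clinical table.
.clinical_levels <- list(
  outcome = c("ND", "PD"),
  nodal   = c("N0", "N+"),
  n_stage = c("N0", "N1", "N2", "N3"),
  t_stage = c("T1c", "T2"),
  stage   = c("IA", "IIA", "IIB", "IIIA", "IIIC"),
  grade   = c("G2", "G3"),
  er      = c("pos", "neg"),
  pr      = c("pos", "neg")
)

#' Validate a clinical metadata table
#'
#' Checks the enumerated clinical fields (outcome ND/PD, nodal status, TNM
#' stage, grade, hormone receptors) and cross-field consistency
#' (`nodal == "N0"` iff `n_stage == "N0"`; TILs percentage in \[0, 100\]).
#'
#' @param metadata Data frame with columns `patient_id`, `outcome`, `nodal`,
#'   `n_stage`, `t_stage`, `stage`, `grade`, `er`, `pr` and optionally
#'   `tils_percent`.
#' @return The validated data frame, invisibly usable downstream.
#' @export
validate_clinical <- function(metadata) {
  required <- c("patient_id", "outcome", "nodal", "n_stage", "t_stage",
                "stage", "grade", "er", "pr")
  miss <- setdiff(required, names(metadata))
  if (length(miss) > 0L) {
    stop("clinical table missing columns: ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(metadata$patient_id)) {
    dup <- metadata$patient_id[duplicated(metadata$patient_id)][1L]
    stop(sprintf("duplicate patient_id '%s'", dup))
  }
  for (col in names(.clinical_levels)) {
    vals <- as.character(metadata[[col]])
    bad <- which(!(vals %in% .clinical_levels[[col]]))
    if (length(bad) > 0L) {
      stop(sprintf("row %d: invalid %s value '%s'", bad[1L], col, vals[bad[1L]]))
    }
    metadata[[col]] <- vals
  }
  n0_mismatch <- xor(metadata$nodal == "N0", metadata$n_stage == "N0")
  if (any(n0_mismatch)) {
    stop(sprintf("row %d: nodal and n_stage disagree on N0 status",
                 which(n0_mismatch)[1L]))
  }
  if ("tils_percent" %in% names(metadata)) {
    tp <- metadata$tils_percent
    if (any(!is.na(tp) & (tp < 0 | tp > 100))) {
      stop("tils_percent must lie in [0, 100]")
    }
  } else {
    metadata$tils_percent <- NA_real_
  }
  metadata
}
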