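#' Write a cohort to the internal container format
#'
#' The internal format is a single serialized container file holding the
#' shared mass axis once, all per-ROI coordinate/intensity matrices, and the
#' embedded clinical table. Round trips are bit-identical. Dense cohorts
#' (10^5 pixels x 10^3 channels) need binary storage, so the container is
#' written with R's native serialization rather than text.
#'
#' @param cohort A [cohort_dataset()].
#' @param path Output file path (conventionally `.msic`).
#' @param overwrite Refuse to clobber an existing file unless `TRUE`.
#' @export
write_cohort <- function(cohort, path, overwrite = FALSE) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  if (file.exists(path) && !overwrite) {
    stop(sprintf("'%s' exists; pass overwrite = TRUE to replace it", path))
  }
  saveRDS(cohort, path, version = 3L)
  invisible(path)
}

#' Read a cohort dataset
#'
#' @param path For `format = "internal"`, a container written by
#'   [write_cohort()]. For `format = "imzml"`, a directory containing one
#'   continuous-mode `.imzML`/`.ibd` pair per ROI, a `roi_manifest.csv`
#'   (columns `file`, `roi_id`, `patient_id`) and a `clinical.csv` clinical
#'   table.
#' @param format `"internal"` or `"imzml"`.
#' @return A [cohort_dataset()]; spectra ordered by roi_id, then y, then x.
#' @export
read_cohort <- function(path, format = c("internal", "imzml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("'%s' does not exist", path))
  if (format == "internal") {
    cohort <- readRDS(path)
    if (!inherits(cohort, "cohort_dataset")) {
      stop("file is not an internal cohort container")
    }
    return(cohort)
  }
  manifest_path <- file.path(path, "roi_manifest.csv")
  clinical_path <- file.path(path, "clinical.csv")
  if (!file.exists(manifest_path)) stop("no ROIs found: roi_manifest.csv missing")
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  if (nrow(manifest) == 0L) stop("no ROIs found")
  metadata <- read_clinical_table(clinical_path)
  rois <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    parsed <- read_imzml(file.path(path, manifest$file[i]))
    rois[[i]] <- roi_dataset(
      roi_id = manifest$roi_id[i], patient_id = manifest$patient_id[i],
      coordinates = parsed$coordinates, intensities = parsed$intensities,
      axis = parsed$axis
    )
  }
  cohort_dataset(rois, metadata)
}

.imzml_read_array <- function(node, con, dtypes) {
  acc <- vapply(xml2::xml_find_all(node, ".//cvParam"),
                function(p) xml2::xml_attr(p, "accession"), character(1L))
  size <- if ("MS:1000523" %in% acc) 8L else 4L
  offset <- as.numeric(xml2::xml_attr(
    xml2::xml_find_first(node, ".//cvParam[@accession='IMS:1000102']"), "value"))
  len <- as.integer(xml2::xml_attr(
    xml2::xml_find_first(node, ".//cvParam[@accession='IMS:1000103']"), "value"))
  if (is.na(offset) || is.na(len)) stop("imzML binary array lacks external offset/length")
  seek(con, where = offset, origin = "start")
  readBin(con, what = "double", n = len, size = size, endian = "little")
}

#' Read one continuous-mode imzML file
#'
#' Minimal reader for continuous-mode imzML: the m/z array is stored once and
#' shared by all pixels; per-pixel intensity arrays live in the sibling `.ibd`
#' binary file at the external offsets recorded in the XML. Supports 32- and
#' 64-bit little-endian floats.
#'
#' @param path Path to the `.imzML` file; the `.ibd` must sit next to it.
#' @return List with `axis` (mass_axis), `coordinates` (P x 2 integer,
#'   0-based) and `intensities` (P x C matrix).
#' @export
read_imzml <- function(path) {
  ibd <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (!file.exists(ibd)) stop(sprintf("companion ibd file '%s' not found", ibd))
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  spectra <- xml2::xml_find_all(doc, ".//spectrum")
  if (length(spectra) == 0L) stop("imzML file contains no spectra")
  con <- file(ibd, "rb")
  on.exit(close(con))
  axis_vals <- NULL
  coords <- matrix(0L, length(spectra), 2L)
  rows <- vector("list", length(spectra))
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    px <- as.integer(xml2::xml_attr(
      xml2::xml_find_first(sp, ".//cvParam[@accession='IMS:1000050']"), "value"))
    py <- as.integer(xml2::xml_attr(
      xml2::xml_find_first(sp, ".//cvParam[@accession='IMS:1000051']"), "value"))
    # imzML positions are 1-based; internal coordinates are 0-based indices
    coords[i, ] <- c(px - 1L, py - 1L)
    for (arr in xml2::xml_find_all(sp, ".//binaryDataArray")) {
      acc <- vapply(xml2::xml_find_all(arr, ".//cvParam"),
                    function(p) xml2::xml_attr(p, "accession"), character(1L))
      if ("MS:1000514" %in% acc) {
        if (is.null(axis_vals)) axis_vals <- .imzml_read_array(arr, con)
      } else if ("MS:1000515" %in% acc) {
        rows[[i]] <- .imzml_read_array(arr, con)
      }
    }
  }
  if (is.null(axis_vals)) stop("imzML file lacks an m/z array")
  intens <- do.call(rbind, rows)
  list(axis = mass_axis(axis_vals), coordinates = coords, intensities = intens)
}

#' Write one continuous-mode imzML file
#'
#' Companion writer for [read_imzml()] (used by the `import` tooling and for
#' constructing test files). Writes 64-bit little-endian arrays.
#'
#' @param axis Mass axis values.
#' @param coordinates P x 2 integer matrix of 0-based (x, y) indices.
#' @param intensities P x C matrix.
#' @param path Output `.imzML` path; the `.ibd` is written alongside.
#' @export
write_imzml <- function(axis, coordinates, intensities, path) {
  ibd <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  con <- file(ibd, "wb")
  writeBin(as.numeric(axis), con, size = 8L, endian = "little")
  mz_len <- length(axis)
  offsets <- 8L * mz_len + 8L * mz_len * (seq_len(nrow(intensities)) - 1L)
  for (i in seq_len(nrow(intensities))) {
    writeBin(as.numeric(intensities[i, ]), con, size = 8L, endian = "little")
  }
  close(con)
  arr <- function(kind_acc, kind_name, offset, len) {
    paste0(
      '<binaryDataArray encodedLength="0">',
      '<cvParam accession="MS:1000523" name="64-bit float" value=""/>',
      sprintf('<cvParam accession="%s" name="%s" value=""/>', kind_acc, kind_name),
      sprintf('<cvParam accession="IMS:1000102" name="external offset" value="%d"/>', offset),
      sprintf('<cvParam accession="IMS:1000103" name="external array length" value="%d"/>', len),
      "<binary/></binaryDataArray>"
    )
  }
  spectra <- character(nrow(intensities))
  for (i in seq_len(nrow(intensities))) {
    spectra[i] <- paste0(
      sprintf('<spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">',
              i - 1L, i, mz_len),
      "<scanList count=\"1\"><scan>",
      sprintf('<cvParam accession="IMS:1000050" name="position x" value="%d"/>',
              coordinates[i, 1L] + 1L),
      sprintf('<cvParam accession="IMS:1000051" name="position y" value="%d"/>',
              coordinates[i, 2L] + 1L),
      "</scan></scanList>",
      '<binaryDataArrayList count="2">',
      arr("MS:1000514", "m/z array", 0L, mz_len),
      arr("MS:1000515", "intensity array", offsets[i], mz_len),
      "</binaryDataArrayList></spectrum>"
    )
  }
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    "<fileDescription><fileContent>",
    '<cvParam accession="IMS:1000030" name="continuous" value=""/>',
    "</fileContent></fileDescription>",
    sprintf('<run id="run"><spectrumList count="%d">', nrow(intensities)),
    paste0(spectra, collapse = ""),
    "</spectrumList></run></mzML>"
  )
  writeLines(xml, path)
  invisible(path)
}

#' Read and validate a clinical metadata table
#'
#' Expects a UTF-8 comma-separated file with one header row and the columns
#' `patient_id, outcome, nodal, n_stage, t_stage, stage, grade, er, pr`
#' (optionally `tils_percent`). Categorical values are validated against the
#' study enumerations; offending rows are reported by number.
#'
#' @param path CSV file path.
#' @return Validated data frame, one row per patient.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("'%s' does not exist", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  validate_clinical(df)
}
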