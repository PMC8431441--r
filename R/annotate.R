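#' Match spectral components to a peptide library by mass
#'
#' A component matches a peptide iff |center - m_expected| / m_expected <=
#' `tolerance`, where m_expected is the peptide's neutral monoisotopic mass
#' plus one proton (1.00728 Da) under the default \[M+H\]+ convention
#' (MALDI produces predominantly singly protonated peptides), or the neutral
#' mass itself under `"neutral"`. All qualifying pairs are returned:
#' annotation by low-resolution ToF masses is intrinsically non-unique, so
#' many-to-many matches are preserved rather than resolved. Decoy entries
#' are matched and flagged through, so the decoy match rate estimates the
#' chance-match rate.
#'
#' @param components `spectral_components` table (uses fitted centers).
#' @param library Peptide table with columns `peptide_id`, `neutral_mass`,
#'   `protein_accession` and optionally `is_decoy`, `sequence`.
#' @param tolerance Relative mass tolerance (default 5e-4, i.e. +-0.05%).
#' @param charge_convention `"MH_plus"` or `"neutral"`.
#' @return Data frame with one row per (component, peptide) match:
#'   `component_id`, `center`, `peptide_id`, `matched_mz`, `relative_error`,
#'   `protein_accession`, `is_decoy`; sorted by component, then |error|.
#' @export
match_components <- function(components, library, tolerance = 5e-4,
                             charge_convention = c("MH_plus", "neutral")) {
  charge_convention <- match.arg(charge_convention)
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance <= 0) {
    stop("tolerance must be a positive number")
  }
  if (nrow(library) == 0L) stop("peptide library is empty")
  proton <- 1.00728
  m_expected <- library$neutral_mass +
    if (charge_convention == "MH_plus") proton else 0
  if (!"is_decoy" %in% names(library)) library$is_decoy <- FALSE
  out <- list()
  for (i in seq_len(nrow(components))) {
    center <- components$center[i]
    rel <- (center - m_expected) / m_expected
    hit <- which(abs(rel) <= tolerance)
    if (length(hit) == 0L) next
    df <- data.frame(
      component_id = components$component_id[i],
      center = center,
      peptide_id = library$peptide_id[hit],
      matched_mz = m_expected[hit],
      relative_error = rel[hit],
      protein_accession = library$protein_accession[hit],
      is_decoy = library$is_decoy[hit],
      stringsAsFactors = FALSE
    )
    out[[length(out) + 1L]] <- df[order(abs(df$relative_error)), ]
  }
  if (length(out) == 0L) {
    return(data.frame(component_id = integer(0), center = numeric(0),
                      peptide_id = character(0), matched_mz = numeric(0),
                      relative_error = numeric(0),
                      protein_accession = character(0),
                      is_decoy = logical(0)))
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res[order(res$component_id, abs(res$relative_error)), , drop = FALSE]
}

#' Summarize matched peptides per protein
#'
#' Groups component-peptide matches by protein accession, optionally
#' restricted to a component subset (typically the screened discriminatory
#' components), and counts distinct matched components per protein.
#'
#' @param matches Data frame from [match_components()].
#' @param restrict_to Optional vector of component ids.
#' @return Data frame `protein_accession`, `n_components`,
#'   `component_ids` (comma-joined), ordered by count descending then
#'   accession.
#' @export
summarize_proteins <- function(matches, restrict_to = NULL) {
  if (!is.null(restrict_to)) {
    matches <- matches[matches$component_id %in% restrict_to, , drop = FALSE]
  }
  if (nrow(matches) == 0L) {
    return(data.frame(protein_accession = character(0),
                      n_components = integer(0),
                      component_ids = character(0)))
  }
  by_prot <- split(matches$component_id, matches$protein_accession)
  out <- data.frame(
    protein_accession = names(by_prot),
    n_components = vapply(by_prot, function(v) length(unique(v)), integer(1L)),
    component_ids = vapply(by_prot, function(v) {
      paste(sort(unique(v)), collapse = ",")
    }, character(1L)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[order(-out$n_components, out$protein_accession), , drop = FALSE]
}
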