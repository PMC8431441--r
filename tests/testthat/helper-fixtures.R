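# Shared fixture builders: everything is generated in code at test time.

tiny_axis <- function(n = 50L, from = 600, to = 700) {
  mass_axis(seq(from, to, length.out = n))
}

tiny_roi <- function(roi_id = "r1", patient_id = "p1", p = 4L, axis = tiny_axis(),
                     intensities = NULL) {
  side <- ceiling(sqrt(p))
  coords <- cbind(x = (seq_len(p) - 1L) %% side, y = (seq_len(p) - 1L) %/% side)
  if (is.null(intensities)) {
    intensities <- matrix(rep(seq_len(p), each = length(axis)),
                          nrow = p, byrow = TRUE)
  }
  roi_dataset(roi_id, patient_id, coords, intensities, axis)
}

tiny_metadata <- function(patient_ids = "p1") {
  n <- length(patient_ids)
  data.frame(patient_id = patient_ids,
             outcome = rep(c("ND", "PD"), length.out = n),
             nodal = "N0", n_stage = "N0", t_stage = "T1c", stage = "IA",
             grade = "G2", er = "pos", pr = "neg",
             tils_percent = NA_real_, stringsAsFactors = FALSE)
}

tiny_cohort <- function(n_rois = 2L, p = 4L, axis = tiny_axis()) {
  rois <- lapply(seq_len(n_rois), function(i) {
    tiny_roi(sprintf("r%02d", i), sprintf("p%02d", i), p, axis)
  })
  cohort_dataset(rois, tiny_metadata(sprintf("p%02d", seq_len(n_rois))))
}

# small desk-scale synthetic config used across modules (coarse axis, wide
# peaks; resolvable on 1200 channels)
small_cohort_config <- function(...) {
  defaults <- list(n_patients_nd = 3L, n_patients_pd = 3L,
                   roi_pixels = c(120L, 160L), n_channels = 1200L,
                   n_peptide_peaks = 50L, regions_nd = 3L, regions_pd = 2L,
                   profile_effect = 1.5, noise_sd = 0.3, sigma_rel = 0.008,
                   seed = 42L)
  args <- utils::modifyList(defaults, list(...))
  do.call(cohort_config, args)
}

# Gaussian peak helper for constructed spectra
gauss_peak <- function(axis, center, sigma, amp = 1) {
  amp * exp(-0.5 * ((as.numeric(axis) - center) / sigma)^2)
}

# truth labels of a cohort aligned to the unflagged feature-matrix rows
truth_labels_unflagged <- function(truth, flags) {
  unlist(lapply(names(truth$rois), function(id) {
    truth$rois[[id]]$region_labels[!flags[[id]]]
  }), use.names = FALSE)
}

clinical_fixture_path <- function() {
  system.file("extdata", "clinical_cohort.csv", package = "msiith")
}
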