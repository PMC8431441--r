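test_that("domain type invariants are enforced", {
  expect_error(mass_axis(c(700, 600)), "increasing")
  expect_error(mass_axis(5), "at least 2")
  expect_error(mass_axis(c(-1, 0)), "nonnegative")

  ax <- tiny_axis()
  expect_error(
    roi_dataset("r", "p", cbind(0L, 0L), matrix(-1, 1, length(ax)), ax),
    "nonnegative")
  expect_error(
    roi_dataset("r", "p", rbind(c(0L, 0L), c(0L, 0L)),
                matrix(1, 2, length(ax)), ax),
    "unique")
  expect_error(
    roi_dataset("r", "p", cbind(0L, 0L), matrix(1, 1, 10), ax),
    "columns")

  # cohort: axis mismatch and missing metadata are hard errors naming the ROI
  r1 <- tiny_roi("a", "p01")
  r2 <- tiny_roi("b", "p02", axis = tiny_axis(from = 600, to = 800))
  expect_error(cohort_dataset(list(r1, r2), tiny_metadata(c("p01", "p02"))),
               "shared mass axis")
  expect_error(cohort_dataset(list(r1), tiny_metadata("other")),
               "'a'.*'p01'|'p01'.*'a'")
})

test_that("internal container round-trips bit-identically", {
  cohort <- tiny_cohort(2L)
  cohort$rois[[1L]]$intensities[] <-
    matrix(runif(prod(dim(cohort$rois[[1L]]$intensities))) * exp(1), nrow = 4L)
  path <- withr::local_tempfile(fileext = ".msic")
  write_cohort(cohort, path)
  back <- read_cohort(path, format = "internal")
  expect_identical(back$rois[[1L]]$intensities, cohort$rois[[1L]]$intensities)
  expect_identical(back$rois[[2L]]$coordinates, cohort$rois[[2L]]$coordinates)
  expect_identical(as.numeric(back$axis), as.numeric(cohort$axis))
  expect_identical(back$metadata, cohort$metadata)
  expect_length(back$rois, 2L)
  # overwrite guard
  expect_error(write_cohort(cohort, path), "overwrite")
  expect_silent(write_cohort(cohort, path, overwrite = TRUE))
})

test_that("imzML reader parses a hand-constructed continuous-mode file", {
  # fixture written with independent writeBin calls, not the package writer
  dir <- withr::local_tempdir()
  axis <- c(600, 601, 602)
  spectra <- rbind(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9), c(10, 11, 12))
  ibd <- file.path(dir, "toy.ibd")
  con <- file(ibd, "wb")
  writeBin(as.numeric(axis), con, size = 8, endian = "little")
  for (i in 1:4) writeBin(as.numeric(spectra[i, ]), con, size = 8, endian = "little")
  close(con)
  arr <- function(kind, off, len) paste0(
    "<binaryDataArray>",
    "<cvParam accession=\"MS:1000523\" name=\"64-bit float\" value=\"\"/>",
    sprintf("<cvParam accession=\"%s\" name=\"x\" value=\"\"/>", kind),
    sprintf("<cvParam accession=\"IMS:1000102\" name=\"external offset\" value=\"%d\"/>", off),
    sprintf("<cvParam accession=\"IMS:1000103\" name=\"external array length\" value=\"%d\"/>", len),
    "</binaryDataArray>")
  pos <- rbind(c(1, 1), c(2, 1), c(1, 2), c(2, 2))  # 1-based imzML positions
  sp <- vapply(1:4, function(i) paste0(
    "<spectrum>",
    sprintf("<scan><cvParam accession=\"IMS:1000050\" name=\"position x\" value=\"%d\"/>", pos[i, 1]),
    sprintf("<cvParam accession=\"IMS:1000051\" name=\"position y\" value=\"%d\"/></scan>", pos[i, 2]),
    arr("MS:1000514", 0, 3), arr("MS:1000515", 24 + (i - 1) * 24, 3),
    "</spectrum>"), character(1))
  writeLines(paste0("<mzML><run><spectrumList>", paste(sp, collapse = ""),
                    "</spectrumList></run></mzML>"),
             file.path(dir, "toy.imzML"))
  parsed <- read_imzml(file.path(dir, "toy.imzML"))
  expect_equal(nrow(parsed$intensities), 4L)
  expect_equal(as.numeric(parsed$axis), axis)
  expect_setequal(paste(parsed$coordinates[, 1], parsed$coordinates[, 2]),
                  c("0 0", "1 0", "0 1", "1 1"))
  expect_equal(parsed$intensities, spectra)
})

test_that("imzML writer round-trips through the reader and read_cohort", {
  dir <- withr::local_tempdir()
  axis <- seq(600, 650, length.out = 20)
  coords <- cbind(x = c(0L, 1L, 0L), y = c(0L, 0L, 1L))
  intens <- matrix(runif(60), 3, 20)
  write_imzml(axis, coords, intens, file.path(dir, "roi1.imzML"))
  parsed <- read_imzml(file.path(dir, "roi1.imzML"))
  expect_equal(parsed$intensities, intens)
  expect_equal(parsed$coordinates, unname(coords))

  write.csv(data.frame(file = "roi1.imzML", roi_id = "r1", patient_id = "p01"),
            file.path(dir, "roi_manifest.csv"), row.names = FALSE)
  write.csv(tiny_metadata("p01"), file.path(dir, "clinical.csv"),
            row.names = FALSE)
  cohort <- read_cohort(dir, format = "imzml")
  expect_length(cohort$rois, 1L)
  expect_equal(nrow(cohort$rois[["r1"]]$intensities), 3L)

  empty <- withr::local_tempdir()
  expect_error(read_cohort(empty, format = "imzml"), "no ROIs found")
})

test_that("clinical table parsing validates categories and accounts groups", {
  md <- read_clinical_table(clinical_fixture_path())
  expect_equal(nrow(md), 59L)
  expect_equal(sum(md$outcome == "ND"), 38L)
  expect_equal(sum(md$outcome == "PD"), 21L)
  expect_equal(sum(md$nodal == "N+"), 32L)

  dir <- withr::local_tempdir()
  bad <- md
  bad$grade[3] <- "G5"
  write.csv(bad, file.path(dir, "bad.csv"), row.names = FALSE)
  expect_error(read_clinical_table(file.path(dir, "bad.csv")), "G5")

  dup <- md
  dup$patient_id[2] <- dup$patient_id[1]
  write.csv(dup, file.path(dir, "dup.csv"), row.names = FALSE)
  expect_error(read_clinical_table(file.path(dir, "dup.csv")), "duplicate")

  inconsistent <- md
  inconsistent$n_stage[inconsistent$nodal == "N0"][1] <- "N2"
  write.csv(inconsistent, file.path(dir, "inc.csv"), row.names = FALSE)
  expect_error(read_clinical_table(file.path(dir, "inc.csv")), "disagree")
})

test_that("pixel ordering is deterministic (roi_id, then y, then x)", {
  axis <- tiny_axis(5L)
  coords <- rbind(c(1L, 1L), c(0L, 0L), c(1L, 0L), c(0L, 1L))
  intens <- matrix(as.numeric(1:4), 4, 5)
  roi <- roi_dataset("r1", "p01", coords, intens, axis)
  cohort <- cohort_dataset(list(roi), tiny_metadata("p01"))
  got <- cohort$rois[["r1"]]$coordinates
  expect_equal(unname(got), rbind(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L)))
  expect_equal(cohort$rois[["r1"]]$intensities[, 1L], c(2, 3, 4, 1))
})
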