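#' Bundled worked-example run (Heme 1)
#'
#' The package ships a plain-text transcription of a published-style Heme 1
#' interpretation template: nine RNA lanes (ids 5, 6, 8, 15, 16, 22, 24,
#' 24C and the positive-control RNA IVS-020), thirteen fusion probe sets
#' with their printed review/positivity cutoffs, five housekeeping probes
#' with their pass thresholds, and the POS_A-F/NEG_A-F assay controls. The
#' run exhibits every interpretation outcome: clean positives, a
#' review-zone flag, a clean negative, a degraded-RNA lane and a
#' collapsed-assay-control lane.
#'
#' @param which `"counts"`, `"calibration"` or `"manifest"`.
#' @return `table2_fixture_path` returns the installed file path.
#' @export
table2_fixture_path <- function(which = c("counts", "calibration", "manifest")) {
  which <- match.arg(which)
  fn <- c(counts = "heme1_worked_example_counts.tsv",
          calibration = "heme1_worked_example_calibration.tsv",
          manifest = "heme1_worked_example_manifest.tsv")[[which]]
  system.file("extdata", fn, package = "fusioncall", mustWork = TRUE)
}

#' @rdname table2_fixture_path
#' @return `table2_fixture` returns the loaded run: `samples` (list of
#'   [sample_counts()], HEME1), `calibration` (printed cutoffs, no
#'   background moments; housekeeping thresholds), `manifest`.
#' @export
table2_fixture <- function() {
  manifest <- read_manifest(table2_fixture_path("manifest"))
  samples <- read_count_table(table2_fixture_path("counts"), manifest,
                              tube = "HEME1")
  calibration <- read_calibration(table2_fixture_path("calibration"))
  list(samples = samples, calibration = calibration, manifest = manifest)
}
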