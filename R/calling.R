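PROBE_STATUSES <- c("NEGATIVE", "REVIEW", "POSITIVE", "UNCALIBRATED", "MISSING")

SAMPLE_STATUSES <- c("POSITIVE", "NEGATIVE", "REVIEW", "FAILED_RNA",
                     "FAILED_ASSAY", "HIGH_BACKGROUND", "NOT_INTERPRETABLE")

RECOMMENDATIONS <- c("NONE", "REPEAT_MORE_RNA", "REPEAT_LESS_RNA",
                     "REFLEX_HEME2")

#' Classify every fusion probe of one lane against its cutoffs
#'
#' A probe is POSITIVE when its count is strictly above the positivity
#' cutoff (background mean + 5 SD), REVIEW when strictly above the review
#' cutoff (mean + 3 SD) but not above the positivity cutoff, and NEGATIVE
#' otherwise. Both comparisons are strict, so a count exactly at the
#' positivity cutoff is REVIEW and a count exactly at the review cutoff is
#' NEGATIVE. Probes without cutoffs are UNCALIBRATED; missing counts are
#' MISSING.
#'
#' @param sample a [sample_counts()].
#' @param calib a [calibration_table()].
#' @param manifest a [panel_manifest()]. Only fusion probes belonging to
#'   the sample's tube (or with no tube restriction) are scored.
#' @return data.frame (class `probe_calls`) with columns `probe_id`,
#'   `fusion_id`, `count`, `cut3`, `cut5`, `status`.
#' @export
score_probes <- function(sample, calib, manifest) {
  stopifnot(inherits(sample, "sample_counts"),
            inherits(calib, "calibration_table"),
            inherits(manifest, "panel_manifest"))
  fids <- probe_ids(manifest, "FUSION", tube = sample$tube)
  idx <- match(fids, calib$fusion$probe_id)
  cut3 <- calib$fusion$cut3[idx]
  cut5 <- calib$fusion$cut5[idx]
  uncal <- is.na(idx) | calib$fusion$uncalibrated[idx] | is.na(cut3) | is.na(cut5)
  cnt <- as.numeric(sample$counts[fids])
  status <- ifelse(uncal, "UNCALIBRATED",
            ifelse(is.na(cnt), "MISSING",
            ifelse(cnt > cut5, "POSITIVE",
            ifelse(cnt > cut3, "REVIEW", "NEGATIVE"))))
  out <- data.frame(probe_id = fids,
                    fusion_id = fusion_id_of(manifest, fids),
                    count = cnt, cut3 = cut3, cut5 = cut5,
                    status = status, stringsAsFactors = FALSE)
  class(out) <- c("probe_calls", "data.frame")
  out
}

#' Interpret one lane: QC gates, fusion calls, recommendation
#'
#' The decision procedure, in precedence order:
#' \enumerate{
#'   \item collapsed assay controls void the lane (`FAILED_ASSAY`): no
#'     fusion calls are emitted even for counts above cutoff, and the lane
#'     is repeated;
#'   \item a lane with half or more of its fusion probes missing is
#'     `NOT_INTERPRETABLE`;
#'   \item more than `high_background_k` distinct fusions at review level
#'     or above means diffuse elevated background (`HIGH_BACKGROUND`),
#'     repeated with less RNA;
#'   \item any probe above its positivity cutoff makes the lane
#'     `POSITIVE`; inadequate RNA is noted but does not veto a positive —
#'     RNA adequacy is a condition for calling a lane negative, not
#'     positive;
#'   \item any probe in the review zone makes the lane `REVIEW`, repeated
#'     with more RNA to check the flagged fusion(s);
#'   \item otherwise the lane is `NEGATIVE` if its RNA is adequate (and,
#'     in reflex mode, a negative first tube triggers the second-tube
#'     recommendation), else `FAILED_RNA`, repeated with more RNA.
#' }
#'
#' @inheritParams score_probes
#' @param config a [call_config()].
#' @return A `sample_interpretation`: `sample_id`, `status`,
#'   `positive_fusions` / `review_fusions` (probe-call rows, positives
#'   ordered by descending count/cutoff ratio), `assay_qc`, `rna_qc`,
#'   `recommendation`, `notes`, `probe_calls`, `tube`.
#' @export
interpret_sample <- function(sample, calib, manifest, config = call_config()) {
  stopifnot(inherits(config, "call_config"))
  aqc <- assess_assay_controls(sample, manifest, config)
  rqc <- tryCatch(assess_rna_quality(sample, calib, manifest),
                  fusioncall_error = function(e) NULL)
  calls <- score_probes(sample, calib, manifest)
  notes <- character(0)

  empty_calls <- calls[0L, , drop = FALSE]
  finish <- function(status, positive, review, recommendation) {
    structure(list(sample_id = sample$sample_id, status = status,
                   positive_fusions = positive, review_fusions = review,
                   assay_qc = aqc, rna_qc = rqc,
                   recommendation = recommendation, notes = notes,
                   probe_calls = calls, tube = sample$tube),
              class = "sample_interpretation")
  }

  if (!aqc$passed) {
    notes <- c(notes, "assay controls failed; fusion counts not interpreted",
               aqc$reasons)
    return(finish("FAILED_ASSAY", empty_calls, empty_calls, "REPEAT_MORE_RNA"))
  }

  n_missing <- sum(calls$status == "MISSING")
  if (nrow(calls) > 0L &&
      n_missing / nrow(calls) >= config$missing_frac_limit) {
    notes <- c(notes, sprintf("%d of %d fusion probes missing", n_missing,
                              nrow(calls)))
    return(finish("NOT_INTERPRETABLE", empty_calls, empty_calls,
                  "REPEAT_MORE_RNA"))
  }

  elevated <- calls$status %in% c("REVIEW", "POSITIVE")
  n_elevated_fusions <- length(unique(calls$fusion_id[elevated]))
  pos <- calls[calls$status == "POSITIVE", , drop = FALSE]
  pos <- pos[order(-(pos$count / pos$cut5)), , drop = FALSE]
  rev <- calls[calls$status == "REVIEW", , drop = FALSE]

  if (n_elevated_fusions > config$high_background_k) {
    notes <- c(notes, sprintf(
      "counts elevated across %d distinct fusions; background too high to call",
      n_elevated_fusions))
    return(finish("HIGH_BACKGROUND", empty_calls, empty_calls,
                  "REPEAT_LESS_RNA"))
  }

  if (nrow(pos) > 0L) {
    if (!is.null(rqc) && !rqc$adequate) {
      notes <- c(notes, sprintf(
        "RNA quality inadequate (%d/5 housekeeping pass); positive call retained",
        rqc$n_pass))
    }
    return(finish("POSITIVE", pos, rev, "NONE"))
  }

  if (nrow(rev) > 0L) {
    notes <- c(notes, sprintf("repeat with more RNA to check %s",
                              paste(unique(rev$fusion_id), collapse = ", ")))
    return(finish("REVIEW", pos, rev, "REPEAT_MORE_RNA"))
  }

  if (is.null(rqc)) {
    notes <- c(notes, "no housekeeping thresholds available; negativity cannot be established")
    return(finish("NOT_INTERPRETABLE", empty_calls, empty_calls,
                  "REPEAT_MORE_RNA"))
  }
  if (rqc$adequate) {
    rec <- if (config$reflex && identical(sample$tube, "HEME1"))
      "REFLEX_HEME2" else "NONE"
    return(finish("NEGATIVE", pos, rev, rec))
  }
  notes <- c(notes, sprintf("RNA quality failed (%d/5 housekeeping pass)",
                            rqc$n_pass))
  finish("FAILED_RNA", empty_calls, empty_calls, "REPEAT_MORE_RNA")
}

#' Interpret every lane of a run
#'
#' @param samples list of [sample_counts()].
#' @inheritParams interpret_sample
#' @return list of `sample_interpretation`, named by sample id.
#' @export
interpret_run <- function(samples, calib, manifest, config = call_config()) {
  out <- lapply(samples, interpret_sample, calib = calib, manifest = manifest,
                config = config)
  names(out) <- vapply(out, `[[`, "", "sample_id")
  out
}

#' Should the second tube be run?
#'
#' Under reflex testing the second panel tube (Heme 2) is run only when the
#' first (Heme 1) is negative. A positive lane needs no second tube; a
#' failed or review lane is repeated, not reflexed.
#'
#' @param heme1 a `sample_interpretation` from a HEME1 lane.
#' @return `TRUE` iff the lane status is `NEGATIVE`.
#' @export
reflex_decision <- function(heme1) {
  stopifnot(inherits(heme1, "sample_interpretation"))
  if (!is.null(heme1$tube) && !identical(heme1$tube, "HEME1")) {
    stop_fc("reflex decision applies to HEME1 lanes, got tube %s", heme1$tube,
            class = "calling_error")
  }
  identical(heme1$status, "NEGATIVE")
}

#' Check a fusion call against the flow-cytometry immunophenotype
#'
#' Most fusions are characteristic of one leukemia subtype, so the fusion
#' call and the flow immunophenotype should agree. A positive lane is
#' concordant when every called fusion's lineage set contains the flow
#' lineage, discordant when some called fusion has a non-empty lineage set
#' excluding it. A negative lane agrees with flow showing no leukemia
#' (`"NONE_DETECTED"`); a negative lane with leukemia present is not
#' assessable (many leukemias carry no panel fusion). Failed, review and
#' uninterpretable lanes are not assessable.
#'
#' @param interp a `sample_interpretation`.
#' @param flow_lineage one of [LINEAGE_LEVELS] or `"NONE_DETECTED"`.
#' @param manifest a [panel_manifest()] providing the fusion-lineage map.
#' @return `"CONCORDANT"`, `"DISCORDANT"` or `"NOT_ASSESSABLE"`.
#' @export
check_concordance <- function(interp, flow_lineage, manifest) {
  stopifnot(inherits(interp, "sample_interpretation"))
  flow_lineage <- match.arg(flow_lineage, c(LINEAGE_LEVELS, "NONE_DETECTED"))
  if (interp$status %in% c("FAILED_RNA", "FAILED_ASSAY", "REVIEW",
                           "HIGH_BACKGROUND", "NOT_INTERPRETABLE")) {
    return("NOT_ASSESSABLE")
  }
  if (interp$status == "NEGATIVE") {
    return(if (flow_lineage == "NONE_DETECTED") "CONCORDANT"
           else "NOT_ASSESSABLE")
  }
  lineage_sets <- lapply(unique(interp$positive_fusions$fusion_id),
                         lineages_for, manifest = manifest)
  nonempty <- lineage_sets[vapply(lineage_sets, length, 0L) > 0L]
  if (length(nonempty) == 0L) return("NOT_ASSESSABLE")
  if (flow_lineage == "NONE_DETECTED") return("DISCORDANT")
  if (all(vapply(nonempty, function(s) flow_lineage %in% s, TRUE))) {
    "CONCORDANT"
  } else {
    "DISCORDANT"
  }
}

#' @export
print.sample_interpretation <- function(x, ...) {
  cat(sprintf("<interpretation '%s'> %s", x$sample_id, x$status))
  if (nrow(x$positive_fusions) > 0L) {
    cat(": ", paste(unique(x$positive_fusions$fusion_id), collapse = ", "),
        sep = "")
  }
  if (nrow(x$review_fusions) > 0L) {
    cat(" [review: ",
        paste(unique(x$review_fusions$fusion_id), collapse = ", "), "]",
        sep = "")
  }
  if (x$recommendation != "NONE") cat(" ->", x$recommendation)
  cat("\n")
  for (n in x$notes) cat("  note: ", n, "\n", sep = "")
  invisible(x)
}
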