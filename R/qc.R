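#' QC configuration
#'
#' Numeric gates for the assay-control and interpretation rules. The
#' positive-control floor, ladder step tolerance and negative-control
#' ceiling have no published values; the defaults separate every passing
#' lane of the worked-example run from its collapsed-control lane by a wide
#' margin and are all overridable.
#'
#' @param pos_floor minimum count for the top (highest concentration)
#'   positive control; default 1000.
#' @param ladder_tolerance each step down the POS titration ladder may be
#'   at most this multiple of its predecessor (counts should decay);
#'   default 1.5.
#' @param neg_ceiling maximum admissible mean negative-control count;
#'   default 50.
#' @param check_neg_controls apply the negative-control ceiling at all;
#'   on by default, switchable because collapsed positive controls alone
#'   already void a lane.
#' @param high_background_k a lane flagging more than this many distinct
#'   fusions at review level or above is treated as high background and
#'   repeated with less RNA; default 5.
#' @param missing_frac_limit a lane with at least this fraction of its
#'   fusion probes missing is not interpretable; default 0.5.
#' @param reflex when `TRUE`, a negative first-tube (HEME1) lane carries a
#'   recommendation to reflex-test the second tube.
#' @export
call_config <- function(pos_floor = 1000, ladder_tolerance = 1.5,
                        neg_ceiling = 50, check_neg_controls = TRUE,
                        high_background_k = 5, missing_frac_limit = 0.5,
                        reflex = FALSE) {
  stopifnot(pos_floor > 0, ladder_tolerance >= 1, neg_ceiling >= 0,
            high_background_k >= 1, missing_frac_limit > 0,
            missing_frac_limit <= 1)
  structure(list(pos_floor = pos_floor, ladder_tolerance = ladder_tolerance,
                 neg_ceiling = neg_ceiling,
                 check_neg_controls = isTRUE(check_neg_controls),
                 high_background_k = high_background_k,
                 missing_frac_limit = missing_frac_limit,
                 reflex = isTRUE(reflex)),
            class = "call_config")
}

#' Assess the internal assay controls of one lane
#'
#' The POS_A-F controls are spiked into the hybridization at a descending
#' concentration ladder and the NEG_A-F controls are absent; together they
#' gauge assay chemistry independent of the sample. The ladder passes when
#' its top control reaches `pos_floor` and counts decay down the ladder
#' (each step at most `ladder_tolerance` times its predecessor); the
#' background check passes when the mean NEG count stays at or below
#' `neg_ceiling`.
#'
#' @param sample a [sample_counts()].
#' @param manifest a [panel_manifest()] declaring at least 4 POS controls
#'   in ladder order and at least 1 NEG control.
#' @param config a [call_config()].
#' @return An `assay_qc`: `passed`, `pos_ladder_ok`, `neg_background_ok`,
#'   `reasons` (one entry per failed check).
#' @export
assess_assay_controls <- function(sample, manifest, config = call_config()) {
  stopifnot(inherits(sample, "sample_counts"), inherits(manifest, "panel_manifest"))
  pos_ids <- manifest$pos_control_ids
  neg_ids <- manifest$neg_control_ids
  if (length(pos_ids) < 4L || length(neg_ids) < 1L) {
    stop_fc("manifest must declare >= 4 POS controls and >= 1 NEG control",
            class = "qc_error")
  }
  pos <- as.numeric(sample$counts[pos_ids])
  neg <- as.numeric(sample$counts[neg_ids])
  reasons <- character(0)

  pos_ok <- TRUE
  if (is.na(pos[[1L]])) {
    pos_ok <- FALSE
    reasons <- c(reasons, "uninterpretable control: top positive control missing")
  } else {
    if (pos[[1L]] < config$pos_floor) {
      pos_ok <- FALSE
      reasons <- c(reasons, sprintf(
        "positive control ladder collapsed: top control %s = %d below floor %g",
        pos_ids[[1L]], as.integer(pos[[1L]]), config$pos_floor))
    }
    obs <- which(!is.na(pos))
    if (length(obs) >= 2L) {
      steps <- pos[obs]
      rising <- steps[-1L] > config$ladder_tolerance * steps[-length(steps)]
      if (any(rising)) {
        pos_ok <- FALSE
        reasons <- c(reasons, sprintf(
          "positive control ladder collapsed: count rises at %s",
          paste(pos_ids[obs][-1L][rising], collapse = ", ")))
      }
    }
  }

  neg_ok <- TRUE
  if (config$check_neg_controls) {
    neg_mean <- mean(neg, na.rm = TRUE)
    if (is.nan(neg_mean) || neg_mean > config$neg_ceiling) {
      neg_ok <- FALSE
      reasons <- c(reasons, sprintf(
        "negative control background high: mean %s above ceiling %g",
        if (is.nan(neg_mean)) "not evaluable" else format(round(neg_mean, 1)),
        config$neg_ceiling))
    }
  }

  structure(list(passed = pos_ok && neg_ok, pos_ladder_ok = pos_ok,
                 neg_background_ok = neg_ok, reasons = reasons),
            class = "assay_qc")
}

#' Assess RNA quality from housekeeping probes
#'
#' A housekeeping probe passes when its count is strictly above its
#' calibrated threshold ("above the cutoff" is read literally: a count
#' equal to the threshold fails). A missing count is evaluable and failed —
#' the conservative reading. The lane's RNA is adequate when at least 3 of
#' the 5 housekeeping probes pass; only adequate lanes may be called
#' fusion-negative.
#'
#' @param sample a [sample_counts()].
#' @param calib a [calibration_table()] carrying housekeeping thresholds.
#' @param manifest a [panel_manifest()].
#' @return An `rna_qc`: `n_pass`, `n_evaluable`, `adequate`, `per_probe`
#'   (data.frame probe_id/count/threshold/pass).
#' @export
assess_rna_quality <- function(sample, calib, manifest) {
  stopifnot(inherits(sample, "sample_counts"),
            inherits(calib, "calibration_table"),
            inherits(manifest, "panel_manifest"))
  hk_ids <- probe_ids(manifest, "HOUSEKEEPING")
  thr <- calib$housekeeping$hk_threshold[match(hk_ids, calib$housekeeping$probe_id)]
  if (length(hk_ids) == 0L || all(is.na(thr))) {
    stop_fc("calibration carries no housekeeping thresholds; cannot assess RNA quality",
            class = "qc_error")
  }
  cnt <- as.numeric(sample$counts[hk_ids])
  evaluable <- !is.na(thr)
  pass <- evaluable & !is.na(cnt) & cnt > thr
  per_probe <- data.frame(probe_id = hk_ids, count = cnt, threshold = thr,
                          pass = pass, stringsAsFactors = FALSE)
  n_pass <- sum(pass)
  structure(list(n_pass = n_pass, n_evaluable = sum(evaluable),
                 adequate = n_pass >= 3L, per_probe = per_probe),
            class = "rna_qc")
}

#' @export
print.assay_qc <- function(x, ...) {
  cat(sprintf("<assay_qc> %s (ladder %s, background %s)\n",
              if (x$passed) "PASS" else "FAIL",
              if (x$pos_ladder_ok) "ok" else "collapsed",
              if (x$neg_background_ok) "ok" else "high"))
  for (r in x$reasons) cat("  - ", r, "\n", sep = "")
  invisible(x)
}

#' @export
print.rna_qc <- function(x, ...) {
  cat(sprintf("<rna_qc> %d/%d housekeeping pass -> %s\n", x$n_pass,
              x$n_evaluable, if (x$adequate) "adequate" else "inadequate"))
  invisible(x)
}
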