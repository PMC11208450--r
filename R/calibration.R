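#' Estimate per-probe background and positivity cutoffs
#'
#' For each fusion probe, background counts are averaged over samples known
#' to be negative for that fusion; the positivity cutoff is the mean plus 5
#' sample standard deviations (n-1 denominator) and the review cutoff the
#' mean plus 3. Missing counts are excluded per probe. A probe with fewer
#' than two usable values is flagged uncalibrated rather than given a
#' fabricated cutoff.
#'
#' @param negatives list of [sample_counts()] from fusion-negative samples
#'   (at least 2).
#' @param manifest a [panel_manifest()].
#' @param exclude optional data.frame `(sample_id, probe_id)` masking
#'   individual sample/probe pairs — use it to leave a sample out of the
#'   background of the one fusion it carries while keeping it for all
#'   others.
#' @param instrument_id recorded on the output table.
#' @return A [calibration_table()] (housekeeping thresholds not set; see
#'   [derive_housekeeping_thresholds()]).
#' @export
estimate_background <- function(negatives, manifest, exclude = NULL,
                                instrument_id = NULL) {
  stopifnot(inherits(manifest, "panel_manifest"))
  if (length(negatives) < 2L) {
    stop_fc("background estimation needs at least 2 negative samples",
            class = "calibration_error")
  }
  fids <- probe_ids(manifest, "FUSION")
  rows <- lapply(fids, function(pid) {
    vals <- vapply(negatives, function(s) {
      v <- s$counts[[pid]] %||% NA_integer_
      if (!is.null(exclude) &&
          any(exclude$sample_id == s$sample_id & exclude$probe_id == pid)) {
        v <- NA_integer_
      }
      as.numeric(v)
    }, numeric(1))
    vals <- vals[!is.na(vals)]
    n <- length(vals)
    if (n < 2L) {
      data.frame(probe_id = pid, bg_mean = NA_real_, bg_sd = NA_real_,
                 cut3 = NA_real_, cut5 = NA_real_, n_negatives = n,
                 uncalibrated = TRUE, stringsAsFactors = FALSE)
    } else {
      m <- mean(vals)
      s <- stats::sd(vals)
      data.frame(probe_id = pid, bg_mean = m, bg_sd = s,
                 cut3 = m + 3 * s, cut5 = m + 5 * s, n_negatives = n,
                 uncalibrated = FALSE, stringsAsFactors = FALSE)
    }
  })
  calibration_table(do.call(rbind, rows), instrument_id = instrument_id)
}

#' Derive housekeeping pass thresholds from RNA-adequate samples
#'
#' The deployed templates ship fixed housekeeping cutoffs; when a site
#' needs to derive its own, this helper takes a cohort judged RNA-adequate
#' by an external criterion and sets each housekeeping threshold at a lower
#' quantile of the observed counts, so that adequate RNA comfortably clears
#' it.
#'
#' @param adequate_samples list of [sample_counts()] (at least 5) deemed
#'   RNA-adequate.
#' @param manifest a [panel_manifest()].
#' @param quantile lower quantile in (0, 0.5]; default 0.05.
#' @param calib optional [calibration_table()] to attach the thresholds to;
#'   otherwise a housekeeping-only table is returned.
#' @return A [calibration_table()] carrying the thresholds.
#' @export
derive_housekeeping_thresholds <- function(adequate_samples, manifest,
                                           quantile = 0.05, calib = NULL) {
  if (!is.numeric(quantile) || length(quantile) != 1L ||
      quantile <= 0 || quantile > 0.5) {
    stop_fc("quantile must lie in (0, 0.5]", class = "calibration_error")
  }
  if (length(adequate_samples) < 5L) {
    stop_fc("housekeeping threshold derivation needs at least 5 adequate samples",
            class = "calibration_error")
  }
  hk_ids <- probe_ids(manifest, "HOUSEKEEPING")
  thr <- vapply(hk_ids, function(pid) {
    vals <- vapply(adequate_samples,
                   function(s) as.numeric(s$counts[[pid]] %||% NA_integer_),
                   numeric(1))
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L) return(NA_real_)
    unname(stats::quantile(vals, probs = quantile))
  }, numeric(1))
  hk <- data.frame(probe_id = hk_ids, hk_threshold = unname(thr),
                   stringsAsFactors = FALSE)
  if (is.null(calib)) {
    calibration_table(data.frame(probe_id = character(0)), housekeeping = hk)
  } else {
    calibration_table(calib$fusion, housekeeping = hk,
                      instrument_id = calib$instrument_id)
  }
}

#' Recalibrate cutoffs for a local instrument
#'
#' Instruments differ in background level (the SSA deployment saw lower
#' backgrounds than the validation instrument), so cutoffs are recomputed
#' from locally run fusion-negative samples. Probes that cannot be
#' calibrated locally (fewer than two usable counts) inherit the base
#' cutoffs and are flagged `inherited`.
#'
#' @param base the validation-instrument [calibration_table()].
#' @param local_negatives list of [sample_counts()] from one local
#'   instrument; if empty, `base` is returned unchanged with a notice.
#' @param manifest a [panel_manifest()].
#' @return A [calibration_table()] for the local instrument; housekeeping
#'   thresholds are carried over from `base`.
#' @export
recalibrate <- function(base, local_negatives, manifest) {
  stopifnot(inherits(base, "calibration_table"))
  if (length(local_negatives) == 0L) {
    message("no local negatives supplied; keeping base calibration")
    return(base)
  }
  ids <- unique(vapply(local_negatives,
                       function(s) s$instrument_id %||% NA_character_,
                       character(1)))
  ids <- ids[!is.na(ids)]
  if (length(ids) > 1L) {
    stop_fc("local negatives span multiple instruments: %s",
            paste(ids, collapse = ", "), class = "calibration_error")
  }
  local <- estimate_background(local_negatives, manifest,
                               instrument_id = if (length(ids)) ids else NULL)
  fus <- local$fusion
  fallback <- fus$uncalibrated
  if (any(fallback)) {
    idx <- match(fus$probe_id[fallback], base$fusion$probe_id)
    for (col in c("bg_mean", "bg_sd", "cut3", "cut5", "n_negatives")) {
      fus[[col]][fallback] <- base$fusion[[col]][idx]
    }
    fus$uncalibrated[fallback] <- base$fusion$uncalibrated[idx]
    fus$inherited[fallback] <- TRUE
  }
  calibration_table(fus, housekeeping = base$housekeeping,
                    instrument_id = local$instrument_id)
}
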