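# Small in-code panel + fixture accessors shared across tests.

tiny_manifest <- function(n_fusion = 4) {
  fus_ids <- sprintf("GENE%d(ex1):PART%d(ex2)", seq_len(n_fusion),
                     seq_len(n_fusion))
  probes <- data.frame(
    probe_id = c(paste0("POS_", LETTERS[1:6]), paste0("NEG_", LETTERS[1:6]),
                 fus_ids, c("B2M", "EEF2", "GUSB", "PGK1", "TBP")),
    kind = c(rep("POS_CONTROL", 6), rep("NEG_CONTROL", 6),
             rep("FUSION", n_fusion), rep("HOUSEKEEPING", 5)),
    fusion_id = c(rep(NA, 12),
                  sprintf("GENE%d::PART%d", seq_len(n_fusion),
                          seq_len(n_fusion)),
                  rep(NA, 5)),
    tube = c(rep(NA, 12), rep("HEME1", n_fusion), rep(NA, 5)),
    lineages = c(rep(NA, 12),
                 rep(c("B-ALL", "AML"), length.out = n_fusion),
                 rep(NA, 5)),
    stringsAsFactors = FALSE)
  panel_manifest(probes, name = "tiny")
}

fixture_sample <- function(fx, id) {
  ids <- vapply(fx$samples, `[[`, "", "sample_id")
  fx$samples[[match(id, ids)]]
}

# Independent naive re-scan of one probe against its cutoffs; deliberately
# scalar if/else, no shared code with score_probes().
oracle_probe_status <- function(count, cut3, cut5, calibrated = TRUE) {
  if (!calibrated || is.na(cut3) || is.na(cut5)) return("UNCALIBRATED")
  if (is.na(count)) return("MISSING")
  if (count > cut5) return("POSITIVE")
  if (count > cut3) return("REVIEW")
  "NEGATIVE"
}

# Lane with explicit control/housekeeping/fusion counts over a manifest.
make_lane <- function(manifest, id = "L1", fusion = NULL,
                      pos = c(30000, 9000, 2700, 800, 240, 70),
                      neg = rep(5, 6),
                      hk = c(30000, 10000, 800, 3000, 200),
                      tube = "HEME1") {
  cnt <- stats::setNames(rep(NA_integer_, nrow(manifest$probes)),
                         manifest$probes$probe_id)
  cnt[manifest$pos_control_ids] <- as.integer(pos)
  cnt[manifest$neg_control_ids] <- as.integer(neg)
  cnt[probe_ids(manifest, "HOUSEKEEPING")] <- as.integer(hk)
  fus_ids <- probe_ids(manifest, "FUSION")
  cnt[fus_ids] <- 5L
  if (!is.null(fusion)) cnt[names(fusion)] <- as.integer(fusion)
  sample_counts(id, cnt, tube = tube)
}
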