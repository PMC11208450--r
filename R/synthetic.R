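#' @title Synthetic run generation
#' @description Simulates complete nCounter fusion-panel runs with known
#'   ground truth, so calibration, QC, calling and reporting can be
#'   exercised end to end without patient data. Background counts are
#'   negative binomial (real hybridization background is overdispersed
#'   relative to Poisson; the dispersion parameter recovers Poisson as a
#'   limit), fusion signal is a tight high-count distribution, housekeeping
#'   and signal means scale with a per-lane RNA quality factor, and
#'   collapsed-control lanes have their POS ladder drawn at negative-
#'   control level.
#' @name synthetic_data
NULL

LANE_ROLES <- c("background", "positive", "degraded", "failed_assay",
                "high_background")

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Build a lane plan
#'
#' @param background,positive,degraded,failed_assay,high_background number
#'   of lanes of each role.
#' @return data.frame `(sample_id, role, q)` usable as the `lanes` argument
#'   of [synthetic_spec()]. Degraded lanes get the degraded default RNA
#'   quality factor at spec construction.
#' @export
lane_plan <- function(background = 0, positive = 0, degraded = 0,
                      failed_assay = 0, high_background = 0) {
  roles <- rep(LANE_ROLES, times = c(background, positive, degraded,
                                     failed_assay, high_background))
  data.frame(sample_id = sprintf("S%03d", seq_along(roles)), role = roles,
             q = NA_real_, stringsAsFactors = FALSE)
}

#' Generative parameters of a simulated run
#'
#' Defaults emulate the count regimes of a typical deployed Heme 1 run:
#' fusion-probe background around 8 counts with negative-binomial
#' dispersion `size = 10` (variance `mu + mu^2/size`), housekeeping means
#' spanning the observed dynamic range (TBP ~200 up to B2M ~30000), a POS
#' control ladder decaying by ~0.3 per step from 30000 counts, and
#' negative controls around 6 counts.
#'
#' @param manifest a [panel_manifest()].
#' @param lanes data.frame `(sample_id, role, q)`; see [lane_plan()]. `q`
#'   is the per-lane RNA quality factor in (0, 1] multiplying housekeeping
#'   and fusion-signal means; `NA` takes the role default (1, or
#'   `degraded_q` for degraded lanes).
#' @param spikes data.frame `(sample_id, fusion_id, fold_over_cut5)`; each
#'   row plants one fusion at `fold_over_cut5` times the true positivity
#'   cutoff of one of its probes. Positive-role lanes without an explicit
#'   spike get one fusion drawn at random at fold `auto_spike_fold`.
#' @param bg_mean fusion-probe background mean; scalar or named per probe.
#' @param bg_size negative-binomial size of background (smaller = more
#'   overdispersed).
#' @param hk_mean housekeeping means at full RNA quality; scalar or named
#'   per housekeeping probe (default: a realistic 5-gene ladder).
#' @param hk_size,signal_size,pos_size negative-binomial sizes for
#'   housekeeping counts, spiked fusion signal (tight: high-count signal),
#'   and assay controls.
#' @param pos_base,pos_decay POS ladder: top-control mean and per-step
#'   decay factor in (0, 1).
#' @param neg_mean negative-control (and collapsed-ladder) mean.
#' @param hb_factor background multiplier for high-background lanes.
#' @param degraded_q default RNA quality factor of degraded lanes.
#' @param auto_spike_fold fold used for auto-spiked positive lanes.
#' @param hk_threshold_frac the reference calibration sets each
#'   housekeeping threshold at this fraction of its full-quality mean.
#' @param seed integer RNG seed; the whole run is reproducible from it.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(manifest, lanes = lane_plan(background = 12),
                           spikes = NULL,
                           bg_mean = 8, bg_size = 10,
                           hk_mean = c(B2M = 30000, EEF2 = 10000, GUSB = 800,
                                       PGK1 = 3000, TBP = 200),
                           hk_size = 10, signal_size = 500, pos_size = 50,
                           pos_base = 30000, pos_decay = 0.3, neg_mean = 6,
                           hb_factor = 8, degraded_q = 0.1,
                           auto_spike_fold = 10, hk_threshold_frac = 0.25,
                           seed = 1L) {
  stopifnot(inherits(manifest, "panel_manifest"))
  lanes <- as.data.frame(lanes, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "role") %in% names(lanes)))
  if (is.null(lanes$q)) lanes$q <- NA_real_
  bad_role <- setdiff(lanes$role, LANE_ROLES)
  if (length(bad_role) > 0L) {
    stop_fc("unknown lane role: %s", paste(bad_role, collapse = ", "),
            class = "synthetic_error")
  }
  lanes$q[is.na(lanes$q)] <-
    ifelse(lanes$role[is.na(lanes$q)] == "degraded", degraded_q, 1)
  if (any(lanes$q <= 0 | lanes$q > 1)) {
    stop_fc("rna quality factor q must lie in (0, 1]", class = "synthetic_error")
  }
  if (!(pos_decay > 0 && pos_decay < 1)) {
    stop_fc("pos_decay must lie in (0, 1)", class = "synthetic_error")
  }
  fus_ids <- probe_ids(manifest, "FUSION")
  fusion_ids <- unique(fusion_id_of(manifest, fus_ids))
  if (!is.null(spikes)) {
    spikes <- as.data.frame(spikes, stringsAsFactors = FALSE)
    stopifnot(all(c("sample_id", "fusion_id", "fold_over_cut5") %in%
                    names(spikes)))
    unknown <- setdiff(spikes$fusion_id, fusion_ids)
    if (length(unknown) > 0L) {
      stop_fc("spike names fusion(s) absent from the manifest: %s",
              paste(unknown, collapse = ", "), class = "synthetic_error")
    }
    if (any(spikes$fold_over_cut5 <= 0)) {
      stop_fc("fold_over_cut5 must be positive", class = "synthetic_error")
    }
  } else {
    spikes <- data.frame(sample_id = character(0), fusion_id = character(0),
                         fold_over_cut5 = numeric(0), stringsAsFactors = FALSE)
  }
  expand <- function(x, ids) {
    if (length(x) == 1L && is.null(names(x))) {
      return(stats::setNames(rep(as.numeric(x), length(ids)), ids))
    }
    miss <- setdiff(ids, names(x))
    if (length(miss) > 0L) {
      stop_fc("per-probe parameter lacks entries for: %s",
              paste(miss, collapse = ", "), class = "synthetic_error")
    }
    stats::setNames(as.numeric(x[ids]), ids)
  }
  structure(list(
    manifest = manifest, lanes = lanes, spikes = spikes,
    bg_mean = expand(bg_mean, fus_ids), bg_size = bg_size,
    hk_mean = expand(hk_mean, probe_ids(manifest, "HOUSEKEEPING")),
    hk_size = hk_size, signal_size = signal_size, pos_size = pos_size,
    pos_base = pos_base, pos_decay = pos_decay, neg_mean = neg_mean,
    hb_factor = hb_factor, auto_spike_fold = auto_spike_fold,
    hk_threshold_frac = hk_threshold_frac, seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' True-moment calibration of a synthetic spec
#'
#' The calibration an infinitely large negative cohort would yield:
#' per-probe mean and SD from the generating negative binomial
#' (`sd = sqrt(mu + mu^2/size)`), cutoffs at mean + 3/5 SD, and
#' housekeeping thresholds at `hk_threshold_frac` of the full-quality
#' means. Used as ground truth in tests and as the reference against which
#' spikes are scaled.
#'
#' @param spec a [synthetic_spec()].
#' @return A [calibration_table()].
#' @export
reference_calibration <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  mu <- spec$bg_mean
  sd <- sqrt(mu + mu^2 / spec$bg_size)
  fus <- data.frame(probe_id = names(mu), bg_mean = unname(mu),
                    bg_sd = unname(sd), cut3 = unname(mu + 3 * sd),
                    cut5 = unname(mu + 5 * sd), n_negatives = NA_real_,
                    stringsAsFactors = FALSE)
  hk <- data.frame(probe_id = names(spec$hk_mean),
                   hk_threshold = unname(spec$hk_mean * spec$hk_threshold_frac),
                   stringsAsFactors = FALSE)
  calibration_table(fus, housekeeping = hk)
}

rnb <- function(n, mu, size) {
  out <- integer(n)
  pos <- mu > 0
  out[pos] <- stats::rnbinom(sum(pos), mu = mu[pos], size = size)
  out
}

#' Simulate a run from a synthetic spec
#'
#' Reproducible from the spec's seed: the same spec yields the same lanes.
#' Background fusion counts follow the spec's negative binomial; spiked
#' probes are drawn around `fold_over_cut5` times the true positivity
#' cutoff (every probe of the spiked fusion is elevated); degraded lanes
#' scale housekeeping and signal means by their quality factor `q`;
#' collapsed-assay lanes draw the whole POS ladder at negative-control
#' level; high-background lanes multiply the fusion background by
#' `hb_factor`.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `samples` (list of [sample_counts()]), `truth`
#'   (data.frame `sample_id`, `role`, `expected_status`, `spiked_fusions`,
#'   `q`) and `calibration` (the [reference_calibration()]).
#' @export
simulate_run <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  manifest <- spec$manifest
  ref <- reference_calibration(spec)
  fus_ids <- probe_ids(manifest, "FUSION")
  hk_ids <- probe_ids(manifest, "HOUSEKEEPING")
  pos_ids <- manifest$pos_control_ids
  neg_ids <- manifest$neg_control_ids
  fusion_of <- fusion_id_of(manifest, fus_ids)
  fusion_ids <- unique(fusion_of)
  cut5 <- stats::setNames(ref$fusion$cut5, ref$fusion$probe_id)
  ladder_mu <- spec$pos_base * spec$pos_decay^(seq_along(pos_ids) - 1L)

  with_seed(spec$seed, {
    samples <- vector("list", nrow(spec$lanes))
    spiked <- character(nrow(spec$lanes))
    for (i in seq_len(nrow(spec$lanes))) {
      sid <- spec$lanes$sample_id[[i]]
      role <- spec$lanes$role[[i]]
      q <- spec$lanes$q[[i]]

      bg_mu <- spec$bg_mean
      if (role == "high_background") bg_mu <- bg_mu * spec$hb_factor
      fus_cnt <- rnb(length(fus_ids), bg_mu, spec$bg_size)
      names(fus_cnt) <- fus_ids

      lane_spikes <- spec$spikes[spec$spikes$sample_id == sid, , drop = FALSE]
      if (role == "positive" && nrow(lane_spikes) == 0L) {
        lane_spikes <- data.frame(sample_id = sid,
                                  fusion_id = sample(fusion_ids, 1L),
                                  fold_over_cut5 = spec$auto_spike_fold,
                                  stringsAsFactors = FALSE)
      }
      for (k in seq_len(nrow(lane_spikes))) {
        probes <- fus_ids[fusion_of == lane_spikes$fusion_id[[k]]]
        mu <- lane_spikes$fold_over_cut5[[k]] * cut5[probes] * q
        fus_cnt[probes] <- rnb(length(probes), mu, spec$signal_size)
      }
      spiked[[i]] <- paste(unique(lane_spikes$fusion_id), collapse = ";")

      hk_cnt <- rnb(length(hk_ids), spec$hk_mean * q, spec$hk_size)
      names(hk_cnt) <- hk_ids

      pmu <- if (role == "failed_assay") rep(spec$neg_mean, length(pos_ids))
             else ladder_mu
      pos_cnt <- stats::setNames(rnb(length(pos_ids), pmu, spec$pos_size),
                                 pos_ids)
      neg_cnt <- stats::setNames(
        rnb(length(neg_ids), rep(spec$neg_mean, length(neg_ids)),
            spec$bg_size), neg_ids)

      all_ids <- manifest$probes$probe_id
      cnt <- stats::setNames(rep(NA_integer_, length(all_ids)), all_ids)
      cnt[names(pos_cnt)] <- pos_cnt
      cnt[names(neg_cnt)] <- neg_cnt
      cnt[names(fus_cnt)] <- fus_cnt
      cnt[names(hk_cnt)] <- hk_cnt
      samples[[i]] <- sample_counts(sid, cnt, tube = "HEME1",
                                    instrument_id = "SIM-001")
    }
    truth <- data.frame(
      sample_id = spec$lanes$sample_id, role = spec$lanes$role,
      expected_status = c(background = "NEGATIVE", positive = "POSITIVE",
                          degraded = "FAILED_RNA",
                          failed_assay = "FAILED_ASSAY",
                          high_background = "HIGH_BACKGROUND")[spec$lanes$role],
      spiked_fusions = spiked, q = spec$lanes$q,
      stringsAsFactors = FALSE, row.names = NULL)
    list(samples = samples, truth = truth, calibration = ref)
  })
}
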