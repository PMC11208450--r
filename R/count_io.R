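#' One lane of probe counts
#'
#' @param sample_id non-empty sample identifier (ids are opaque strings;
#'   `"24C"` is a valid id).
#' @param counts named integer vector, one element per probe; values are
#'   non-negative counts or `NA` for a missing/unparseable cell. `NA` is a
#'   real marker: it never coerces to 0 downstream.
#' @param rna_input_ng optional RNA input mass in nanograms.
#' @param instrument_id optional instrument identifier.
#' @param tube optional tube ("HEME1"/"HEME2").
#' @return A `sample_counts` object.
#' @export
sample_counts <- function(sample_id, counts, rna_input_ng = NULL,
                          instrument_id = NULL, tube = NULL) {
  sample_id <- as.character(sample_id)
  if (length(sample_id) != 1L || is.na(sample_id) || !nzchar(sample_id)) {
    stop_fc("sample_id must be a non-empty string", class = "counts_error")
  }
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop_fc("counts must be named by probe_id", class = "counts_error")
  }
  cnt <- counts
  if (any(!is.na(cnt) & (cnt < 0 | cnt != floor(cnt)))) {
    stop_fc("counts must be non-negative integers or NA", class = "counts_error")
  }
  storage.mode(cnt) <- "integer"
  if (!is.null(tube)) tube <- match.arg(tube, c("HEME1", "HEME2"))
  structure(
    list(sample_id = sample_id, counts = cnt,
         rna_input_ng = rna_input_ng, instrument_id = instrument_id,
         tube = tube),
    class = "sample_counts"
  )
}

#' @export
print.sample_counts <- function(x, ...) {
  cat(sprintf("<sample_counts '%s'> %d probes (%d missing)%s\n",
              x$sample_id, length(x$counts), sum(is.na(x$counts)),
              if (!is.null(x$tube)) paste0(", tube ", x$tube) else ""))
  invisible(x)
}

rcc_code_class <- function(probe_id, manifest = NULL) {
  if (!is.null(manifest)) {
    kind <- manifest$probes$kind[match(probe_id, manifest$probes$probe_id)]
    cls <- c(FUSION = "Endogenous", HOUSEKEEPING = "Housekeeping",
             POS_CONTROL = "Positive", NEG_CONTROL = "Negative")[kind]
    cls[is.na(cls)] <- "Endogenous"
    return(unname(cls))
  }
  ifelse(startsWith(probe_id, "POS_"), "Positive",
         ifelse(startsWith(probe_id, "NEG_"), "Negative", "Endogenous"))
}

#' Read and write nCounter RCC lane files
#'
#' RCC is the plain-text per-lane output of an nCounter run: bracket
#' delimited sections (`<Header>`, `<Sample_Attributes>`,
#' `<Lane_Attributes>`, `<Code_Summary>`), the last holding
#' `CodeClass,Name,Accession,Count` rows. Probe ids are taken from `Name`;
#' a non-numeric count becomes `NA` with a warning.
#'
#' @param path file path.
#' @return `read_rcc` returns a [sample_counts()].
#' @export
read_rcc <- function(path) {
  if (!file.exists(path)) stop_fc("RCC file not found: %s", path,
                                  class = "rcc_error")
  lines <- readLines(path, warn = FALSE)
  section_of <- function(name) {
    open <- which(lines == sprintf("<%s>", name))
    close <- which(lines == sprintf("</%s>", name))
    if (length(open) != 1L || length(close) != 1L || close < open) return(NULL)
    lines[seq(open + 1L, close - 1L)]
  }
  code <- section_of("Code_Summary")
  if (is.null(code)) {
    stop_fc("RCC file %s is missing its Code_Summary section", path,
            class = "rcc_error")
  }
  attrs <- function(name) {
    sec <- section_of(name)
    if (is.null(sec)) return(list())
    parts <- strsplit(sec, ",", fixed = TRUE)
    stats::setNames(lapply(parts, function(p) paste(p[-1L], collapse = ",")),
                    vapply(parts, `[[`, "", 1L))
  }
  samp_attrs <- attrs("Sample_Attributes")
  lane_attrs <- attrs("Lane_Attributes")

  tab <- utils::read.csv(text = code, stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = "character")
  if (!all(c("Name", "Count") %in% names(tab))) {
    stop_fc("RCC Code_Summary lacks Name/Count columns in %s", path,
            class = "rcc_error")
  }
  counts <- parse_count(tab$Count)
  bad <- attr(counts, "bad")
  if (length(bad) > 0L) {
    warning(sprintf("non-numeric Count for probe(s) %s in %s; set to MISSING",
                    paste(tab$Name[bad], collapse = ", "), basename(path)),
            call. = FALSE)
  }
  tube <- samp_attrs$GeneRLF
  if (!is.null(tube) && !tube %in% c("HEME1", "HEME2")) tube <- NULL
  rna <- suppressWarnings(as.numeric(samp_attrs$SampleInput %||% NA))
  scanner <- lane_attrs$ScannerID
  if (!is.null(scanner) && !nzchar(scanner)) scanner <- NULL
  sample_counts(
    sample_id = samp_attrs$ID %||% sub("\\.rcc$", "", basename(path), ignore.case = TRUE),
    counts = stats::setNames(as.integer(counts), tab$Name),
    rna_input_ng = if (is.na(rna)) NULL else rna,
    instrument_id = scanner,
    tube = tube
  )
}

#' @rdname read_rcc
#' @param sample a [sample_counts()].
#' @param manifest optional [panel_manifest()] used to emit proper
#'   `CodeClass` values (Positive/Negative/Housekeeping/Endogenous);
#'   without it the class is inferred from the `POS_`/`NEG_` name prefix.
#' @export
write_rcc <- function(sample, path, manifest = NULL) {
  stopifnot(inherits(sample, "sample_counts"))
  cls <- rcc_code_class(names(sample$counts), manifest)
  cnt <- ifelse(is.na(sample$counts), "F", as.character(sample$counts))
  lines <- c(
    "<Header>", "FileVersion,1.7", "SoftwareVersion,4.0.0.3", "</Header>",
    "<Sample_Attributes>",
    paste0("ID,", sample$sample_id),
    paste0("GeneRLF,", sample$tube %||% ""),
    paste0("SampleInput,", sample$rna_input_ng %||% ""),
    "</Sample_Attributes>",
    "<Lane_Attributes>",
    "ID,1",
    paste0("ScannerID,", sample$instrument_id %||% ""),
    "</Lane_Attributes>",
    "<Code_Summary>",
    "CodeClass,Name,Accession,Count",
    sprintf("%s,%s,NA,%s", cls, names(sample$counts), cnt),
    "</Code_Summary>"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a wide count table (probes x samples)
#'
#' The layout mirrors the run interpretation template: first column probe
#' labels, one column per sample, samples in column order. Cutoff or
#' annotation columns appended to the right of the samples are dropped via
#' `ignore_cols`. Cells accept thousands separators; unparseable cells
#' (e.g. `"F"`) become `NA`.
#'
#' @param path CSV or TSV file (delimiter sniffed from the header line).
#' @param manifest optional [panel_manifest()]; probe labels absent from it
#'   are kept under their literal id with a warning.
#' @param ignore_cols column names to drop (cutoffs, interpretation notes).
#' @param tube,instrument_id optional annotations applied to every lane.
#' @return list of [sample_counts()], one per sample column, in column
#'   order.
#' @export
read_count_table <- function(path, manifest = NULL, ignore_cols = character(),
                             tube = NULL, instrument_id = NULL) {
  df <- read_delim_kv(path)
  probe_col <- names(df)[[1L]]
  sample_ids <- names(df)[-1L]
  sample_ids <- sample_ids[!sample_ids %in% ignore_cols]
  if (anyDuplicated(sample_ids)) {
    stop_fc("duplicate sample column names: %s",
            paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
            class = "counts_error")
  }
  probes <- df[[probe_col]]
  if (anyDuplicated(probes)) {
    stop_fc("duplicate probe labels: %s",
            paste(unique(probes[duplicated(probes)]), collapse = ", "),
            class = "counts_error")
  }
  if (!is.null(manifest)) {
    unknown <- setdiff(probes, manifest$probes$probe_id)
    if (length(unknown) > 0L) {
      warning(sprintf("probe label(s) not in manifest, retained literally: %s",
                      paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  lapply(sample_ids, function(sid) {
    cnt <- parse_count(df[[sid]])
    sample_counts(sid, stats::setNames(as.integer(cnt), probes),
                  tube = tube, instrument_id = instrument_id)
  })
}

#' @rdname read_count_table
#' @param samples list of [sample_counts()] sharing one probe set.
#' @param sep field delimiter (`"\t"` or `","`).
#' @export
write_count_table <- function(samples, path, sep = "\t") {
  stopifnot(length(samples) > 0L)
  probes <- names(samples[[1L]]$counts)
  df <- data.frame(probe_id = probes, check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (s in samples) {
    stopifnot(identical(names(s$counts), probes))
    df[[s$sample_id]] <- ifelse(is.na(s$counts), "F", as.character(s$counts))
  }
  write_delim_kv(df, path, sep = sep)
  invisible(path)
}

#' Per-probe calibration: background moments, cutoffs, housekeeping
#' thresholds
#'
#' Holds, for each fusion probe, the background mean and sample SD over
#' fusion-negative samples and the derived review (`cut3 = mean + 3 SD`)
#' and positivity (`cut5 = mean + 5 SD`) cutoffs; and for each housekeeping
#' probe the minimum count regarded as adequate RNA. A table may carry
#' cutoffs without moments (printed templates ship only the cutoffs); such
#' rows skip the moment-consistency check.
#'
#' @param fusion data.frame with columns `probe_id`, `bg_mean`, `bg_sd`,
#'   `cut3`, `cut5`, `n_negatives`, and optional logicals `uncalibrated`,
#'   `inherited`.
#' @param housekeeping data.frame with columns `probe_id`, `hk_threshold`,
#'   or `NULL`.
#' @param instrument_id instrument the calibration belongs to, if known.
#' @param tol absolute tolerance for the `cut = mean + k sd` consistency
#'   check; the default admits integer-rounded cutoffs.
#' @return A `calibration_table`.
#' @export
calibration_table <- function(fusion, housekeeping = NULL,
                              instrument_id = NULL, tol = 0.51) {
  fusion <- as.data.frame(fusion, stringsAsFactors = FALSE)
  num_cols <- c("bg_mean", "bg_sd", "cut3", "cut5")
  for (col in c(num_cols, "n_negatives")) {
    if (is.null(fusion[[col]])) fusion[[col]] <- rep(NA_real_, nrow(fusion))
    fusion[[col]] <- as.numeric(fusion[[col]])
  }
  for (col in c("uncalibrated", "inherited")) {
    if (is.null(fusion[[col]])) fusion[[col]] <- rep(FALSE, nrow(fusion))
    fusion[[col]] <- as.logical(fusion[[col]])
    fusion[[col]][is.na(fusion[[col]])] <- FALSE
  }
  rownames(fusion) <- NULL
  fusion$uncalibrated <- fusion$uncalibrated | is.na(fusion$cut5) | is.na(fusion$cut3)
  if (anyDuplicated(fusion$probe_id)) {
    stop_fc("duplicate probe_id in calibration", class = "calibration_error")
  }
  if (any(!is.na(fusion$bg_sd) & fusion$bg_sd < 0)) {
    stop_fc("bg_sd must be non-negative", class = "calibration_error")
  }
  both <- !is.na(fusion$cut3) & !is.na(fusion$cut5)
  if (any(both & fusion$cut5 < fusion$cut3)) {
    bad <- fusion$probe_id[both & fusion$cut5 < fusion$cut3]
    stop_fc("cut5 below cut3 for probe(s): %s", paste(bad, collapse = ", "),
            class = "calibration_error")
  }
  moments <- both & !is.na(fusion$bg_mean) & !is.na(fusion$bg_sd)
  bad3 <- moments & abs(fusion$cut3 - (fusion$bg_mean + 3 * fusion$bg_sd)) > tol
  bad5 <- moments & abs(fusion$cut5 - (fusion$bg_mean + 5 * fusion$bg_sd)) > tol
  if (any(bad3 | bad5)) {
    stop_fc("cutoffs inconsistent with background moments for probe(s): %s",
            paste(fusion$probe_id[bad3 | bad5], collapse = ", "),
            class = "calibration_error")
  }
  if (!is.null(housekeeping)) {
    housekeeping <- as.data.frame(housekeeping, stringsAsFactors = FALSE)
    housekeeping$hk_threshold <- as.numeric(housekeeping$hk_threshold)
    rownames(housekeeping) <- NULL
  } else {
    housekeeping <- data.frame(probe_id = character(0),
                               hk_threshold = numeric(0),
                               stringsAsFactors = FALSE)
  }
  structure(list(fusion = fusion, housekeeping = housekeeping,
                 instrument_id = instrument_id),
            class = "calibration_table")
}

#' @export
print.calibration_table <- function(x, ...) {
  cat(sprintf("<calibration_table> %d fusion probes (%d uncalibrated), %d housekeeping thresholds%s\n",
              nrow(x$fusion), sum(x$fusion$uncalibrated),
              nrow(x$housekeeping),
              if (!is.null(x$instrument_id))
                paste0(", instrument ", x$instrument_id) else ""))
  invisible(x)
}

#' Read / write calibration files
#'
#' Columnar text format, one row per probe: `probe_id`, `role`
#' (fusion/housekeeping), `bg_mean`, `bg_sd`, `cut3`, `cut5`,
#' `hk_threshold`, `n_negatives`, `uncalibrated`, `inherited`; an
#' `#instrument_id` comment line above the header. Reading re-validates the
#' cutoff invariants (`cut5 >= cut3`, consistency with moments when both
#' are present).
#'
#' @param path file path.
#' @export
read_calibration <- function(path) {
  kv <- read_kv_header(path)
  df <- read_delim_kv(path, sep = "\t")
  fus <- df[df$role == "fusion", , drop = FALSE]
  hk <- df[df$role == "housekeeping", , drop = FALSE]
  calibration_table(
    fusion = fus[c("probe_id", "bg_mean", "bg_sd", "cut3", "cut5",
                   "n_negatives", "uncalibrated", "inherited")],
    housekeeping = if (nrow(hk) > 0L) hk[c("probe_id", "hk_threshold")],
    instrument_id = kv$instrument_id %||% NULL
  )
}

#' @rdname read_calibration
#' @param calib a [calibration_table()].
#' @export
write_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "calibration_table"))
  fus <- calib$fusion
  fus$role <- "fusion"
  fus$hk_threshold <- NA_real_
  hk <- calib$housekeeping
  cols <- c("probe_id", "role", "bg_mean", "bg_sd", "cut3", "cut5",
            "hk_threshold", "n_negatives", "uncalibrated", "inherited")
  if (nrow(hk) > 0L) {
    hk$role <- "housekeeping"
    for (col in setdiff(cols, names(hk))) hk[[col]] <- NA
    df <- rbind(fus[cols], hk[cols])
  } else {
    df <- fus[cols]
  }
  # full precision survives the round-trip
  for (col in c("bg_mean", "bg_sd", "cut3", "cut5", "hk_threshold")) {
    df[[col]] <- ifelse(is.na(df[[col]]), NA_character_,
                        sprintf("%.17g", as.numeric(df[[col]])))
  }
  write_delim_kv(df, path, kv = list(instrument_id = calib$instrument_id))
  invisible(path)
}
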