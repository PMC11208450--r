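#' @title Panel manifests
#' @description The panel manifest is the probe universe of one fusion assay
#'   tube: fusion probe sets (each spanning one breakpoint of a chimeric
#'   transcript), the five housekeeping probes used for RNA-quality gating,
#'   the POS_A-F/NEG_A-F internal assay controls, and the map from each
#'   fusion to the leukemia lineages it is associated with.
#' @name panel_manifest
NULL

#' Lineage labels recognised by the concordance check
#'
#' Fusions associated with entities outside the acute/chronic leukemia
#' immunophenotypes (lymphoma, ALCL, histiocytosis, ...) map to `"other"`.
#' @export
LINEAGE_LEVELS <- c("B-ALL", "T-ALL", "AML", "CML", "MPAL", "other")

PROBE_KINDS <- c("FUSION", "HOUSEKEEPING", "POS_CONTROL", "NEG_CONTROL")

#' Construct a panel manifest
#'
#' @param probes data.frame with columns `probe_id`, `kind` (one of FUSION,
#'   HOUSEKEEPING, POS_CONTROL, NEG_CONTROL), `fusion_id` (required for
#'   FUSION probes, `NA` otherwise), `tube` ("HEME1"/"HEME2", `NA` for
#'   probes present in both tubes, e.g. controls) and `lineages`
#'   (semicolon-separated lineage labels, FUSION probes only).
#'   POS controls must appear in titration-ladder order, highest spiked
#'   concentration first: QC relies on that ordering.
#' @param name manifest name.
#' @return A `panel_manifest`: the validated probe table plus derived
#'   `lineage_map` (fusion_id -> character vector of lineages),
#'   `housekeeping_ids`, `pos_control_ids` (ladder order) and
#'   `neg_control_ids`.
#' @export
panel_manifest <- function(probes, name = "panel") {
  required <- c("probe_id", "kind", "fusion_id", "tube", "lineages")
  probes <- as.data.frame(probes)
  missing_cols <- setdiff(required, names(probes))
  for (col in missing_cols) probes[[col]] <- rep(NA_character_, nrow(probes))
  probes <- as.data.frame(probes)[required]
  for (col in required) {
    probes[[col]] <- as.character(probes[[col]])
    probes[[col]][!is.na(probes[[col]]) & probes[[col]] == ""] <- NA_character_
  }

  dup <- probes$probe_id[duplicated(probes$probe_id)]
  if (length(dup) > 0L) {
    stop_fc("duplicate probe_id in manifest: %s",
            paste(unique(dup), collapse = ", "), class = "manifest_error")
  }
  bad_kind <- setdiff(probes$kind, PROBE_KINDS)
  if (length(bad_kind) > 0L) {
    stop_fc("unknown probe kind: %s", paste(bad_kind, collapse = ", "),
            class = "manifest_error")
  }
  is_fusion <- probes$kind == "FUSION"
  if (any(is_fusion & is.na(probes$fusion_id))) {
    stop_fc("fusion probe without fusion_id: %s",
            paste(probes$probe_id[is_fusion & is.na(probes$fusion_id)],
                  collapse = ", "), class = "manifest_error")
  }
  if (any(!is_fusion & !is.na(probes$fusion_id))) {
    stop_fc("non-fusion probe carries a fusion_id: %s",
            paste(probes$probe_id[!is_fusion & !is.na(probes$fusion_id)],
                  collapse = ", "), class = "manifest_error")
  }

  lineage_map <- list()
  for (i in which(is_fusion & !is.na(probes$lineages))) {
    fid <- probes$fusion_id[[i]]
    lin <- strsplit(probes$lineages[[i]], ";", fixed = TRUE)[[1L]]
    lin <- trimws(lin[nzchar(trimws(lin))])
    bad <- setdiff(lin, LINEAGE_LEVELS)
    if (length(bad) > 0L) {
      stop_fc("unknown lineage label '%s' for probe %s", bad[[1L]],
              probes$probe_id[[i]], class = "manifest_error")
    }
    lineage_map[[fid]] <- sort(unique(c(lineage_map[[fid]], lin)))
  }

  structure(
    list(
      name = name,
      probes = probes,
      lineage_map = lineage_map,
      housekeeping_ids = probes$probe_id[probes$kind == "HOUSEKEEPING"],
      pos_control_ids = probes$probe_id[probes$kind == "POS_CONTROL"],
      neg_control_ids = probes$probe_id[probes$kind == "NEG_CONTROL"]
    ),
    class = "panel_manifest"
  )
}

#' Read / write a panel manifest
#'
#' The manifest file is a UTF-8 tab-separated table with a header row and
#' columns `probe_id`, `kind`, `fusion_id`, `tube`, `lineages` (lineage
#' labels semicolon-separated). A `#name<TAB>value` comment line above the
#' header carries the manifest name. Row order is preserved; POS controls
#' are expected in ladder order (highest concentration first).
#'
#' @param path file path.
#' @return `read_manifest` returns a [panel_manifest()].
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    stop_fc("manifest file not found: %s", path, class = "manifest_error")
  }
  kv <- read_kv_header(path)
  df <- read_delim_kv(path, sep = "\t")
  need <- c("probe_id", "kind")
  if (!all(need %in% names(df))) {
    stop_fc("manifest file lacks required columns: %s",
            paste(setdiff(need, names(df)), collapse = ", "),
            class = "manifest_error")
  }
  name <- kv$name %||% sub("\\.[^.]*$", "", basename(path))
  panel_manifest(df, name = name)
}

#' @rdname read_manifest
#' @param manifest a [panel_manifest()].
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "panel_manifest"))
  write_delim_kv(manifest$probes, path, kv = list(name = manifest$name))
  invisible(path)
}

#' Lineages associated with a fusion
#'
#' @param manifest a [panel_manifest()].
#' @param fusion_id fusion identifier, e.g. `"BCR::ABL1"`.
#' @return Character vector of lineage labels; empty for an unknown fusion
#'   (so downstream concordance degrades to "not assessable" rather than
#'   erroring).
#' @export
lineages_for <- function(manifest, fusion_id) {
  stopifnot(inherits(manifest, "panel_manifest"))
  manifest$lineage_map[[fusion_id]] %||% character(0)
}

#' Probe ids of a given kind, optionally restricted to a tube
#'
#' Probes with no tube annotation (controls, shared probes) match every
#' tube.
#' @inheritParams lineages_for
#' @param kind one of `"FUSION"`, `"HOUSEKEEPING"`, `"POS_CONTROL"`,
#'   `"NEG_CONTROL"`.
#' @param tube optional tube filter (`"HEME1"` / `"HEME2"`).
#' @export
probe_ids <- function(manifest, kind, tube = NULL) {
  stopifnot(inherits(manifest, "panel_manifest"))
  p <- manifest$probes
  sel <- p$kind == kind
  if (!is.null(tube) && !is.na(tube)) {
    sel <- sel & (is.na(p$tube) | p$tube == tube)
  }
  p$probe_id[sel]
}

fusion_id_of <- function(manifest, probe_id) {
  p <- manifest$probes
  p$fusion_id[match(probe_id, p$probe_id)]
}

#' @export
print.panel_manifest <- function(x, ...) {
  k <- table(factor(x$probes$kind, levels = PROBE_KINDS))
  cat(sprintf("<panel_manifest '%s'>\n", x$name))
  cat(sprintf("  %d fusion probes (%d fusions), %d housekeeping, %d POS, %d NEG controls\n",
              k[["FUSION"]], length(x$lineage_map) +
                length(setdiff(unique(stats::na.omit(x$probes$fusion_id)),
                               names(x$lineage_map))),
              k[["HOUSEKEEPING"]], k[["POS_CONTROL"]], k[["NEG_CONTROL"]]))
  invisible(x)
}
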