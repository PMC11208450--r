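CELL_CLASSES <- c("positive", "review", "hk_pass", "hk_fail", "plain")

#' Default display palette for rendered run templates
#'
#' Mirrors the conditional formatting of the interpretation spreadsheet:
#' yellow marks counts above the positivity cutoff, brown the review zone,
#' green/red adequate/inadequate housekeeping. Swap colors here without
#' touching report logic.
#' @export
report_palette <- function() {
  c(positive = "#ffe84d", review = "#b5651d", hk_pass = "#b6e3b6",
    hk_fail = "#f4a0a0", plain = "#ffffff")
}

#' Render the color-coded run template
#'
#' Rebuilds the spreadsheet analysts review in the field: probes as rows,
#' samples as columns, a display class per cell (fusion cells classed from
#' their probe call, housekeeping cells from the RNA QC), and a final
#' interpretation row. Cell classes are a pure function of the probe-call
#' and QC statuses.
#'
#' @param interps list of `sample_interpretation` (from [interpret_run()]).
#' @param counts list of [sample_counts()] in the same order.
#' @param calib a [calibration_table()].
#' @param manifest a [panel_manifest()].
#' @param format `"html"` or `"csv"` (CSV grid plus a JSON sidecar of cell
#'   classes); anything else errors, listing the supported formats.
#' @param path optional output path (for `"csv"`, the sidecar is written
#'   next to it as `<path>.classes.json`).
#' @return Invisibly, a `run_report`: `grid` (character matrix of display
#'   values), `classes` (matrix of cell classes), `interpretation`
#'   (one-line summary per sample), `files` (paths written, if any).
#' @export
render_run <- function(interps, counts, calib, manifest,
                       format = c("html", "csv"), path = NULL) {
  if (!is.character(format) || !all(format %in% c("html", "csv"))) {
    stop_fc("unknown report format '%s'; supported: html, csv",
            paste(setdiff(format, c("html", "csv")), collapse = ", "),
            class = "report_error")
  }
  format <- match.arg(format)
  sample_ids <- unname(vapply(counts, `[[`, "", "sample_id"))
  stopifnot(identical(sample_ids,
                      unname(vapply(interps, `[[`, "", "sample_id"))))
  probes <- manifest$probes$probe_id
  kinds <- manifest$probes$kind

  grid <- matrix("", nrow = length(probes), ncol = length(counts),
                 dimnames = list(probes, sample_ids))
  classes <- matrix("plain", nrow = length(probes), ncol = length(counts),
                    dimnames = list(probes, sample_ids))
  for (j in seq_along(counts)) {
    cnt <- counts[[j]]$counts[probes]
    grid[, j] <- ifelse(is.na(cnt), "F", as.character(cnt))
    calls <- interps[[j]]$probe_calls
    idx <- match(calls$probe_id, probes)
    classes[idx[calls$status == "POSITIVE" &
                  interps[[j]]$status != "FAILED_ASSAY"], j] <- "positive"
    classes[idx[calls$status == "REVIEW" &
                  interps[[j]]$status != "FAILED_ASSAY"], j] <- "review"
    rqc <- interps[[j]]$rna_qc
    if (!is.null(rqc)) {
      hk_idx <- match(rqc$per_probe$probe_id, probes)
      classes[hk_idx, j] <- ifelse(rqc$per_probe$pass, "hk_pass", "hk_fail")
    }
  }

  interp_row <- vapply(interps, function(x) {
    switch(x$status,
           POSITIVE = paste(unique(x$positive_fusions$fusion_id), collapse = ", "),
           REVIEW = sprintf("likely negative; repeat with more RNA to check %s",
                            paste(unique(x$review_fusions$fusion_id), collapse = ", ")),
           NEGATIVE = "negative sample",
           FAILED_RNA = "failed RNA; repeat with more RNA",
           FAILED_ASSAY = "failed assay controls; repeat",
           HIGH_BACKGROUND = "high background; repeat with less RNA",
           NOT_INTERPRETABLE = "not interpretable")
  }, "")

  files <- character(0)
  if (!is.null(path)) {
    if (format == "html") {
      writeLines(report_html(grid, classes, interp_row), path)
      files <- path
    } else {
      df <- data.frame(probe_id = rownames(grid), grid, check.names = FALSE,
                       stringsAsFactors = FALSE)
      df <- rbind(df, c("Interpretation", unname(interp_row)))
      utils::write.csv(df, path, row.names = FALSE)
      sidecar <- paste0(path, ".classes.json")
      jsonlite::write_json(
        list(classes = as.data.frame(classes, stringsAsFactors = FALSE),
             palette = as.list(report_palette())),
        sidecar, auto_unbox = TRUE, pretty = TRUE)
      files <- c(path, sidecar)
    }
  }
  invisible(structure(list(grid = grid, classes = classes,
                           interpretation = interp_row, files = files),
                      class = "run_report"))
}

report_html <- function(grid, classes, interp_row) {
  pal <- report_palette()
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  header <- paste0("<tr><th>Probe set</th>",
                   paste0("<th>", esc(colnames(grid)), "</th>", collapse = ""),
                   "</tr>")
  rows <- vapply(seq_len(nrow(grid)), function(i) {
    cells <- paste0(sprintf('<td style="background:%s">%s</td>',
                            pal[classes[i, ]], esc(grid[i, ])), collapse = "")
    paste0("<tr><td>", esc(rownames(grid)[i]), "</td>", cells, "</tr>")
  }, "")
  interp <- paste0("<tr><td><b>Interpretation</b></td>",
                   paste0("<td>", esc(interp_row), "</td>", collapse = ""),
                   "</tr>")
  c("<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<style>table{border-collapse:collapse}td,th{border:1px solid #999;padding:2px 6px;font:12px sans-serif}</style>",
    "</head><body><table>", header, rows, interp, "</table></body></html>")
}

#' Tally a cohort of interpretations
#'
#' @param interps list of `sample_interpretation`.
#' @param is_control optional logical vector (one per interpretation);
#'   control lanes (e.g. the run's positive-control RNA) are excluded from
#'   the tallies.
#' @return list with `status_counts` (named count per interpretation
#'   status, totalling the number of tallied lanes), `fusion_counts`
#'   (positive calls per fusion id) and `positive_fraction` (fraction of
#'   interpretable lanes — positive, negative or review — that are
#'   positive; `NA` when none are interpretable).
#' @export
summarize_cohort <- function(interps, is_control = NULL) {
  if (!is.null(is_control)) {
    stopifnot(length(is_control) == length(interps))
    interps <- interps[!is_control]
  }
  statuses <- vapply(interps, `[[`, "", "status")
  tab <- table(factor(statuses, levels = SAMPLE_STATUSES))
  status_counts <- stats::setNames(as.integer(tab), names(tab))
  fusions <- unlist(lapply(interps, function(x)
    unique(x$positive_fusions$fusion_id)))
  fusion_counts <- if (length(fusions) > 0L) {
    sort(table(fusions), decreasing = TRUE)
  } else {
    table(character(0))
  }
  interpretable <- sum(statuses %in% c("POSITIVE", "NEGATIVE", "REVIEW"))
  list(status_counts = status_counts,
       fusion_counts = fusion_counts,
       positive_fraction = if (interpretable > 0L)
         sum(statuses == "POSITIVE") / interpretable else NA_real_)
}
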