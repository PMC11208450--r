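`%||%` <- function(x, y) if (is.null(x)) y else x

#' Parse a count cell from a spreadsheet export
#'
#' Accepts integers with optional surrounding whitespace and thousands
#' separators ("1,234"). Anything else (e.g. the literal "F" sometimes left
#' in exported templates) becomes `NA`, the missing-count marker.
#'
#' @param x character vector of raw cell contents.
#' @return integer vector with `NA` where the cell is not a count.
#' @keywords internal
parse_count <- function(x) {
  x <- gsub("[[:space:],]", "", as.character(x))
  x[x == ""] <- NA_character_
  suppressWarnings(out <- as.numeric(x))
  bad <- !is.na(x) & (is.na(out) | out < 0 | out != floor(out))
  out[bad] <- NA_real_
  structure(as.integer(round(out)), bad = which(bad))
}

is_missing_count <- function(x) is.na(x)

#' @keywords internal
stop_fc <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "fusioncall_error")))
}

sniff_sep <- function(path) {
  header <- readLines(path, n = 25L)
  header <- header[!startsWith(header, "#")]
  if (length(header) == 0L) return("\t")
  if (grepl("\t", header[[1L]])) "\t" else ","
}

# '#key<TAB>value' comment lines above a delimited table
read_kv_header <- function(path) {
  lines <- readLines(path)
  kv <- lines[startsWith(lines, "#")]
  out <- list()
  for (l in kv) {
    parts <- strsplit(sub("^#", "", l), "\t", fixed = TRUE)[[1L]]
    if (length(parts) == 2L) out[[parts[[1L]]]] <- parts[[2L]]
  }
  out
}

write_delim_kv <- function(df, path, kv = list(), sep = "\t") {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (k in names(kv)) {
    if (!is.null(kv[[k]]) && !is.na(kv[[k]])) {
      writeLines(sprintf("#%s\t%s", k, kv[[k]]), con)
    }
  }
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "")
}

read_delim_kv <- function(path, sep = NULL) {
  sep <- sep %||% sniff_sep(path)
  utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character", quote = "", fill = TRUE,
                    na.strings = c("NA", ""))
}
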