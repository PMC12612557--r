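# Flat keyed-text and delimited-table IO shared by the parameter,
# adherence, cost and target readers. All output is locale-independent:
# period decimal separator, no thousands grouping.

read_keyed_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  m <- regmatches(lines, regexec("^\\s*([^=]+?)\\s*=\\s*(.*?)\\s*$", lines))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "),
                     call. = FALSE)
  vals <- lapply(m, `[`, 3L)
  names(vals) <- vapply(m, `[`, "", 2L)
  vals
}

fmt_num <- function(x) {
  ifelse(is.na(x), "NA",
         format(x, digits = 15, scientific = FALSE, trim = TRUE,
                big.mark = "", decimal.mark = "."))
}

#' Write a table as schema-checked delimited text
#'
#' Tab-separated with a header row, fixed column order taken from
#' `schema`, and locale-independent number formatting. Rows must contain
#' exactly the schema's columns.
#'
#' @param rows data.frame
#' @param schema character vector of required column names (default: the
#'   columns of `rows`)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_table <- function(rows, schema = names(rows), path) {
  if (!is.data.frame(rows)) stop("rows must be a data.frame", call. = FALSE)
  if (!setequal(names(rows), schema)) {
    stop("schema violation: expected columns {", paste(schema, collapse = ", "),
         "}, got {", paste(names(rows), collapse = ", "), "}", call. = FALSE)
  }
  rows <- rows[, schema, drop = FALSE]
  out <- rows
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(schema, collapse = "\t"), con)
  if (nrow(out) > 0) {
    writeLines(do.call(paste, c(unname(as.list(out)), sep = "\t")), con)
  }
  invisible(path)
}

#' @rdname write_table
#' @export
read_table_file <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
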