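#' Write / read the long prediction-and-uncertainty table
#'
#' One row per (image, cell type): `image_id`, `cell_type`, `mu`,
#' `H_plugin`, `H_jackknife`, `mutual_info`, `cppd`, `dhc_raw`,
#' `dhc_normalized`, `call`, `manual_label`. Numeric columns are written
#' locale-independently with 17 significant digits, so a read-back reproduces
#' every double bit-identically. An empty record set writes a header-only
#' file.
#'
#' @param records An `"ihc_uncertainty"` tibble (see
#'   [uncertainty_records()]).
#' @param path Output path; `.csv` writes CSV, anything else TSV.
#' @return `path` invisibly (writer); the records tibble (reader).
#' @export
write_prediction_table <- function(records, path) {
  cols <- c(
    "image_id", "cell_type", "mu", "H_plugin", "H_jackknife", "mutual_info",
    "cppd", "dhc_raw", "dhc_normalized", "call", "manual_label"
  )
  missing <- setdiff(cols, names(records))
  if (length(missing)) {
    stop("prediction records are missing column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  out <- records[cols]
  for (col in c("mu", "H_plugin", "H_jackknife", "mutual_info", "cppd", "dhc_raw", "dhc_normalized")) {
    out[[col]] <- vapply(out[[col]], function(x) {
      if (is.na(x)) NA_character_ else sprintf("%.17g", x)
    }, character(1))
  }
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  con <- tryCatch(file(path, open = "wt", encoding = "UTF-8"),
    error = function(e) stop("cannot write prediction table: ", conditionMessage(e), call. = FALSE)
  )
  on.exit(close(con))
  utils::write.table(out, con,
    sep = sep, quote = FALSE, row.names = FALSE,
    col.names = TRUE, na = "NA"
  )
  invisible(path)
}

#' @rdname write_prediction_table
#' @export
read_prediction_table <- function(path) {
  if (!file.exists(path)) stop("prediction table not found: ", path, call. = FALSE)
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  tbl <- utils::read.table(path,
    header = TRUE, sep = sep, quote = "",
    colClasses = c(image_id = "character", cell_type = "character"),
    stringsAsFactors = FALSE, na.strings = "NA"
  )
  tbl <- tibble::as_tibble(tbl)
  for (col in c("mu", "H_plugin", "H_jackknife", "mutual_info", "cppd", "dhc_raw", "dhc_normalized")) {
    tbl[[col]] <- as.numeric(tbl[[col]])
  }
  for (col in c("call", "manual_label")) tbl[[col]] <- as.integer(tbl[[col]])
  class(tbl) <- unique(c("ihc_uncertainty", class(tbl)))
  tbl
}
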