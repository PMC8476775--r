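#' Read a per-image multilabel annotation table
#'
#' The annotation table is the manual scoring sheet: one row per image, with
#' an `image_id` column, a `split` column (`train`, `validation`, `test` or
#' `external`), optional `protein_id` / `antibody_id` / `path` columns, and
#' per-cell-type columns `<celltype>_intensity` (integer 0..3: negative,
#' weak, moderate, strong) and `<celltype>_location` (a `+`-joined subset of
#' `cytoplasm`, `nucleus`, `membrane`; empty when negative).
#'
#' Validation enforces the scoring invariants: intensities must lie in 0..3,
#' a location set is present iff intensity > 0, and any `*_intensity` /
#' `*_location` column naming an unknown cell type is rejected.
#'
#' @param path CSV or TSV file with a header row.
#' @param dialect `"tsv"` or `"csv"`; default guessed from the extension.
#' @param cell_types Cell-type vocabulary the table must cover.
#' @return A tibble with class `"ihc_annotations"`, one row per image.
#' @export
read_annotation_table <- function(path, dialect = NULL,
                                  cell_types = cell_type_vocabulary()) {
  if (!file.exists(path)) stop("annotation table not found: ", path, call. = FALSE)
  dialect <- dialect %||% if (tolower(tools::file_ext(path)) == "csv") "csv" else "tsv"
  dialect <- match.arg(dialect, c("csv", "tsv"))
  reader <- if (dialect == "csv") readr::read_csv else readr::read_tsv
  tbl <- reader(path, show_col_types = FALSE, progress = FALSE)
  validate_annotations(tbl, cell_types)
}

#' Validate an in-memory annotation table
#'
#' @param tbl A data frame shaped as described in [read_annotation_table()].
#' @inheritParams read_annotation_table
#' @return The validated tibble with class `"ihc_annotations"`.
#' @export
validate_annotations <- function(tbl, cell_types = cell_type_vocabulary()) {
  tbl <- tibble::as_tibble(tbl)
  for (col in c("image_id", "split")) {
    if (!col %in% names(tbl)) {
      stop("annotation table is missing required column '", col, "'", call. = FALSE)
    }
  }
  bad_split <- setdiff(unique(tbl$split), c("train", "validation", "test", "external"))
  if (length(bad_split)) {
    stop("unknown split value(s): ", paste(bad_split, collapse = ", "), call. = FALSE)
  }
  suffix_cols <- grep("_(intensity|location)$", names(tbl), value = TRUE)
  declared <- unique(sub("_(intensity|location)$", "", suffix_cols))
  unknown <- setdiff(declared, cell_types)
  if (length(unknown)) {
    stop("unknown cell-type column(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (ct in cell_types) {
    icol <- paste0(ct, "_intensity")
    lcol <- paste0(ct, "_location")
    for (col in c(icol, lcol)) {
      if (!col %in% names(tbl)) {
        stop("annotation table is missing column '", col, "'", call. = FALSE)
      }
    }
    iv <- tbl[[icol]]
    if (!is.numeric(iv) || anyNA(iv) || any(iv != as.integer(iv)) || any(iv < 0 | iv > 3)) {
      bad <- which(is.na(iv) | suppressWarnings(iv < 0 | iv > 3 | iv != as.integer(iv)))
      stop("column '", icol, "' has intensity outside {0,1,2,3} at row(s) ",
        paste(utils::head(bad, 5), collapse = ", "),
        call. = FALSE
      )
    }
    tbl[[icol]] <- as.integer(iv)
    lv <- tbl[[lcol]]
    lv[is.na(lv)] <- ""
    tbl[[lcol]] <- as.character(lv)
    locs <- strsplit(tbl[[lcol]], "+", fixed = TRUE)
    bad_loc <- which(!vapply(locs, function(l) all(l %in% subcellular_locations()), TRUE))
    if (length(bad_loc)) {
      stop("column '", lcol, "' has unknown location at row(s) ",
        paste(utils::head(bad_loc, 5), collapse = ", "),
        call. = FALSE
      )
    }
    has_loc <- nzchar(tbl[[lcol]])
    mism <- which((tbl[[icol]] == 0L) != !has_loc)
    if (length(mism)) {
      stop("cell type '", ct, "': intensity 0 must have empty location (and ",
        "positive intensity a non-empty one); violated at row(s) ",
        paste(utils::head(mism, 5), collapse = ", "),
        call. = FALSE
      )
    }
  }
  if (anyDuplicated(tbl$image_id)) {
    stop("duplicated image_id values in annotation table", call. = FALSE)
  }
  attr(tbl, "cell_types") <- cell_types
  class(tbl) <- unique(c("ihc_annotations", class(tbl)))
  tbl
}

#' Write an annotation table
#'
#' @param tbl An annotation tibble (see [read_annotation_table()]).
#' @param path Output path; `.csv` writes CSV, anything else TSV.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(tbl, path) {
  if (tolower(tools::file_ext(path)) == "csv") {
    readr::write_csv(tbl, path, progress = FALSE)
  } else {
    readr::write_tsv(tbl, path, progress = FALSE)
  }
  invisible(path)
}

#' Binary label matrix from annotations
#'
#' A cell type is positive for an image iff its staining intensity is >= 1
#' (weak or stronger); intensity grades are kept only for stratified
#' reporting.
#'
#' @param tbl An annotation tibble.
#' @param cell_types Label order; defaults to the table's vocabulary.
#' @return `n x C` integer matrix with `image_id` rownames.
#' @export
annotation_labels <- function(tbl, cell_types = NULL) {
  cell_types <- cell_types %||% attr(tbl, "cell_types") %||% cell_type_vocabulary()
  Y <- vapply(cell_types, function(ct) as.integer(tbl[[paste0(ct, "_intensity")]] > 0L),
    integer(nrow(tbl))
  )
  Y <- matrix(Y, nrow = nrow(tbl), dimnames = list(tbl$image_id, cell_types))
  Y
}

#' Intensity matrix from annotations
#'
#' @inheritParams annotation_labels
#' @return `n x C` integer matrix of intensities 0..3.
#' @export
annotation_intensities <- function(tbl, cell_types = NULL) {
  cell_types <- cell_types %||% attr(tbl, "cell_types") %||% cell_type_vocabulary()
  M <- vapply(cell_types, function(ct) as.integer(tbl[[paste0(ct, "_intensity")]]),
    integer(nrow(tbl))
  )
  matrix(M, nrow = nrow(tbl), dimnames = list(tbl$image_id, cell_types))
}
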