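#' Read a delimited score table
#'
#' Parses a delimited text export of a screened library into a
#' [screening_table()]. The file needs a header row, an identifier column, a
#' label column, and at least one numeric score column. Score columns whose
#' native orientation is "lower is better" are sign-flipped at load so that
#' every stored score obeys the higher-is-better contract. Empty score cells
#' become `NA`; a ligand whose every score is missing is flagged
#' `docked = FALSE` (the reader never drops rows — exclusion is an analysis
#' choice made downstream via `missing_policy`).
#'
#' @param path Path to a UTF-8 CSV or TSV file with a header row.
#' @param id_col,label_col Names of the identifier and label columns.
#' @param score_cols Character vector of score column names; default: every
#'   column other than `id_col` and `label_col`.
#' @param directions Named character vector/list mapping score columns to
#'   `"higher_better"` (default) or `"lower_better"`.
#' @param label_map List with elements `active` and `decoy` giving the raw
#'   label values (case-insensitive) mapped onto each class.
#' @param delim Field delimiter; `NULL` (default) sniffs `,` vs tab from the
#'   header line.
#' @return A `screening_table`.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("id,label,dockscore", "a1,active,3.2", "d1,decoy,1.1"), tf)
#' read_score_table(tf)
read_score_table <- function(path,
                             id_col = "id",
                             label_col = "label",
                             score_cols = NULL,
                             directions = NULL,
                             label_map = list(
                               active = c("active", "1"),
                               decoy = c("decoy", "inactive", "0")
                             ),
                             delim = NULL) {
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, trim_ws = TRUE
  )
  for (col in c(id_col, label_col)) {
    if (!col %in% names(raw)) stop("column '", col, "' not found in ", path, call. = FALSE)
  }
  if (is.null(score_cols)) score_cols <- setdiff(names(raw), c(id_col, label_col))
  if (length(score_cols) == 0) stop("no score columns found", call. = FALSE)

  scores <- lapply(score_cols, function(fn) {
    cell <- raw[[fn]]
    if (is.null(cell)) stop("score column '", fn, "' not found", call. = FALSE)
    empty <- is.na(cell) | cell == ""
    val <- suppressWarnings(as.numeric(cell))
    bad <- which(!empty & is.na(val))
    if (length(bad) > 0) {
      stop("non-numeric score in column '", fn, "', data row ", bad[1],
           ": '", cell[bad[1]], "'", call. = FALSE)
    }
    dir <- if (is.null(directions) || is.null(directions[[fn]])) "higher_better" else directions[[fn]]
    dir <- match.arg(dir, c("higher_better", "lower_better"))
    if (dir == "lower_better") val <- -val
    val
  })
  names(scores) <- score_cols

  screening_table(
    ligand_id = raw[[id_col]],
    label = normalize_labels(raw[[label_col]], label_map = label_map),
    scores = scores
  )
}

#' Write a screening table as CSV
#'
#' Inverse of [read_score_table()] under default directions: scores are
#' written in stored (higher-is-better) orientation and missing scores as
#' empty cells, so a written table re-reads into an identical
#' `screening_table`.
#'
#' @param x A `screening_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(x, path) {
  x <- validate_screening_table(x)
  out <- tibble::as_tibble(x)[c("ligand_id", "label", score_functions(x))]
  names(out)[1:2] <- c("id", "label")
  out$label <- as.character(out$label)
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}
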