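#' Construct a screening table
#'
#' A screening table holds one row per ligand of a screened library: a unique
#' identifier, an active/decoy label, a `docked` flag, and one numeric column
#' per scoring function. All stored scores follow the "higher is better"
#' orientation; columns whose native direction is "lower is better" must be
#' sign-flipped before (or while, see [read_score_table()]) entering the
#' table. Ligands that failed to dock carry `docked = FALSE` and `NA` in
#' every score column; how such ligands enter the analysis is decided
#' downstream by a `missing_policy`, never by the container.
#'
#' @param ligand_id Character vector of unique ligand identifiers.
#' @param label Vector coercible to the levels `"active"`/`"decoy"`.
#' @param scores A data frame, named list, or named numeric vector of score
#'   columns (one per scoring function). `NA` marks a missing score.
#' @param docked Optional logical vector; defaults to "any score present".
#'   A row with `docked = FALSE` must have all scores missing.
#'
#' @return A tibble of class `screening_table` with columns `ligand_id`,
#'   `label` (factor with levels active/decoy), `docked`, then one column per
#'   scoring function.
#' @seealso [read_score_table()], [gen_score_table()], [score_functions()]
#' @export
#' @examples
#' screening_table(
#'   ligand_id = c("a1", "a2", "d1", "d2"),
#'   label = c("active", "active", "decoy", "decoy"),
#'   scores = data.frame(dockscore = c(3, 2, 1, NA))
#' )
screening_table <- function(ligand_id, label, scores, docked = NULL) {
  scores <- tibble::as_tibble(as.list(scores))
  tbl <- tibble::tibble(
    ligand_id = as.character(ligand_id),
    label = normalize_labels(label)
  )
  if (ncol(scores) == 0) {
    stop("at least one score column is required", call. = FALSE)
  }
  for (fn in names(scores)) {
    tbl[[fn]] <- as.numeric(scores[[fn]])
  }
  if (is.null(docked)) {
    docked <- rowSums(!is.na(scores)) > 0
  }
  tbl <- tibble::add_column(tbl, docked = as.logical(docked), .after = "label")
  validate_screening_table(tbl)
}

#' @rdname screening_table
#' @param x A `screening_table` (or any data frame shaped like one).
#' @return `score_functions()`: the character vector of scoring-function
#'   column names.
#' @export
score_functions <- function(x) {
  setdiff(names(x), c("ligand_id", "label", "docked"))
}

#' Validate the screening-table invariants
#'
#' Checks identifier uniqueness, the active/decoy label set, score-column
#' types, and that undocked ligands carry no scores.
#'
#' @param x A data frame to validate.
#' @return `x`, classed as `screening_table`, invisibly usable downstream.
#' @export
validate_screening_table <- function(x) {
  stopifnot(is.data.frame(x))
  needed <- c("ligand_id", "label", "docked")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  dup <- x$ligand_id[duplicated(x$ligand_id)]
  if (length(dup) > 0) {
    stop("duplicate ligand_id: ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (!all(levels(x$label) == c("active", "decoy")) || anyNA(x$label)) {
    stop("label must be a factor with levels active/decoy and no NA", call. = FALSE)
  }
  fns <- score_functions(x)
  if (length(fns) == 0) stop("no score columns present", call. = FALSE)
  for (fn in fns) {
    if (!is.numeric(x[[fn]])) stop("score column '", fn, "' is not numeric", call. = FALSE)
  }
  score_mat <- as.matrix(x[fns])
  bad <- !x$docked & rowSums(!is.na(score_mat)) > 0
  if (any(bad)) {
    stop(
      "undocked ligand(s) with non-missing scores: ",
      paste(x$ligand_id[bad], collapse = ", "),
      call. = FALSE
    )
  }
  class(x) <- unique(c("screening_table", class(x)))
  x
}

# Map arbitrary label vocabulary onto the active/decoy factor.
# Default dictionary covers DUD-E-style exports ("active"/"decoy"),
# "inactive", and 0/1 codings; matching is case-insensitive.
normalize_labels <- function(label,
                             label_map = list(
                               active = c("active", "1"),
                               decoy = c("decoy", "inactive", "0")
                             )) {
  raw <- tolower(trimws(as.character(label)))
  out <- rep(NA_character_, length(raw))
  out[raw %in% tolower(label_map$active)] <- "active"
  out[raw %in% tolower(label_map$decoy)] <- "decoy"
  if (anyNA(out)) {
    bad <- unique(as.character(label)[is.na(out)])
    stop("unmappable label value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  factor(out, levels = c("active", "decoy"))
}

# Resolve a missing-score policy for one scoring function.
# exclude     : drop ligands with a missing score (the docked-only analysis).
# worst_score : keep them with a score strictly below the observed minimum,
#               i.e. ranked last / never called active before any real score.
resolve_missing <- function(x, function_name,
                            missing_policy = c("exclude", "worst_score")) {
  missing_policy <- match.arg(missing_policy)
  if (!function_name %in% score_functions(x)) {
    stop("unknown scoring function: ", function_name, call. = FALSE)
  }
  s <- x[[function_name]]
  if (missing_policy == "exclude") {
    keep <- !is.na(s)
    tibble::tibble(ligand_id = x$ligand_id[keep], label = x$label[keep],
                   score = s[keep])
  } else {
    lo <- if (all(is.na(s))) 0 else min(s, na.rm = TRUE)
    s[is.na(s)] <- lo - 1
    tibble::tibble(ligand_id = x$ligand_id, label = x$label, score = s)
  }
}
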