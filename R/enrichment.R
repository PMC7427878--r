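#' Rank a screened library by one scoring function
#'
#' Orders ligands by descending score. Ties are resolved by an explicit,
#' recorded policy, because the enrichment factor at small fractions can be
#' sensitive to the order inside a tied block: `"pessimistic"` places decoys
#' before actives (a conservative enrichment estimate), `"optimistic"` the
#' reverse, `"stable_id"` orders a block lexicographically by ligand id.
#'
#' @inheritParams build_roc
#' @param tie_policy `"pessimistic"`, `"optimistic"`, or `"stable_id"`.
#' @return A tibble `ligand_id`, `label`, `score`, `rank`, with attributes
#'   `tie_policy` and `missing_policy` recording the choices used.
#' @export
rank_ligands <- function(table, function_name,
                         tie_policy = c("pessimistic", "optimistic", "stable_id"),
                         missing_policy = c("exclude", "worst_score")) {
  tie_policy <- match.arg(tie_policy)
  missing_policy <- match.arg(missing_policy)
  d <- resolve_missing(table, function_name, missing_policy)
  if (nrow(d) == 0) stop("no usable ligands", call. = FALSE)
  tie_key <- switch(tie_policy,
    pessimistic = -xtfrm(d$label),    # decoy (level 2) first inside a block
    optimistic = xtfrm(d$label),      # active first
    stable_id = xtfrm(d$ligand_id)
  )
  ord <- order(-d$score, tie_key)
  out <- d[ord, ]
  out$rank <- seq_len(nrow(out))
  attr(out, "tie_policy") <- tie_policy
  attr(out, "missing_policy") <- missing_policy
  out
}

#' Enrichment factor at a fraction of the ranked library
#'
#' `EF = (Hits_sampled / N_sampled) * (N_total / Hits_total)`: the active
#' concentration in the top X% of the ranking relative to the whole library.
#' 1 means no enrichment over random picking; the ceiling is
#' `min(1/fraction, N_total/Hits_total)` up to the rounding of the window.
#' The window size is `N_sampled = max(1, round(fraction * N_total))`
#' (round half up, so 0.5% of 8935 ligands is a window of 45).
#'
#' @param ranking Output of [rank_ligands()], or any data frame with a
#'   `label` column ordered best-first.
#' @param fraction Fraction of the library to sample, in (0, 1].
#' @return A one-row tibble: `fraction`, `n_total`, `hits_total`,
#'   `n_sampled`, `hits_sampled`, `ef`.
#' @export
#' @examples
#' r <- tibble::tibble(label = factor(
#'   c("active", rep("decoy", 8), "active"), levels = c("active", "decoy")
#' ))
#' enrichment_factor(r, fraction = 0.2)  # 1 of 2 sampled vs 2 of 10: EF 2.5
enrichment_factor <- function(ranking, fraction) {
  if (length(fraction) != 1 || fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]", call. = FALSE)
  }
  lab <- ranking$label
  n_total <- length(lab)
  hits_total <- sum(lab == "active")
  if (hits_total < 1) stop("ranking contains no actives", call. = FALSE)
  n_sampled <- max(1L, as.integer(floor(fraction * n_total + 0.5)))
  hits_sampled <- sum(lab[seq_len(n_sampled)] == "active")
  tibble::tibble(
    fraction = fraction,
    n_total = n_total,
    hits_total = hits_total,
    n_sampled = n_sampled,
    hits_sampled = hits_sampled,
    # ratio of products, not product of ratios: keeps EF(fraction = 1)
    # exactly 1 in floating point
    ef = (as.numeric(hits_sampled) * n_total) /
      (as.numeric(n_sampled) * hits_total)
  )
}

#' Enrichment-factor profile across scoring functions and fractions
#'
#' One EF per (scoring function, fraction), the shape in which screening
#' benchmarks tabulate early-recognition performance. Default fractions are
#' the early-recognition ones: 0.5%, 1%, 2%.
#'
#' @inheritParams rank_ligands
#' @param function_names Scoring-function columns to profile; default all.
#' @param fractions Numeric vector of fractions in (0, 1].
#' @return A tibble with one row per (function, fraction): `function_name`,
#'   the [enrichment_factor()] columns, `tie_policy`.
#' @export
ef_profile <- function(table, function_names = NULL,
                       fractions = c(0.005, 0.01, 0.02),
                       tie_policy = c("pessimistic", "optimistic", "stable_id"),
                       missing_policy = c("exclude", "worst_score")) {
  tie_policy <- match.arg(tie_policy)
  missing_policy <- match.arg(missing_policy)
  if (is.null(function_names)) function_names <- score_functions(table)
  rows <- lapply(function_names, function(fn) {
    ranking <- rank_ligands(table, fn, tie_policy, missing_policy)
    out <- dplyr::bind_rows(lapply(fractions, function(f) {
      enrichment_factor(ranking, f)
    }))
    tibble::add_column(out, function_name = fn, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  out$tie_policy <- tie_policy
  out
}
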