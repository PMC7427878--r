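#' Configuration for a full virtual-screening evaluation
#'
#' Bundles every choice the pipeline needs: the inputs, the scoring
#' functions and their native directions, the missing-score and tie
#' policies, the RMSD success threshold, the specificity targets of the PPV
#' analysis, and the enrichment fractions.
#'
#' @param score_table Path to a delimited score table, or a
#'   [screening_table()] already in memory.
#' @param reference_sdf,docked_sdf Optional SDF paths for the pose stage.
#' @param functions Scoring-function columns to evaluate; `NULL` = all.
#' @param directions Named map of native score directions for
#'   [read_score_table()].
#' @param missing_policy,tie_policy Analysis policies (see [build_roc()],
#'   [rank_ligands()]).
#' @param rmsd_threshold Pose success threshold in Angstrom.
#' @param symmetry Use symmetry-corrected RMSD in the pose stage.
#' @param sp_targets Specificity targets of the PPV analysis.
#' @param ef_fractions Enrichment fractions.
#' @param seed Integer seed recorded in the report.
#' @return A list of class `eval_config`.
#' @export
eval_config <- function(score_table,
                        reference_sdf = NULL, docked_sdf = NULL,
                        functions = NULL, directions = NULL,
                        missing_policy = c("exclude", "worst_score"),
                        tie_policy = c("pessimistic", "optimistic", "stable_id"),
                        rmsd_threshold = 2.0, symmetry = FALSE,
                        sp_targets = c(0.80, 0.90, 0.95, 0.99),
                        ef_fractions = c(0.005, 0.01, 0.02),
                        seed = 1L) {
  stopifnot(rmsd_threshold > 0,
            all(sp_targets > 0 & sp_targets < 1),
            all(ef_fractions > 0 & ef_fractions <= 1))
  structure(
    list(score_table = score_table,
         reference_sdf = reference_sdf, docked_sdf = docked_sdf,
         functions = functions, directions = directions,
         missing_policy = match.arg(missing_policy),
         tie_policy = match.arg(tie_policy),
         rmsd_threshold = rmsd_threshold, symmetry = symmetry,
         sp_targets = sp_targets, ef_fractions = ef_fractions,
         seed = as.integer(seed)),
    class = "eval_config"
  )
}

stage <- function(name, verbose, expr) {
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  if (verbose) {
    message(sprintf("[%s] done in %.2fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  out
}

#' Run the full virtual-screening evaluation
#'
#' Orchestrates every stage of the benchmark from one [eval_config()]:
#' (1) per-complex RMSD and docking success rates (if pose files are given);
#' (2) per-function AUC/CI/p plus Youden-optimal cutoff, sorted by AUC
#' descending; (3) the all-pairs DeLong p-value matrix (raw plus
#' Holm-adjusted, since many pairs are tested); (4) PPV at the configured
#' specificity targets; (5) the enrichment-factor profile. The consolidated
#' result is deterministic given config and seed.
#'
#' @param config An [eval_config()].
#' @param out_path Optional path; if given, the consolidated report is
#'   written there via [write_report()] (removed again if writing fails).
#' @param verbose Log each stage with timing via `message()`.
#' @return A list of class `screening_evaluation`: `poses` (list or NULL),
#'   `scoring` (tibble), `pairwise` (tibble), `ppv` (tibble), `ef` (tibble),
#'   `config`.
#' @export
run_full_evaluation <- function(config, out_path = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "eval_config"))

  poses <- NULL
  if (!is.null(config$reference_sdf) && !is.null(config$docked_sdf)) {
    poses <- stage("pose_eval", verbose, {
      pp <- read_pose_pairs(config$reference_sdf, config$docked_sdf)
      ev <- evaluate_poses(pp$pairs, threshold = config$rmsd_threshold,
                           symmetry = config$symmetry)
      list(per_ligand = ev$per_ligand, summary = ev$summary,
           unmatched = pp$unmatched, errors = pp$errors)
    })
  }

  tab <- stage("load_scores", verbose, {
    if (is.character(config$score_table)) {
      read_score_table(config$score_table, directions = config$directions)
    } else {
      validate_screening_table(config$score_table)
    }
  })
  fns <- config$functions %||% score_functions(tab)
  missing_fns <- setdiff(fns, score_functions(tab))
  if (length(missing_fns) > 0) {
    stop("stage 'load_scores' failed: function(s) not in table: ",
         paste(missing_fns, collapse = ", "), call. = FALSE)
  }

  scoring <- stage("roc_auc", verbose, {
    rows <- lapply(fns, function(fn) {
      est <- auc_estimate(tab, fn, config$missing_policy)
      cut <- optimal_cutoff(tab, fn, config$missing_policy)
      dplyr::bind_cols(est, cut[setdiff(names(cut), "function_name")])
    })
    out <- dplyr::bind_rows(rows)
    out[order(-out$auc, out$function_name), ]
  })

  pairwise <- stage("delong_pairs", verbose, {
    if (length(fns) == 1) {
      tibble::tibble(function_a = fns, function_b = fns,
                     auc_a = scoring$auc[1], auc_b = scoring$auc[1],
                     auc_diff = 0, z = 0, p_value = 1, p_holm = 1,
                     n_active = scoring$n_active[1],
                     n_decoy = scoring$n_decoy[1])
    } else {
      pairs <- utils::combn(fns, 2)
      out <- dplyr::bind_rows(lapply(seq_len(ncol(pairs)), function(i) {
        delong_paired_test(tab, pairs[1, i], pairs[2, i],
                           config$missing_policy)
      }))
      out$p_holm <- stats::p.adjust(out$p_value, method = "holm")
      out
    }
  })

  ppv_tab <- stage("ppv_at_sp", verbose, {
    dplyr::bind_rows(lapply(fns, function(fn) {
      ppv_at_specificity(tab, fn, config$sp_targets, config$missing_policy)
    }))
  })

  ef_tab <- stage("enrichment", verbose, {
    ef_profile(tab, fns, config$ef_fractions, config$tie_policy,
               config$missing_policy)
  })

  result <- structure(
    list(poses = poses, scoring = scoring, pairwise = pairwise,
         ppv = ppv_tab, ef = ef_tab,
         config = config[setdiff(names(config), "score_table")]),
    class = "screening_evaluation"
  )

  if (!is.null(out_path)) {
    stage("report", verbose, {
      tryCatch(
        write_report(unclass(result)[setdiff(names(result), "config")],
                     out_path, config = result$config),
        error = function(e) {
          if (file.exists(out_path)) unlink(out_path)
          stop(conditionMessage(e), call. = FALSE)
        }
      )
    })
  }
  result
}

#' @export
print.screening_evaluation <- function(x, ...) {
  cat("<screening_evaluation>\n")
  if (!is.null(x$poses)) {
    s <- x$poses$summary
    cat(sprintf("  poses: %d/%d within %.1f A (%d%%)\n", s$n_success,
                s$n_total, x$config$rmsd_threshold, s$success_pct))
  }
  cat(sprintf("  scoring functions (AUC desc): %s\n",
              paste(sprintf("%s=%.3f", x$scoring$function_name,
                            x$scoring$auc), collapse = ", ")))
  cat(sprintf("  %d pairwise DeLong tests, %d PPV rows, %d EF rows\n",
              nrow(x$pairwise), nrow(x$ppv), nrow(x$ef)))
  invisible(x)
}
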