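#' ROC curve of a scoring function over a screening table
#'
#' Builds the sensitivity/specificity staircase of one scoring function.
#' Calls follow the strict convention `score > t`: at `t = +Inf` nothing is
#' called active (SE 0, SP 1) and at `t = -Inf` everything is (SE 1, SP 0);
#' between the terminals there is one point per distinct score value.
#' Ligands with a missing score are dropped (`missing_policy = "exclude"`,
#' mirroring a docked-only evaluation) or assigned a score below the observed
#' minimum (`"worst_score"`, which penalizes docking failures).
#'
#' @param table A [screening_table()].
#' @param function_name Scoring-function column to evaluate.
#' @param missing_policy `"exclude"` or `"worst_score"`.
#' @return An object of class `roc_curve`: list with `function_name`,
#'   `points` (tibble of threshold/se/sp, strictest first), `n_active`,
#'   `n_decoy`, `missing_policy`.
#' @export
build_roc <- function(table, function_name,
                      missing_policy = c("exclude", "worst_score")) {
  missing_policy <- match.arg(missing_policy)
  d <- resolve_missing(table, function_name, missing_policy)
  n_active <- sum(d$label == "active")
  n_decoy <- sum(d$label == "decoy")
  if (n_active < 1 || n_decoy < 1) {
    stop("need at least one usable active and one usable decoy for '",
         function_name, "' under policy '", missing_policy, "'", call. = FALSE)
  }
  cuts <- threshold_scan(d$score, d$label)
  pts <- tibble::tibble(threshold = cuts$threshold,
                        se = cuts$tp / n_active,
                        sp = cuts$tn / n_decoy)
  pts <- pts[!duplicated(pts[c("se", "sp")]), ]
  structure(
    list(function_name = function_name, points = pts,
         n_active = n_active, n_decoy = n_decoy,
         missing_policy = missing_policy),
    class = "roc_curve"
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("<roc_curve> ", x$function_name, ": ", nrow(x$points), " points, ",
      x$n_active, " actives / ", x$n_decoy, " decoys\n", sep = "")
  invisible(x)
}

# Confusion counts at every candidate cutoff. Cut j calls the top j distinct
# score blocks active (j = 0..k); reported threshold is +Inf for j = 0, the
# midpoint between adjacent distinct scores for interior cuts, -Inf for the
# call-everything cut. Returns one row per cut, strictest first.
threshold_scan <- function(score, label) {
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]
  act <- label[ord] == "active"
  # last index of each distinct score block in descending order
  block_end <- which(!duplicated(s, fromLast = TRUE))
  tp <- c(0, cumsum(act)[block_end])
  fp <- c(0, cumsum(!act)[block_end])
  v <- s[block_end]
  thr <- c(Inf, (v[-length(v)] + v[-1]) / 2, -Inf)
  m <- sum(act); n <- sum(!act)
  list(threshold = thr, tp = tp, fp = fp, fn = m - tp, tn = n - fp)
}

#' Trapezoidal area under a ROC curve
#'
#' Integrates SE against (1 - SP) across the curve's points. For curves built
#' by [build_roc()] this equals the pair-counting AUC of [auc_estimate()] to
#' numerical precision (a consistency identity the test suite enforces at
#' 1e-10).
#'
#' @param curve A `roc_curve`.
#' @return AUC in `[0, 1]`.
#' @export
trapezoid_auc <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  x <- 1 - curve$points$sp
  y <- curve$points$se
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

# DeLong structural components from raw scores, via midranks.
# v10: one pseudo-value per active; v01: one per decoy; mean(v10) = auc.
delong_components <- function(score, label) {
  is_act <- label == "active"
  m <- sum(is_act); n <- sum(!is_act)
  r_all <- rank(score, ties.method = "average")
  v10 <- (r_all[is_act] - rank(score[is_act], ties.method = "average")) / n
  v01 <- 1 - (r_all[!is_act] - rank(score[!is_act], ties.method = "average")) / m
  list(auc = mean(v10), v10 = v10, v01 = v01, m = m, n = n)
}

#' AUC with DeLong variance, confidence interval and significance versus 0.5
#'
#' The AUC is the Mann-Whitney pair-counting statistic: the fraction of
#' active-decoy pairs in which the active outscores the decoy, ties counting
#' one half. Its variance comes from the DeLong structural-components
#' estimator, giving an asymptotic normal confidence interval (clipped to
#' `[0, 1]`) and a two-sided z-test of AUC = 0.5 (the random-ranking model).
#'
#' @inheritParams build_roc
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return A one-row tibble: `function_name`, `auc`, `variance`, `ci_low`,
#'   `ci_high`, `p_vs_half`, `n_active`, `n_decoy`.
#' @export
#' @examples
#' tab <- screening_table(
#'   ligand_id = c("a1", "a2", "d1", "d2"),
#'   label = c("active", "active", "decoy", "decoy"),
#'   scores = data.frame(f = c(3, 2, 1, 2))
#' )
#' auc_estimate(tab, "f")  # 3.5 of 4 pairs -> 0.875
auc_estimate <- function(table, function_name,
                         missing_policy = c("exclude", "worst_score"),
                         conf_level = 0.95) {
  missing_policy <- match.arg(missing_policy)
  d <- resolve_missing(table, function_name, missing_policy)
  if (sum(d$label == "active") < 1 || sum(d$label == "decoy") < 1) {
    stop("need at least one usable active and one usable decoy", call. = FALSE)
  }
  comp <- delong_components(d$score, d$label)
  variance <- stats::var(comp$v10) / comp$m + stats::var(comp$v01) / comp$n
  if (comp$m == 1) variance <- stats::var(comp$v01) / comp$n
  if (comp$n == 1) variance <- stats::var(comp$v10) / comp$m
  if (!is.finite(variance)) variance <- NA_real_
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(variance)
  p <- if (is.na(variance)) {
    NA_real_
  } else if (variance == 0) {
    if (comp$auc == 0.5) 1 else 0
  } else {
    2 * stats::pnorm(-abs((comp$auc - 0.5) / se))
  }
  tibble::tibble(
    function_name = function_name,
    auc = comp$auc,
    variance = variance,
    ci_low = max(0, comp$auc - z * se),
    ci_high = min(1, comp$auc + z * se),
    p_vs_half = p,
    n_active = comp$m,
    n_decoy = comp$n
  )
}

#' DeLong paired comparison of two scoring functions' AUCs
#'
#' Tests the AUC difference of two scoring functions evaluated on the same
#' ligands, using the covariance of their DeLong structural components (the
#' pairing makes this far more powerful than comparing two independent AUCs).
#' Under `missing_policy = "exclude"` the comparison restricts to ligands
#' scored by both functions.
#'
#' @inheritParams build_roc
#' @param function_a,function_b The two scoring-function columns.
#' @return A one-row tibble: `function_a`, `function_b`, `auc_a`, `auc_b`,
#'   `auc_diff`, `z`, `p_value`, `n_active`, `n_decoy`. Identical (or rank-
#'   identical) score vectors give `auc_diff` 0 and `p_value` 1.
#' @export
delong_paired_test <- function(table, function_a, function_b,
                               missing_policy = c("exclude", "worst_score")) {
  missing_policy <- match.arg(missing_policy)
  da <- resolve_missing(table, function_a, missing_policy)
  db <- resolve_missing(table, function_b, missing_policy)
  shared <- intersect(da$ligand_id, db$ligand_id)
  da <- da[match(shared, da$ligand_id), ]
  db <- db[match(shared, db$ligand_id), ]
  m <- sum(da$label == "active"); n <- sum(da$label == "decoy")
  if (m < 2 || n < 2) {
    stop("need at least two shared usable actives and decoys", call. = FALSE)
  }
  ca <- delong_components(da$score, da$label)
  cb <- delong_components(db$score, db$label)
  var_diff <- stats::var(ca$v10 - cb$v10) / m + stats::var(ca$v01 - cb$v01) / n
  diff <- ca$auc - cb$auc
  if (var_diff <= .Machine$double.eps) {
    z <- 0
    p <- 1
  } else {
    z <- diff / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  tibble::tibble(
    function_a = function_a, function_b = function_b,
    auc_a = ca$auc, auc_b = cb$auc, auc_diff = diff,
    z = z, p_value = p, n_active = m, n_decoy = n
  )
}

#' Youden index J
#'
#' `J = SE + SP - 1`, the vertical distance of a ROC point above the chance
#' diagonal; its maximum over cutoffs locates a balanced optimal threshold.
#'
#' @param se,sp Sensitivity and specificity, as fractions in `[0, 1]`, or as
#'   percentages if `percent = TRUE`.
#' @param percent Set `TRUE` when `se`/`sp` are given on the 0-100 scale.
#' @return J on the `[-1, 1]` scale (a fraction, regardless of input units).
#' @export
#' @examples
#' youden_index(78.80, 80.38, percent = TRUE)  # 0.5918
youden_index <- function(se, sp, percent = FALSE) {
  if (percent) {
    se <- se / 100
    sp <- sp / 100
  }
  if (any(se < 0 | se > 1) || any(sp < 0 | sp > 1)) {
    stop("SE and SP must lie in [0, 1] (or [0, 100] with percent = TRUE)",
         call. = FALSE)
  }
  se + sp - 1
}

#' Positive predictive value
#'
#' `PPV = TP / (TP + FP)`: the fraction of called positives that are truly
#' active. In low-prevalence screening libraries PPV is driven far more by
#' specificity than by sensitivity.
#'
#' @param tp,fp True-positive and false-positive counts.
#' @return PPV in `[0, 1]`.
#' @export
#' @examples
#' ppv(222, 1904 - 222)  # 222 of 1904 calls correct: 0.1166
ppv <- function(tp, fp) {
  if (any(tp < 0) || any(fp < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(tp + fp == 0)) {
    stop("PPV undefined: no ligand called positive (TP + FP = 0)", call. = FALSE)
  }
  tp / (tp + fp)
}

# One-row cutoff summary from confusion counts.
cutoff_summary_row <- function(threshold, tp, fp, tn, fn) {
  tibble::tibble(
    threshold = threshold, tp = tp, fp = fp, tn = tn, fn = fn,
    se = tp / (tp + fn),
    sp = tn / (tn + fp),
    ppv = ifelse(tp + fp > 0, tp / (tp + fp), NA_real_),
    youden_j = tp / (tp + fn) + tn / (tn + fp) - 1
  )
}

#' Youden-optimal cutoff of a scoring function
#'
#' Scans every candidate cutoff (strict calls `score > t`, with `t` placed
#' midway between adjacent distinct scores) and returns the confusion-matrix
#' summary maximizing the Youden index. Ties in J are broken toward the
#' stricter cutoff, i.e. higher specificity.
#'
#' @inheritParams build_roc
#' @return A one-row cutoff-summary tibble: `function_name`, `threshold`,
#'   `tp`, `fp`, `tn`, `fn`, `se`, `sp`, `ppv`, `youden_j`.
#' @export
optimal_cutoff <- function(table, function_name,
                           missing_policy = c("exclude", "worst_score")) {
  missing_policy <- match.arg(missing_policy)
  d <- resolve_missing(table, function_name, missing_policy)
  if (sum(d$label == "active") < 1 || sum(d$label == "decoy") < 1) {
    stop("need at least one usable active and one usable decoy", call. = FALSE)
  }
  cuts <- threshold_scan(d$score, d$label)
  j <- cuts$tp / (cuts$tp + cuts$fn) + cuts$tn / (cuts$tn + cuts$fp) - 1
  best <- which(j == max(j))[1]  # first = strictest = highest SP
  out <- cutoff_summary_row(cuts$threshold[best], cuts$tp[best], cuts$fp[best],
                            cuts$tn[best], cuts$fn[best])
  tibble::add_column(out, function_name = function_name, .before = 1)
}

#' Cutoff summaries at fixed specificity targets
#'
#' For each specificity target, finds the most sensitive cutoff whose
#' realized specificity still meets the target, and reports the full
#' confusion-matrix summary there, including the realized PPV. When several
#' qualifying cutoffs reach the same sensitivity, the strictest one is
#' reported (same true positives, fewer false calls). A target met only by
#' the empty call set is returned with `tp = fp = 0`, undefined PPV, and
#' `reachable = FALSE`.
#'
#' @inheritParams build_roc
#' @param sp_targets Numeric vector of specificity targets in (0, 1).
#' @return A cutoff-summary tibble with one row per target, plus columns
#'   `sp_target` and `reachable`.
#' @export
ppv_at_specificity <- function(table, function_name,
                               sp_targets = c(0.80, 0.90, 0.95, 0.99),
                               missing_policy = c("exclude", "worst_score")) {
  missing_policy <- match.arg(missing_policy)
  if (any(sp_targets <= 0 | sp_targets >= 1)) {
    stop("sp_targets must lie strictly inside (0, 1)", call. = FALSE)
  }
  d <- resolve_missing(table, function_name, missing_policy)
  if (sum(d$label == "active") < 1 || sum(d$label == "decoy") < 1) {
    stop("need at least one usable active and one usable decoy", call. = FALSE)
  }
  cuts <- threshold_scan(d$score, d$label)
  sp <- cuts$tn / (cuts$tn + cuts$fp)
  rows <- lapply(sp_targets, function(target) {
    ok <- which(sp >= target)
    # maximal sensitivity among qualifying cutoffs; SE ties broken toward
    # the strictest cutoff (fewer false positives at the same sensitivity)
    i <- ok[which.max(cuts$tp[ok])]
    out <- cutoff_summary_row(cuts$threshold[i], cuts$tp[i], cuts$fp[i],
                              cuts$tn[i], cuts$fn[i])
    out$sp_target <- target
    out$reachable <- cuts$tp[i] + cuts$fp[i] > 0
    out
  })
  out <- dplyr::bind_rows(rows)
  tibble::add_column(out, function_name = function_name, .before = 1)
}
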