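test_that("ROC curves satisfy the staircase invariants", {
  set.seed(1)
  tab <- make_table(rnorm(20, 1), rnorm(40))
  curve <- build_roc(tab, "f")
  pts <- curve$points
  expect_equal(pts$se[1], 0)
  expect_equal(pts$sp[1], 1)
  expect_equal(pts$se[nrow(pts)], 1)
  expect_equal(pts$sp[nrow(pts)], 0)
  expect_true(all(diff(pts$se) >= 0))
  expect_true(all(diff(pts$sp) <= 0))
})

test_that("perfect separation passes through SE = SP = 1", {
  tab <- make_table(c(5, 6, 7), c(1, 2, 3))
  pts <- build_roc(tab, "f")$points
  expect_true(any(pts$se == 1 & pts$sp == 1))
  expect_equal(auc_estimate(tab, "f")$auc, 1.0)
  expect_equal(trapezoid_auc(build_roc(tab, "f")), 1.0)
})

test_that("a fully tied table degenerates to the chance diagonal", {
  tab <- make_table(rep(2, 5), rep(2, 7))
  curve <- build_roc(tab, "f")
  expect_equal(nrow(curve$points), 2)
  expect_equal(trapezoid_auc(curve), 0.5)
  expect_equal(auc_estimate(tab, "f")$auc, 0.5)
})

test_that("curve points equal hand-counted confusion matrices", {
  tab <- make_table(c(3, 2.5, 2, 1, 0.5), c(2.5, 2, 1.5, 0.5, 0))
  curve <- build_roc(tab, "f")
  oracle <- unique(data.frame(
    se = brute_confusions(tab$f, tab$label)$tp / 5,
    sp = brute_confusions(tab$f, tab$label)$tn / 5
  ))
  expect_equal(curve$points$se, oracle$se)
  expect_equal(curve$points$sp, oracle$sp)
})

test_that("pair-counting AUC matches enumeration, including ties", {
  tab <- make_table(c(3, 2), c(1, 2))
  expect_equal(auc_estimate(tab, "f")$auc, 3.5 / 4)  # one tied pair at 0.5
  set.seed(2)
  for (i in 1:5) {
    a <- round(rnorm(8, 0.5), 1)  # rounding induces ties
    d <- round(rnorm(12), 1)
    expect_equal(auc_estimate(make_table(a, d), "f")$auc, brute_auc(a, d),
                 tolerance = 1e-12)
  }
})

test_that("AUC under label-independent scores centres on one half", {
  set.seed(3)
  aucs <- replicate(300, {
    auc_estimate(make_table(rnorm(40), rnorm(160)), "f")$auc
  })
  se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 3 * se)
})

test_that("AUC is invariant under monotone transforms and flips sign", {
  set.seed(4)
  a <- rnorm(15, 1); d <- rnorm(30)
  tab <- make_table(a, d)
  tab_t <- make_table(exp(a / 2), exp(d / 2))
  tab_neg <- make_table(-a, -d)
  expect_equal(auc_estimate(tab_t, "f")$auc, auc_estimate(tab, "f")$auc)
  expect_equal(auc_estimate(tab_neg, "f")$auc, 1 - auc_estimate(tab, "f")$auc)
})

test_that("AUC, DeLong CI and paired test agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(5)
  a1 <- rnorm(30, 1.2); d1 <- rnorm(60)
  a2 <- a1 * 0.6 + rnorm(30, 0, 0.8); d2 <- d1 * 0.6 + rnorm(60, 0, 0.8)
  tab <- screening_table(
    ligand_id = sprintf("l%02d", 1:90),
    label = c(rep("active", 30), rep("decoy", 60)),
    scores = list(f1 = c(a1, d1), f2 = c(a2, d2))
  )
  est <- auc_estimate(tab, "f1")
  ref <- pROC::roc(response = c(rep(1, 30), rep(0, 60)), predictor = c(a1, d1),
                   direction = "<", quiet = TRUE)
  expect_equal(est$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(c(est$ci_low, est$ci_high), ci[c(1, 3)], tolerance = 1e-10)

  ours <- delong_paired_test(tab, "f1", "f2")
  ref2 <- pROC::roc(response = c(rep(1, 30), rep(0, 60)), predictor = c(a2, d2),
                    direction = "<", quiet = TRUE)
  theirs <- pROC::roc.test(ref, ref2, method = "delong", paired = TRUE)
  expect_equal(ours$p_value, theirs$p.value, tolerance = 1e-10)
})

test_that("paired DeLong test is null for rank-identical scores", {
  set.seed(6)
  a <- rnorm(10, 1); d <- rnorm(10)
  tab <- screening_table(
    ligand_id = sprintf("l%02d", 1:20),
    label = c(rep("active", 10), rep("decoy", 10)),
    scores = list(f1 = c(a, d), f2 = c(a, d), f3 = exp(c(a, d)))
  )
  same <- delong_paired_test(tab, "f1", "f2")
  expect_equal(same$auc_diff, 0)
  expect_equal(same$p_value, 1)
  mono <- delong_paired_test(tab, "f1", "f3")
  expect_equal(mono$auc_diff, 0)
})

test_that("youden_index reproduces published cutoff rows and rejects junk", {
  expect_equal(youden_index(0.7880, 0.8038), 0.5918)
  expect_equal(youden_index(85.51, 69.14, percent = TRUE), 0.5465)
  expect_equal(youden_index(0.5, 0.5), 0)
  expect_error(youden_index(1.2, 0.5), "\\[0, 1\\]")
})

test_that("optimal_cutoff maximizes J, breaking ties toward specificity", {
  # perfect separation: J = 1
  tab <- make_table(c(5, 6), c(1, 2))
  best <- optimal_cutoff(tab, "f")
  expect_equal(best$youden_j, 1)
  expect_equal(best$se + best$sp - 1, best$youden_j)

  # fully tied: the chance cutoffs, J = 0
  expect_equal(optimal_cutoff(make_table(c(1, 1), c(1, 1)), "f")$youden_j, 0)

  # 6-ligand table against exhaustive scan
  tab6 <- make_table(c(4, 3, 1), c(3, 2, 0))
  oracle <- brute_confusions(tab6$f, tab6$label)
  oracle_j <- oracle$tp / 3 + oracle$tn / 3 - 1
  best6 <- optimal_cutoff(tab6, "f")
  expect_equal(best6$youden_j, max(oracle_j))
  # tie-break: among maximizers, ours has the highest SP
  max_rows <- oracle[oracle_j == max(oracle_j), ]
  expect_equal(best6$sp, max(max_rows$tn / 3))
})

test_that("ppv follows its definition and the published worked examples", {
  expect_equal(ppv(222, 1904 - 222), 222 / 1904)
  expect_equal(round(100 * ppv(222, 1904 - 222)), 12)
  expect_equal(round(ppv(118, 547 - 118), 4), 0.2157)
  expect_equal(round(100 * ppv(118, 547 - 118)), 22)
  expect_equal(ppv(5, 0), 1.0)
  expect_error(ppv(0, 0), "undefined")
})

test_that("ppv_at_specificity picks the most sensitive qualifying cutoff", {
  # perfect separation: every target met with PPV 1
  tab <- make_table(c(5, 6, 7), c(1, 2, 3))
  out <- ppv_at_specificity(tab, "f", sp_targets = c(0.5, 0.9))
  expect_equal(out$ppv, c(1, 1))
  expect_true(all(out$reachable))

  # hand-built 10-ligand table against an exhaustive threshold scan
  tab10 <- make_table(c(9, 8, 6, 4), c(7, 6, 5, 3, 2, 1))
  oracle <- brute_confusions(tab10$f, tab10$label)
  for (target in c(0.6, 0.8, 0.95)) {
    got <- ppv_at_specificity(tab10, "f", sp_targets = target)
    ok <- oracle[oracle$tn / 6 >= target, ]
    best <- ok[which.max(ok$tp / 4), ]
    expect_equal(got$tp, best$tp)
    expect_equal(got$fp, best$fp)
  }

  # an unreachable target is flagged, with an empty call set
  tied <- make_table(c(1, 1), c(1, 1))
  un <- ppv_at_specificity(tied, "f", sp_targets = 0.5)
  expect_false(un$reachable)
  expect_equal(un$tp + un$fp, 0)
  expect_true(is.na(un$ppv))
})

test_that("PPV rises with the specificity target on a low-prevalence library", {
  tab <- gen_score_table(binormal_spec(60, 1940, target_auc = 0.86, seed = 9))
  out <- ppv_at_specificity(tab, "score", sp_targets = c(0.80, 0.90, 0.95, 0.99))
  expect_true(all(diff(out$ppv) > 0))
})

test_that("missing-score policies differ as documented", {
  tab <- screening_table(
    ligand_id = c("a1", "a2", "d1", "d2", "d3"),
    label = c("active", "active", "decoy", "decoy", "decoy"),
    scores = list(f = c(3, NA, 1, 2, NA))
  )
  excl <- auc_estimate(tab, "f", missing_policy = "exclude")
  expect_equal(c(excl$n_active, excl$n_decoy), c(1L, 2L))
  worst <- auc_estimate(tab, "f", missing_policy = "worst_score")
  expect_equal(c(worst$n_active, worst$n_decoy), c(2L, 3L))
  # under worst_score the undocked active loses to every scored decoy,
  # but ties with the undocked decoy
  expect_equal(worst$auc, brute_auc(c(3, 0), c(1, 2, 0)))
})
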