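test_that("tie policies order tied blocks as documented", {
  tab <- screening_table(
    ligand_id = c("act1", "dec1", "dec2", "act2"),
    label = c("active", "decoy", "decoy", "active"),
    scores = list(f = c(2, 2, 1, 3))
  )
  pess <- rank_ligands(tab, "f", tie_policy = "pessimistic")
  expect_equal(pess$label[1:2], factor(c("active", "decoy"),
                                       levels = c("active", "decoy")))
  expect_equal(pess$ligand_id[2:3], c("dec1", "act1"))  # decoy first in block
  opt <- rank_ligands(tab, "f", tie_policy = "optimistic")
  expect_equal(opt$ligand_id[2:3], c("act1", "dec1"))
  stab <- rank_ligands(tab, "f", tie_policy = "stable_id")
  expect_equal(stab$ligand_id[2:3], sort(c("act1", "dec1")))
  expect_equal(attr(pess, "tie_policy"), "pessimistic")

  # without ties, all policies agree with the plain score sort
  tab2 <- make_table(c(5, 3), c(4, 2))
  for (pol in c("pessimistic", "optimistic", "stable_id")) {
    expect_equal(rank_ligands(tab2, "f", pol)$score, c(5, 4, 3, 2))
  }
})

test_that("pessimistic EF never exceeds optimistic EF", {
  set.seed(21)
  for (i in 1:10) {
    tab <- gen_score_table(
      binormal_spec(20, 180, target_auc = 0.8, tie_quantum = 0.5, seed = i)
    )
    for (f in c(0.01, 0.05, 0.1)) {
      ef_p <- enrichment_factor(rank_ligands(tab, "score", "pessimistic"), f)$ef
      ef_o <- enrichment_factor(rank_ligands(tab, "score", "optimistic"), f)$ef
      expect_lte(ef_p, ef_o)
    }
  }
})

test_that("enrichment_factor matches direct substitution into the formula", {
  # 100 compounds, 10 actives, 5 of them in the top-10 window
  lab <- rep("decoy", 100)
  lab[c(1, 3, 5, 7, 9, 20, 30, 40, 50, 60)] <- "active"
  ranking <- tibble::tibble(label = factor(lab, levels = c("active", "decoy")))
  ef <- enrichment_factor(ranking, 0.10)
  expect_equal(ef$n_sampled, 10)
  expect_equal(ef$hits_sampled, 5)
  expect_equal(ef$ef, (5 / 10) * (100 / 10))

  # all actives on top: the 1/fraction ceiling
  lab2 <- c(rep("active", 10), rep("decoy", 990))
  ef2 <- enrichment_factor(
    tibble::tibble(label = factor(lab2, levels = c("active", "decoy"))), 0.01)
  expect_equal(ef2$ef, 100)

  expect_error(enrichment_factor(ranking, 0), "fraction")
  expect_error(enrichment_factor(ranking, 1.5), "fraction")
})

test_that("the sampled window uses round-half-up with floor one", {
  lab <- factor(c("active", rep("decoy", 8934)), levels = c("active", "decoy"))
  ranking <- tibble::tibble(label = lab)
  expect_equal(enrichment_factor(ranking, 0.005)$n_sampled, 45)  # 44.675 -> 45
  expect_equal(enrichment_factor(ranking, 1e-5)$n_sampled, 1)    # floor 1
})

test_that("EF of the whole database is exactly one", {
  set.seed(22)
  tab <- gen_score_table(binormal_spec(30, 300, target_auc = 0.7, seed = 3))
  ef <- enrichment_factor(rank_ligands(tab, "score"), 1)
  expect_identical(ef$ef, 1.0)
})

test_that("EF is invariant under monotone score transforms", {
  set.seed(23)
  a <- rnorm(20, 1); d <- rnorm(180)
  tab <- make_table(a, d)
  tab_t <- make_table(a^3 + 10, d^3 + 10)  # odd power: strictly monotone
  for (f in c(0.01, 0.05)) {
    expect_equal(enrichment_factor(rank_ligands(tab, "f"), f)$ef,
                 enrichment_factor(rank_ligands(tab_t, "f"), f)$ef)
  }
})

test_that("hit counts are nested across fractions", {
  set.seed(24)
  tab <- gen_score_table(binormal_spec(25, 475, target_auc = 0.8, seed = 4))
  ranking <- rank_ligands(tab, "score")
  hits <- vapply(c(0.005, 0.01, 0.02, 0.1, 0.5, 1),
                 function(f) enrichment_factor(ranking, f)$hits_sampled,
                 integer(1))
  expect_true(all(diff(hits) >= 0))
})

test_that("a perfect scorer saturates at the prevalence ceiling", {
  # 3% prevalence: the N_total/Hits_total cap (~33.3) binds before 1/fraction
  n_act <- 300; n_dec <- 9700
  lab <- factor(c(rep("active", n_act), rep("decoy", n_dec)),
                levels = c("active", "decoy"))
  ranking <- tibble::tibble(label = lab)
  for (f in c(0.005, 0.01, 0.02)) {
    ef <- enrichment_factor(ranking, f)
    expect_equal(ef$ef, 10000 / 300, tolerance = 1e-12)
  }
})

test_that("ef_profile is the cross product of direct calls", {
  tab <- gen_score_table(binormal_spec(20, 180, target_auc = 0.8, seed = 6),
                         function_names = c("f1", "f2"))
  prof <- ef_profile(tab, fractions = c(0.01, 0.02))
  expect_equal(nrow(prof), 4)
  direct <- enrichment_factor(rank_ligands(tab, "f2"), 0.02)
  got <- prof[prof$function_name == "f2" & prof$fraction == 0.02, ]
  expect_equal(got$ef, direct$ef)
  expect_equal(got$hits_sampled, direct$hits_sampled)
})

test_that("undocked handling changes the EF denominator as documented", {
  tab <- screening_table(
    ligand_id = sprintf("l%02d", 1:10),
    label = c(rep("active", 3), rep("decoy", 7)),
    scores = list(f = c(5, 4, NA, 3, 2, 1, NA, 0.5, 0.2, 0.1))
  )
  excl <- enrichment_factor(rank_ligands(tab, "f", missing_policy = "exclude"), 1)
  expect_equal(c(excl$n_total, excl$hits_total), c(8L, 2L))
  worst <- enrichment_factor(rank_ligands(tab, "f", missing_policy = "worst_score"), 1)
  expect_equal(c(worst$n_total, worst$hits_total), c(10L, 3L))
  # under worst_score the undocked ligands sit at the bottom of the ranking
  rk <- rank_ligands(tab, "f", missing_policy = "worst_score")
  expect_setequal(rk$ligand_id[9:10], c("l03", "l07"))
})
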