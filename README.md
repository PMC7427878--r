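# screeneval

Benchmarking tools for structure-based virtual screening, for computational
chemists validating a docking setup before committing to a large screen. The
package answers the two questions such a validation asks:

1. **Does the docking program reproduce known binding poses?** Heavy-atom
   RMSD between each re-docked pose and its crystal conformation, computed
   in the fixed receptor frame (no superposition), with success defined by
   an inclusive threshold, RMSD ≤ 2.0 Å by default. Optional
   symmetry-corrected RMSD minimizes over the automorphisms of the
   molecular graph.
2. **Does the scoring function rank actives above decoys?** ROC analysis on
   a labelled active/decoy library: pair-counting (Mann–Whitney) AUC with
   DeLong variance, 95% CI and a z-test against AUC = 0.5; paired DeLong
   comparison of scoring functions; Youden-index (J = SE + SP − 1) optimal
   cutoffs; positive predictive value PPV = TP/(TP + FP) at fixed
   specificity targets; and enrichment factors

   EF^X% = (Hits_sampled / N_sampled) · (N_total / Hits_total)

   at 0.5%, 1% and 2% of the ranked library.

Because the scoring engines behind such benchmarks are proprietary, the
package includes a binormal synthetic generator (decoys ~ N(0,1), actives ~
N(μ,1), AUC = Φ(μ/√2)) with configurable ties, docking failures and
inter-function correlation, so every stage runs and is testable with known
ground truth. The published TβR1 validation tables (22 re-docking RMSDs,
scoring-function cutoff summaries, PPV worked examples, EF reference
values) are bundled as data functions and used as worked examples.

## Worked example

```r
library(screeneval)

# pose stage: the bundled 22-complex re-docking benchmark
success_rate(tbr1_redocking_rmsd()$libdock_rmsd)
#> n_total n_success success_rate success_pct
#>      22        13        0.591          59
success_rate(tbr1_redocking_rmsd()$cdocker_rmsd)$success_pct
#> [1] 95

# scoring stage on a synthetic library with known truth
paths <- gen_benchmark_suite(tempfile("bench"), seed = 20260924)
cfg <- eval_config(score_table = paths$scores,
                   reference_sdf = paths$reference_sdf,
                   docked_sdf = paths$docked_sdf, seed = 20260924)
res <- run_full_evaluation(cfg, verbose = FALSE)
res$scoring[, c("function_name", "auc", "ci_low", "ci_high", "youden_j")]
#> function_name   auc ci_low ci_high youden_j
#> score_a       0.854  0.832   0.876    0.555
#> score_b       0.776  0.749   0.804    0.415
#> score_c       0.663  0.631   0.695    0.248
```

The three synthetic functions were generated with true AUCs 0.86, 0.77 and
0.66 (281 actives, 8677 decoys, 23 undockable ligands excluded); the
pipeline recovers them within their confidence intervals, ranks them
correctly, and its paired DeLong tests separate all three (Holm-adjusted
p < 1e-5). The numbered scripts under `analysis/` run this workflow step by
step — pose accuracy, fixture generation, ROC/AUC ranking, PPV and
enrichment — printing a short narrative and writing tables under
`results/`.

## Package layout

- `R/` — screening-table container and IO, SDF pose IO, RMSD/success
  metrics, ROC/AUC/DeLong/Youden/PPV, enrichment factors, the binormal
  generator, the bundled benchmark tables, and the pipeline orchestrator.
- `analysis/` — numbered narrative drivers over the package.
- `vignettes/virtual-screening-evaluation.Rmd` — the methods vignette:
  model conventions, tie and missing-score policies, numerical choices, and
  what the synthetic tests do and do not show about real screens.
- `tests/testthat/` — unit, property and acceptance suites, including
  brute-force oracles for RMSD, symmetry correction, AUC and confusion
  matrices.
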