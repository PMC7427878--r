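---
title: "Evaluating docking protocols and scoring functions for virtual screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating docking protocols and scoring functions for virtual screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screeneval)
```

Structure-based virtual screening has two separable failure modes: the
docking program can place a ligand wrongly in the binding site, and the
scoring function can rank a well-placed decoy above a well-placed active.
`screeneval` implements the standard evaluation battery for both stages —
pose accuracy by heavy-atom RMSD against crystal conformations, and
discrimination by ROC/AUC, Youden cutoffs, positive predictive value and
enrichment factors — together with a synthetic score generator with known
ground truth, so the whole battery can be exercised and validated without a
docking engine. The package ships the published TβR1 (transforming growth
factor-β type 1 receptor) benchmark tables as worked examples; their
arithmetic is recomputed by the test suite and by `scripts/acceptance.R`.

## Pose accuracy

For a ligand re-docked into its own crystal structure, the deviation is

$$\mathrm{RMSD} = \sqrt{\tfrac{1}{N}\sum_{i=1}^{N}\lVert r_i^{\mathrm{ref}} - r_i^{\mathrm{dock}}\rVert^2}$$

over the $N$ heavy atoms (`heavy_atom_rmsd()`). Three conventions matter and
are fixed deliberately:

* **No superposition.** Both poses are compared in the receptor frame. A
  least-squares fit before the RMSD would remove exactly the placement error
  a docking evaluation must detect; the property tests check that
  translating one pose by a vector $t$ of an otherwise identical pair
  changes the RMSD to $\lVert t\rVert$.
* **Heavy atoms only.** Hydrogens are stripped on input; their positions are
  usually model-built rather than docked, and many export formats omit them.
* **Inclusive threshold.** A pose succeeds when $\mathrm{RMSD} \le 2.0$ Å
  (`success_rate()`, threshold configurable). The bundled benchmark contains
  the instructive boundary case: a LibDock pose at 2.0171 Å fails while
  1.8278 Å succeeds, and on the 22 bundled complexes the criterion yields
  13/22 (59%) for LibDock and 21/22 (95%) for CDOCKER.

`symmetry_corrected_rmsd()` additionally minimizes over all element- and
bond-preserving automorphisms of the molecular graph, because chemically
indistinguishable relabelings (the flip of a para-disubstituted ring, a
rotated *tert*-butyl) can inflate the naive RMSD. The automorphism group is
counted first with bliss; groups above 10,000 mappings (a default chosen
well above anything drug-like; pathological graphs such as long repeated
chains can exceed it) fall back to the identity mapping with a warning
rather than enumerate. Plain RMSD remains the default, since published
re-docking tables rarely state symmetry handling; correction is opt-in via
`symmetry = TRUE` in `evaluate_poses()` or the config.

Pose files are read from SDF V2000 (`read_pose_pairs()`); molecules are
paired by title, and the docked record's atoms are matched onto the
reference order through an element-colored graph isomorphism, so files that
reorder atoms still pair correctly. V3000 is rejected outright rather than
half-supported. Mismatches are collected per ligand and reported, never
silently dropped.

## Scoring-function discrimination

All stored scores follow a single orientation contract — higher is better —
enforced at load time by per-column direction flags (`read_score_table()`
sign-flips `lower_better` columns). Calls are strict: at cutoff $t$ a ligand
is called active when its score exceeds $t$, and reported thresholds are
placed midway between adjacent distinct scores.

The AUC is the Mann–Whitney pair-counting statistic: the probability that a
random active outscores a random decoy, with active–decoy ties contributing
one half (the conventional treatment; the tie rate is a real feature of
quantized scoring functions, which the synthetic generator can reproduce via
`tie_quantum`). Its variance comes from the DeLong structural-components
estimator, computed via midranks; this gives the asymptotic 95% confidence
interval (clipped to $[0,1]$) and a two-sided normal test of
$\mathrm{AUC}=0.5$. Benchmarks of this kind sometimes label that test
loosely (e.g. as a chi-square); the DeLong z-test is the reproducible,
standard choice and matches MedCalc-style output. `trapezoid_auc()`
integrates the ROC staircase directly and must agree with pair counting to
$10^{-10}$ — an identity, not an approximation, which the suite enforces on
random tables with ties.

Two functions evaluated on the *same* ligands are compared with the paired
DeLong test (`delong_paired_test()`), whose power comes from the covariance
of the per-ligand structural components. The pipeline reports the full
pairwise matrix with raw p-values plus a Holm-adjusted column: raw values
for comparability with published pairwise tables, Holm because the matrix
grows quadratically in the number of functions. Both implementations are
cross-checked in the tests against `pROC` (as an independent reference) and
against a permutation oracle that swaps the two functions' scores per
ligand.

Cutoff selection uses the Youden index $J = SE + SP - 1$
(`youden_index()`, `optimal_cutoff()`); ties in $J$ resolve toward higher
specificity, the conservative choice for screening. The PPV analysis
(`ppv_at_specificity()`) reports, for each specificity target, the
most sensitive qualifying cutoff — with sensitivity ties broken toward the
strictest cutoff, since a looser one would add false positives without
gaining a single true positive. In a ~3%-prevalence library PPV is driven
almost entirely by specificity; the bundled worked examples show PPV rising
from 12% at $SP \ge 80\%$ to 28% at $SP \ge 99\%$ for one function, and the
same monotone pattern holds on synthetic libraries.

## Enrichment factors

$$\mathrm{EF}^{X\%} = \frac{\mathrm{Hits}^{X\%}_{\mathrm{sampled}}}{N^{X\%}_{\mathrm{sampled}}}\cdot\frac{N_{\mathrm{total}}}{\mathrm{Hits}_{\mathrm{total}}}$$

at the early fractions 0.5%, 1% and 2% of the ranked library
(`enrichment_factor()`, `ef_profile()`). Conventions the formula leaves
open:

* **Window size.** $N_{\mathrm{sampled}} = \max(1,
  \mathrm{round}(X\% \cdot N_{\mathrm{total}}))$, round half up — 0.5% of
  8935 docked ligands is a window of 45.
* **Ties.** A tied block straddling the window boundary is ordered by an
  explicit policy: `pessimistic` (decoys first, the default — a conservative
  estimate, since the true tie order of a scoring engine is unknowable),
  `optimistic`, or `stable_id`. The dominance `pessimistic EF ≤ optimistic
  EF` is property-tested.
* **Exactness.** EF is computed as a ratio of integer-valued products, so
  $\mathrm{EF}(X{=}100\%) = 1$ holds exactly in floating point, and a random
  ranking has mean EF 1 (checked over 10,000 shuffles).

## Missing scores

Real screens have undockable ligands (23 of 8958 in the bundled benchmark:
1 active, 22 decoys). The reader never drops them — it only flags
`docked = FALSE` — and every analysis takes an explicit `missing_policy`:
`exclude` (default, the docked-only evaluation most published tables use)
removes them from numerator *and* denominator, while `worst_score` keeps
them, ranked behind every scored ligand. Making the exclusion a visible
analysis parameter, rather than a parsing side effect, is deliberate: the
two policies answer different questions ("how good is the scoring function?"
vs "how good is the screen end-to-end?") and differ exactly when docking
failures correlate with activity.

## The synthetic generator

`gen_score_table()` draws decoy scores from $\mathcal N(0,1)$ and active
scores from $\mathcal N(\mu,1)$, the equal-variance binormal model — the
simplest family with a closed-form AUC, $\Phi(\mu/\sqrt2)$, which makes
ground truth exact and parameter recovery testable (the suite checks
$|\mathrm{bias}| < 0.01$ over 200 seeds at AUC 0.66/0.77/0.86 and the
benchmark composition of 281/8677). Optional knobs: `tie_quantum` rounds
scores to a grid, reproducing quantized engines; `undocked_fraction` (or
exact per-class counts) marks uniformly random ligands undocked;
`correlation` shares a latent component across functions, emulating scoring
functions that partially agree (real inter-function correlations are
unknown, so this stays a free parameter). `gen_pose_pair()` builds a random
bonded chain and rescales a random displacement field so the pair's RMSD
equals the target to $10^{-9}$; written to SDF the value is preserved to the
format's $10^{-4}$ coordinate precision.

What the generator does **not** emulate — and hence what passing tests do
not show about real screens: real score distributions are skewed and
heavy-tailed rather than Gaussian; docking failures correlate with ligand
properties, not uniform chance; decoys are property-matched to actives, not
i.i.d.; and pose fixtures are geometric chains, not chemically valid
molecules. The published AUC and EF values of the original eleven
proprietary scoring functions depend on score tables that are not available,
so they are shipped as reference documentation
(`tbr1_scoring_summary()`, `tbr1_ef_reference()`) and only their *internal*
arithmetic (Youden from SE/SP, PPV from counts, success rates from RMSDs) is
asserted. Three published Youden values and one published PPV percentage
disagree with their own printed inputs in the last digit — evidently
computed from unrounded upstream values — and are flagged in the bundled
tables rather than asserted.

## Problem sizes and determinism

The simulation-based checks use sizes chosen to give stable statistics at
interactive cost: 100 random tables for the trapezoid/pair-counting
identity, 10,000 shuffles for the random-ranking EF mean, 200 seeds per AUC
level for recovery bias, 1,000 tables of 100/100 for DeLong CI coverage
(95% ± 2%), and a 10,000-draw permutation oracle on 10/10 tables for the
paired test. All generators are pure functions of (spec, seed);
`run_full_evaluation()` with a fixed config and seed writes byte-identical
JSON reports, which the suite verifies.

## A minimal end-to-end run

```{r, eval = FALSE}
library(screeneval)

paths <- gen_benchmark_suite(tempfile("bench"), seed = 1)
cfg <- eval_config(score_table = paths$scores,
                   reference_sdf = paths$reference_sdf,
                   docked_sdf = paths$docked_sdf, seed = 1)
res <- run_full_evaluation(cfg, out_path = "report.json")
res$scoring   # AUC/CI/p + Youden cutoff per function, best first
res$pairwise  # paired DeLong matrix, raw and Holm-adjusted
res$ef        # enrichment profile at 0.5 / 1 / 2%
```

## Known limitations

Beyond the generator's idealizations above: no partial AUC, no
BEDROC/RIE-style weighted early-recognition metrics (natural extensions,
deliberately out of scope), no mol2/PDBQT input, and no protein-side
analysis of any kind. The DeLong interval is asymptotic; for very small
libraries (a handful of actives) an exact or bootstrap interval would be
preferable to its normal approximation.
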