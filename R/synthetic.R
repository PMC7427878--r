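#' Specification for a binormal synthetic score table
#'
#' The equal-variance binormal model is the simplest score model with a
#' closed-form AUC: decoys score `Normal(0, 1)`, actives `Normal(mu, 1)`, and
#' `AUC = pnorm(mu / sqrt(2))`. Exactly one of `target_auc` and `mu` is
#' given; the other is derived. A positive `tie_quantum` rounds scores to
#' multiples of the quantum, inducing ties; `undocked_fraction` marks a
#' uniformly random subset of ligands as docking failures (all scores
#' missing). The model is a testbed with known ground truth, not a claim
#' about the distribution of real docking scores.
#'
#' @param n_active,n_decoy Positive ligand counts.
#' @param target_auc True AUC in (0.5, 1); alternative to `mu`.
#' @param mu Active-score mean shift, `>= 0`; alternative to `target_auc`.
#' @param tie_quantum Non-negative rounding quantum (0 = continuous scores).
#' @param undocked_fraction Fraction of ligands marked undocked, in [0, 1).
#' @param seed Integer seed; generation is a pure function of (spec, seed).
#' @return A list of class `binormal_spec` with both `mu` and `target_auc`
#'   populated.
#' @export
#' @examples
#' binormal_spec(281, 8677, target_auc = 0.86, seed = 1)
binormal_spec <- function(n_active, n_decoy, target_auc = NULL, mu = NULL,
                          tie_quantum = 0, undocked_fraction = 0, seed = 1L) {
  if (n_active < 1 || n_decoy < 1) {
    stop("n_active and n_decoy must both be at least 1", call. = FALSE)
  }
  if (is.null(target_auc) == is.null(mu)) {
    stop("give exactly one of target_auc and mu", call. = FALSE)
  }
  if (is.null(mu)) {
    if (target_auc <= 0.5 || target_auc >= 1) {
      stop("target_auc must lie in (0.5, 1)", call. = FALSE)
    }
    mu <- sqrt(2) * stats::qnorm(target_auc)
  } else {
    if (mu < 0) stop("mu must be non-negative", call. = FALSE)
    target_auc <- stats::pnorm(mu / sqrt(2))
  }
  stopifnot(tie_quantum >= 0, undocked_fraction >= 0, undocked_fraction < 1)
  structure(
    list(n_active = as.integer(n_active), n_decoy = as.integer(n_decoy),
         target_auc = target_auc, mu = mu, tie_quantum = tie_quantum,
         undocked_fraction = undocked_fraction, seed = as.integer(seed)),
    class = "binormal_spec"
  )
}

#' Generate a synthetic screening table
#'
#' Draws one binormal score column per scoring-function name from a
#' [binormal_spec()]. Columns are independent by default; `correlation > 0`
#' shares a latent component across functions, emulating scoring functions
#' that partially agree. `mu` (or `target_auc`) may be a vector recycled over
#' `function_names` to give the functions different discriminative power.
#' Undocked ligands are chosen uniformly at random — or by the exact
#' `undocked` counts — and carry `NA` in every score column.
#'
#' @param spec A [binormal_spec()].
#' @param function_names Character vector of score column names.
#' @param correlation Shared-latent fraction of score variance, in [0, 1].
#' @param undocked Optional exact counts, `c(active = ..., decoy = ...)`,
#'   overriding `spec$undocked_fraction`.
#' @return A [screening_table()] with `spec$n_active + spec$n_decoy` rows.
#' @export
#' @examples
#' tab <- gen_score_table(binormal_spec(50, 500, target_auc = 0.86, seed = 7))
#' auc_estimate(tab, "score")
gen_score_table <- function(spec, function_names = "score", correlation = 0,
                            undocked = NULL) {
  stopifnot(inherits(spec, "binormal_spec"), correlation >= 0, correlation <= 1)
  n <- spec$n_active + spec$n_decoy
  k <- length(function_names)
  mu <- rep_len(spec$mu, k)
  withr::with_seed(spec$seed, {
    shift <- c(rep(1, spec$n_active), rep(0, spec$n_decoy))
    latent <- stats::rnorm(n)
    scores <- lapply(seq_len(k), function(j) {
      eps <- stats::rnorm(n)
      s <- mu[j] * shift +
        sqrt(correlation) * latent + sqrt(1 - correlation) * eps
      if (spec$tie_quantum > 0) {
        s <- round(s / spec$tie_quantum) * spec$tie_quantum
      }
      s
    })
    names(scores) <- function_names
    if (is.null(undocked)) {
      n_un <- as.integer(floor(spec$undocked_fraction * n + 0.5))
      idx_un <- if (n_un > 0) sample.int(n, n_un) else integer(0)
    } else {
      idx_un <- c(
        sample.int(spec$n_active, undocked[["active"]]),
        spec$n_active + sample.int(spec$n_decoy, undocked[["decoy"]])
      )
    }
  })
  for (j in seq_len(k)) scores[[j]][idx_un] <- NA_real_
  width <- nchar(as.character(n))
  screening_table(
    ligand_id = sprintf(paste0("lig%0", width, "d"), seq_len(n)),
    label = c(rep("active", spec$n_active), rep("decoy", spec$n_decoy)),
    scores = scores
  )
}

#' Generate a synthetic pose pair with an exact RMSD
#'
#' Builds a random chain "molecule" (bonded walk with ~1.5 Angstrom steps)
#' as the reference conformation, then displaces every atom along a random
#' direction field rescaled so that [heavy_atom_rmsd()] of the pair equals
#' `target_rmsd` to machine precision. Pose fixtures are geometric, not
#' chemically valid molecules.
#'
#' @param n_atoms Number of heavy atoms, `>= 1`.
#' @param target_rmsd Desired RMSD in Angstrom, `>= 0`.
#' @param seed Integer seed.
#' @param ligand_id Identifier for the pair.
#' @return A [pose_pair()] with carbon atoms and chain bonds.
#' @export
gen_pose_pair <- function(n_atoms, target_rmsd, seed = 1L,
                          ligand_id = sprintf("synthetic_%d", seed)) {
  stopifnot(n_atoms >= 1, target_rmsd >= 0)
  withr::with_seed(as.integer(seed), {
    steps <- matrix(stats::rnorm(3 * n_atoms), ncol = 3)
    steps <- 1.5 * steps / sqrt(rowSums(steps^2))
    ref <- apply(steps, 2, cumsum)
    ref <- matrix(ref, ncol = 3)
    disp <- matrix(stats::rnorm(3 * n_atoms), ncol = 3)
  })
  scale <- if (target_rmsd == 0) 0 else target_rmsd / sqrt(mean(rowSums(disp^2)))
  bonds <- if (n_atoms > 1) {
    cbind(seq_len(n_atoms - 1), seq_len(n_atoms - 1) + 1L)
  } else {
    matrix(integer(0), ncol = 2)
  }
  pose_pair(
    ligand_id = ligand_id,
    reference_coords = ref,
    docked_coords = ref + scale * disp,
    elements = rep("C", n_atoms),
    bonds = bonds
  )
}

#' Write a complete synthetic benchmark fixture set
#'
#' Emulates the composition of a DUD-E-style TbetaR1 screening benchmark:
#' a score table of 281 actives and 8677 decoys (8958 ligands) with three
#' scoring functions of true AUC 0.86, 0.77 and 0.66 and with exactly
#' 1 active + 22 decoys undocked, plus reference/docked SDF pose pairs whose
#' RMSDs equal the published CDOCKER re-docking values for the 22 TbetaR1
#' co-crystal ligands (so the pose stage reproduces the 21/22 success rate).
#' Re-running with the same seed reproduces the files byte-identically.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, a list of the written paths (`scores`, `reference_sdf`,
#'   `docked_sdf`).
#' @export
gen_benchmark_suite <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- binormal_spec(281, 8677, target_auc = 0.86, seed = seed)
  spec$mu <- sqrt(2) * stats::qnorm(c(0.86, 0.77, 0.66))
  tab <- gen_score_table(
    spec, function_names = c("score_a", "score_b", "score_c"),
    undocked = c(active = 1, decoy = 22)
  )
  scores_path <- file.path(dir, "scores.csv")
  write_score_table(tab, scores_path)

  redock <- tbr1_redocking_rmsd()
  mols_ref <- vector("list", nrow(redock))
  mols_dock <- vector("list", nrow(redock))
  for (i in seq_len(nrow(redock))) {
    p <- gen_pose_pair(
      n_atoms = 20, target_rmsd = redock$cdocker_rmsd[i],
      seed = as.integer(seed) + i, ligand_id = redock$ligand_id[i]
    )
    mols_ref[[i]] <- list(id = p$ligand_id, elements = p$elements,
                          coords = p$reference_coords, bonds = p$bonds)
    mols_dock[[i]] <- list(id = p$ligand_id, elements = p$elements,
                           coords = p$docked_coords, bonds = p$bonds)
  }
  ref_path <- file.path(dir, "reference.sdf")
  dock_path <- file.path(dir, "docked.sdf")
  write_sdf(mols_ref, ref_path)
  write_sdf(mols_dock, dock_path)
  invisible(list(scores = scores_path, reference_sdf = ref_path,
                 docked_sdf = dock_path))
}
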