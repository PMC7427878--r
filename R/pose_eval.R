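#' Heavy-atom RMSD between a docked pose and its reference conformation
#'
#' Computes `sqrt(mean(||ref_i - dock_i||^2))` over the N heavy atoms of a
#' [pose_pair()]. Both poses must already be expressed in the receptor frame;
#' no least-squares superposition is performed — superposing would hide
#' exactly the placement errors a docking evaluation must measure.
#'
#' @param pair A [pose_pair()].
#' @return Non-negative RMSD in Angstrom.
#' @export
#' @examples
#' p <- gen_pose_pair(n_atoms = 10, target_rmsd = 1.5, seed = 1)
#' heavy_atom_rmsd(p)
heavy_atom_rmsd <- function(pair) {
  stopifnot(inherits(pair, "pose_pair"))
  d <- pair$reference_coords - pair$docked_coords
  sqrt(mean(rowSums(d * d)))
}

#' Symmetry-corrected heavy-atom RMSD
#'
#' Minimum of [heavy_atom_rmsd()] over all element- and bond-preserving
#' automorphisms of the molecular graph, so that chemically indistinguishable
#' atom relabellings (e.g. the two-fold flip of a para-disubstituted ring)
#' cannot inflate the deviation. Always `<=` the plain RMSD; equal to it for
#' molecules whose only automorphism is the identity.
#'
#' The automorphism group is counted first (bliss); if it exceeds
#' `max_automorphisms` the function falls back to the identity mapping with a
#' warning rather than enumerate an intractable group.
#'
#' @param pair A [pose_pair()] with bond information.
#' @param max_automorphisms Enumeration cap (default 10000).
#' @return Non-negative RMSD in Angstrom.
#' @export
symmetry_corrected_rmsd <- function(pair, max_automorphisms = 10000) {
  stopifnot(inherits(pair, "pose_pair"))
  plain <- heavy_atom_rmsd(pair)
  g <- mol_graph(pair$elements, pair$bonds)
  colors <- element_colors(pair$elements)[[1]]
  n_auto <- suppressWarnings(
    as.numeric(igraph::count_automorphisms(g, colors = colors)$group_size)
  )
  if (!is.finite(n_auto) || n_auto > max_automorphisms) {
    warning("automorphism group size ", n_auto, " exceeds cap ",
            max_automorphisms, "; returning uncorrected RMSD", call. = FALSE)
    return(plain)
  }
  if (n_auto == 1) return(plain)
  maps <- igraph::isomorphisms(g, g, method = "vf2",
                               vertex.color1 = colors, vertex.color2 = colors)
  best <- plain
  ref <- pair$reference_coords
  dock <- pair$docked_coords
  for (m in maps) {
    # automorphism m relabels the docked pose's atoms
    d <- ref - dock[as.integer(m), , drop = FALSE]
    best <- min(best, sqrt(mean(rowSums(d * d))))
  }
  best
}

#' Docking success rate at an RMSD threshold
#'
#' Counts poses whose RMSD is at or below the threshold (the comparison is
#' inclusive: a pose at exactly the threshold succeeds, one at 2.0171 with
#' the default 2.0 Angstrom criterion fails).
#'
#' @param rmsds Non-empty numeric vector of non-negative RMSD values (Angstrom).
#' @param threshold Success threshold in Angstrom; default 2.0.
#' @return A tibble with `n_total`, `n_success`, `success_rate` (exact
#'   fraction), and `success_pct` (nearest-integer percentage, the form in
#'   which docking benchmarks usually report it).
#' @export
#' @examples
#' success_rate(c(0.3, 1.9, 2.0, 2.1))  # 3/4 succeed: 2.0 is inclusive
success_rate <- function(rmsds, threshold = 2.0) {
  rmsds <- as.numeric(rmsds)
  if (length(rmsds) == 0) stop("empty RMSD list", call. = FALSE)
  if (anyNA(rmsds) || any(rmsds < 0)) {
    stop("RMSD values must be non-negative and non-missing", call. = FALSE)
  }
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  n_success <- sum(rmsds <= threshold)
  tibble::tibble(
    n_total = length(rmsds),
    n_success = n_success,
    success_rate = n_success / length(rmsds),
    success_pct = round(100 * n_success / length(rmsds))
  )
}

#' Evaluate a set of pose pairs
#'
#' Per-ligand RMSD table plus the overall success summary, the shape in which
#' re-docking validations are reported.
#'
#' @param pairs List of [pose_pair()] objects.
#' @param threshold Success threshold in Angstrom.
#' @param symmetry If `TRUE`, use [symmetry_corrected_rmsd()].
#' @return List with `per_ligand` (tibble: ligand_id, rmsd, threshold,
#'   success, symmetry_corrected) and `summary` (the [success_rate()] tibble).
#' @export
evaluate_poses <- function(pairs, threshold = 2.0, symmetry = FALSE) {
  stopifnot(length(pairs) > 0)
  rmsd <- vapply(
    pairs,
    if (symmetry) symmetry_corrected_rmsd else heavy_atom_rmsd,
    numeric(1)
  )
  per_ligand <- tibble::tibble(
    ligand_id = vapply(pairs, function(p) p$ligand_id, character(1)),
    rmsd = unname(rmsd),
    threshold = threshold,
    success = unname(rmsd <= threshold),
    symmetry_corrected = symmetry
  )
  list(per_ligand = per_ligand, summary = success_rate(rmsd, threshold))
}
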