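# Small builders and independent brute-force oracles shared across tests.
# Oracles deliberately re-derive each quantity from its definition, never
# through the code paths they check.

make_table <- function(active_scores, decoy_scores, function_name = "f") {
  scores <- list(c(active_scores, decoy_scores))
  names(scores) <- function_name
  screening_table(
    ligand_id = sprintf("lig%03d", seq_len(length(active_scores) + length(decoy_scores))),
    label = c(rep("active", length(active_scores)),
              rep("decoy", length(decoy_scores))),
    scores = scores
  )
}

# Pair-counting AUC straight from the Mann-Whitney definition.
brute_auc <- function(active_scores, decoy_scores) {
  cmp <- outer(active_scores, decoy_scores,
               function(a, d) (a > d) + 0.5 * (a == d))
  mean(cmp)
}

# RMSD as an explicit per-atom loop over the defining sum.
brute_rmsd <- function(pair) {
  n <- nrow(pair$reference_coords)
  total <- 0
  for (i in seq_len(n)) {
    total <- total + sum((pair$reference_coords[i, ] - pair$docked_coords[i, ])^2)
  }
  sqrt(total / n)
}

# Exhaustive symmetry-corrected RMSD: try every atom permutation that
# preserves elements and the bond set (feasible for <= 8 atoms).
brute_symmetry_rmsd <- function(pair) {
  n <- nrow(pair$reference_coords)
  stopifnot(n <= 8)
  adj <- matrix(FALSE, n, n)
  if (nrow(pair$bonds) > 0) {
    adj[pair$bonds] <- TRUE
    adj[pair$bonds[, 2:1, drop = FALSE]] <- TRUE
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- Inf
  for (p in perms(seq_len(n))) {
    if (!identical(pair$elements[p], pair$elements)) next
    if (!identical(adj[p, p], adj)) next
    d <- pair$reference_coords - pair$docked_coords[p, , drop = FALSE]
    best <- min(best, sqrt(mean(rowSums(d * d))))
  }
  best
}

# Exhaustive confusion matrices under the strict score > t call rule,
# one per candidate cut between distinct score values.
brute_confusions <- function(score, label) {
  vals <- sort(unique(score), decreasing = TRUE)
  cuts <- c(Inf, (vals[-length(vals)] + vals[-1]) / 2, -Inf)
  do.call(rbind, lapply(cuts, function(t) {
    call_pos <- score > t
    data.frame(
      threshold = t,
      tp = sum(call_pos & label == "active"),
      fp = sum(call_pos & label == "decoy"),
      tn = sum(!call_pos & label == "decoy"),
      fn = sum(!call_pos & label == "active")
    )
  }))
}

write_test_sdf <- function(path, mols) {
  write_sdf(mols, path)
  path
}

# A small asymmetric molecule (no non-trivial automorphism): C-C-O-N chain
# with a fluorine branch (distinct element, so the two substituents on the
# branch atom cannot be swapped).
asymmetric_mol <- function(coords = NULL) {
  elements <- c("C", "C", "O", "N", "F")
  bonds <- rbind(c(1, 2), c(2, 3), c(3, 4), c(2, 5))
  if (is.null(coords)) {
    coords <- matrix(c(0, 0, 0,  1.5, 0, 0,  2.2, 1.2, 0,
                       3.6, 1.2, 0.4,  1.9, -1.4, 0.3),
                     ncol = 3, byrow = TRUE)
  }
  list(elements = elements, bonds = bonds, coords = coords)
}

# A 2-fold symmetric "para-disubstituted ring": 4-ring of carbons with two
# identical O substituents on opposite corners; flipping the ring is an
# automorphism.
symmetric_mol <- function() {
  elements <- c("C", "C", "C", "C", "O", "O")
  bonds <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1), c(1, 5), c(3, 6))
  coords <- matrix(c(1, 0, 0,   0, 1, 0,  -1, 0, 0,   0, -1, 0,
                     2.4, 0, 0, -2.4, 0, 0),
                   ncol = 3, byrow = TRUE)
  list(elements = elements, bonds = bonds, coords = coords)
}
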