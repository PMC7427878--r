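#' Construct a pose pair
#'
#' A pose pair holds two conformations of the same ligand expressed in the
#' same (receptor) coordinate frame: the reference crystal conformation and
#' the docked pose. Only heavy atoms are stored; atom `i` of the docked pose
#' corresponds to atom `i` of the reference. No superposition is ever applied
#' to either pose — a docking evaluation compares placements in the fixed
#' receptor frame.
#'
#' @param ligand_id Ligand identifier.
#' @param reference_coords,docked_coords Numeric `N x 3` matrices of heavy-atom
#'   coordinates in Angstrom, row `i` of both matrices being the same atom.
#' @param elements Character vector of length `N` of element symbols.
#' @param bonds Integer `M x 2` matrix of 1-based atom-index pairs (used for
#'   symmetry correction); may have zero rows.
#' @return An object of class `pose_pair`.
#' @seealso [heavy_atom_rmsd()], [read_pose_pairs()], [gen_pose_pair()]
#' @export
pose_pair <- function(ligand_id, reference_coords, docked_coords, elements,
                      bonds = matrix(integer(0), ncol = 2)) {
  ref <- as.matrix(reference_coords)
  dock <- as.matrix(docked_coords)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  n <- nrow(ref)
  if (n < 1) stop("pose pair needs at least one atom", call. = FALSE)
  if (!all(dim(ref) == c(n, 3)) || !all(dim(dock) == c(n, 3))) {
    stop("reference and docked coordinates must both be N x 3 with equal N",
         call. = FALSE)
  }
  if (length(elements) != n) stop("elements length must match atom count", call. = FALSE)
  if (!all(is.finite(ref)) || !all(is.finite(dock))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  if (nrow(bonds) > 0 && (min(bonds) < 1 || max(bonds) > n)) {
    stop("bond indices out of range", call. = FALSE)
  }
  structure(
    list(ligand_id = as.character(ligand_id), reference_coords = ref,
         docked_coords = dock, elements = as.character(elements), bonds = bonds),
    class = "pose_pair"
  )
}

#' @export
print.pose_pair <- function(x, ...) {
  cat("<pose_pair> ", x$ligand_id, ": ", nrow(x$reference_coords),
      " heavy atoms, ", nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}

# Parse an SDF (V2000) file into heavy-atom molecule records:
# list of (id, elements, coords N x 3, bonds M x 2). Hydrogens are dropped and
# bond indices re-mapped onto the heavy-atom numbering; bonds touching a
# dropped hydrogen disappear.
read_sdf_molecules <- function(path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop("ChemmineR is required to read SDF files", call. = FALSE)
  }
  if (any(grepl("V3000", readLines(path, warn = FALSE), fixed = TRUE))) {
    stop("V3000 SDF records are not supported; supply V2000 (", path, ")",
         call. = FALSE)
  }
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(path))
  ids <- ChemmineR::sdfid(sdfs)
  mols <- vector("list", length(sdfs))
  for (i in seq_along(sdfs)) {
    ab <- ChemmineR::atomblock(sdfs[[i]])
    bb <- ChemmineR::bondblock(sdfs[[i]])
    elements <- sub("_\\d+$", "", rownames(ab))
    coords <- unname(ab[, 1:3, drop = FALSE])
    bonds <- if (nrow(bb) > 0) {
      unname(cbind(as.integer(bb[, 1]), as.integer(bb[, 2])))
    } else {
      matrix(integer(0), ncol = 2)
    }
    heavy <- which(toupper(elements) != "H")
    remap <- rep(NA_integer_, length(elements))
    remap[heavy] <- seq_along(heavy)
    keep_bond <- if (nrow(bonds) > 0) {
      !is.na(remap[bonds[, 1]]) & !is.na(remap[bonds[, 2]])
    } else logical(0)
    mols[[i]] <- list(
      id = ids[i],
      elements = elements[heavy],
      coords = coords[heavy, , drop = FALSE],
      bonds = matrix(remap[bonds[keep_bond, , drop = FALSE]], ncol = 2)
    )
  }
  names(mols) <- ids
  mols
}

# Element-colored molecular graph for igraph matching.
mol_graph <- function(elements, bonds) {
  g <- igraph::make_empty_graph(n = length(elements), directed = FALSE)
  if (nrow(bonds) > 0) g <- igraph::add_edges(g, t(bonds))
  g
}

element_colors <- function(...) {
  all_el <- unlist(list(...))
  lapply(list(...), function(e) as.integer(factor(e, levels = sort(unique(all_el)))))
}

# First element-preserving graph isomorphism mapping molecule a onto b,
# as an integer vector m with a's atom i corresponding to b's atom m[i].
# NULL if the graphs are not isomorphic.
match_atoms <- function(mol_a, mol_b) {
  if (identical(mol_a$elements, mol_b$elements) &&
      identical(mol_a$bonds[order(mol_a$bonds[, 1], mol_a$bonds[, 2]), , drop = FALSE],
                mol_b$bonds[order(mol_b$bonds[, 1], mol_b$bonds[, 2]), , drop = FALSE])) {
    return(seq_along(mol_a$elements))
  }
  cols <- element_colors(mol_a$elements, mol_b$elements)
  maps <- igraph::isomorphisms(
    mol_graph(mol_a$elements, mol_a$bonds),
    mol_graph(mol_b$elements, mol_b$bonds),
    method = "vf2", vertex.color1 = cols[[1]], vertex.color2 = cols[[2]]
  )
  if (length(maps) == 0) return(NULL)
  as.integer(maps[[1]])
}

#' Read matched reference/docked pose pairs from two SDF files
#'
#' Reads two SDF (V2000) files — the reference crystal conformations and the
#' docked poses — and pairs molecules with identical titles. Hydrogens are
#' dropped from both records; the docked record's atoms are matched onto the
#' reference atom order through an element-preserving isomorphism of the
#' molecular graphs, so the two files need not list atoms in the same order.
#' IDs present in only one file are reported as unmatched, not fatal;
#' per-ligand failures (heavy-atom count mismatch, non-isomorphic graphs)
#' become error entries.
#'
#' @param reference_path,docked_path Paths to the two SDF V2000 files.
#' @return A list with elements `pairs` (named list of [pose_pair()]),
#'   `unmatched` (tibble of id/file for molecules missing a partner), and
#'   `errors` (tibble of id/message).
#' @export
read_pose_pairs <- function(reference_path, docked_path) {
  ref <- read_sdf_molecules(reference_path)
  dock <- read_sdf_molecules(docked_path)
  shared <- intersect(names(ref), names(dock))
  unmatched <- tibble::tibble(
    ligand_id = c(setdiff(names(ref), shared), setdiff(names(dock), shared)),
    file = c(rep("docked", length(setdiff(names(ref), shared))),
             rep("reference", length(setdiff(names(dock), shared))))
  )
  names(unmatched)[2] <- "missing_from"

  pairs <- list()
  errors <- list()
  for (id in shared) {
    r <- ref[[id]]
    d <- dock[[id]]
    if (length(r$elements) != length(d$elements)) {
      errors[[id]] <- sprintf(
        "heavy-atom count mismatch: %d (reference) vs %d (docked)",
        length(r$elements), length(d$elements))
      next
    }
    m <- match_atoms(d, r)
    if (is.null(m)) {
      errors[[id]] <- "molecular graphs are not element-isomorphic"
      next
    }
    dock_coords <- d$coords
    dock_coords[m, ] <- d$coords
    pairs[[id]] <- pose_pair(
      ligand_id = id,
      reference_coords = r$coords,
      docked_coords = dock_coords,
      elements = r$elements,
      bonds = r$bonds
    )
  }
  list(
    pairs = pairs,
    unmatched = unmatched,
    errors = tibble::tibble(
      ligand_id = names(errors),
      message = unlist(unname(errors), use.names = FALSE) %||% character(0)
    )
  )
}

#' Write molecules as an SDF V2000 file
#'
#' Emits a minimal V2000 molblock per molecule (single bonds only; the bond
#' order is irrelevant to RMSD evaluation and symmetry matching, which use
#' connectivity). Coordinates are written at the format's 4-decimal
#' precision. Round-trips through [read_pose_pairs()].
#'
#' @param mols List of molecule records: each a list with `id`, `elements`,
#'   `coords` (`N x 3`), `bonds` (`M x 2`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path) {
  blocks <- vapply(mols, function(m) {
    n <- length(m$elements)
    bonds <- matrix(as.integer(m$bonds), ncol = 2)
    lines <- c(
      m$id,
      "  screeneval",
      "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(bonds)),
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              m$coords[, 1], m$coords[, 2], m$coords[, 3], m$elements),
      if (nrow(bonds) > 0) sprintf("%3d%3d  1  0", bonds[, 1], bonds[, 2]),
      "M  END",
      "$$$$"
    )
    paste(lines, collapse = "\n")
  }, character(1))
  writeLines(blocks, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
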