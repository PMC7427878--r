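test_that("identical SDF files give identity pose pairs", {
  m <- asymmetric_mol()
  ref <- write_test_sdf(withr::local_tempfile(fileext = ".sdf"),
                        list(list(id = "mol1", elements = m$elements,
                                  coords = m$coords, bonds = m$bonds)))
  res <- read_pose_pairs(ref, ref)
  expect_length(res$pairs, 1)
  expect_equal(res$pairs$mol1$reference_coords,
               res$pairs$mol1$docked_coords, tolerance = 1e-8)
  expect_equal(nrow(res$unmatched), 0)
  expect_equal(heavy_atom_rmsd(res$pairs$mol1), 0)
})

test_that("molecules present in only one file are reported, not fatal", {
  m <- asymmetric_mol()
  mk <- function(ids) lapply(ids, function(id) {
    list(id = id, elements = m$elements, coords = m$coords, bonds = m$bonds)
  })
  ref <- write_test_sdf(withr::local_tempfile(fileext = ".sdf"),
                        mk(c("A", "B", "C")))
  dock <- write_test_sdf(withr::local_tempfile(fileext = ".sdf"),
                         mk(c("B", "C", "D")))
  res <- read_pose_pairs(ref, dock)
  expect_setequal(names(res$pairs), c("B", "C"))
  expect_setequal(res$unmatched$ligand_id, c("A", "D"))
})

test_that("hydrogens are stripped so H-explicit and H-free records agree", {
  m <- asymmetric_mol()
  with_h <- list(
    id = "mol1",
    elements = c(m$elements, "H", "H"),
    coords = rbind(m$coords, c(9, 9, 9), c(8, 8, 8)),
    bonds = rbind(m$bonds, c(1, 6), c(4, 7))
  )
  without_h <- list(id = "mol1", elements = m$elements,
                    coords = m$coords, bonds = m$bonds)
  ref <- write_test_sdf(withr::local_tempfile(fileext = ".sdf"), list(with_h))
  dock <- write_test_sdf(withr::local_tempfile(fileext = ".sdf"), list(without_h))
  res <- read_pose_pairs(ref, dock)
  pair <- res$pairs$mol1
  expect_equal(pair$elements, m$elements)
  expect_equal(heavy_atom_rmsd(pair), 0)
  # oracle: manual hydrogen stripping of the H-explicit record
  expect_equal(nrow(pair$reference_coords), nrow(m$coords))
})

test_that("docked atoms listed in scrambled order are matched by the graph", {
  m <- asymmetric_mol()
  perm <- c(3, 5, 1, 4, 2)  # docked file lists atoms in this order
  inv <- order(perm)
  scrambled <- list(
    id = "mol1",
    elements = m$elements[perm],
    coords = m$coords[perm, ],
    bonds = matrix(inv[m$bonds], ncol = 2)
  )
  ref <- write_test_sdf(withr::local_tempfile(fileext = ".sdf"),
                        list(list(id = "mol1", elements = m$elements,
                                  coords = m$coords, bonds = m$bonds)))
  dock <- write_test_sdf(withr::local_tempfile(fileext = ".sdf"), list(scrambled))
  res <- read_pose_pairs(ref, dock)
  expect_equal(heavy_atom_rmsd(res$pairs$mol1), 0)
})

test_that("heavy-atom count mismatches become per-ligand errors", {
  m <- asymmetric_mol()
  short <- list(id = "mol1", elements = m$elements[1:4],
                coords = m$coords[1:4, ], bonds = rbind(c(1, 2), c(2, 3), c(3, 4)))
  ref <- write_test_sdf(withr::local_tempfile(fileext = ".sdf"),
                        list(list(id = "mol1", elements = m$elements,
                                  coords = m$coords, bonds = m$bonds)))
  dock <- write_test_sdf(withr::local_tempfile(fileext = ".sdf"), list(short))
  res <- read_pose_pairs(ref, dock)
  expect_length(res$pairs, 0)
  expect_match(res$errors$message, "count mismatch")
})

test_that("V3000 records are rejected with a clear message", {
  tf <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c("mol1", "", "", "  0  0  0  0  0  0  0  0  0  0999 V3000",
               "M  END", "$$$$"), tf)
  expect_error(read_pose_pairs(tf, tf), "V3000")
})

test_that("write_sdf round-trips coordinates at format precision", {
  p <- gen_pose_pair(n_atoms = 15, target_rmsd = 1.3, seed = 5,
                     ligand_id = "syn1")
  path <- write_test_sdf(withr::local_tempfile(fileext = ".sdf"),
                         list(list(id = "syn1", elements = p$elements,
                                   coords = p$reference_coords, bonds = p$bonds)))
  mols <- screeneval:::read_sdf_molecules(path)
  expect_equal(mols$syn1$coords, p$reference_coords, tolerance = 1e-4)
  expect_equal(mols$syn1$elements, p$elements)
  expect_equal(mols$syn1$bonds, p$bonds)
})
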