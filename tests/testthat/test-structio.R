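# PDB IO, bond perception, ligand/site detection, rotatable bonds

test_that("readPDB parses single structures and multi-model trajectories", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1      11.104   6.134  -6.504  1.00  0.00           C",
    "END"), f)
  tr <- readPDB(f)
  expect_equal(nFrames(tr), 1)
  expect_equal(nAtoms(tr), 1)
  expect_equal(unname(coords(frameSystem(tr, 1))[1, ]),
               c(11.104, 6.134, -6.504))

  # three MODEL blocks of the same 10 atoms
  sys <- chain_system(rep("C", 10))
  f2 <- tempfile(fileext = ".pdb")
  writePDB(trajectory(sys, coords = list(coords(sys), coords(sys) + 0.5,
                                         coords(sys) + 1.0)), f2)
  tr2 <- readPDB(f2)
  expect_equal(nFrames(tr2), 3)
  expect_equal(nAtoms(tr2), 10)
  expect_equal(tr2@coords[[3]] - tr2@coords[[1]],
               matrix(1, 10, 3), tolerance = 1e-6)
})

test_that("readPDB reports format and empty-input errors", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1      xx.xxx   6.134  -6.504  1.00  0.00           C"),
    f)
  expect_error(readPDB(f), class = "afp_format_error")
  expect_error(readPDB(f), "line 1")
  f2 <- tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", f2)
  expect_error(readPDB(f2), class = "afp_empty_input")
})

test_that("PDB round-trip preserves counts, identity and 3-decimal coords", {
  p <- makeToyPocket(6, seed = 11, n_waters = 2)
  f <- tempfile(fileext = ".pdb")
  writeChargeTable(p$system, sub("pdb$", "csv", f))
  writePDB(p$system, f)
  back <- frameSystem(readPDB(f, chargeFile = sub("pdb$", "csv", f)), 1)
  expect_equal(nAtoms(back), nAtoms(p$system))
  expect_equal(atoms(back)$name, atoms(p$system)$name)
  expect_equal(residueLabels(back), residueLabels(p$system))
  expect_equal(coords(back), coords(p$system), tolerance = 6e-4)
  expect_equal(atoms(back)$charge, atoms(p$system)$charge, tolerance = 1e-6)
})

test_that("generated complexes match their manifest bookkeeping", {
  p <- makeToyPocket(5, seed = 1)
  expect_equal(nAtoms(p$system), p$manifest$n_atoms)
  expect_equal(length(unique(residueLabels(p$system))),
               p$manifest$n_residues)
  expect_equal(length(p$ligand), p$manifest$n_ligand_atoms)
})

test_that("bond perception follows the covalent-radius rule", {
  # C-C at 1.54 A: 0.77 + 0.77 + 0.45 = 1.99 >= 1.54 -> bonded
  s <- chain_system(c("C", "C"), spacing = 1.54)
  expect_equal(nrow(bonds(s)), 1)
  # C-C at 3.0 A: beyond any covalent threshold
  s2 <- chain_system(c("C", "C"), spacing = 3.0)
  expect_equal(nrow(bonds(s2)), 0)
  # O-H at 0.96 A: 0.66 + 0.37 + 0.45 = 1.48 >= 0.96 -> bonded
  s3 <- chain_system(c("O", "H"), spacing = 0.96)
  expect_equal(nrow(bonds(s3)), 1)
  # H-H never bonded
  s4 <- chain_system(c("H", "H"), spacing = 0.74)
  expect_equal(nrow(bonds(s4)), 0)
  # unknown element
  s5 <- molecularSystem(atom_row(1L, "X", "XX", 0, 0, 0))
  s5@atoms <- rbind(s5@atoms, atom_row(2L, "C", "C", 1, 0, 0))
  expect_error(perceiveBonds(s5), class = "afp_param_missing")
  expect_error(perceiveBonds(s5), "XX")
})

test_that("bond perception is invariant under atom reordering", {
  p <- makeToyPocket(4, seed = 3)
  at <- atoms(p$system)
  perm <- rev(seq_len(nrow(at)))
  sys_perm <- perceiveBonds(molecularSystem(at[perm, ]))
  b1 <- bonds(p$system)
  # map permuted bond indices back to original atom identities
  b2 <- apply(bonds(sys_perm), 2, function(i) perm[i])
  key <- function(b) sort(paste(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2])))
  expect_equal(key(b2), key(b1))
})

test_that("ligand detection picks the largest hetero component", {
  p <- makeToyPocket(5, seed = 2, n_waters = 3)
  expect_equal(detectLigand(p$system), p$ligand)

  # two candidates: a 4-atom and a 2-atom hetero molecule -> the larger
  big <- do.call(rbind, lapply(1:4, function(i)
    atom_row(i, paste0("C", i), "C", (i - 1) * 1.5, 0, 0)))
  small <- rbind(atom_row(5L, "C1", "C", 20, 0, 0, resseq = 2L),
                 atom_row(6L, "O1", "O", 21.4, 0, 0, resseq = 2L))
  sys <- perceiveBonds(molecularSystem(rbind(big, small)))
  expect_equal(detectLigand(sys), 1:4)

  # protein only -> no-ligand error
  prot <- molecularSystem(atom_row(1L, "CA", "C", 0, 0, 0,
                                   resname = "ALA", hetero = FALSE))
  expect_error(detectLigand(perceiveBonds(prot)), class = "afp_no_ligand")

  # waters and single-atom ions are not ligand candidates
  wat <- rbind(atom_row(1L, "O", "O", 0, 0, 0, resname = "HOH"),
               atom_row(2L, "NA", "NA", 8, 0, 0, resname = "NA",
                        resseq = 2L))
  expect_error(detectLigand(perceiveBonds(molecularSystem(wat))),
               class = "afp_no_ligand")
})

test_that("binding site obeys the distance threshold and ordering", {
  # ligand atom at origin; residues with nearest atoms at 7.9 and 8.1 A
  lig <- atom_row(1L, "C1", "C", 0, 0, 0)
  r1 <- atom_row(2L, "CA", "C", 7.9, 0, 0, resname = "ALA", chain = "A",
                 resseq = 1L, hetero = FALSE)
  r2 <- atom_row(3L, "CA", "C", -8.1, 0, 0, resname = "GLY", chain = "A",
                 resseq = 2L, hetero = FALSE)
  sys <- molecularSystem(rbind(lig, r1, r2))
  site <- bindingSite(sys, 1L, cutoff = 8.0)
  expect_equal(site, "A:ALA:1")
  expect_error(bindingSite(sys, integer()), class = "afp_precondition")

  # formal default of the site cutoff
  expect_identical(formals(bindingSite)$cutoff, 8.0)
  expect_equal(profilerConfig()@site_cutoff, 8.0)
})

test_that("binding site equals a brute-force scan and grows with cutoff", {
  p <- makeToyPocket(10, seed = 5)
  sys <- p$system; lig <- p$ligand
  at <- atoms(sys); labs <- residueLabels(sys); xyz <- coords(sys)
  for (cutoff in c(4, 6, 8)) {
    brute <- character()
    for (lab in setdiff(unique(labs), unique(labs[lig]))) {
      idx <- which(labs == lab)
      dmin <- min(sqrt(outer(rowSums(xyz[lig, , drop = FALSE]^2),
                             rowSums(xyz[idx, , drop = FALSE]^2), "+") -
                         2 * xyz[lig, , drop = FALSE] %*%
                         t(xyz[idx, , drop = FALSE])))
      if (dmin <= cutoff) brute <- c(brute, lab)
    }
    expect_setequal(bindingSite(sys, lig, cutoff), brute)
  }
  sizes <- vapply(c(2, 4, 6, 8, 10), function(ct)
    length(bindingSite(sys, lig, ct)), numeric(1))
  expect_true(all(diff(sizes) >= 0))
  # the generator places every pocket residue within the 8 A default
  expect_equal(length(bindingSite(sys, lig, 8)),
               p$manifest$n_pocket_residues)
})

test_that("rotatable-bond counting applies the heavy-neighbour, ring and amide rules", {
  expect_equal(countRotatableBonds(chain_system(c("C", "C"))), 0)  # ethane
  expect_equal(countRotatableBonds(chain_system(rep("C", 5))), 2)  # n-pentane

  # cyclohexane: planar hexagon, all bonds in the ring
  ang <- 2 * pi * (0:5) / 6
  hexa <- do.call(rbind, lapply(1:6, function(i)
    atom_row(i, paste0("C", i), "C", 1.54 * cos(ang[i]),
             1.54 * sin(ang[i]), 0)))
  expect_equal(countRotatableBonds(perceiveBonds(molecularSystem(hexa))), 0)

  # N-methylacetamide heavy atoms: the C-N bond is amide, the rest terminal
  nma <- rbind(
    atom_row(1L, "CB", "C", -1.50, 0, 0),
    atom_row(2L, "C", "C", 0, 0, 0),
    atom_row(3L, "O", "O", 0.55, 1.10, 0),       # 1.23 A from C
    atom_row(4L, "N", "N", 0.65, -1.15, 0),
    atom_row(5L, "CG", "C", 2.10, -1.30, 0))
  sys <- perceiveBonds(molecularSystem(nma))
  expect_equal(countRotatableBonds(sys), 0)
})

test_that("fallback charges sum to zero over a neutral molecule", {
  s <- chain_system(c("C", "O"), spacing = 1.4)
  s <- assignFallbackCharges(s)
  expect_equal(sum(atoms(s)$charge), 0, tolerance = 1e-12)
  expect_true(atoms(s)$charge[2] < 0)  # oxygen pulls density
})
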