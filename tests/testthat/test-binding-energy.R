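# SASA, desolvation, entropy/strain penalties, pose filter, dG <-> pIC50

test_that("SASA of an isolated atom is the analytic sphere", {
  ov <- data.frame(element = "C", vdw_radius = 1.6)
  s <- single_atom_system("C")
  expect_equal(atomSASA(s, probe = 1.4, overrides = ov),
               4 * pi * 3.0^2, tolerance = 1e-9)
})

test_that("a caged atom has zero exposure", {
  # central atom surrounded by an octahedral cage of large spheres
  cage <- do.call(rbind, lapply(seq_len(6), function(i) {
    d <- rbind(c(1.8, 0, 0), c(-1.8, 0, 0), c(0, 1.8, 0), c(0, -1.8, 0),
               c(0, 0, 1.8), c(0, 0, -1.8))[i, ]
    atom_row(i + 1L, "S", "S", d[1], d[2], d[3])
  }))
  sys <- molecularSystem(rbind(atom_row(1L, "H", "H", 0, 0, 0), cage))
  expect_equal(atomSASA(sys)[1], 0)
})

test_that("two overlapping spheres agree with a high-density oracle", {
  sys <- molecularSystem(rbind(atom_row(1L, "C1", "C", 0, 0, 0),
                               atom_row(2L, "O1", "O", 1.9, 0, 0)))
  a <- atomSASA(sys, points = 960)
  oracle <- atomSASA(sys, points = 9600)
  expect_equal(a, oracle, tolerance = 0.01)
  # and both are below the isolated-sphere areas
  expect_lt(a[1], 4 * pi * 3.1^2)
})

test_that("desolvation is the per-atom parameter-weighted SASA sum", {
  s <- single_atom_system("O")
  area <- 4 * pi * (1.52 + 1.4)^2
  expect_equal(desolvationEnergy(s), 0.025 * area, tolerance = 1e-9)
  # all parameters zero -> 0
  ov <- data.frame(element = c("C", "O"), solvation_parameter = c(0, 0))
  s2 <- chain_system(c("C", "O"), spacing = 1.4)
  expect_equal(desolvationEnergy(s2, overrides = ov), 0)
  # brute-force per-atom sum on a toy ligand
  p <- makeToyPocket(3, seed = 4)
  lig_sys <- molecularSystem(atoms(p$system)[p$ligand, ])
  par <- elementParams(atoms(lig_sys)$element)$solvation_parameter
  expect_equal(desolvationEnergy(lig_sys),
               sum(par * atomSASA(lig_sys)), tolerance = 1e-9)
})

test_that("desolvation is additive over fragments at infinite separation", {
  a <- single_atom_system("O")
  b <- single_atom_system("N", x = 500)
  both <- molecularSystem(rbind(atom_row(1L, "O", "O", 0, 0, 0),
                                atom_row(2L, "N", "N", 500, 0, 0)))
  expect_equal(desolvationEnergy(both),
               desolvationEnergy(a) + desolvationEnergy(b),
               tolerance = 1e-9)
})

test_that("entropy penalty is rotors x fraction x per-rotor cost", {
  expect_equal(entropyPenalty(0), 0)
  expect_equal(entropyPenalty(5), 2.0)                     # default 0.4
  expect_equal(entropyPenalty(4, 0.4, 0.5), 0.8)
})

test_that("strain energy clamps at zero and warns on bad references", {
  expect_equal(strainEnergy(10, 10), 0)
  expect_equal(strainEnergy(13.2, 10), 3.2)
  expect_warning(out <- strainEnergy(9, 10),
                 class = "afp_inconsistent_reference")
  expect_gte(out, 0)
  for (d in runif(20, -5, 5))
    expect_gte(suppressWarnings(strainEnergy(10 + d, 10)), 0)
})

test_that("pose filter keeps the 10 kcal/mol window", {
  expect_equal(poseFilter(c(0, 5, 12)), c(1, 2))
  expect_equal(poseFilter(rep(3.3, 4)), 1:4)
  expect_identical(formals(poseFilter)$window, 10)
  expect_error(poseFilter(numeric()), class = "afp_precondition")
  # always retains the minimum; monotone in window
  set.seed(42)
  for (i in 1:10) {
    e <- runif(8, 0, 30)
    keep5 <- poseFilter(e, 5)
    keep10 <- poseFilter(e, 10)
    expect_true(which.min(e) %in% keep5)
    expect_true(all(keep5 %in% keep10))
  }
})

test_that("binding free energy sums components and converts to pIC50", {
  m <- nonbondedModel()
  est0 <- bindingFreeEnergy(energyComponents(), m)
  expect_equal(est0@delta_g, 0)
  expect_equal(est0@pic50, 0)

  # pIC50 7 <-> dG = -7 ln(10) R T (independent arithmetic: -9.6090)
  est <- bindingFreeEnergy(energyComponents(e_interaction = -7 * PIC50_SLOPE), m)
  expect_equal(est@delta_g, -9.6090, tolerance = 1e-3)
  expect_equal(est@pic50, 7.0, tolerance = 1e-9)

  # one extra rotor at 0.4 kcal/mol costs 0.4/1.3727 = 0.2914 pIC50 units
  est2 <- bindingFreeEnergy(
    energyComponents(e_interaction = -7 * PIC50_SLOPE,
                     tds_rotors = entropyPenalty(1)), m)
  expect_equal(est@pic50 - est2@pic50, 0.29139, tolerance = 1e-4)

  # linear and monotone: raising any cost never raises pIC50
  base <- energyComponents(e_interaction = -9, e_strain = 1,
                           dg_desolvation = 2, tds_rotors = 0.8,
                           e_induced_fit = 0.5)
  p0 <- bindingFreeEnergy(base, m)@pic50
  for (slot_name in c("e_strain", "dg_desolvation", "tds_rotors",
                      "e_induced_fit")) {
    up <- base
    slot(up, slot_name) <- slot(base, slot_name) + 1
    expect_equal(bindingFreeEnergy(up, m)@pic50, p0 - 1 / PIC50_SLOPE,
                 tolerance = 1e-9)
  }
})

test_that("component CSV serialization round-trips", {
  comps <- list(cpd1 = energyComponents(e_interaction = -10, e_strain = 1),
                cpd2 = energyComponents(e_interaction = -8))
  f <- tempfile(fileext = ".csv")
  df <- writeComponentsCSV(comps, f)
  back <- read.csv(f)
  expect_equal(names(back),
               c("compound_id", "e_interaction", "e_strain",
                 "dg_desolvation", "tds_rotors", "e_induced_fit",
                 "delta_g", "pic50"))
  expect_equal(back$delta_g, c(-9, -8))
  expect_equal(back$pic50, c(9, 8) / PIC50_SLOPE, tolerance = 1e-6)
})
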