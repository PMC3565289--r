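# envelope construction, surrogate scoring, pose combination, GA training
# and the validation metrics

test_that("envelope particle density matches the sphere-area oracle", {
  ens <- poseEnsemble("a", list(single_atom_system("C")), 0)
  for (sp in c(0.8, 1.5)) {
    env <- buildEnvelope(list(ens), spacing = sp)
    area <- 4 * pi * (1.7 + 1.4)^2  # vdW 1.7 + probe offset 1.4
    expect_equal(nrow(env@positions), area / sp^2, tolerance = 0.2)
    # particles sit on the contact sphere
    rr <- sqrt(rowSums(env@positions^2))
    expect_true(all(abs(rr - 3.1) < 1e-6))
  }
})

test_that("envelope is deterministic and grows monotonically", {
  ens1 <- poseEnsemble("a", list(chain_system(c("C", "O"), 1.4)), 0)
  e1 <- buildEnvelope(list(ens1))
  e2 <- buildEnvelope(list(ens1))
  expect_identical(e1@positions, e2@positions)
  # adding a distant second ligand never removes existing coverage
  far <- single_atom_system("C", x = 30)
  ens2 <- poseEnsemble("b", list(far), 0)
  eb <- buildEnvelope(list(ens1, ens2))
  key <- function(m) paste(round(m[, 1], 6), round(m[, 2], 6),
                           round(m[, 3], 6))
  expect_true(all(key(e1@positions) %in% key(eb@positions)))
  expect_error(buildEnvelope(list()), class = "afp_precondition")
})

test_that("pose scoring follows the compatibility table and scenarios", {
  # acceptor atom (O, no H) at the contact optimum from one particle
  acc <- single_atom_system("O", charge = -0.35)
  env <- point_envelope(c(3.0, 0, 0))
  tab <- compatibilityTable()

  m_donor <- surrogateModel(env, "donor", base_energy = 0)
  expect_equal(scorePose(m_donor, acc), tab["donor", "acceptor"],
               tolerance = 1e-12)
  m_void <- surrogateModel(env, "void", base_energy = 0)
  expect_equal(scorePose(m_void, acc), 0)
  # all-void model returns exactly the induced-fit penalty
  m_pen <- surrogateModel(env, "void", induced_fit_scenario = 5L,
                          induced_fit_penalty = 2.0, base_energy = 0)
  expect_equal(scorePose(m_pen, acc), 2.0 * 0.5, tolerance = 1e-12)
  # beyond the interaction range the particle contributes nothing
  far_env <- point_envelope(c(10, 0, 0))
  expect_equal(scorePose(surrogateModel(far_env, "donor", base_energy = 0),
                         acc), 0)
  # brute-force particle x atom loop on a toy pose
  pose <- chain_system(c("C", "O", "N"), spacing = 1.45,
                       charges = c(0, -0.35, -0.2))
  env3 <- point_envelope(c(0, 3.2, 0, 1.45, -3.1, 0, 4, 4, 4))
  mod3 <- surrogateModel(env3, c("hydrophobic", "acceptor", "positive"),
                         base_energy = 0)
  cls <- c("nonpolar", "acceptor", "acceptor")  # C; O no H; N no H
  expected <- 0
  for (p in 1:3) {
    d <- sqrt(colSums((t(coords(pose)) - env3@positions[p, ])^2))
    nn <- which.min(d)
    w <- exp(-(d[nn] - 3)^2 / (2 * 1.5^2)) * (d[nn] <= 6)
    expected <- expected +
      tab[c("hydrophobic", "acceptor", "positive")[p], cls[nn]] * w
  }
  expect_equal(scorePose(mod3, pose), expected, tolerance = 1e-9)
})

test_that("Boltzmann weights are normalized with closed-form ratios", {
  w <- boltzmannWeights(rep(1.5, 4))
  expect_equal(w, rep(0.25, 4))
  rt <- 0.0019872 * 300
  w2 <- boltzmannWeights(c(0, rt * log(2)))
  expect_equal(w2, c(2 / 3, 1 / 3), tolerance = 1e-12)
  set.seed(1)
  for (i in 1:5) {
    w <- boltzmannWeights(runif(6, -5, 5))
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w > 0))
  }
  expect_error(boltzmannWeights(numeric()), class = "afp_precondition")
})

test_that("ensemble prediction is invariant to pose bookkeeping", {
  bench <- makeQsarBenchmark(n_ligands = 8, poses_per_ligand = 3, seed = 21)
  model <- bench$true_model
  ens <- bench$dataset@ensembles[[1]]
  p0 <- modelPredict(model, ens)

  # single pose equals that pose's converted score
  one <- poseEnsemble(ens@ligand_id, ens@poses[1], ens@conf_energies[1])
  expect_equal(modelPredict(model, one),
               -scorePose(model, ens@poses[[1]]) / PIC50_SLOPE,
               tolerance = 1e-9)

  # duplicating a pose leaves the prediction unchanged
  dup <- poseEnsemble(ens@ligand_id, c(ens@poses, ens@poses[2]),
                      c(ens@conf_energies, ens@conf_energies[2]))
  expect_equal(modelPredict(model, dup), p0, tolerance = 1e-12)

  # permuting pose order leaves it unchanged
  perm <- poseEnsemble(ens@ligand_id, ens@poses[c(3, 1, 2)],
                       ens@conf_energies[c(3, 1, 2)])
  expect_equal(modelPredict(model, perm), p0, tolerance = 1e-12)

  # a pose at infinite conformational energy has zero weight
  inf_pose <- poseEnsemble(ens@ligand_id, c(ens@poses, ens@poses[1]),
                           c(ens@conf_energies, 1e6))
  expect_equal(modelPredict(model, inf_pose), p0, tolerance = 1e-9)
})

test_that("family consensus reports mean and population sd", {
  env <- point_envelope(c(3, 0, 0))
  acc <- single_atom_system("O", charge = -0.35)
  ens <- poseEnsemble("a", list(acc), 0)
  m1 <- surrogateModel(env, "donor", base_energy = -6 * PIC50_SLOPE)
  m2 <- surrogateModel(env, "donor", base_energy = -8 * PIC50_SLOPE)
  fam_id <- new("ModelFamily", envelope = env, members = list(m1, m1),
                config = list(), seed = 1L)
  expect_equal(familyPredict(fam_id, ens)$sd, 0)
  fam <- new("ModelFamily", envelope = env, members = list(m1, m2),
             config = list(), seed = 1L)
  fp <- familyPredict(fam, ens)
  p1 <- modelPredict(m1, ens); p2 <- modelPredict(m2, ens)
  expect_equal(fp$mean, (p1 + p2) / 2, tolerance = 1e-12)
  expect_equal(fp$sd, abs(p1 - p2) / 2, tolerance = 1e-12)
  # member permutation invariance
  fam_rev <- new("ModelFamily", envelope = env, members = list(m2, m1),
                 config = list(), seed = 1L)
  expect_equal(familyPredict(fam_rev, ens), fp)
  # default family size follows the consensus protocol
  expect_equal(gaConfig()$family_size, 200L)
  expect_equal(formals(poseEnsemble)$maxPoses, 8)
})

test_that("predictive r2 and the factor-10 band match manual arithmetic", {
  expect_equal(predictiveR2(c(6, 7), c(6, 7), 6.5),
               list(r2_pred = 1, fraction_within_factor10 = 1))
  # inclusive boundary: |residual| exactly 1.0 counts as within
  out <- predictiveR2(c(6, 8), c(7, 7), 5)
  expect_equal(out$fraction_within_factor10, 1)
  # 4-point hand-computed case
  out2 <- predictiveR2(c(6, 7, 8, 5), c(6.5, 7, 7.5, 5.5), 6.4)
  expect_equal(out2$r2_pred, 1 - 0.75 / 2.39, tolerance = 1e-9)
  expect_error(predictiveR2(c(6, 7), c(5, 5), 5),
               class = "afp_undefined_metric")
})

test_that("GA training is reproducible and learns a noiseless signal", {
  bench <- makeQsarBenchmark(n_ligands = 14, poses_per_ligand = 2, seed = 5)
  cfg <- gaConfig(population = 30, generations = 15, family_size = 10)
  fam1 <- gaTrain(bench$dataset, bench$envelope, cfg, seed = 3)
  fam2 <- gaTrain(bench$dataset, bench$envelope, cfg, seed = 3)
  lab <- function(f) vapply(familyMembers(f),
                            function(m) paste(m@labels, collapse = ""),
                            character(1))
  expect_identical(lab(fam1), lab(fam2))
  fam3 <- gaTrain(bench$dataset, bench$envelope, cfg, seed = 4)
  expect_false(identical(lab(fam1), lab(fam3)))

  # even a tiny budget must beat the mean-prediction baseline on train
  tr <- which(bench$dataset@split == "train")
  pred <- vapply(tr, function(i)
    familyPredict(fam1, bench$dataset@ensembles[[i]])$mean, numeric(1))
  y <- bench$dataset@pic50[tr]
  expect_lt(sqrt(mean((pred - y)^2)), sd(y))
  small <- qsarDataset(letters[1:4], bench$dataset@ensembles[1:4],
                       bench$dataset@pic50[1:4], rep("train", 4))
  expect_error(gaTrain(small, bench$envelope, cfg), class = "afp_precondition")
})

test_that("cross-validated q2 matches its own PRESS arithmetic", {
  bench <- makeQsarBenchmark(n_ligands = 20, poses_per_ligand = 2, seed = 6)
  cfg <- gaConfig(population = 20, generations = 8, family_size = 5)
  cv <- crossValidatedR2(bench$dataset, bench$envelope, cfg, n_folds = 3,
                         seed = 2)
  tr <- which(bench$dataset@split == "train")
  y <- bench$dataset@pic50[tr]
  press <- sum((cv$predictions[bench$dataset@ids[tr]] - y)^2)
  expect_equal(cv$press, press, tolerance = 1e-9)
  expect_equal(cv$q2, 1 - cv$press / cv$ss_tot, tolerance = 1e-12)
  expect_lte(cv$q2, 1)
  expect_error(crossValidatedR2(bench$dataset, bench$envelope, cfg,
                                n_folds = 1), class = "afp_precondition")
})

test_that("consensus flags follow the force-field and water criteria", {
  expect_equal(consensusFlag(7, -20, -30, -25)$status, "accept")
  out <- consensusFlag(7, -20, -20, -25)
  expect_equal(out$status, "flag")
  expect_true(any(grepl("prefers water", out$reasons)))
  expect_equal(consensusFlag(7, 5, -30, -25)$reasons,
               "unfavourable force-field score")
  # tie resolves toward binding
  expect_equal(consensusFlag(7, -20, -25, -25)$status, "accept")
  expect_equal(consensusFlag(7, -20, -25, -25)$pic50, 7)
})

test_that("model-family JSON serialization round-trips predictions", {
  bench <- makeQsarBenchmark(n_ligands = 12, poses_per_ligand = 2, seed = 8)
  cfg <- gaConfig(population = 12, generations = 4, family_size = 6)
  fam <- gaTrain(bench$dataset, bench$envelope, cfg, seed = 2)
  f <- tempfile(fileext = ".json")
  writeModelFamily(fam, f)
  back <- readModelFamily(f)
  ens <- bench$dataset@ensembles[[1]]
  expect_equal(familyPredict(back, ens), familyPredict(fam, ens),
               tolerance = 1e-6)
  expect_equal(back@seed, fam@seed)
})
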