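# frame extraction, dynamic profiles, H-bond occupancy, CSV/VMD/plots

make_event_traj <- function(n_frames = 16, k = 10, seed = 13) {
  p <- makeToyPocket(6, seed = seed, anchor = TRUE)
  tt <- makeToyTrajectory(p, n_frames = n_frames, jitter_sd = 0.02,
                          event = list(target = "A:ASN:801", frame = k,
                                       displacement = 30), seed = seed + 1)
  list(pocket = p, traj = tt$trajectory, k = k)
}

test_that("frame extraction keeps the right frames and times", {
  p <- makeToyPocket(3, seed = 1)
  tt <- makeToyTrajectory(p, n_frames = 10, jitter_sd = 0, seed = 1)
  expect_equal(nFrames(extractFrames(tt$trajectory, 1)), 10)
  sub <- extractFrames(tt$trajectory, 2)
  expect_equal(nFrames(sub), 5)
  expect_equal(frameTimes(sub), frameTimes(tt$trajectory)[c(1, 3, 5, 7, 9)])
  expect_identical(sub@coords[[2]], tt$trajectory@coords[[3]])
  expect_error(extractFrames(tt$trajectory, 0), class = "afp_precondition")
})

test_that("identical frames give identical profile rows", {
  p <- makeToyPocket(5, seed = 2)
  tt <- makeToyTrajectory(p, n_frames = 4, jitter_sd = 0, seed = 1)
  prof <- suppressMessages(dynamicProfile(tt$trajectory))
  E <- profileEnergies(prof)
  for (f in 2:4) expect_equal(E[f, ], E[1, ], tolerance = 1e-12)
  # row sums equal the whole-site vdW+elec energy of that frame
  f1 <- perceiveBonds(frameSystem(tt$trajectory, 1))
  lig <- detectLigand(f1)
  direct <- sum(vapply(prof@residue_labels, function(lab)
    residueInteraction(f1, lig, lab), numeric(1)))
  expect_equal(sum(E[1, ]), direct, tolerance = 1e-9)
})

test_that("a scripted contact loss zeroes one residue column only", {
  et <- make_event_traj()
  prof <- suppressMessages(dynamicProfile(et$traj))
  E <- profileEnergies(prof)
  j <- match("A:ASN:801", prof@residue_labels)
  expect_false(is.na(j))
  post <- (et$k + 1):nrow(E)     # event frame k is 0-based
  expect_true(all(abs(E[post, j]) < 0.1))
  expect_true(all(abs(E[seq_len(et$k), j]) > 1))
  other <- setdiff(seq_len(ncol(E)), j)
  expect_true(all(abs(colMeans(E[post, other])) > 1))
})

test_that("site residues are fixed at frame 1 and grow with the cutoff", {
  et <- make_event_traj()
  p5 <- suppressMessages(dynamicProfile(et$traj,
                                        profilerConfig(site_cutoff = 5)))
  p8 <- suppressMessages(dynamicProfile(et$traj,
                                        profilerConfig(site_cutoff = 8)))
  expect_true(all(p5@residue_labels %in% p8@residue_labels))
  shared <- match(p5@residue_labels, p8@residue_labels)
  expect_equal(p8@energies[, shared], p5@energies, tolerance = 1e-12)
  # provenance carries the MD protocol constants
  expect_equal(p8@provenance$temperature_K, 300)
  expect_equal(p8@provenance$relaxation_ps, 24)
})

test_that("hbond occupancy tracks the scripted break", {
  et <- make_event_traj(n_frames = 16, k = 10)
  hb <- hbondOccupancy(et$traj, "A:801:ND2", "A:900:O5")
  expect_equal(hb$occupancy, et$k / 16)
  expect_equal(hb$first_break_frame, et$k)
  expect_equal(hb$first_break_time_ns, frameTimes(et$traj)[et$k + 1])
  # never satisfied: a far-apart pair
  hb0 <- hbondOccupancy(et$traj, "A:801:ND2", "serial:1")
  expect_equal(hb0$occupancy, 0)
  expect_equal(hb0$first_break_frame, 0)
  # always satisfied without an event
  p <- makeToyPocket(6, seed = 13, anchor = TRUE)
  tt <- makeToyTrajectory(p, n_frames = 6, jitter_sd = 0.02, seed = 5)
  hb1 <- hbondOccupancy(tt$trajectory, "A:801:ND2", "A:900:O5")
  expect_equal(hb1$occupancy, 1)
  expect_true(is.na(hb1$first_break_frame))
  # monotone in the distance threshold
  occ <- vapply(c(2.5, 3.0, 3.5, 4.5), function(dmax)
    hbondOccupancy(et$traj, "A:801:ND2", "A:900:O5",
                   profilerConfig(hbond_distance_max = dmax))$occupancy,
    numeric(1))
  expect_true(all(diff(occ) >= 0))
  expect_error(hbondOccupancy(et$traj, "A:999:XX", "A:900:O5"),
               class = "afp_selection_error")
})

test_that("profile CSV round-trips to 1e-6", {
  et <- make_event_traj(n_frames = 5, k = 3)
  prof <- suppressMessages(dynamicProfile(et$traj))
  f <- tempfile(fileext = ".csv")
  writeProfileCSV(prof, f)
  lines <- readLines(f)
  expect_equal(length(lines), 1 + nFrames(et$traj))
  expect_equal(strsplit(lines[1], ",")[[1]],
               c("time_ns", prof@residue_labels))
  back <- readProfileCSV(f)
  expect_equal(back@energies, prof@energies, tolerance = 1e-6)
  expect_equal(back@times, prof@times, tolerance = 1e-9)
})

test_that("VMD state files list frames in order with the chosen style", {
  paths <- sprintf("frame%02d.pdb", 1:5)
  f <- tempfile(fileext = ".vmd")
  generateVMDState(paths, style = "cartoon", path = f)
  txt <- readLines(f)
  refs <- grep("frame[0-9]+\\.pdb", txt, value = TRUE)
  expect_equal(length(refs), 5)
  expect_equal(regmatches(refs, regexpr("frame[0-9]+\\.pdb", refs)), paths)
  expect_true(any(grepl("NewCartoon", txt)))
  expect_error(generateVMDState(character(), path = f),
               class = "afp_precondition")
  err <- tryCatch(generateVMDState(paths, style = "sparkle", path = f),
                  error = function(e) conditionMessage(e))
  expect_match(err, "licorice")  # unknown style lists the available ones
})

test_that("profile plots overlay one labelled curve per simulation", {
  et <- make_event_traj(n_frames = 5, k = 3)
  prof1 <- suppressMessages(dynamicProfile(et$traj))
  prof2 <- prof1
  prof2@ligand_id <- "LIG2"
  prof2@energies <- prof2@energies * 0.5
  f <- tempfile(fileext = ".pdf")
  curves <- plotProfiles(list(prof1, prof2), prof1@residue_labels[1], f)
  expect_true(file.exists(f))
  expect_equal(length(curves), 2)
  expect_equal(curves[[2]][, 2], curves[[1]][, 2] * 0.5)
  expect_error(plotProfiles(list(prof1), "Z:XXX:9", tempfile(fileext = ".pdf")),
               class = "afp_selection_error")
})
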