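# Synthetic generators: toy binding pockets, ground-truth QSAR benchmarks
# and scripted trajectories.  All generators are pure functions of
# (parameters, seed): the RNG state is restored on exit.

# scaffold positions shared by all toy ligands (A); sites sit inside the
# toy pocket, within the particle interaction range of the envelope
.SCAFFOLD_SITES <- matrix(c(
  0.0,  0.0,  0.0,
  1.5,  0.0,  0.0,
 -1.2,  0.9,  0.0,
  0.6, -1.4,  0.0,
  2.2,  1.2,  0.4,
 -0.4, -0.9,  1.3,
  0.9,  1.4, -0.9
), ncol = 3, byrow = TRUE)

.SITE_CLASS_POOL <- c("nonpolar", "donor", "acceptor")

# build one ligand pose system from site subset / classes / jitter
.build_toy_ligand <- function(sites, classes, jitter) {
  rows <- list()
  serial <- 0L
  for (k in seq_along(sites)) {
    p <- .SCAFFOLD_SITES[sites[k], ] + jitter[k, ]
    cls <- classes[k]
    serial <- serial + 1L
    el <- if (cls == "nonpolar") "C" else "O"
    q <- if (cls == "nonpolar") 0.0 else -0.35
    rows[[length(rows) + 1]] <- data.frame(
      serial = serial, name = paste0(el, k), element = el,
      resname = "LIG", chain = "A", resseq = 900L, icode = "",
      x = p[1], y = p[2], z = p[3], charge = q, hetero = TRUE,
      stringsAsFactors = FALSE)
    if (cls == "donor") {
      u <- p
      nrm <- sqrt(sum(u^2))
      u <- if (nrm < 1e-6) c(0, 0, 1) else u / nrm
      hp <- p + 0.97 * u
      serial <- serial + 1L
      rows[[length(rows) + 1]] <- data.frame(
        serial = serial, name = paste0("H", k), element = "H",
        resname = "LIG", chain = "A", resseq = 900L, icode = "",
        x = hp[1], y = hp[2], z = hp[3], charge = 0.30, hetero = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  perceiveBonds(molecularSystem(do.call(rbind, rows)))
}

# generate n toy ligand pose ensembles (geometry only, no labels)
.make_toy_ligands <- function(n_ligands, poses_per_ligand, seed,
                              jitter_sd = 0.25) {
  .with_seed(seed, {
    lapply(seq_len(n_ligands), function(i) {
      n_sites <- sample(5:nrow(.SCAFFOLD_SITES), 1)
      sites <- sort(sample(nrow(.SCAFFOLD_SITES), n_sites))
      classes <- sample(.SITE_CLASS_POOL, n_sites, replace = TRUE)
      poses <- lapply(seq_len(poses_per_ligand), function(p)
        .build_toy_ligand(sites, classes,
                          matrix(stats::rnorm(3 * n_sites, 0, jitter_sd),
                                 ncol = 3)))
      poseEnsemble(sprintf("lig%03d", i), poses,
                   stats::runif(poses_per_ligand, 0, 3))
    })
  })
}

#' Generate a toy binding pocket with a bound polar ligand
#'
#' A ring of simplified four-atom residues (N-H, CA, C, O) around a small
#' polar hetero ligand, clash-free (minimum interatomic distance between
#' groups >= 2.2 A), with charges assigned and bonds perceived.  All
#' pocket residues lie within 8 A of the ligand by construction.
#'
#' @param n_residues number of pocket residues (>= 1, default 8).
#' @param seed integer seed.
#' @param n_waters optional single-O water molecules placed outside the
#'   pocket (default 0).
#' @param radius ring radius in A (default 6.5).
#' @param anchor also place a donor residue (ASN-like N-H) 3.2 A from the
#'   ligand carbonyl oxygen along its outward direction, forming a genuine
#'   hydrogen bond (default FALSE; the H...acceptor contact is then
#'   intentionally shorter than the 2.2 A clash floor that applies between
#'   heavy atoms).
#' @return list with `system` ([MolecularSystem-class]), `ligand` (atom
#'   indices) and `manifest`.
#' @export
makeToyPocket <- function(n_residues = 8, seed = 1, n_waters = 0,
                          radius = 6.5, anchor = FALSE) {
  stopifnot(n_residues >= 1)
  .with_seed(seed, {
    rows <- list()
    serial <- 0L
    add <- function(name, element, resname, chain, resseq, p, q, het) {
      serial <<- serial + 1L
      rows[[length(rows) + 1]] <<- data.frame(
        serial = serial, name = name, element = element, resname = resname,
        chain = chain, resseq = resseq, icode = "", x = p[1], y = p[2],
        z = p[3], charge = q, hetero = het, stringsAsFactors = FALSE)
    }
    # ligand: two carbons, a hydroxyl (donor), an amine-like N-H and a
    # carbonyl-like acceptor oxygen
    add("C1", "C", "LIG", "A", 900L, c(0, 0, 0), 0.05, TRUE)
    add("C2", "C", "LIG", "A", 900L, c(1.52, 0, 0), 0.05, TRUE)
    o3 <- c(-0.72, 1.18, 0)
    add("O3", "O", "LIG", "A", 900L, o3, -0.40, TRUE)
    add("HO3", "H", "LIG", "A", 900L, o3 + 0.97 * o3 / sqrt(sum(o3^2)),
        0.30, TRUE)
    n4 <- c(-0.10, -1.50, 0)
    add("N4", "N", "LIG", "A", 900L, n4, -0.45, TRUE)
    add("HN4", "H", "LIG", "A", 900L, n4 + 1.01 * n4 / sqrt(sum(n4^2)),
        0.32, TRUE)
    add("O5", "O", "LIG", "A", 900L, c(2.25, 1.10, 0.30), -0.40, TRUE)
    lig_atoms <- serial

    if (anchor) {
      o5 <- c(2.25, 1.10, 0.30)
      w <- o5 / sqrt(sum(o5^2))
      npos <- o5 + 3.20 * w
      add("ND2", "N", "ASN", "A", 801L, npos, -0.35, FALSE)
      add("HD2", "H", "ASN", "A", 801L, o5 + (3.20 - 1.01) * w, 0.35, FALSE)
      add("CG", "C", "ASN", "A", 801L, npos + 1.47 * w, 0.10, FALSE)
    }

    resnames <- rep(c("SER", "GLY", "ASP", "TYR", "GLN", "ALA"),
                    length.out = n_residues)
    for (r in seq_len(n_residues)) {
      ang <- 2 * pi * (r - 1) / n_residues + stats::rnorm(1, 0, 0.03)
      rad <- radius + stats::rnorm(1, 0, 0.15)
      u <- c(cos(ang), sin(ang), 0)          # radial unit
      tpar <- c(-sin(ang), cos(ang), 0)      # tangential unit
      base <- rad * u + c(0, 0, stats::rnorm(1, 0, 0.2))
      add("N", "N", resnames[r], "A", r, base, -0.10, FALSE)
      add("H", "H", resnames[r], "A", r, base - 1.01 * u, 0.30, FALSE)
      add("CA", "C", resnames[r], "A", r, base + 1.46 * tpar, 0.00, FALSE)
      add("C", "C", resnames[r], "A", r, base + 1.46 * tpar + 1.52 * u,
          0.20, FALSE)
      add("O", "O", resnames[r], "A", r,
          base + 1.46 * tpar + 1.52 * u + c(0, 0, 1.23), -0.30, FALSE)
    }
    for (w in seq_len(n_waters)) {
      ang <- 2 * pi * (w - 0.5) / max(1, n_waters)
      add("O", "O", "HOH", "W", w,
          c(11 * cos(ang), 11 * sin(ang), 1.5), -0.40, TRUE)
    }
    sys <- perceiveBonds(molecularSystem(do.call(rbind, rows)))
    ligand <- seq_len(lig_atoms)
    manifest <- list(seed = seed, n_atoms = nAtoms(sys),
                     n_residues = n_residues + 1L + n_waters +
                       as.integer(anchor),
                     n_pocket_residues = n_residues + as.integer(anchor),
                     anchor = anchor,
                     n_ligand_atoms = length(ligand), n_waters = n_waters,
                     radius = radius)
    manifest$hash <- .json_hash(c(manifest, list(xyz = round(coords(sys), 6))))
    list(system = sys, ligand = ligand, manifest = manifest)
  })
}

#' Random ground-truth surrogate model on an envelope
#' @param envelope an [Envelope-class].
#' @param seed integer seed.
#' @param ... passed to [surrogateModel()] (penalty, base energy).
#' @return A [SurrogateModel-class] with random property labels and
#'   scenarios.
#' @export
randomSurrogateModel <- function(envelope, seed = 1, ...) {
  .with_seed(seed, surrogateModel(
    envelope, sample.int(7L, nrow(envelope@positions), replace = TRUE),
    induced_fit_scenario = sample(0:5, 1),
    solvation_scenario = sample(0:1, 1), ...))
}

# label ensembles with a ground-truth model + Gaussian noise, split 70/30
.label_dataset <- function(ensembles, true_model, noise_sd, seed, nb) {
  y0 <- vapply(ensembles, function(e) modelPredict(true_model, e, nb),
               numeric(1))
  .with_seed(seed, {
    y <- y0 + stats::rnorm(length(y0), 0, noise_sd)
    perm <- sample(length(y0))
    n_train <- ceiling(0.7 * length(y0))
    split <- rep("test", length(y0))
    split[perm[seq_len(n_train)]] <- "train"
    qsarDataset(vapply(ensembles, function(e) e@ligand_id, character(1)),
                ensembles, y, split)
  })
}

#' Simulate a QSAR dataset from a known surrogate model
#'
#' Generates toy ligand pose ensembles (scaffold-site subsets with random
#' interaction classes, per-pose coordinate jitter), labels them with
#' `modelPredict(true_model, .)` plus Gaussian noise in pIC50 space, and
#' assigns a seeded 70/30 train/test split.
#'
#' @param true_model a [SurrogateModel-class] (the ground truth).
#' @param n_ligands number of ligands (>= 8).
#' @param poses_per_ligand poses per ensemble (<= 8, default 3).
#' @param noise_sd Gaussian label noise, pIC50 units (default 0).
#' @param seed integer seed.
#' @param nb a [NonbondedModel-class].
#' @return list with `dataset` ([QsarDataset-class]) and `manifest`.
#' @export
simulateQsarDataset <- function(true_model, n_ligands = 40,
                                poses_per_ligand = 3, noise_sd = 0,
                                seed = 1, nb = nonbondedModel()) {
  stopifnot(n_ligands >= 8, poses_per_ligand >= 1, poses_per_ligand <= 8)
  ens <- .make_toy_ligands(n_ligands, poses_per_ligand, seed)
  ds <- .label_dataset(ens, true_model, noise_sd, seed + 1L, nb)
  manifest <- list(seed = seed, n_ligands = n_ligands,
                   poses_per_ligand = poses_per_ligand, noise_sd = noise_sd,
                   n_train = sum(ds@split == "train"),
                   n_test = sum(ds@split == "test"))
  manifest$hash <- .json_hash(c(manifest, list(pic50 = round(ds@pic50, 9))))
  list(dataset = ds, manifest = manifest)
}

#' Self-contained ground-truth QSAR benchmark
#'
#' Generates toy ligands, builds the envelope from the training ensembles
#' (spacing 1.5 A at the toy-pocket scale), draws a random ground-truth
#' model on it, and labels the ligands with it plus optional noise.  This
#' is the dataset used by the parameter-recovery and Y-scrambling
#' validation suites.
#'
#' @param n_ligands number of ligands (default 40).
#' @param poses_per_ligand poses per ensemble (default 3).
#' @param noise_sd label noise, pIC50 units (default 0).
#' @param seed integer seed.
#' @param spacing envelope particle spacing, A (default 1.5 for the toy
#'   scale).
#' @param nb a [NonbondedModel-class].
#' @return list with `dataset`, `envelope`, `true_model`, `manifest`.
#' @export
makeQsarBenchmark <- function(n_ligands = 40, poses_per_ligand = 3,
                              noise_sd = 0, seed = 1, spacing = 1.5,
                              nb = nonbondedModel()) {
  ens <- .make_toy_ligands(n_ligands, poses_per_ligand, seed)
  # the eventual split must not influence the envelope inputs: use all
  # ensembles (train \subset all; coverage identical by construction)
  env <- buildEnvelope(ens, spacing = spacing)
  true_model <- randomSurrogateModel(env, seed + 101L)
  ds <- .label_dataset(ens, true_model, noise_sd, seed + 1L, nb)
  manifest <- list(seed = seed, n_ligands = n_ligands,
                   poses_per_ligand = poses_per_ligand, noise_sd = noise_sd,
                   spacing = spacing, n_particles = nrow(env@positions),
                   true_if_scenario = true_model@induced_fit_scenario,
                   true_solv_scenario = true_model@solvation_scenario)
  manifest$hash <- .json_hash(c(manifest, list(pic50 = round(ds@pic50, 9))))
  list(dataset = ds, envelope = env, true_model = true_model,
       manifest = manifest)
}

#' Scripted toy trajectory
#'
#' Per-frame Gaussian coordinate jitter around a base complex; from a
#' scripted event frame onward, the named residue (or the ligand) is
#' rigidly displaced, emulating a contact-loss / hydrogen-bond-break
#' event.
#'
#' @param complex output of [makeToyPocket()] (or a list with `system`
#'   and `ligand`).
#' @param n_frames number of frames (>= 2).
#' @param jitter_sd per-coordinate Gaussian jitter, A (default 0.05).
#' @param event NULL or list(target = "ligand" or a residue label,
#'   frame = k (0-based), displacement = d in A); from frame k onward the
#'   target is displaced by d along +z.
#' @param seed integer seed.
#' @param interval_ns snapshot interval (default 0.01 ns).
#' @return list with `trajectory` ([Trajectory-class]) and `manifest`.
#' @export
makeToyTrajectory <- function(complex, n_frames, jitter_sd = 0.05,
                              event = NULL, seed = 1, interval_ns = 0.01) {
  stopifnot(n_frames >= 2)
  sys <- complex$system
  base <- coords(sys)
  target_idx <- NULL
  if (!is.null(event)) {
    if (event$frame >= n_frames || event$frame < 0)
      .afp_stop("event frame must be within 0..n_frames-1",
                "afp_precondition")
    target_idx <- if (identical(event$target, "ligand")) complex$ligand
                  else residueAtomIndices(sys, event$target)
    if (length(target_idx) == 0)
      .afp_stop(paste("event target not found:", event$target),
                "afp_selection_error")
  }
  coords_list <- .with_seed(seed, lapply(seq_len(n_frames), function(f) {
    m <- base + matrix(stats::rnorm(length(base), 0, jitter_sd),
                       ncol = 3)
    if (!is.null(target_idx) && (f - 1) >= event$frame)
      m[target_idx, 3] <- m[target_idx, 3] + event$displacement
    m
  }))
  traj <- trajectory(sys, coords = coords_list, interval_ns = interval_ns)
  manifest <- list(seed = seed, n_frames = n_frames, jitter_sd = jitter_sd,
                   interval_ns = interval_ns,
                   event = if (is.null(event)) NULL else
                     event[c("target", "frame", "displacement")])
  list(trajectory = traj, manifest = manifest)
}

.TABLE1_MD5 <- "e29ea3f11712299c3f8f37920fe7facf"

#' Load the packaged 52-compound affinity table
#'
#' Transcription of the published training-table of 52 mannose-based FimH
#' inhibitors: compound number, experimental pIC50 (-log10 IC50 [M]),
#' predicted pIC50 and residual.  Structures are not included (not
#' publicly disclosed); typographic minus signs are normalized to ASCII.
#'
#' @param check verify the recorded checksum (default TRUE).
#' @return data.frame with columns compound_no, exp_pic50, pred_pic50,
#'   residual (52 rows).
#' @export
loadTable1 <- function(check = TRUE) {
  path <- system.file("extdata", "table1_affinities.csv",
                      package = "AffinityProfiler", mustWork = TRUE)
  if (check && unname(tools::md5sum(path)) != .TABLE1_MD5)
    .afp_stop("affinity-table fixture is corrupted (checksum mismatch)",
              "afp_fixture_corruption")
  utils::read.csv(path)
}
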